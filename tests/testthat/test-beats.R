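test_that("valley frames are recovered exactly without noise and within one frame with noise", {
  mv <- clean_movie()
  tks <- tracked(mv)
  d <- pillartrack:::pillar_displacement(tks)
  expect_identical(find_valleys(d$contraction), mv$valley_frames)
  # noisy movie: sigma at 5% of the gray range
  mvn <- fixture("noisy_movie", function() {
    render_movie(synthetic_movie_spec(peak_amplitude_px = 4,
                                      noise_sigma = 0.05, texture_seed = 13L))
  })
  dn <- pillartrack:::pillar_displacement(tracked(mvn))
  vn <- find_valleys(dn$contraction)
  expect_equal(length(vn), length(mvn$valley_frames))
  expect_true(all(abs(vn - mvn$valley_frames) <= 1))
})

test_that("aperiodic or too-short traces are rejected as insufficient beats", {
  expect_error(find_valleys(seq(0, 10, length.out = 100)),
               class = "pt_insufficient_beats")
  w <- as.numeric(make_waveform(45, 30, 4))     # 1.5 beats
  expect_error(find_valleys(w), class = "pt_insufficient_beats")
})

test_that("complete-beat count ignores a trailing partial beat", {
  w3 <- as.numeric(make_waveform(95, 30, 4))
  w3p <- as.numeric(make_waveform(110, 30, 4))  # 3 beats + 19 spare frames
  expect_identical(find_valleys(w3), find_valleys(w3p))
  seg <- beat_segmentation(find_valleys(w3p), 110)
  expect_equal(seg$n_complete_beats, 3L)
  expect_equal(seg$beats$start, c(1L, 31L, 61L))
  expect_equal(seg$beats$end, c(31L, 61L, 91L))
})

test_that("movies starting mid-beat are rebased to the first true valley", {
  mv <- fixture("phase_movie", function() {
    render_movie(synthetic_movie_spec(peak_amplitude_px = 4,
                                      noise_sigma = 0.02, start_phase = 0.5,
                                      n_frames = 110, texture_seed = 17L))
  })
  tks <- tracked(mv)
  d <- pillartrack:::pillar_displacement(tks)
  v <- find_valleys(d$contraction)
  expect_gt(v[1], 1)
  expect_lte(abs(v[1] - mv$valley_frames[1]), 1)
  adj <- adjust_start(mv$stack, tks, v, mv$masks)
  expect_true(adj$retracked)
  expect_equal(length(adj$stack), 110 - v[1] + 1)
  expect_equal(adj$valleys[1], 1L)
  # the rebased movie now measures the true amplitude from a relaxed state
  expect_lt(abs(max(adj$displacement$mean_abs) - 4) / 4, 0.1)
  # a movie already opening at a valley passes through untouched
  mv0 <- clean_movie()
  tks0 <- tracked(mv0)
  v0 <- find_valleys(pillartrack:::pillar_displacement(tks0)$contraction)
  adj0 <- adjust_start(mv0$stack, tks0, v0, mv0$masks)
  expect_false(adj0$retracked)
  expect_identical(adj0$valleys, v0)
})

test_that("drift is flagged above tolerance with a strict inequality", {
  expect_false(detect_drift(c(0, 0.1, 0.2), c(1L, 2L, 3L))$drift_detected)
  expect_false(detect_drift(c(0, 0.5), c(1L, 2L))$drift_detected)   # boundary
  expect_true(detect_drift(c(0, 0.51), c(1L, 2L))$drift_detected)
  mv <- drift_movie()
  d <- pillartrack:::pillar_displacement(tracked(mv))
  v <- find_valleys(d$contraction)
  dr <- detect_drift(d$mean_abs, v)
  expect_true(dr$drift_detected)
  expect_gt(max(dr$valley_offsets), 5)   # 0.05 px/frame over 120 frames
})

test_that("per-beat splitting removes drift bias from peak amplitudes", {
  mv <- drift_movie()
  tks <- tracked(mv)
  d <- pillartrack:::pillar_displacement(tks)
  v <- find_valleys(d$contraction)
  expect_gte(length(v) - 1L, 3L)
  beats <- split_beats(tks, v)
  true_amp <- 4
  split_amps <- vapply(beats, function(b) max(b$mean_abs), numeric(1))
  expect_true(all(abs(split_amps - true_amp) / true_amp < 0.10))
  unsplit_amps <- vapply(seq_len(length(v) - 1L), function(b)
    max(d$mean_abs[v[b]:v[b + 1L]]) - d$mean_abs[v[b]], numeric(1))
  expect_gt(max(abs(unsplit_amps - true_amp) / true_amp), 0.10)
  # per-beat displacement is exactly 0 at each beat start
  expect_true(all(vapply(beats, function(b) b$mean_abs[1], numeric(1)) == 0))
  # without drift the split reproduces the global trace beat by beat
  mv0 <- clean_movie()
  tks0 <- tracked(mv0)
  d0 <- pillartrack:::pillar_displacement(tks0)
  v0 <- find_valleys(d0$contraction)
  b0 <- split_beats(tks0, v0)
  for (b in seq_along(b0)) {
    rng <- v0[b]:v0[b + 1L]
    expect_lt(max(abs(b0[[b]]$mean_abs - d0$mean_abs[rng])), 0.1)
  }
})

test_that("splitting is refused below three complete beats", {
  mv <- clean_movie()
  tks <- tracked(mv)
  v <- find_valleys(pillartrack:::pillar_displacement(tks)$contraction)
  expect_error(split_beats(tks, v[1:3]), class = "pt_insufficient_beats")
})

test_that("irregular beats are flagged by amplitude or period deviation", {
  expect_false(any(detect_irregular_beats(c(30, 30, 30, 31), c(4, 4.1, 4, 3.9),
                                          warn = FALSE)))
  # one beat at half amplitude
  mv_a <- fixture("irregular_amp_movie", function() {
    render_movie(synthetic_movie_spec(peak_amplitude_px = 4,
                                      noise_sigma = 0.02,
                                      amp_mult = c(1, 0.5, 1, 1),
                                      n_frames = 121, texture_seed = 23L))
  })
  d <- pillartrack:::pillar_displacement(tracked(mv_a))
  v <- find_valleys(d$contraction)
  amps <- vapply(seq_len(length(v) - 1L), function(b)
    max(d$mean_abs[v[b]:v[b + 1L]]) - d$mean_abs[v[b]], numeric(1))
  expect_warning(
    flags <- detect_irregular_beats(diff(v), amps),
    class = "pt_irregular_beats")
  expect_identical(which(flags), 2L)
  # one beat at 1.5x period
  mv_p <- fixture("irregular_period_movie", function() {
    render_movie(synthetic_movie_spec(peak_amplitude_px = 4,
                                      noise_sigma = 0.02,
                                      period_mult = c(1, 1, 1.5, 1),
                                      n_frames = 140, texture_seed = 29L))
  })
  dp <- pillartrack:::pillar_displacement(tracked(mv_p))
  vp <- find_valleys(dp$contraction)
  ampsp <- vapply(seq_len(length(vp) - 1L), function(b)
    max(dp$mean_abs[vp[b]:vp[b + 1L]]) - dp$mean_abs[vp[b]], numeric(1))
  flagsp <- detect_irregular_beats(diff(vp), ampsp, warn = FALSE)
  expect_identical(which(flagsp), 3L)
})
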