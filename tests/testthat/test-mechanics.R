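test_that("moments of inertia match the closed-form beam formulas", {
  rect <- mechanics_params(E = 1, a = 1, L = 1, w = 2, t = 2,
                           cross_section = "rectangular")
  expect_equal(moment_of_inertia(rect), 16 / 12)
  circ <- mechanics_params(E = 1, a = 1, L = 1, D = 2,
                           cross_section = "circular")
  expect_equal(moment_of_inertia(circ), pi / 4)
  # cubic thickness scaling
  rect2 <- mechanics_params(E = 1, a = 1, L = 1, w = 2, t = 4,
                            cross_section = "rectangular")
  expect_equal(moment_of_inertia(rect2), 8 * moment_of_inertia(rect))
  expect_error(mechanics_params(E = 1, a = 1, L = 1,
                                cross_section = "rectangular"), "requires")
})

test_that("cantilever stiffness follows k = 6EI / (a^2 (3L - a))", {
  # hand-evaluated: E = I = 1, L = 2, a = 1 -> 6 / (1 * 5) = 1.2
  p <- mechanics_params(E = 1, a = 1, L = 2, w = 12^(1/3), t = 12^(1/3) / 1,
                        cross_section = "rectangular")
  p$w <- 12; p$t <- 1   # I = 12 * 1 / 12 = 1
  expect_equal(pillar_stiffness(p), 1.2)
  # end-loaded limit a = L reduces to 3EI/L^3 exactly
  for (L in c(1, 2.5, 10)) {
    q <- mechanics_params(E = 2, a = L, L = L, w = 3, t = 2,
                          cross_section = "rectangular")
    I <- moment_of_inertia(q)
    expect_equal(pillar_stiffness(q), 3 * 2 * I / L^3, tolerance = 1e-15)
  }
  # k decreases monotonically in the loading height a
  ks <- vapply(seq(0.2, 2, by = 0.2), function(a) {
    q <- mechanics_params(E = 1, a = a, L = 2, w = 12, t = 1)
    pillar_stiffness(q)
  }, numeric(1))
  expect_true(all(diff(ks) < 0))
  expect_error(mechanics_params(E = 1, a = 3, L = 2, w = 1, t = 1), "exceed")
})

test_that("Hooke's law converts deflection to force exactly", {
  expect_equal(force_trace(0, 2.677), 0)
  expect_equal(force_trace(1, 2.677), 2.677)
  expect_equal(force_trace(c(0, 1.5, 3), 2), c(0, 3, 6))
  expect_error(force_trace(1, -1), "positive")
  # unit conversion commutes with the force computation
  d_px <- c(0, 2, 4); ls <- 0.75; k <- 2.677
  expect_equal(force_trace(d_px * ls, k), force_trace(d_px, k) * ls)
})

test_that("the two pillars report symmetric forces on a mirrored fixture", {
  mv <- default_movie()
  tks <- tracked(mv)
  d <- pillartrack:::pillar_displacement(tks)
  fl <- force_trace(max(d$abs_left), 2.677)
  fr <- force_trace(max(d$abs_right), 2.677)
  expect_lt(abs(fl - fr) / fr, 0.1)
})

test_that("tissue width is measured on the valley frame in calibrated units", {
  mv <- default_movie()
  w1 <- measure_tissue_width(get_frame_1(mv), mv$masks, length_scale = 1)
  expect_lt(abs(w1 - 41) / 41, 0.1)   # rendered band is 41 px tall
  w2 <- measure_tissue_width(get_frame_1(mv), mv$masks, length_scale = 2)
  expect_equal(w2, 2 * w1)
  no_band <- fixture("no_band_movie", function() {
    render_movie(synthetic_movie_spec(noise_sigma = 0, tissue_band = FALSE,
                                      n_frames = 2))
  })
  expect_error(measure_tissue_width(get_frame_1(no_band), no_band$masks, 1))
})

test_that("stress is force over tissue cross-section", {
  expect_equal(stress_trace(10, 100, 10), 0.01)
  expect_equal(stress_trace(10, 100, 20), 0.005)
  expect_equal(stress_trace(0, 100, 10), 0)
  expect_error(stress_trace(10, 0, 10), "positive")
})

test_that("temporal metrics match the triangular-pulse closed form", {
  # symmetric triangle, 1 s base at 20 fps, peak 3
  tri <- 3 * pmin(0:20, 20:0) / 10
  tm <- temporal_metrics(tri, fps = 20)
  expect_equal(tm$amplitude, 3)
  expect_equal(tm$fwhm, 0.5)
  expect_equal(tm$fw80m, 0.2)
  expect_equal(tm$contraction_velocity, 6)   # slope 0.3/frame * 20 fps
  expect_equal(tm$relaxation_velocity, 6)
  # FW80M < FWHM for any unimodal beat
  w <- as.numeric(make_waveform(31, 30, 2))
  tmw <- temporal_metrics(w[1:31], fps = 30)
  expect_lt(tmw$fw80m, tmw$fwhm)
  # flat beat: skipped with a warning
  expect_warning(flat <- temporal_metrics(rep(1, 10), fps = 30),
                 class = "pt_flat_beat")
  expect_null(flat)
})

test_that("a 30-frame beat at 30 fps yields a 1 Hz beating rate", {
  mv <- default_movie()
  cfg <- run_config("type1", fps = 30, length_scale = 1, stiffness = 2.677,
                    tissue_depth = 10)
  res <- fixture("default_result", function() run_single(mv$stack, cfg))
  expect_equal(res$beating_rate_hz, 1, tolerance = 0.02)
  expect_equal(res$beat_table$period_s, rep(1, 3), tolerance = 0.05)
})
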