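test_that("corner auto-tuning keeps defaults on rich texture and lowers them on poor texture", {
  # a large, richly textured cap offers plenty of corners at the default
  # quality level, so the tuner leaves the parameters untouched
  set.seed(3)
  rich <- matrix(0.35, 140, 140)
  rich[30:110, 30:110] <- runif(81 * 81, 0.5, 0.9)
  reg_rich <- matrix(FALSE, 140, 140)
  reg_rich[30:110, 30:110] <- TRUE
  p0 <- tracking_params()
  tuned <- auto_tune_params(rich, pillar_mask(reg_rich, "left"), p0)
  expect_equal(tuned$quality, p0$quality)
  # weak texture: a flat cap with only four isolated speckles can never
  # reach the target marker count, so the quality level is tuned down
  weak <- matrix(0.3, 120, 160)
  weak[30:60, 60:100] <- 0.6
  weak[cbind(c(38, 45, 52, 40), c(70, 85, 72, 92))] <- 0.9
  reg <- matrix(FALSE, 120, 160)
  reg[35:55, 65:95] <- TRUE   # interior region, clear of the cap edges
  wmask <- pillar_mask(reg, "left")
  tuned_w <- auto_tune_params(weak, wmask, p0)
  expect_lt(tuned_w$quality, p0$quality)
  # a perfectly flat region has no gradients, hence no corners at all
  flat <- matrix(0.5, 120, 160)
  fmask <- pillar_mask(reg, "left")
  expect_error(auto_tune_params(flat, fmask, p0),
               class = "pt_tracking_failure")
})

test_that("detected markers are deterministic and confined to the mask", {
  mv <- default_movie()
  f <- get_frame_1(mv)
  p <- auto_tune_params(f, mv$masks$left)
  mk1 <- detect_features(f, mv$masks$left, p)
  mk2 <- detect_features(f, mv$masks$left, p)
  expect_identical(mk1, mk2)
  expect_gte(nrow(mk1), 3)
  expect_true(all(mv$masks$left[mk1]))
  # textured square on a flat background: every corner falls in the square
  f2 <- matrix(0.4, 100, 140)
  set.seed(11)
  f2[30:60, 50:90] <- runif(31 * 41, 0.2, 0.9)
  full <- pillar_mask(matrix(TRUE, 100, 140), "left")
  mk <- detect_features(f2, full, tracking_params())
  # corner responses spread by the smoothing and block windows: allow 3 px
  expect_true(all(mk[, 1] >= 27 & mk[, 1] <= 63))
  expect_true(all(mk[, 2] >= 47 & mk[, 2] <= 93))
})

test_that("the tracker recovers rigid motion to sub-pixel accuracy", {
  set.seed(21)
  f0 <- matrix(runif(120 * 160), 120, 160)
  # static scene
  st0 <- frame_stack(array(rep(f0, 3), c(120, 160, 3)))
  pts <- as.matrix(expand.grid(row = seq(30, 90, 15), col = seq(30, 130, 20)))
  tr0 <- track_markers(st0, pts)
  expect_lt(max(mean_displacement(tr0)$mean_abs), 0.1)
  # rigid +3 column shift
  f1 <- cbind(f0[, 158:160], f0[, 1:157])
  st1 <- frame_stack(array(c(f0, f1), c(120, 160, 2)))
  d <- mean_displacement(track_markers(st1, pts))
  expect_equal(d$mean_dcol[2], 3, tolerance = 0.1 / 3)
  expect_lt(abs(d$mean_drow[2]), 0.1)
})

test_that("markers that leave the image are flagged and excess loss fails", {
  set.seed(22)
  nfr <- 8
  f0 <- matrix(runif(60 * 60), 60, 60)
  frames <- array(0, c(60, 60, nfr))
  for (t in seq_len(nfr)) {   # content rolls right 5 px per frame
    sh <- 5 * (t - 1)
    frames[, , t] <- f0[, ((seq_len(60) - 1 - sh) %% 60) + 1]
  }
  pts <- cbind(row = c(25, 30, 35), col = c(40, 42, 40))
  expect_error(track_markers(frame_stack(frames), pts),
               class = "pt_tracking_failure")
})

test_that("beating-movie tracking error stays below a tenth of the true peak", {
  mv <- default_movie()
  tks <- tracked(mv)
  true_peak <- max(abs(mv$ground_truth$dcol1))
  expect_lt(abs(peak_mean_abs(tks) - true_peak) / true_peak, 0.10)
})

test_that("tracking is equivariant to global translation and near-reversible in time", {
  mv <- default_movie()
  fr <- mv$stack$frames
  nr <- dim(fr)[1]; nc <- dim(fr)[2]; nf <- dim(fr)[3]
  # translate the whole movie by (5, 8)
  sh <- array(0.35, dim(fr))
  sh[6:nr, 9:nc, ] <- fr[1:(nr - 5), 1:(nc - 8), ]
  mk <- detect_features(fr[, , 1], mv$masks$left,
                        auto_tune_params(fr[, , 1], mv$masks$left))
  tr <- track_markers(frame_stack(fr), mk)
  tr_sh <- track_markers(frame_stack(sh), cbind(mk[, 1] + 5, mk[, 2] + 8))
  ok <- tr$valid & tr_sh$valid
  expect_gt(mean(ok), 0.9)
  expect_lt(max(abs(tr_sh$pos[ok, , 1] - tr$pos[ok, , 1] - 5)), 0.25)
  expect_lt(max(abs(tr_sh$pos[ok, , 2] - tr$pos[ok, , 2] - 8)), 0.25)
  # time reversal on a whole number of beats (frames 1..91 end at a
  # valley): the reversed movie yields the same peak deflection
  nb <- 91
  fwd <- mean_displacement(track_markers(frame_stack(fr[, , 1:nb]), mk))
  rev_stack <- frame_stack(fr[, , nb:1])
  mk_r <- detect_features(fr[, , nb], mv$masks$left,
                          auto_tune_params(fr[, , nb], mv$masks$left))
  bwd <- mean_displacement(track_markers(rev_stack, mk_r))
  fwd_err <- abs(max(fwd$mean_abs) - max(abs(mv$ground_truth$dcol1)))
  expect_lt(abs(max(bwd$mean_abs) - max(fwd$mean_abs)),
            2 * pmax(fwd_err, 0.05) + 0.1)
})

test_that("mean displacement separates signed and absolute components", {
  # hand-built trajectories: two markers moving (0, +1) and (0, -1)
  pos <- array(0, c(2, 2, 2))
  pos[, , 1] <- matrix(c(10, 20, 10, 20), 2)         # rows constant
  pos[, , 2] <- matrix(c(10, 10, 11, 9), 2)          # cols diverge
  traj <- structure(list(pos = pos, valid = c(TRUE, TRUE), n_frames = 2L),
                    class = "trajectory")
  d <- mean_displacement(traj)
  expect_equal(d$mean_dcol, c(0, 0))
  expect_equal(d$mean_abs, c(0, 1))
  # self-reference gives zeros; a single (0, 2) move gives |d| = 2
  traj1 <- structure(list(pos = array(c(5, 5, 3, 5), c(1, 2, 2)),
                          valid = TRUE, n_frames = 2L), class = "trajectory")
  expect_equal(mean_displacement(traj1, reference_frame = 2)$mean_abs[2], 0)
  expect_equal(mean_displacement(traj1)$mean_abs[2], 2)
})
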