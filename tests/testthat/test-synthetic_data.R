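test_that("phase profiles follow the pattern equations", {
  src <- pattern_spec("source_sink", x0 = 5, y0 = 5)
  expect_equal(phase_profile(src, 8, 5, 0), 3)         # distance 3
  expect_equal(phase_profile(src, 5 + 3 / sqrt(2), 5 + 3 / sqrt(2), 0), 3)

  spl <- pattern_spec("spiral", x0 = 5, y0 = 5)
  r <- 2.5
  expect_equal(phase_profile(spl, 5 + r, 5, 0), r)     # atan2 = 0 on +x axis
  expect_equal(phase_profile(spl, 5, 5 + r, 0),
               r + (pi / 2) / spl$k)                   # atan2 = pi/2 on +y

  sad <- pattern_spec("saddle", x0 = 5, y0 = 5)
  expect_equal(phase_profile(sad, 6, 5, 0), 1)
  expect_equal(phase_profile(sad, 5, 6, 0), -1)

  # drift moves the centre linearly: x_t = x0 + vx * t
  drifting <- pattern_spec("source_sink", x0 = 2, y0 = 3, vx = 0.1, vy = 0)
  expect_equal(phase_profile(drifting, 2 + 1, 3, 10), 0)  # centre at t = 10

  # sign flips the profile
  sink <- pattern_spec("source_sink", x0 = 5, y0 = 5, sign = -1)
  expect_equal(phase_profile(sink, 8, 5, 0), -3)
})

test_that("amplitude envelope is radial with maximum A0 at the centre", {
  for (env in c("super_gaussian", "gaussian")) {
    sp <- pattern_spec("source_sink", x0 = 4, y0 = 7, A0 = 1.8, c_width = 3,
                       envelope = env)
    expect_equal(amplitude_profile(sp, 4, 7, 0), 1.8)  # exp(0) = 1
    a1 <- amplitude_profile(sp, 4 + 2, 7, 0)
    a2 <- amplitude_profile(sp, 4, 7 - 2, 0)
    expect_equal(a1, a2)                               # radial symmetry
    expect_lt(amplitude_profile(sp, 4 + 30, 7, 0), 1e-12)
  }
  sp_g <- pattern_spec("source_sink", c_width = 3, envelope = "gaussian")
  expect_equal(amplitude_profile(sp_g, sp_g$x0 + 2, sp_g$y0, 0),
               exp(-4 / 18))
  sp_s <- pattern_spec("source_sink", c_width = 3)
  expect_equal(amplitude_profile(sp_s, sp_s$x0 + 2, sp_s$y0, 0),
               exp(-16 / 18))
})

test_that("simulate_patterns: determinism, drift truth, noise scaling", {
  sp <- pattern_spec("source_sink", x0 = 5, y0 = 6, vx = 0.1, vy = 0)
  s1 <- simulate_patterns(list(sp), n_steps = 11, noise_sigma_rel = 0.3,
                          seed = 4)
  s2 <- simulate_patterns(list(sp), n_steps = 11, noise_sigma_rel = 0.3,
                          seed = 4)
  expect_identical(s1$z, s2$z)                          # same seed, same data

  # ground-truth centre displaced exactly vx * t
  tr <- s1$truth
  expect_equal(tr$x[tr$t == 11], 5 + 0.1 * 10)
  expect_equal(tr$y[tr$t == 11], 6)

  s0 <- simulate_patterns(list(sp), n_steps = 5, noise_sigma_rel = 0)
  expect_equal(Mod(s0$z), s0$amplitude)
  expect_equal(Arg(s0$z), s0$phase)
  # zero-noise signal is exactly the planted sum
  g <- grid_xy(12, 12)
  expect_equal(s0$z[, , 1],
               amplitude_profile(sp, g$x, g$y, 0) *
                 exp(1i * sp$k * phase_profile(sp, g$x, g$y, 0)),
               tolerance = 1e-12)

  # mean-mode noise SD: residual sd close to rel * mean amplitude
  sn <- simulate_patterns(list(sp), n_steps = 50, noise_sigma_rel = 0.5,
                          seed = 8)
  resid <- Re(sn$z) - Re(simulate_patterns(list(sp), n_steps = 50,
                                           noise_sigma_rel = 0)$z)
  target <- 0.5 * mean(simulate_patterns(list(sp), n_steps = 50,
                                         noise_sigma_rel = 0)$amplitude)
  expect_equal(stats::sd(resid), target, tolerance = 0.05)
})

test_that("random benchmark specs respect the rejection rules", {
  for (seed in 1:25) {
    specs <- random_fig_spec(seed = seed)
    expect_length(specs, 2L)
    xs <- vapply(specs, `[[`, 0, "x0"); ys <- vapply(specs, `[[`, 0, "y0")
    expect_true(all(xs >= 2 & xs <= 9 & ys >= 2 & ys <= 9))  # >= 2 from edges
    expect_gte(sqrt(diff(xs)^2 + diff(ys)^2), 2)             # >= 2 apart
    for (sp in specs) {
      expect_equal(sp$w, 2 * pi * 0.01)
      expect_equal(sp$k, 2 * pi / 5)
      expect_true(sp$A0 >= 1 && sp$A0 <= 2)
      expect_true(sp$c_width >= 3 && sp$c_width <= 5)
      expect_true(abs(sp$vx) <= 0.1 && abs(sp$vy) <= 0.1)
    }
  }
  expect_identical(random_fig_spec(seed = 3), random_fig_spec(seed = 3))

  # drift components sampled uniformly on [-0.1, 0.1]
  vxs <- vapply(1:400, function(s) random_fig_spec(seed = s)[[1]]$vx, 0)
  ks <- stats::ks.test(vxs, "punif", -0.1, 0.1)
  expect_gt(ks$p.value, 0.01)
})

test_that("surrogates match per-site moments and are seed-reproducible", {
  set.seed(10)
  arr <- array(rnorm(6 * 6 * 400, mean = rep(1:36, 400),
                     sd = rep(seq(0.5, 2, length.out = 36), 400)),
               c(6, 6, 400, 1))
  # note: rnorm recycles over (site, time); just use per-site stats below
  rec <- recording(arr, fs = 100)
  sur <- make_surrogate(rec, seed = 1)
  for (idx in list(c(1, 1), c(3, 5), c(6, 6))) {
    x <- rec$signal[idx[1], idx[2], , 1]
    y <- sur$signal[idx[1], idx[2], , 1]
    se_m <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(y) - mean(x)), 3 * se_m)
    expect_lt(abs(stats::sd(y) / stats::sd(x) - 1), 0.15)
  }
  expect_identical(make_surrogate(rec, seed = 1)$signal, sur$signal)
  expect_false(identical(make_surrogate(rec, seed = 2)$signal, sur$signal))

  const <- recording(array(5, c(3, 3, 10, 1)), fs = 1)
  expect_true(all(make_surrogate(const, seed = 1)$signal == 5))
})

test_that("evaluate_detection metrics on constructed cases", {
  truth <- data.frame(t = rep(1:3, each = 1), pattern = 1,
                      ptype = "source_sink", motion = "outward",
                      x = 5, y = 5)
  hit <- data.frame(x = 5, y = 5, cls = "stable_node", motion = "outward",
                    tau = 1, delta = 1, extent = 3)
  det <- replicate(3, hit, simplify = FALSE)
  ev <- evaluate_detection(truth, det)
  expect_equal(ev$mean_displacement, 0)
  expect_equal(ev$pct_missed_or_misclassified, 0)
  expect_equal(ev$false_per_step, 0)

  ev0 <- evaluate_detection(truth, replicate(3, hit[0, ], simplify = FALSE))
  expect_equal(ev0$pct_missed_or_misclassified, 100)
  expect_equal(ev0$false_per_step, 0)

  far <- hit; far$x <- 11; far$y <- 11
  ev_f <- evaluate_detection(truth, replicate(3, rbind(hit, far),
                                              simplify = FALSE))
  expect_equal(ev_f$false_per_step, 1)
  expect_equal(ev_f$pct_missed_or_misclassified, 0)

  # matched but wrong class counts as misclassified, not missed
  wrong <- hit; wrong$cls <- "saddle"; wrong$motion <- "saddle"
  ev_w <- evaluate_detection(truth, replicate(3, wrong, simplify = FALSE))
  expect_equal(ev_w$pct_missed_or_misclassified, 100)
  expect_equal(ev_w$mean_displacement, 0)
  expect_equal(ev_w$false_per_step, 0)
})

test_that("single-pattern movies are detected and tracked end to end", {
  # drift below the pattern phase speed w/k = 0.05: the lab-frame critical
  # point then stays pinned to the moving centre (drifts at or above the
  # phase speed cancel the slow side's flow and remove the zero crossing)
  sp <- pattern_spec("source_sink", x0 = 5.5, y0 = 5.5, vx = 0.02, vy = 0)
  sim <- simulate_patterns(list(sp), n_steps = 10, noise_sigma_rel = 0)
  vf <- compute_velocity_fields(sim$phase, alpha = 0.5, beta = 10,
                                is_phase = TRUE)
  det <- detect_series(vf)
  # the detected centre tracks the planted drift within 1 grid space
  for (t in c(1, 5, 9)) {
    expect_gte(nrow(det[[t]]), 1L)
    tr <- sim$truth[sim$truth$t == t, ]
    dmin <- min(sqrt((det[[t]]$x - tr$x)^2 + (det[[t]]$y - tr$y)^2))
    expect_lt(dmin, 1)
  }
  pats <- link_patterns(det)
  expect_gte(nrow(pats), 1L)
  expect_equal(pats$ptype[1], "source")
  expect_gte(pats$duration[1], 9L)
})
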