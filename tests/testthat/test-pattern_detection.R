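test_that("find_critical_points solves the bilinear intersection exactly", {
  f <- field_source()
  cp <- find_critical_points(f$u, f$v)
  expect_equal(nrow(cp), 1L)
  expect_equal(c(cp$x, cp$y), c(5.5, 5.5))

  expect_equal(nrow(find_critical_points(matrix(1, 8, 8), matrix(1, 8, 8))),
               0L)

  # planted quadratic: u = (x-3)(x-8), v = y-5 -> zeros at (3,5) and (8,5)
  g <- grid_xy(12, 12)
  cp2 <- find_critical_points((g$x - 3) * (g$x - 8), g$y - 5)
  cp2 <- cp2[order(cp2$x), ]
  expect_equal(nrow(cp2), 2L)
  expect_lt(max(abs(cp2$x - c(3, 8))), 0.05)
  expect_lt(max(abs(cp2$y - 5)), 0.05)

  # duplicates on shared cell edges are merged
  cp3 <- find_critical_points(g$x - 5, g$y - 5)   # node exactly on a vertex
  expect_equal(nrow(cp3), 1L)
})

test_that("jacobian_at is exact for low-order fields", {
  g <- grid_xy(12, 12)
  J <- jacobian_at(2 * g$x, -g$y, c(4.3, 7.2))
  expect_equal(J, matrix(c(2, 0, 0, -1), 2, 2), tolerance = 1e-12)
  J2 <- jacobian_at(-g$y, g$x, c(5.5, 5.5))
  expect_equal(J2, matrix(c(0, 1, -1, 0), 2, 2), tolerance = 1e-12)
  # centred differences exact for quadratics: du/dx of x^2 at x = 2 is 4
  J3 <- jacobian_at(g$x^2, 0 * g$x, c(2, 5))
  expect_equal(J3[1, 1], 4, tolerance = 1e-12)
  expect_error(jacobian_at(g$x, g$y, c(0.2, 5)), "boundary")
})

test_that("classify_critical_point follows the trace/determinant rules", {
  cl <- classify_critical_point(matrix(c(2, 0, 0, 1), 2, 2))
  expect_equal(cl$cls, "stable_node")        # tau = 3 > 0, paper convention
  expect_equal(cl$motion, "outward")
  cl2 <- classify_critical_point(matrix(c(1, 2, -2, 1), 2, 2))
  expect_equal(cl2$cls, "stable_focus")      # tau = 2, delta = 5, tau^2 < 4 delta
  cl3 <- classify_critical_point(matrix(c(1, 0, 0, -1), 2, 2))
  expect_equal(cl3$cls, "saddle")
  # standard dynamical-systems convention inverts the labels
  cl4 <- classify_critical_point(matrix(c(2, 0, 0, 1), 2, 2), "standard")
  expect_equal(cl4$cls, "unstable_node")
  expect_equal(cl4$motion, "outward")        # motion is convention-free
  # boundary tau^2 = 4 delta -> node; delta = 0 -> degenerate
  expect_equal(classify_critical_point(diag(2))$cls, "stable_node")
  expect_equal(classify_critical_point(matrix(0, 2, 2))$cls, "degenerate")
})

test_that("winding number: +1 nodes/foci, -1 saddles, 0 uniform", {
  src <- field_source(); sad <- field_saddle(); rot <- field_rotation()
  for (r in 2:4) {
    ring <- ring_path(c(5.5, 5.5), r, 12, 12)
    expect_equal(winding_number(src$u, src$v, ring), 1L, ignore_attr = TRUE)
    expect_equal(winding_number(sad$u, sad$v, ring), -1L, ignore_attr = TRUE)
    expect_equal(winding_number(rot$u, rot$v, ring), 1L, ignore_attr = TRUE)
    expect_equal(winding_number(matrix(1, 12, 12), matrix(0, 12, 12), ring),
                 0L, ignore_attr = TRUE)
  }
  ring <- ring_path(c(5.5, 5.5), 2, 12, 12)
  zf <- matrix(1, 12, 12); zf[6, 8] <- 0
  expect_error(winding_number(zf, zf, ring), "zero-magnitude")
})

test_that("winding numbers are additive over enclosed critical points", {
  # complex-polynomial fields u + iv = prod (z - z_k) or conj factors: the
  # planted roots are the field's only zeros, with index +1 per analytic
  # factor and -1 per conjugated factor, so ring indices must add exactly
  g <- grid_xy(16, 16)
  z <- g$x + 1i * g$y
  z1 <- 5 + 7.5i; z2 <- 11 + 7.5i
  ring_1 <- ring_path(c(5, 7.5), 2, 16, 16)
  ring_2 <- ring_path(c(11, 7.5), 2, 16, 16)
  ring_both <- ring_path(c(8, 7.5), 6, 16, 16)

  f <- (z - z1) * Conj(z - z2)              # +1 at z1, -1 at z2
  expect_equal(winding_number(Re(f), Im(f), ring_1), 1L, ignore_attr = TRUE)
  expect_equal(winding_number(Re(f), Im(f), ring_2), -1L, ignore_attr = TRUE)
  expect_equal(winding_number(Re(f), Im(f), ring_both), 0L,
               ignore_attr = TRUE)

  f2 <- (z - z1) * (z - z2)                 # two +1 zeros -> enclosing +2
  expect_equal(winding_number(Re(f2), Im(f2), ring_both), 2L,
               ignore_attr = TRUE)
  f3 <- Conj(z - z1) * Conj(z - z2)         # two saddles -> enclosing -2
  expect_equal(winding_number(Re(f3), Im(f3), ring_both), -2L,
               ignore_attr = TRUE)
})

test_that("pattern extent grows to the boundary for isolated patterns", {
  src <- field_source()                       # centre (5.5, 5.5) on 12x12
  ext <- pattern_extent(src$u, src$v, c(5.5, 5.5), "stable_node")
  expect_equal(ext, 4L)                       # floor(edge distance) - 1
  sad <- field_saddle()
  expect_equal(pattern_extent(sad$u, sad$v, c(5.5, 5.5), "saddle"), 4L)
  # a field with the wrong index everywhere has extent 0
  expect_equal(pattern_extent(src$u, src$v, c(5.5, 5.5), "saddle"), 0L)
})

test_that("two nearby patterns limit each other's extent", {
  # two localised sources 6 apart: rings reaching the far pattern lose
  # index consistency (enclosing both sums to +2)
  g <- grid_xy(18, 18)
  w1 <- exp(-((g$x - 5.5)^2 + (g$y - 8.5)^2) / 8)
  w2 <- exp(-((g$x - 11.5)^2 + (g$y - 8.5)^2) / 8)
  u <- w1 * (g$x - 5.5) + w2 * (g$x - 11.5)
  v <- w1 * (g$y - 8.5) + w2 * (g$y - 8.5)
  e1 <- pattern_extent(u, v, c(5.5, 8.5), "stable_node")
  e2 <- pattern_extent(u, v, c(11.5, 8.5), "stable_node")
  expect_lt(e1, 4)
  expect_lt(e2, 4)
  # an isolated copy of the same pattern keeps growing further
  u_iso <- w1 * (g$x - 5.5); v_iso <- w1 * (g$y - 8.5)
  expect_gt(pattern_extent(u_iso + 1e-9, v_iso + 1e-9, c(5.5, 8.5),
                           "stable_node"), e1)
})

test_that("order parameters: limits, cancellation, invariances", {
  expect_equal(order_parameter_phi(matrix(0.7, 10, 10),
                                   matrix(-0.3, 10, 10)), 1)
  half <- matrix(rep(c(1, -1), each = 5), 10, 1)
  expect_equal(order_parameter_phi(matrix(half, 10, 10), matrix(0, 10, 10)),
               0, tolerance = 1e-12)
  expect_equal(order_parameter_phi(matrix(c(1, 0), 1, 2),
                                   matrix(c(0, 1), 1, 2)),
               sqrt(2) / 2, tolerance = 1e-12)
  expect_error(order_parameter_phi(matrix(0, 3, 3), matrix(0, 3, 3)),
               "all-zero")

  expect_equal(order_parameter_R(matrix(1.234, 10, 10)), 1)
  n <- 8
  expect_equal(order_parameter_R(matrix(2 * pi * (0:(n - 1)) / n, 1, n)), 0,
               tolerance = 1e-12)
  expect_equal(order_parameter_R(matrix(c(0, pi / 2), 1, 2)), sqrt(2) / 2)

  # invariance under global rotation / global phase shift
  set.seed(2)
  u <- matrix(rnorm(64), 8, 8); v <- matrix(rnorm(64), 8, 8)
  a <- 0.83
  ur <- cos(a) * u - sin(a) * v; vr <- sin(a) * u + cos(a) * v
  expect_equal(order_parameter_phi(ur, vr), order_parameter_phi(u, v),
               tolerance = 1e-12)
  th <- matrix(runif(64, -pi, pi), 8, 8)
  th_shift <- ((th + a + pi) %% (2 * pi)) - pi
  expect_equal(order_parameter_R(th_shift), order_parameter_R(th),
               tolerance = 1e-12)
  # 1 - R is the circular variance
  expect_equal(1 - order_parameter_R(th),
               1 - Mod(mean(exp(1i * th))), tolerance = 1e-12)
})

test_that("detect_global_intervals applies duration and gap rules", {
  x <- c(rep(0.9, 10), rep(0.1, 10))
  iv <- detect_global_intervals(x, 0.85, tdur = 5, tgap = 1)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$duration, 10L)

  # 3 steps above threshold < tdur = 5 -> discarded
  x2 <- c(rep(0.9, 3), rep(0.1, 10))
  expect_equal(nrow(detect_global_intervals(x2, 0.85, 5, 1)), 0L)

  # gap of 1 step bridged: 4 above, 1 below, 4 above -> one interval of 9
  x3 <- c(rep(0.9, 4), 0.1, rep(0.9, 4))
  iv3 <- detect_global_intervals(x3, 0.85, 5, 1)
  expect_equal(nrow(iv3), 1L)
  expect_equal(iv3$duration, 9L)
  # gap of 2 steps breaks the run with tgap = 1
  x4 <- c(rep(0.9, 4), 0.1, 0.1, rep(0.9, 4))
  expect_equal(nrow(detect_global_intervals(x4, 0.85, 5, 1)), 0L)
})

test_that("analytic normal-flow fields of planted patterns classify exactly", {
  # Oracle independent of the optical-flow solver: the normal flow of a
  # phase movie theta = k*s - w*t is v = w * grad(s) / |grad(s)|^2.
  # Eq-14-style radial patterns give nodes (they sit exactly on the
  # tau^2 = 4*delta boundary, resolved as nodes by the tie rule), spirals
  # give foci, saddle profiles give saddles.
  g <- grid_xy(12, 12)
  k <- 2 * pi / 5; w <- 2 * pi * 0.01
  normal_flow <- function(sp) {
    h <- 1e-5
    sx <- (phase_profile(sp, g$x + h, g$y, 0) -
             phase_profile(sp, g$x - h, g$y, 0)) / (2 * h)
    sy <- (phase_profile(sp, g$x, g$y + h, 0) -
             phase_profile(sp, g$x, g$y - h, 0)) / (2 * h)
    gg <- k^2 * (sx^2 + sy^2)
    list(u = w * k * sx / gg, v = w * k * sy / gg)
  }
  cases <- list(
    list(ptype = "source_sink", sign = 1, kind = "node", motion = "outward"),
    list(ptype = "source_sink", sign = -1, kind = "node", motion = "inward"),
    list(ptype = "spiral", sign = 1, kind = "focus", motion = "outward"),
    list(ptype = "spiral", sign = -1, kind = "focus", motion = "inward"),
    list(ptype = "saddle", sign = 1, kind = "saddle", motion = "saddle"))
  for (cs in cases) {
    sp <- pattern_spec(cs$ptype, x0 = 5.5, y0 = 5.5, sign = cs$sign)
    fl <- normal_flow(sp)
    cp <- find_critical_points(fl$u, fl$v)
    d2c <- sqrt((cp$x - 5.5)^2 + (cp$y - 5.5)^2)
    expect_true(any(d2c < 0.5), info = cs$ptype)
    i <- which.min(d2c)
    cl <- classify_critical_point(jacobian_at(fl$u, fl$v,
                                              c(cp$x[i], cp$y[i])))
    kind <- if (grepl("node", cl$cls)) "node"
            else if (grepl("focus", cl$cls)) "focus" else "saddle"
    expect_equal(kind, cs$kind, info = paste(cs$ptype, cs$sign))
    expect_equal(cl$motion, cs$motion, info = paste(cs$ptype, cs$sign))
  }
})

test_that("optical-flow detection recovers planted patterns and motion", {
  # End-to-end zero-noise single-pattern movies at alpha <= 1.  Radial
  # source/sink patterns sit exactly on the node/focus boundary, so the
  # kind is asserted at the saddle/non-saddle level with the motion sense;
  # spirals and saddles are asserted exactly.
  cases <- list(
    list(ptype = "source_sink", sign = 1, saddle = FALSE, motion = "outward"),
    list(ptype = "source_sink", sign = -1, saddle = FALSE, motion = "inward"),
    list(ptype = "spiral", sign = 1, kind = "focus", saddle = FALSE,
         motion = "outward"),
    list(ptype = "spiral", sign = -1, kind = "focus", saddle = FALSE,
         motion = "inward"),
    list(ptype = "saddle", sign = 1, saddle = TRUE, motion = "saddle"))
  for (alpha in c(0.1, 0.5, 1)) for (cs in cases) {
    sp <- pattern_spec(cs$ptype, x0 = 5.5, y0 = 5.5, sign = cs$sign)
    sim <- simulate_patterns(list(sp), n_steps = 3, noise_sigma_rel = 0)
    vf <- compute_velocity_fields(sim$phase, alpha = alpha, beta = 10,
                                  is_phase = TRUE)
    det <- detect_critical_points_frame(vf$u[, , 2, 1], vf$v[, , 2, 1])
    expect_equal(nrow(det), 1L, info = paste(cs$ptype, cs$sign, alpha))
    expect_lt(sqrt((det$x - 5.5)^2 + (det$y - 5.5)^2), 1)
    expect_equal(det$cls == "saddle", cs$saddle,
                 info = paste(cs$ptype, cs$sign, alpha))
    if (!is.null(cs$kind))
      expect_true(grepl(cs$kind, det$cls),
                  info = paste(cs$ptype, cs$sign, alpha))
    expect_equal(det$motion, cs$motion, info = paste(cs$ptype, cs$sign))
  }
})
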