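# Frozen-adaptation E-I phase plane, effective I/O curve, separatrix, and
# full-system regime.

test_that("with all weights zero the frozen E-I system has one forced fixed point", {
  p <- ei_params(w_ee = 0, w_ei = 0, w_ie = 0, w_ii = 0, I_e = 0.8, I_i = 0.5,
                 b = 0.7)
  a0 <- 0.4
  pp <- ei_fixed_points(p, a_frozen = a0)
  expect_equal(nrow(pp$fixed_points), 1)
  expect_equal(pp$fixed_points$r_e,
               transfer_eval(p$io_e, p$I_e - p$b * a0), tolerance = 1e-7)
  expect_equal(pp$fixed_points$r_i, transfer_eval(p$io_i, p$I_i),
               tolerance = 1e-7)
  expect_match(pp$fixed_points$stability, "^stable")
})

test_that("the default network is bistable with frozen adaptation at low drive", {
  p <- ei_params(I_e = 0)
  pp <- ei_fixed_points(p, a_frozen = 0)
  fp <- pp$fixed_points
  expect_equal(sum(startsWith(fp$stability, "stable")), 2)
  expect_equal(sum(fp$stability == "saddle"), 1)
  # the UP fixed point is an attracting spiral (E-I transient oscillation)
  up <- fp[which.max(fp$r_e), ]
  expect_equal(up$stability, "stable_spiral")
  expect_true(up$spiral)
})

test_that("frozen-a fixed points match a dense nullcline-intersection oracle", {
  set.seed(55)
  for (k in 1:20) {
    p <- ei_params(w_ee = runif(1, 0, 4.5), w_ei = runif(1, 1, 4),
                   w_ie = runif(1, 1, 5), w_ii = runif(1, 0.5, 3),
                   I_e = runif(1, -1, 1), I_i = runif(1, -1.5, 0.5))
    a0 <- runif(1, 0, 1)
    fp <- ei_fixed_points(p, a_frozen = a0)$fixed_points
    ora <- oracle_ei_fixed_points(p, a0)
    expect_equal(nrow(fp), length(ora))
    if (length(ora))
      expect_lt(max(abs(sort(fp$r_e) - ora)), 1e-3)
  }
})

test_that("the effective I/O curve shows a bistable segment bracketed by folds", {
  p <- ei_params()
  eio <- ei_effective_io(p, drive_range = c(-2, 2), n_points = 81,
                         a_frozen = 0)
  expect_equal(eio$shape, "bistable_centered")
  sn <- eio$bifurcations[eio$bifurcations$type == "saddle_node", ]
  expect_equal(nrow(sn), 2)
  # the fold drives bracket the frozen-a bistability interval found by
  # scanning fixed points directly
  inside <- mean(sn$drive)
  q <- p; q$I_e <- inside
  expect_equal(sum(startsWith(
    ei_fixed_points(q, 0)$fixed_points$stability, "stable")), 2)
  outside <- max(sn$drive) + 0.5
  q$I_e <- outside
  expect_equal(sum(startsWith(
    ei_fixed_points(q, 0)$fixed_points$stability, "stable")), 1)
  # weak recurrence: monotonic stable curve
  w0 <- ei_params(w_ee = 0.5, w_ei = 3, w_ie = 4, w_ii = 2)
  expect_equal(ei_effective_io(w0, c(-2, 2), 41, 0)$shape,
               "monotonic_stable")
})

test_that("the separatrix separates the simulated basins of attraction", {
  p <- ei_params(I_e = 0)
  sep <- ei_separatrix(p, a_frozen = 0)
  up <- attr(sep, "up_fp"); dn <- attr(sep, "down_fp")
  # the fixed points themselves classify to their own basins
  expect_equal(separatrix_side(sep, rbind(up)), "UP")
  expect_equal(separatrix_side(sep, rbind(dn)), "DOWN")
  set.seed(66)
  pts <- cbind(runif(200, 0, 1.2), runif(200, 0, 1.2))
  pred <- separatrix_side(sep, pts)
  sim <- ei_forward_basin(p, pts, a_frozen = 0)
  expect_gte(mean(pred == sim), 0.99)
  # a brief rate increase large enough to cross the separatrix ends DOWN
  kicked <- rbind(up + c(1.5, 0))
  expect_equal(ei_forward_basin(p, kicked, 0), "DOWN")
  # requesting a separatrix without a saddle names the structure found
  mono <- ei_params(w_ee = 0.5, w_ei = 3, w_ie = 4, w_ii = 2)
  expect_error(ei_separatrix(mono, a_frozen = 0), "saddle")
})

test_that("the full network classifies excitable_up at the reference point", {
  p <- ei_params()
  rg <- ei_regime(p)
  expect_equal(rg$label, "excitable_up")
  expect_equal(nrow(rg$fixed_points[rg$fixed_points$stable, ]), 1)
  expect_equal(rg$fixed_points$branch[rg$fixed_points$stable], "UP")
  expect_equal(ei_regime(ei_params(w_ee = 0, w_ei = 0, w_ie = 0,
                                   w_ii = 0))$label,
               "monostable_no_alternations")
})

test_that("the DOWN-to-UP transition shows damped oscillations at the E-I time scale", {
  p <- ei_params()
  # start in the DOWN state; the system recovers to UP through a spiral
  tr <- simulate_rate(p, noise = NULL, duration = 3000, seed = 1,
                      init = c(r = 0, a = 1, r_i = 0))
  re <- tr$r
  # find the transition: first time r_e exceeds half the final rate
  r_end <- tail(re, 1)
  t0 <- which(re > r_end / 2)[1]
  seg <- re[t0:min(t0 + round(100 / tr$dt), length(re))] - r_end
  sign_changes <- sum(diff(sign(seg[seg != 0])) != 0)
  expect_gt(sign_changes, 2)   # ringing, not monotone settling
  # ringing period of order 2 pi sqrt(tau_e tau_i) (a few ms), well under tau_a
  pk <- which(diff(sign(diff(seg))) == -2) + 1
  if (length(pk) >= 2) expect_lt(median(diff(pk)) * tr$dt, p$tau_a / 4)
})

test_that("removing inhibition reduces to the excitation-only fixed-point structure", {
  p <- ei_params(w_ei = 0, w_ie = 0)
  a0 <- 0.3
  fp <- ei_fixed_points(p, a_frozen = a0)$fixed_points
  # E equation decouples: roots of r = R_e(w_ee r - b a + I_e)
  g <- function(r) r - transfer_eval(p$io_e,
                                     p$w_ee * r - p$b * a0 + p$I_e)
  for (r in fp$r_e) expect_lt(abs(g(r)), 1e-6)
  # and r_i is pinned at its feedforward value
  expect_true(all(abs(fp$r_i - transfer_eval(p$io_i, p$I_i)) < 1e-7))
})
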