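# Fixed points, regime classification, and I/O curves of the two-variable
# adapting population model.

test_that("without feedback the unique fixed point is R_inf(I), stable", {
  p <- rate_pop_params(w = 0, b = 0, I = 3)
  fp <- steady_states(p)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$r_star, transfer_eval(p$r_inf, 3), tolerance = 1e-7)
  expect_match(fp$stability, "^stable")
})

test_that("parameter validation rejects non-finite and inverted inputs", {
  expect_error(rate_pop_params(w = NaN, b = 1, I = 2), "non-finite")
  expect_error(rate_pop_params(w = 6, b = 1, I = 2, tau_r = 2, tau_a = 1),
               "tau_a")
  expect_error(rate_pop_params(w = -1, b = 1, I = 2), "non-negative")
})

test_that("bistable anchor parameters give two stable outer states and a saddle", {
  fp <- steady_states(rate_pop_params(w = 6.3, b = 1, I = 2.35))
  expect_equal(nrow(fp), 3)
  expect_equal(sum(startsWith(fp$stability, "stable")), 2)
  expect_equal(sum(fp$stability == "saddle"), 1)
  stable <- fp[startsWith(fp$stability, "stable"), ]
  expect_setequal(stable$branch, c("DOWN", "UP"))
})

test_that("fixed-point finder agrees with the dense sign-change oracle", {
  draws <- random_params(50, seed = 101)
  for (p in draws) {
    fp <- steady_states(p)
    ora <- oracle_fixed_points(p)
    expect_equal(nrow(fp), length(ora))
    if (length(ora))
      expect_true(max(abs(sort(fp$r_star) - ora)) < 1e-3)
  }
})

test_that("regime labels reproduce the captioned anchors", {
  expect_equal(classify_regime(rate_pop_params(6.3, 1, 2.35))$label,
               "bistable")
  expect_equal(classify_regime(rate_pop_params(6, 1, 2.4))$label,
               "excitable_down")
  expect_equal(classify_regime(rate_pop_params(6, 1, 2.5))$label,
               "oscillatory")
  # weak recurrence: monotonic I/O, no alternations possible
  expect_equal(classify_regime(rate_pop_params(2, 1, 2.5))$label,
               "monostable_no_alternations")
})

test_that("any bistable classification has exactly 2 stable points and 1 saddle", {
  draws <- random_params(60, seed = 77)
  for (p in draws) {
    rg <- classify_regime(p)
    if (rg$label == "bistable") {
      expect_equal(sum(startsWith(rg$fixed_points$stability, "stable")), 2)
      expect_equal(sum(rg$fixed_points$stability == "saddle"), 1)
    }
  }
})

test_that("no-feedback I/O curve is a single monotonic stable branch", {
  cv <- io_curve(rate_pop_params(w = 0, b = 0, I = 0), c(0, 10),
                 n_points = 60)
  expect_equal(cv$shape, "monotonic_stable")
  expect_equal(nrow(cv$bifurcations), 0)
  expect_true(all(cv$branches$stable))
  expect_true(!is.unsorted(cv$branches$r_ss))
})

test_that("recurrence strength sets the I/O curve shape", {
  # strong recurrence relative to adaptation: bistable-centered
  expect_equal(io_curve(rate_pop_params(w = 6.6, b = 1, I = 2.5),
                        c(1.2, 3.2), n_points = 120)$shape,
               "bistable_centered")
  # stronger adaptation at moderate recurrence: oscillatory-centered
  expect_equal(io_curve(rate_pop_params(w = 6, b = 1.5, I = 2.5),
                        c(1.2, 4.2), n_points = 120)$shape,
               "oscillatory_centered")
})

test_that("raising adaptation gain never turns an oscillatory-centered curve bistable-centered", {
  shapes <- vapply(c(0.8, 1.2, 1.6, 2), function(b)
    io_curve(rate_pop_params(w = 6.1, b = b, I = 2.5),
             c(5 - 6.1 / 2 + b / 2 - 1.2, 5 - 6.1 / 2 + b / 2 + 1.2),
             n_points = 90)$shape, character(1))
  osc_seen <- FALSE
  for (s in shapes) {
    if (s == "oscillatory_centered") osc_seen <- TRUE
    if (osc_seen) expect_false(s == "bistable_centered")
  }
})

test_that("excitable regimes are ordered in drive: stable DOWN below stable UP", {
  for (w in c(6, 6.3)) {
    lab_lo <- classify_regime(rate_pop_params(w, 1, 5 - w / 2 + 0.5 - 0.2))$label
    lab_hi <- classify_regime(rate_pop_params(w, 1, 5 - w / 2 + 0.5 + 0.2))$label
    expect_equal(lab_lo, "excitable_down")
    expect_equal(lab_hi, "excitable_up")
  }
})

test_that("regime map covers the plane and matches pointwise classification", {
  base <- rate_pop_params(6, 1, 2.5)
  ax1 <- list(name = "I", values = seq(2.1, 2.9, by = 0.2))
  ax2 <- list(name = "w", values = c(0, 5, 6.3))
  rm <- regime_map(base, ax1, ax2)
  expect_equal(nrow(rm), length(ax1$values) * length(ax2$values))
  # w = 0 row can never alternate
  expect_true(all(rm$regime[rm$w == 0] == "monostable_no_alternations"))
  # spot-check random cells against independent classification
  set.seed(5)
  for (k in sample(nrow(rm), 12)) {
    p <- base; p$I <- rm$I[k]; p$w <- rm$w[k]
    expect_equal(rm$regime[k], classify_regime(p)$label)
  }
  expect_error(regime_map(base, list(name = "tau_r", values = 1), ax2),
               "axis name")
  expect_error(regime_map(base, list(name = "I", values = numeric(0)), ax2),
               "empty")
})

test_that("config round-trips through YAML preserve parameters", {
  p <- rate_pop_params(6.28, 1, 2.64, tau_a = 35,
                       a_inf = sigmoid_spec(gain = 9, half = 0.45, max = 1))
  f <- tempfile(fileext = ".yml")
  write_model_config(p, f)
  q <- read_model_config(f)
  expect_equal(q[names(q) != "r_inf" & names(q) != "a_inf"],
               p[names(p) != "r_inf" & names(p) != "a_inf"])
  expect_equal(unclass(q$a_inf), unclass(p$a_inf))
})
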