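# Bimodality gate, sticky thresholds, hysteresis detection, duration
# statistics.

test_that("interval sets enforce ordering and positive lengths", {
  expect_error(interval_set(c(0, 1), c(1, 0.5), c("UP", "DOWN")),
               "stop > start")
  expect_error(interval_set(c(0, 0.2), c(0.5, 0.7), c("UP", "DOWN")),
               "overlap")
  iv <- interval_set(c(0, 1), c(1, 2), c("UP", "DOWN"), units = "s")
  expect_true(is_interval_set(iv))
  expect_equal(attr(iv, "units"), "s")
})

test_that("the dip gate separates unimodal from well-separated bimodal samples", {
  set.seed(42)
  uni <- rnorm(2000)
  g1 <- bimodality_gate(uni)
  expect_false(g1$bimodal)
  bi <- c(rnorm(1000), rnorm(1000, mean = 6))   # 6 sd separation
  g2 <- bimodality_gate(bi)
  expect_true(g2$bimodal)
  expect_gt(g2$dip, g1$dip)
})

test_that("a constant trace degenerates the dip and closes the gate", {
  expect_warning(g <- bimodality_gate(rep(1, 2000)), "constant")
  expect_false(g$bimodal)
  expect_equal(g$dip, 0)
})

test_that("dip statistic matches a from-scratch prefix/suffix recomputation", {
  # independent oracle: for every candidate mode, rebuild the convex
  # minorant / concave majorant from scratch and take deviations
  oracle_dip <- function(x) {
    x <- sort(x); n <- length(x)
    gcm_dev <- function(xs, ylo, yhi) {
      m <- length(xs)
      if (m == 1) return(yhi - ylo)
      hull <- 1L
      for (i in seq_len(m)[-1]) {
        while (length(hull) >= 2) {
          a <- hull[length(hull) - 1]; b <- hull[length(hull)]
          if ((xs[b] - xs[a]) * (ylo[i] - ylo[a]) -
              (ylo[b] - ylo[a]) * (xs[i] - xs[a]) <= 0)
            hull <- hull[-length(hull)] else break
        }
        hull <- c(hull, i)
      }
      hv <- approx(xs[hull], ylo[hull], xout = xs, ties = min)$y
      max(yhi - hv)
    }
    dl <- vapply(seq_len(n), function(m)
      gcm_dev(x[1:m], (0:(m - 1)) / n, (1:m) / n), numeric(1))
    du <- vapply(seq_len(n), function(m) {
      ix <- m:n
      gcm_dev(-rev(x[ix]), -rev(ix) / n, -(rev(ix) - 1) / n)
    }, numeric(1))
    0.5 * min(pmax(dl, du))
  }
  set.seed(13)
  for (k in 1:20) {
    x <- switch(1 + k %% 3,
                rnorm(40 + k), runif(40 + k),
                c(rnorm(20 + k), rnorm(20, 4)))
    expect_equal(dip_statistic(x), oracle_dip(x), tolerance = 1e-12)
  }
})

test_that("sticky thresholds follow the midpoint-of-peak-and-trough rule", {
  set.seed(7)
  # two sharp peaks at 0 and 1: trough near 0.5
  r <- c(rnorm(5000, 0, 0.03), rnorm(5000, 1, 0.03))
  thr <- sticky_thresholds(r)
  expect_equal(thr[["down_to_up"]], 0.75, tolerance = 0.03)
  expect_equal(thr[["up_to_down"]], 0.25, tolerance = 0.03)
  expect_gt(thr[["down_to_up"]], thr[["up_to_down"]])
  # symmetric sample: thresholds symmetric about the trough
  expect_lt(abs((thr[["down_to_up"]] + thr[["up_to_down"]]) / 2 - 0.5), 0.03)
  expect_error(sticky_thresholds(rnorm(5000)), "two peaks")
})

test_that("hysteresis detection recovers exact square-wave durations", {
  dt <- 0.1
  period <- 100
  tt <- seq(0, 2000, by = dt)
  r <- ifelse((tt %/% period) %% 2 == 1, 1, 0)
  st <- detect_updown(list(r = r, time = tt), gate = FALSE)
  d <- st$stop - st$start
  expect_true(all(abs(d - period) <= dt + 1e-9))
  expect_true(all(st$label[seq(1, nrow(st), by = 2)] ==
                    st$label[1]))
  # strict alternation and exact tiling of the analyzed span
  expect_true(all(st$label[-1] != st$label[-nrow(st)]))
  expect_equal(st$start[-1], st$stop[-nrow(st)])
})

test_that("excursions crossing the trough but not the far threshold are ignored", {
  dt <- 0.1
  tt <- seq(0, 600, by = dt)
  r <- ifelse((tt %/% 100) %% 2 == 1, 1, 0)
  # brief dip from UP to 0.45: below the trough (0.5) but above a
  # plausible up_to_down threshold (0.25)
  r[tt >= 150 & tt < 153] <- 0.45
  st0 <- detect_updown(list(r = ifelse((tt %/% 100) %% 2 == 1, 1, 0),
                            time = tt),
                       thresholds = c(down_to_up = 0.75, up_to_down = 0.25),
                       gate = FALSE)
  st1 <- detect_updown(list(r = r, time = tt),
                       thresholds = c(down_to_up = 0.75, up_to_down = 0.25),
                       gate = FALSE)
  expect_equal(nrow(st1), nrow(st0))
  expect_equal(st1$start, st0$start)
})

test_that("detection is invariant to affine rescaling of the trace", {
  p <- rate_pop_params(6.28, 1, 2.64)
  tr <- simulate_rate(p, duration = 20000, seed = 3)
  st1 <- detect_updown(tr)
  tr2 <- tr; tr2$r <- 100 + 40 * tr$r
  st2 <- detect_updown(tr2)
  expect_equal(st1$start, st2$start, tolerance = 1e-9)
  expect_equal(st1$label, st2$label)
})

test_that("duration statistics use population CV and flag empty labels", {
  iv <- interval_set(c(0, 1, 2, 3, 4, 5), c(1, 2, 3, 4, 5, 6),
                     rep(c("UP", "DOWN"), 3))
  d <- duration_stats(iv)
  expect_equal(d$mean_up, 1)
  expect_equal(d$cv_up, 0)
  expect_equal(d$ratio, 1)
  only_up <- interval_set(c(0, 2), c(1, 3), c("UP", "UP"))
  d2 <- duration_stats(only_up)
  expect_true(is.na(d2$mean_down))
  expect_equal(d2$n_down, 0)
})

test_that("exponential dwell times have unit CV", {
  set.seed(21)
  dur <- rexp(1e4, rate = 2)
  stops <- cumsum(dur)
  iv <- interval_set(c(0, head(stops, -1)), stops,
                     rep(c("UP", "DOWN"), length.out = 1e4))
  d <- duration_stats(iv)
  expect_lt(abs(d$cv_up - 1), 0.05)
  expect_lt(abs(d$cv_down - 1), 0.05)
})

test_that("excitable simulations put the higher CV on the stable state", {
  # Excitable_UP: stable UP, transient DOWN
  st_up <- detect_updown(simulate_rate(rate_pop_params(6.28, 1, 2.64),
                                       duration = 30000, seed = 8))
  d_up <- duration_stats(st_up)
  expect_gt(d_up$cv_up, d_up$cv_down)
  # Excitable_DOWN: long variable DOWN states, brief stereotyped UP states
  st_dn <- detect_updown(simulate_rate(rate_pop_params(6, 1, 2.3),
                                       duration = 30000, seed = 8))
  d_dn <- duration_stats(st_dn)
  expect_gt(d_dn$cv_down, d_dn$cv_up)
  expect_gt(d_dn$mean_down, d_dn$mean_up)
})

test_that("the duration map marks non-alternating cells instead of failing", {
  dm <- duration_map(rate_pop_params(6, 1, 2.5),
                     axis1 = list(name = "I", values = c(2.5, 2.64)),
                     axis2 = list(name = "w", values = c(0, 6.28)),
                     duration = 12000, seed = 6)
  expect_equal(nrow(dm$cells), 4)
  expect_true(all(dm$cells$status[dm$cells$w == 0] == "no_alternation"))
  ok <- dm$cells$status == "ok"
  expect_true(any(ok))
  expect_true(all(!is.na(dm$cells$mean_up[ok])))
})

test_that("drive increases UP durations while DOWN durations track tau_a", {
  p <- rate_pop_params(6, 1, 2.5)
  dm <- duration_map(p, axis1 = list(name = "I",
                                     values = c(2.56, 2.62, 2.68)),
                     duration = 30000, seed = 9)
  cells <- dm$cells[dm$cells$status == "ok", ]
  expect_equal(nrow(cells), 3)
  expect_true(all(diff(cells$mean_up) > 0))
  # transient DOWN durations stay on the adaptation time scale throughout
  expect_true(all(cells$mean_down > 0.5 * p$tau_a))
  expect_true(all(cells$mean_down < 4 * p$tau_a))
  expect_lt(max(cells$mean_down) / min(cells$mean_down), 1.6)
})
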