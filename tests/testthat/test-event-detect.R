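# LFP detectors on ground-truthed synthetic recordings: NREM scoring,
# channel selection, threshold calibration, slow-wave and SWR detection,
# delta-power stratification.

make_updown_rec <- function(seed = 7, length_s = 150, ...) {
  synth_updown_recording(synth_config(length_s = length_s, seed = seed, ...))
}

test_that("NREM scoring separates high-delta from desynchronized epochs", {
  rec <- make_updown_rec(seed = 3, length_s = 600)
  sig <- rec$lfp$signal[, 1]
  t <- (seq_along(sig) - 1) / 1250
  # middle third is replaced by a desynchronized (pure noise) segment
  wake <- t >= 200 & t < 400
  set.seed(9)
  sig[wake] <- rnorm(sum(wake))
  nr <- score_nrem(lfp_record(matrix(sig, ncol = 1), 1250))
  expect_gt(nrow(nr), 0)
  agreement <- mean(nremdyn:::restrict_mask(t, nr) == !wake)
  expect_gte(agreement, 0.95)
})

test_that("a pure-noise recording yields a warning and no NREM epochs", {
  set.seed(12)
  lfp <- lfp_record(matrix(rnorm(1250 * 120), ncol = 1), 1250)
  expect_warning(nr <- score_nrem(lfp), "unimodal")
  expect_equal(nrow(nr), 0)
})

test_that("channel selection finds the channel carrying DOWN-locked delta", {
  rec <- synth_updown_recording(
    synth_config(length_s = 120, seed = 5, n_channels = 3,
                 channel_scale = c(0, 1, 0)))
  ch <- select_channels(rec$lfp, rec$spikes)
  expect_equal(ch$delta_channel, 2)
  expect_equal(ch$gamma_channel, 2)
  # single-channel recordings use that channel for both roles
  rec1 <- make_updown_rec(seed = 6, length_s = 100)
  ch1 <- select_channels(rec1$lfp, rec1$spikes)
  expect_equal(ch1$delta_channel, 1)
  expect_equal(ch1$gamma_channel, 1)
  empty <- spike_raster(list(numeric(0)))
  expect_error(select_channels(rec1$lfp, empty), "spikes")
})

test_that("threshold calibration tracks the amplitude at which spiking vanishes", {
  rec <- make_updown_rec(seed = 8)
  thr <- calibrate_sw_thresholds(rec$lfp, rec$spikes, sensitivity = 0.5)
  expect_s3_class(thr, "sw_thresholds")
  expect_gt(thr$delta[["peak"]], 0.25)
  expect_gt(thr$delta[["peak"]], thr$delta[["window"]])
  expect_gt(thr$gamma[["peak"]], thr$gamma[["window"]])
  # flat delta signal: no candidates to calibrate on
  flat <- lfp_record(matrix(sin(2 * pi * 50 * seq(0, 120, by = 1 / 1250)) +
                              1e-4, ncol = 1), 1250)
  expect_error(calibrate_sw_thresholds(flat, rec$spikes,
                                       channels = list(delta_channel = 1,
                                                       gamma_channel = 1)),
               "candidate|sensitivity")
})

test_that("slow-wave detection recovers ground-truth DOWN states", {
  rec <- make_updown_rec(seed = 7, length_s = 180)
  sw <- detect_slow_waves(rec$lfp, rec$spikes)
  dn <- sw[sw$label == "DOWN", ]
  truth_dn <- rec$truth[rec$truth$label == "DOWN", ]
  expect_gte(nrow(truth_dn), 50)
  pr <- event_precision_recall(dn, truth_dn)
  expect_gte(pr[["precision"]], 0.9)
  expect_gte(pr[["recall"]], 0.9)
  # alternation and the 40 ms duration floor
  expect_true(all(dn$stop - dn$start >= 0.04))
  expect_true(all(sw$label[-1] != sw$label[-nrow(sw)]))
})

test_that("DOWN candidates with spiking and sub-40 ms events are rejected", {
  rec <- make_updown_rec(seed = 9, length_s = 150)
  thr <- calibrate_sw_thresholds(rec$lfp, rec$spikes)
  sw <- detect_slow_waves(rec$lfp, rec$spikes, thresholds = thr)
  dn <- sw[sw$label == "DOWN", ]
  all_t <- sort(unlist(rec$spikes$times))
  mean_rate <- length(all_t) / (nrow(rec$lfp$signal) / rec$lfp$rate)
  within <- vapply(seq_len(nrow(dn)), function(i)
    sum(all_t >= dn$start[i] & all_t < dn$stop[i]) /
      (dn$stop[i] - dn$start[i]), numeric(1))
  expect_true(all(within < thr$sensitivity * mean_rate))
  expect_true(all(dn$stop - dn$start >= 0.04))
})

test_that("SWR detection recovers ground-truth events and duration limits hold", {
  rec <- synth_swr_recording(synth_config(length_s = 200, seed = 11))
  expect_gte(nrow(rec$truth), 40)
  sw <- detect_swr(rec$lfp, deep = 1, superficial = 2)
  pr <- event_precision_recall(sw, rec$truth, tol = 0.02)
  expect_gte(pr[["precision"]], 0.9)
  expect_gte(pr[["recall"]], 0.9)
  expect_error(detect_swr(rec$lfp, deep = 1, superficial = 5),
               "channel")
  # zero event rate: detectors return an empty set
  quiet <- synth_swr_recording(synth_config(length_s = 60, seed = 2,
                                            swr_rate = 0))
  expect_equal(nrow(quiet$truth), 0)
  expect_equal(nrow(detect_swr(quiet$lfp, 1, 2)), 0)
})

test_that("constructed edge cases exercise every duration-limit filter", {
  rate <- 1250
  t <- seq(0, 60, by = 1 / rate)
  n <- length(t)
  mk_event <- function(x, at, dur, f = NULL, amp = 8) {
    ix <- which(t >= at & t < at + dur)
    env <- rep(1, length(ix))
    ph <- seq(0, 1, length.out = length(ix))
    env[ph < 0.1] <- 0.5 * (1 - cos(pi * ph[ph < 0.1] / 0.1))
    env[ph > 0.9] <- 0.5 * (1 - cos(pi * (1 - ph[ph > 0.9]) / 0.1))
    add <- if (is.null(f)) amp * env else
      amp * env * sin(2 * pi * f * (t[ix] - t[ix][1]))
    x[ix] <- x[ix] + add
    x
  }
  set.seed(31)
  deep <- rnorm(n); sup <- rnorm(n)
  # one valid SWR (80 ms sharp wave + ripple), one 700 ms deflection with
  # ripple (too long), one ripple burst of 20 ms (too short). The band is
  # widened to 0.2 Hz so a > 500 ms unipolar deflection survives the
  # zero-phase filter as one long suprathreshold span; in the standard
  # 2-50 Hz band such events are removed by the filter itself.
  deep <- mk_event(deep, 10, 0.08); sup <- mk_event(sup, 10, 0.08, f = 150)
  deep <- mk_event(deep, 25, 0.70); sup <- mk_event(sup, 25, 0.70, f = 150)
  deep <- mk_event(deep, 40, 0.02); sup <- mk_event(sup, 40, 0.02, f = 150)
  cfg <- detection_config(sharp_wave_band = c(0.2, 50))
  sw <- detect_swr(lfp_record(cbind(deep, sup), rate), 1, 2, config = cfg)
  covers <- function(iv, time) any(iv$start <= time & iv$stop >= time)
  expect_true(covers(sw, 10.04))
  expect_false(covers(sw, 25.35))  # sharp wave > 500 ms discarded
  expect_false(covers(sw, 40.01))  # ripple < 25 ms discarded
})

test_that("detection output is invariant to a global LFP gain", {
  rec <- make_updown_rec(seed = 13, length_s = 120)
  sw1 <- detect_slow_waves(rec$lfp, rec$spikes)
  lfp2 <- rec$lfp; lfp2$signal <- lfp2$signal * 37
  sw2 <- detect_slow_waves(lfp2, rec$spikes)
  expect_equal(as.data.frame(sw1), as.data.frame(sw2), tolerance = 1e-9)
  rec2 <- synth_swr_recording(synth_config(length_s = 100, seed = 14))
  s1 <- detect_swr(rec2$lfp, 1, 2)
  lfp3 <- rec2$lfp; lfp3$signal <- lfp3$signal * 0.05
  s2 <- detect_swr(lfp3, 1, 2)
  expect_equal(as.data.frame(s1), as.data.frame(s2), tolerance = 1e-9)
})

test_that("zero-phase filtering keeps impulse event times aligned", {
  rate <- 1250
  n <- 60 * rate
  x <- rnorm(n, sd = 0.01)
  ctr <- 30 * rate
  x[ctr + (-30:30)] <- x[ctr + (-30:30)] +
    8 * exp(-(-30:30)^2 / 200)           # smooth impulse at t = 30 s
  f <- nremdyn:::bandpass(x, rate, c(2, 50))
  expect_lte(abs(which.max(f) - ctr), 1)
})

test_that("UP durations shorten with surrounding delta power while DOWN stays flat", {
  # construction: DOWN states arrive faster (so UP durations shorten) in
  # epochs of stronger delta amplitude; DOWN lengths are drawn
  # independently of delta
  rate <- 1250
  set.seed(17)
  segs <- list(list(amp = 2, up_mean = 2.4), list(amp = 4, up_mean = 1.2),
               list(amp = 7, up_mean = 0.6))
  seg_len <- 100
  t0 <- 0; starts <- c(); stops <- c(); labs <- c(); amps <- c()
  for (si in seq_along(segs)) {
    sg <- segs[[si]]
    while (t0 < si * seg_len) {
      up_d <- max(rexp(1, 1 / sg$up_mean), 0.1)
      dn_d <- max(rgamma(1, shape = 7, rate = 7 / 0.21), 0.08)
      starts <- c(starts, t0, t0 + up_d)
      stops <- c(stops, t0 + up_d, t0 + up_d + dn_d)
      labs <- c(labs, "UP", "DOWN")
      amps <- c(amps, NA, sg$amp)
      t0 <- t0 + up_d + dn_d
    }
  }
  L <- ceiling(t0) + 1
  n <- L * rate
  tt <- (seq_len(n) - 1) / rate
  sig <- rnorm(n)
  for (k in which(labs == "DOWN")) {
    ix <- which(tt >= starts[k] & tt < stops[k])
    if (length(ix) < 4) next
    ph <- seq(0, 2 * pi, length.out = length(ix))
    sig[ix] <- sig[ix] + amps[k] * 0.5 * (1 - cos(ph))
  }
  states <- interval_set(starts, pmin(stops, L), labs, units = "s")
  dc <- delta_conditioned_stats(states, lfp_record(matrix(sig, ncol = 1),
                                                   rate),
                                n_groups = 3)
  g <- dc$groups
  expect_equal(nrow(g), 3)
  # mean UP duration decreases monotonically across delta groups
  expect_true(all(diff(g$mean_up) < 0))
  # DOWN durations were generated independently of delta: roughly flat
  expect_lt(max(g$mean_down) / min(g$mean_down), 1.5)
  # normalization: median delta power over the recording maps to 1
  expect_equal(median(nremdyn:::band_power(sig, rate, c(1, 4), 0.5) /
                        dc$delta_median), 1, tolerance = 1e-9)
})
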