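# The synthetic-data generator: determinism, construction guarantees, and
# round-trips through the plain-text/binary writers.

test_that("DOWN states are silent when the DOWN rate is zero", {
  rec <- synth_updown_recording(synth_config(length_s = 60, seed = 4,
                                             down_rate = 0))
  truth_dn <- rec$truth[rec$truth$label == "DOWN", ]
  all_t <- sort(unlist(rec$spikes$times))
  for (k in seq_len(nrow(truth_dn)))
    expect_equal(sum(all_t >= truth_dn$start[k] & all_t < truth_dn$stop[k]),
                 0)
})

test_that("the same seed reproduces recordings exactly", {
  cfg <- synth_config(length_s = 40, seed = 99)
  r1 <- synth_updown_recording(cfg)
  r2 <- synth_updown_recording(cfg)
  expect_identical(r1$lfp$signal, r2$lfp$signal)
  expect_identical(r1$spikes$times, r2$spikes$times)
  expect_identical(as.data.frame(r1$truth), as.data.frame(r2$truth))
  s1 <- synth_swr_recording(cfg)
  s2 <- synth_swr_recording(cfg)
  expect_identical(s1$lfp$signal, s2$lfp$signal)
})

test_that("generated durations match the configured moments at large n", {
  up_gen <- list(dist = "lognormal", mean = 1.7, cv = 1.1)
  dn_gen <- list(dist = "gamma", mean = 0.21, cv = 0.38)
  ds <- synth_durations(up_gen, dn_gen, n = 2000, seed = 12)
  cv <- function(x) sd(x) / mean(x)
  expect_lt(abs(mean(ds$up) - 1.7) / 1.7, 0.05)
  expect_lt(abs(cv(ds$up) - 1.1) / 1.1, 0.05)
  expect_lt(abs(mean(ds$down) - 0.21) / 0.21, 0.05)
  expect_lt(abs(cv(ds$down) - 0.38) / 0.38, 0.05)
})

test_that("parametric generators cover the declared families and reject others", {
  pt <- synth_durations(list(dist = "point", mean = 1, cv = 0), n = 50,
                        seed = 1)
  expect_true(all(pt$up == 1))
  ex <- synth_durations(list(dist = "exponential", mean = 2, cv = 1),
                        n = 4000, seed = 2)
  expect_lt(abs(mean(ex$up) - 2), 2 * 2 / sqrt(4000))
  expect_identical(synth_durations(list(dist = "gamma", mean = 1, cv = 0.5),
                                   n = 10, seed = 3)$up,
                   synth_durations(list(dist = "gamma", mean = 1, cv = 0.5),
                                   n = 10, seed = 3)$up)
  expect_error(synth_durations(list(dist = "weibull", mean = 1, cv = 1),
                               n = 5, seed = 1), "supported")
})

test_that("SWR recordings honour their configured event structure", {
  rec <- synth_swr_recording(synth_config(length_s = 150, seed = 6,
                                          swr_rate = 0.5,
                                          ripple_freq = 150))
  d <- rec$truth$stop - rec$truth$start
  expect_true(all(d >= 0.025))
  expect_lt(abs(mean(d) - 0.06), 0.02)
  # ripple oscillation carries its energy inside the 80-250 Hz band
  sup <- rec$lfp$signal[, 2]
  inband <- nremdyn:::band_power(sup, 1250, c(80, 250), 0.01)
  k <- which.max(inband)
  tt <- (k - 1) / 1250
  expect_true(any(rec$truth$start - 0.02 <= tt & rec$truth$stop + 0.02 >= tt))
  # end-to-end: detector-recovered duration means within 15% of truth
  det <- detect_swr(rec$lfp, 1, 2)
  expect_lt(abs(mean(det$stop - det$start) - mean(d)) / mean(d), 0.15)
  gaps_truth <- rec$truth$start[-1] - head(rec$truth$stop, -1)
  gaps_det <- det$start[-1] - head(det$stop, -1)
  expect_lt(abs(mean(gaps_det) - mean(gaps_truth)) / mean(gaps_truth), 0.15)
})

test_that("recordings round-trip bit-exactly through the binary LFP format", {
  rec <- synth_updown_recording(synth_config(length_s = 20, seed = 44,
                                             n_channels = 2,
                                             channel_scale = c(1, 0.5)))
  f <- tempfile(fileext = ".lfp")
  write_lfp_binary(rec$lfp, f)
  back <- read_lfp_binary(f)
  f2 <- tempfile(fileext = ".lfp")
  write_lfp_binary(back, f2, scale = jsonlite::read_json(
    paste0(f, ".json"))$scale)
  expect_identical(readBin(f, "raw", file.info(f)$size),
                   readBin(f2, "raw", file.info(f2)$size))
  expect_equal(back$rate, rec$lfp$rate)
  expect_equal(dim(back$signal), dim(rec$lfp$signal))
  expect_lt(max(abs(back$signal - rec$lfp$signal)),
            jsonlite::read_json(paste0(f, ".json"))$scale)
})

test_that("interval, duration and spike tables round-trip through TSV", {
  iv <- interval_set(c(0, 1.5), c(1.2, 2.5), c("UP", "DOWN"), units = "s")
  f <- tempfile(fileext = ".tsv")
  write_intervals(iv, f)
  expect_equal(as.data.frame(read_intervals(f)), as.data.frame(iv))
  expect_equal(attr(read_intervals(f), "units"), "s")
  ds <- synth_durations(list(dist = "gamma", mean = 2, cv = 0.4), n = 30,
                        seed = 5, units = "s")
  f2 <- tempfile(fileext = ".tsv")
  write_durations(ds, f2)
  back <- read_durations(f2)
  expect_equal(back$up, ds$up)
  expect_equal(back$down, ds$down)
  sp <- spike_raster(list(c(0.1, 0.5), c(0.2, 0.3, 0.9)),
                     class = c("pE", "pI"))
  f3 <- tempfile(fileext = ".tsv")
  write_spikes(sp, f3)
  back_sp <- read_spikes(f3)
  expect_equal(back_sp$times, sp$times)
  expect_equal(back_sp$class, sp$class)
})
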