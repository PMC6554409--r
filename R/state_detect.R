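# UP/DOWN state detection on simulated rate traces: bimodality gate, sticky
# thresholds, hysteresis scan, and duration statistics.

#' Labeled interval set
#'
#' Ordered, non-overlapping half-open `[start, stop)` intervals with a state
#' label each. UP/DOWN tilings must alternate strictly.
#'
#' @param start,stop interval bounds (`stop > start`, sorted,
#'   non-overlapping).
#' @param label per-interval state tag.
#' @param units time units of the bounds (e.g. `"s"` or `"model"`).
#' @return A data frame of class `interval_set` with columns `start`,
#'   `stop`, `label`.
#' @export
interval_set <- function(start = numeric(0), stop = numeric(0),
                         label = character(0), units = "model") {
  stopifnot(length(start) == length(stop), length(start) == length(label))
  if (length(start)) {
    if (any(stop <= start)) stop("every interval needs stop > start")
    if (is.unsorted(start, strictly = TRUE))
      stop("intervals must be sorted by start time")
    if (any(start[-1] < stop[-length(stop)]))
      stop("intervals must not overlap")
  }
  structure(data.frame(start = start, stop = stop, label = as.character(label),
                       stringsAsFactors = FALSE),
            units = units, class = c("interval_set", "data.frame"))
}

#' @rdname interval_set
#' @param x an object.
#' @export
is_interval_set <- function(x) inherits(x, "interval_set")

#' Hartigan dip statistic
#'
#' Departure of a sample's empirical CDF from the nearest unimodal
#' distribution function, computed as half the smallest (over candidate
#' modes) maximal deviation from a greatest-convex-minorant /
#' least-concave-majorant pair. Larger values indicate stronger bimodality.
#'
#' @param x numeric sample.
#' @return The dip statistic (0 for degenerate samples).
#' @export
dip_statistic <- function(x) {
  x <- sort(x[is.finite(x)])
  cpp_dip(x)
}

# bootstrap null of the dip under the uniform distribution; depends only on
# the sample size, so realizations are cached per (n, n_boot, seed)
.dip_null_cache <- new.env(parent = emptyenv())

dip_null <- function(n, n_boot, seed) {
  key <- paste(n, n_boot, seed, sep = "_")
  if (!is.null(.dip_null_cache[[key]])) return(.dip_null_cache[[key]])
  set.seed(seed)
  null <- vapply(seq_len(n_boot),
                 function(i) cpp_dip(sort(runif(n))), numeric(1))
  .dip_null_cache[[key]] <- null
  null
}

#' Bimodality gate for simulated rate traces
#'
#' A trace is accepted as having UP/DOWN states only if the distribution of
#' `r(t)` is bimodal by a dip test. The null distribution of the dip is
#' calibrated by parametric bootstrap from the uniform distribution, the
#' asymptotically least-favourable unimodal null. Long traces are thinned
#' by a deterministic stride to at most `max_n` samples before testing.
#'
#' @param trace a `sim_trace` or numeric vector of rate samples.
#' @param alpha test level.
#' @param n_boot bootstrap replicates for the null.
#' @param max_n maximum sample size used for the dip.
#' @param seed seed for the bootstrap draws.
#' @return A list: `dip`, `p_value`, `bimodal` (decision at `alpha`),
#'   `n_used`.
#' @export
bimodality_gate <- function(trace, alpha = 0.05, n_boot = 500,
                            max_n = 10000, seed = 171) {
  r <- if (inherits(trace, "sim_trace")) trace$r else as.numeric(trace)
  if (length(r) < 1000)
    stop("bimodality gate needs at least 1000 samples")
  stride <- max(1L, length(r) %/% max_n)
  r <- r[seq(1L, length(r), by = stride)]
  if (diff(range(r)) == 0) {
    warning("constant trace: dip degenerate, gate closed")
    return(list(dip = 0, p_value = 1, bimodal = FALSE, n_used = length(r)))
  }
  dip <- dip_statistic(r)
  null <- dip_null(length(r), n_boot, seed)
  p <- (sum(null >= dip) + 1) / (n_boot + 1)
  list(dip = dip, p_value = p, bimodal = p < alpha, n_used = length(r))
}

# Smoothed histogram of the rate sample: Freedman-Diaconis bin width,
# clamped to 64-128 bins (long traces otherwise resolve sampling noise as
# spurious micro-peaks), then a 3-bin moving average.
rate_histogram <- function(r) {
  iqr <- diff(quantile(r, c(0.25, 0.75), names = FALSE))
  span <- diff(range(r))
  h <- if (iqr > 0) 2 * iqr / length(r)^(1 / 3) else span / 64
  nb <- min(max(ceiling(span / h), 64), 128)
  brks <- seq(min(r), max(r), length.out = nb + 1)
  brks[nb + 1] <- brks[nb + 1] + span * 1e-9
  counts <- tabulate(findInterval(r, brks, rightmost.closed = TRUE),
                     nbins = nb)
  sm <- as.numeric(stats::filter(counts, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- counts[is.na(sm)]
  list(mids = (brks[-1] + brks[-(nb + 1)]) / 2, density = sm)
}

# Drop local maxima that are not separated by a sufficiently deep trough
# (relative depth >= min_depth of the smaller peak): distinct distribution
# modes must be divided by a genuine density dip, not a noise wiggle.
merge_shallow_peaks <- function(d, pk, min_depth = 0.5) {
  pk <- sort(pk)
  while (length(pk) > 1) {
    depths <- vapply(seq_len(length(pk) - 1), function(i) {
      tr <- min(d[pk[i]:pk[i + 1]])
      1 - tr / min(d[pk[i]], d[pk[i + 1]])
    }, numeric(1))
    shallow <- which(depths < min_depth)
    if (!length(shallow)) break
    i <- shallow[which.min(depths[shallow])]
    drop <- if (d[pk[i]] <= d[pk[i + 1]]) i else i + 1
    pk <- pk[-drop]
  }
  pk
}

local_maxima <- function(d) {
  n <- length(d)
  idx <- which(diff(sign(diff(d))) < 0) + 1
  if (n >= 2 && d[1] > d[2]) idx <- c(1L, idx)
  if (n >= 2 && d[n] > d[n - 1]) idx <- c(idx, as.integer(n))
  unique(idx)
}

#' Sticky (hysteresis) detection thresholds
#'
#' From the bimodal rate distribution locates the low-rate peak, the
#' high-rate peak and the trough between them, and places the DOWN-to-UP
#' threshold at the midpoint of the high peak and the trough and the
#' UP-to-DOWN threshold at the midpoint of the low peak and the trough.
#' The gap between the two suppresses spurious transitions from noise.
#'
#' @param r numeric rate sample from a gated (bimodal) trace.
#' @return Named vector `c(down_to_up, up_to_down)` with
#'   `down_to_up > up_to_down`; peak/trough locations in attributes.
#' @export
sticky_thresholds <- function(r) {
  hh <- rate_histogram(r)
  pk <- local_maxima(hh$density)
  pk <- merge_shallow_peaks(hh$density, pk)
  # keep only peaks whose basin (bins up to the neighbouring troughs)
  # carries real probability mass; isolated tail bins are not modes
  if (length(pk) > 1) {
    pk <- sort(pk)
    cuts <- vapply(seq_len(length(pk) - 1), function(i) {
      seg <- pk[i]:pk[i + 1]
      seg[which.min(hh$density[seg])]
    }, 0L)
    bounds <- c(0L, cuts, length(hh$density))
    mass <- vapply(seq_along(pk), function(i)
      sum(hh$density[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
    pk <- pk[mass >= 0.01 * sum(hh$density)]
  }
  if (length(pk) < 2)
    stop("rate distribution has fewer than two peaks; ",
         "run bimodality_gate() first")
  # two most massive basins; ties broken toward the larger mode
  cuts <- vapply(seq_len(length(pk) - 1), function(i) {
    seg <- pk[i]:pk[i + 1]
    seg[which.min(hh$density[seg])]
  }, 0L)
  bounds <- c(0L, cuts, length(hh$density))
  mass <- vapply(seq_along(pk), function(i)
    sum(hh$density[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
  ord <- order(mass, hh$mids[pk], decreasing = TRUE)
  pk2 <- sort(pk[ord[1:2]])
  lo_peak <- hh$mids[pk2[1]]; hi_peak <- hh$mids[pk2[2]]
  between <- seq(pk2[1], pk2[2])
  dmin <- min(hh$density[between])
  # centre of the minimal-density plateau (a wide empty valley has many
  # tied bins; its midpoint is the natural trough location)
  flat <- between[hh$density[between] <= dmin + 1e-12]
  trough <- (hh$mids[min(flat)] + hh$mids[max(flat)]) / 2
  thr <- c(down_to_up = (hi_peak + trough) / 2,
           up_to_down = (lo_peak + trough) / 2)
  attr(thr, "peaks") <- c(low = lo_peak, high = hi_peak)
  attr(thr, "trough") <- trough
  thr
}

#' Detect UP and DOWN states with a sticky threshold
#'
#' Hysteresis scan of the rate trace: the state switches to UP only on an
#' upward crossing of the DOWN-to-UP threshold and back to DOWN only on a
#' downward crossing of the (lower) UP-to-DOWN threshold, so excursions
#' that cross the trough but not the far threshold cause no transition.
#' The first and last partial states are discarded, leaving a strictly
#' alternating UP/DOWN tiling.
#'
#' @param trace a `sim_trace` (or list with `r` and `time`).
#' @param thresholds optional thresholds from [sticky_thresholds()];
#'   computed from the trace when `NULL`.
#' @param gate apply [bimodality_gate()] first; if the gate rejects, an
#'   empty interval set with `attr(, "status") = "no_alternations"` is
#'   returned.
#' @param units time units recorded on the result.
#' @return An [interval_set()] of alternating UP/DOWN intervals.
#' @export
detect_updown <- function(trace, thresholds = NULL, gate = TRUE,
                          units = "model") {
  r <- trace$r
  tm <- trace$time
  if (gate) {
    g <- bimodality_gate(trace)
    if (!g$bimodal) {
      out <- interval_set(units = units)
      attr(out, "status") <- "no_alternations"
      attr(out, "gate") <- g
      return(out)
    }
  }
  if (is.null(thresholds)) thresholds <- sticky_thresholds(r)
  hi <- thresholds[["down_to_up"]]; lo <- thresholds[["up_to_down"]]
  n <- length(r)
  up_x <- which(r[-1] >= hi & r[-n] < hi)
  dn_x <- which(r[-1] <= lo & r[-n] > lo)
  ev <- rbind(cbind(up_x, 1L), cbind(dn_x, -1L))
  if (!nrow(ev)) {
    out <- interval_set(units = units)
    attr(out, "status") <- "no_transitions"
    return(out)
  }
  ev <- ev[order(ev[, 1]), , drop = FALSE]
  keep <- c(TRUE, diff(ev[, 2]) != 0)  # crossings while already in-state
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev) < 3) {
    out <- interval_set(units = units)
    attr(out, "status") <- "no_transitions"
    return(out)
  }
  tt <- tm[ev[, 1] + 1]
  lab <- ifelse(ev[, 2] == 1L, "UP", "DOWN")
  # interval i spans transition i -> i+1; first/last states are partial and
  # already excluded by construction of the transition list
  out <- interval_set(start = tt[-length(tt)], stop = tt[-1],
                      label = lab[-length(lab)], units = units)
  attr(out, "thresholds") <- thresholds
  attr(out, "status") <- "ok"
  out
}

#' Dwell-time statistics of an UP/DOWN tiling
#'
#' Per-label mean and coefficient of variation (population standard
#' deviation over mean) of interval durations, the UP/DOWN mean-duration
#' ratio, and counts.
#'
#' @param states an [interval_set()] with labels `UP` and `DOWN` (other
#'   label pairs are mapped positionally).
#' @param labels length-2 character: the labels to treat as UP and DOWN.
#' @return A list of class `duration_stats`: `mean_up`, `mean_down`,
#'   `cv_up`, `cv_down`, `ratio`, `n_up`, `n_down`.
#' @export
duration_stats <- function(states, labels = c("UP", "DOWN")) {
  stopifnot(is_interval_set(states))
  dur <- states$stop - states$start
  up <- dur[states$label == labels[1]]
  dn <- dur[states$label == labels[2]]
  pop_cv <- function(x) {
    if (length(x) < 2) return(NA_real_)
    sqrt(mean((x - mean(x))^2)) / mean(x)
  }
  out <- list(mean_up = if (length(up)) mean(up) else NA_real_,
              mean_down = if (length(dn)) mean(dn) else NA_real_,
              cv_up = pop_cv(up), cv_down = pop_cv(dn),
              ratio = if (length(up) && length(dn)) mean(up) / mean(dn)
              else NA_real_,
              n_up = length(up), n_down = length(dn))
  class(out) <- "duration_stats"
  out
}

#' @export
print.duration_stats <- function(x, ...) {
  cat(sprintf(
    "UP: mean %.3g, CV %.3g (n = %d) | DOWN: mean %.3g, CV %.3g (n = %d) | ratio %.3g\n",
    x$mean_up, x$cv_up, x$n_up, x$mean_down, x$cv_down, x$n_down, x$ratio))
  invisible(x)
}

#' Extract the UP/DOWN duration sample from a tiling
#'
#' @param states an [interval_set()].
#' @param labels labels taken as the UP-like and DOWN-like state.
#' @return A [duration_sample()].
#' @export
interval_durations <- function(states, labels = c("UP", "DOWN")) {
  dur <- states$stop - states$start
  duration_sample(up = dur[states$label == labels[1]],
                  down = dur[states$label == labels[2]],
                  units = attr(states, "units"))
}

#' Duration statistics over a parameter grid
#'
#' For each cell of a one- or two-axis parameter grid: simulate with noise,
#' apply the bimodality gate, detect UP/DOWN states and summarize dwell
#' times. Cells whose traces fail the gate are marked `no_alternation`
#' rather than aborting the map.
#'
#' @param base a [rate_pop_params()] object.
#' @param axis1 list `list(name, values)`, name in `I`, `w`, `b`.
#' @param axis2 optional second axis.
#' @param noise an [ou_params()].
#' @param duration simulated time per cell.
#' @param seed seed; per-cell seeds are derived from it.
#' @param n_hist_bins log-spaced duration histogram bins per cell.
#' @return A list of class `duration_map`: `cells` (data frame of axis
#'   values, status and the [duration_stats()] fields), `histograms`
#'   (per-cell list with log-binned UP and DOWN counts), `samples`
#'   (per-cell [duration_sample()] or `NULL`).
#' @export
duration_map <- function(base, axis1, axis2 = NULL, noise = ou_params(),
                         duration = 25000, seed = 1, n_hist_bins = 25) {
  axes <- list(axis1)
  if (!is.null(axis2)) axes <- c(axes, list(axis2))
  for (ax in axes) {
    if (!ax$name %in% c("I", "w", "b")) stop("axis name must be I, w or b")
    if (!length(ax$values)) stop("empty axis grid")
  }
  grid <- if (is.null(axis2)) data.frame(v1 = axis1$values)
  else expand.grid(v1 = axis1$values, v2 = axis2$values,
                   KEEP.OUT.ATTRS = FALSE)
  seeds <- derive_seeds(seed, nrow(grid))
  samples <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    p <- base
    p[[axis1$name]] <- grid$v1[k]
    if (!is.null(axis2)) p[[axis2$name]] <- grid$v2[k]
    res <- tryCatch({
      tr <- simulate_rate(p, noise, duration = duration, seed = seeds[k])
      st <- detect_updown(tr)
      if (identical(attr(st, "status"), "ok") && nrow(st) >= 4) {
        samples[[k]] <- interval_durations(st)
        c(list(status = "ok"), unclass(duration_stats(st)))
      } else {
        list(status = "no_alternation", mean_up = NA, mean_down = NA,
             cv_up = NA, cv_down = NA, ratio = NA, n_up = 0, n_down = 0)
      }
    }, error = function(e) {
      list(status = paste0("error: ", conditionMessage(e)),
           mean_up = NA, mean_down = NA, cv_up = NA, cv_down = NA,
           ratio = NA, n_up = 0, n_down = 0)
    })
    rows[[k]] <- as.data.frame(res)
  }
  cells <- cbind(grid, do.call(rbind, rows))
  names(cells)[1] <- axis1$name
  if (!is.null(axis2)) names(cells)[2] <- axis2$name
  all_dur <- unlist(lapply(samples, function(s)
    if (is.null(s)) NULL else c(s$up, s$down)))
  hists <- vector("list", nrow(grid))
  if (length(all_dur)) {
    edges <- exp(seq(log(min(all_dur)), log(max(all_dur) * (1 + 1e-9)),
                     length.out = n_hist_bins + 1))
    hists <- lapply(samples, function(s) {
      if (is.null(s)) return(NULL)
      list(edges = edges,
           up = tabulate(findInterval(s$up, edges, rightmost.closed = TRUE),
                         nbins = n_hist_bins),
           down = tabulate(findInterval(s$down, edges,
                                        rightmost.closed = TRUE),
                           nbins = n_hist_bins))
    })
  }
  structure(list(cells = cells, histograms = hists, samples = samples),
            class = "duration_map")
}
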