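# Non-parametric matching of UP/DOWN dwell-time distributions: exact KS
# statistic, the (1 - KS_UP)(1 - KS_DOWN) similarity, time-scale scan, and
# similarity maps over a parameter grid.

#' UP and DOWN duration sample
#'
#' @param up,down positive dwell-time multisets.
#' @param units `"s"`, `"ms"` or `"model"`.
#' @return Object of class `duration_sample`.
#' @export
duration_sample <- function(up, down, units = "model") {
  up <- as.numeric(up); down <- as.numeric(down)
  if (any(up <= 0) || any(down <= 0))
    stop("durations must be strictly positive")
  structure(list(up = up, down = down, units = units),
            class = "duration_sample")
}

#' @export
print.duration_sample <- function(x, ...) {
  cat(sprintf("duration sample: %d UP, %d DOWN (%s)\n",
              length(x$up), length(x$down), x$units))
  invisible(x)
}

#' Exact two-sample Kolmogorov-Smirnov statistic
#'
#' `sup_x |F_a(x) - F_b(x)|` of the two empirical CDFs, evaluated exactly at
#' every CDF step point.
#'
#' @param a,b non-empty numeric samples.
#' @return The KS statistic in `[0, 1]`.
#' @examples
#' ks_stat(c(1, 2), c(1, 3)) # 0.5
#' @export
ks_stat <- function(a, b) {
  if (!length(a) || !length(b)) stop("KS statistic needs non-empty samples")
  sa <- sort(a); sb <- sort(b)
  pts <- sort(unique(c(sa, sb)))
  Fa <- findInterval(pts, sa) / length(sa)
  Fb <- findInterval(pts, sb) / length(sb)
  max(abs(Fa - Fb))
}

#' KS-product similarity between duration distributions
#'
#' The similarity between a simulated and an observed UP/DOWN duration
#' sample is `s = (1 - KS_UP) * (1 - KS_DOWN)`: `s = 1` when both the UP
#' and the DOWN distributions are identical, `s = 0` when either is
#' non-overlapping. Simulated durations are multiplied by the time-scale
#' factor `tau` before comparison, mapping model time units onto the
#' observed units.
#'
#' @param sim,obs [duration_sample()] objects.
#' @param tau time-scale factor applied to `sim` (> 0).
#' @return A list of class `similarity_result`: `ks_up`, `ks_down`, `s`,
#'   `tau`.
#' @export
similarity <- function(sim, obs, tau = 1) {
  stopifnot(inherits(sim, "duration_sample"), inherits(obs, "duration_sample"),
            tau > 0)
  if (!length(sim$up) || !length(sim$down) ||
      !length(obs$up) || !length(obs$down))
    stop("similarity needs non-empty UP and DOWN duration samples")
  ks_up <- ks_stat(sim$up * tau, obs$up)
  ks_down <- ks_stat(sim$down * tau, obs$down)
  structure(list(ks_up = ks_up, ks_down = ks_down,
                 s = (1 - ks_up) * (1 - ks_down), tau = tau),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("similarity s = %.4f (KS_UP %.4f, KS_DOWN %.4f, tau %.4g)\n",
              x$s, x$ks_up, x$ks_down, x$tau))
  invisible(x)
}

#' Best time-scale factor by grid scan
#'
#' Scans the time-scale factor over a fixed grid (1 ms to 25 ms in 0.1 ms
#' increments by default, expressed in the observed sample's units) and
#' returns the similarity at the argmax, taking the first maximum on ties.
#' Observed samples in seconds are compared on the millisecond scale.
#'
#' @param sim simulated [duration_sample()] in model time units.
#' @param obs observed [duration_sample()].
#' @param tau_grid candidate scale factors in ms per model time unit.
#' @return A `similarity_result` with the winning `tau` (ms) and an
#'   attribute `scan` holding the full `s(tau)` profile.
#' @export
best_tau <- function(sim, obs, tau_grid = seq(1, 25, by = 0.1)) {
  stopifnot(all(tau_grid > 0))
  obs_ms <- obs
  if (identical(obs$units, "s"))
    obs_ms <- duration_sample(obs$up * 1000, obs$down * 1000, units = "ms")
  # scaling preserves order: sort once, scan taus over sorted samples
  svals <- vapply(tau_grid, function(tau)
    similarity(sim, obs_ms, tau = tau)$s, numeric(1))
  k <- which.max(svals)  # first maximum on ties
  out <- similarity(sim, obs_ms, tau = tau_grid[k])
  attr(out, "scan") <- data.frame(tau = tau_grid, s = svals)
  out
}

#' Experimental duration statistics with dispersions
#'
#' Summary statistics of observed dwell times (mean and standard deviation
#' over recordings) used to outline the constraint region of a similarity
#' map.
#'
#' @param cv_up,cv_up_sd,cv_down,cv_down_sd,ratio,ratio_sd means and
#'   between-recording standard deviations of CV_UP, CV_DOWN and the
#'   mean_UP/mean_DOWN ratio.
#' @return A list of class `exp_duration_stats`.
#' @export
exp_duration_stats <- function(cv_up, cv_up_sd, cv_down, cv_down_sd,
                               ratio, ratio_sd) {
  structure(list(cv_up = cv_up, cv_up_sd = cv_up_sd,
                 cv_down = cv_down, cv_down_sd = cv_down_sd,
                 ratio = ratio, ratio_sd = ratio_sd),
            class = "exp_duration_stats")
}

#' Similarity map over a simulated parameter grid
#'
#' For every grid cell with a simulated duration sample, computes the
#' best-time-scale similarity to each recording, the mean similarity over
#' recordings, each recording's best cell (first index on ties), and the
#' constraint mask of cells whose simulated CV_UP, CV_DOWN and mean ratio
#' all fall within `n_sd` experimental standard deviations. Cells without
#' alternations (a `NULL` sample) contribute `s = 0` and are flagged.
#'
#' @param grid data frame of cell coordinates (one row per cell).
#' @param sims list (same length) of [duration_sample()] or `NULL`.
#' @param recordings list of observed [duration_sample()] objects.
#' @param exp_stats optional [exp_duration_stats()] for the mask.
#' @param n_sd half-width of the constraint region in experimental SDs.
#' @return A list of class `similarity_map`: `cells` (grid plus `mean_s`,
#'   `no_alternation`, `in_constraint`), `per_recording` (matrix of s),
#'   `best_cells` (per-recording argmax row indices), `best_taus`.
#' @export
similarity_map <- function(grid, sims, recordings, exp_stats = NULL,
                           n_sd = 2) {
  stopifnot(nrow(grid) == length(sims), length(recordings) >= 1)
  ncell <- nrow(grid)
  smat <- matrix(0, ncell, length(recordings))
  tmat <- matrix(NA_real_, ncell, length(recordings))
  for (i in seq_len(ncell)) {
    if (is.null(sims[[i]])) next
    for (j in seq_along(recordings)) {
      bt <- best_tau(sims[[i]], recordings[[j]])
      smat[i, j] <- bt$s
      tmat[i, j] <- bt$tau
    }
  }
  mean_s <- rowMeans(smat)
  best_cells <- apply(smat, 2, which.max)
  no_alt <- vapply(sims, is.null, logical(1))
  in_constraint <- rep(NA, ncell)
  if (!is.null(exp_stats)) {
    in_constraint <- vapply(seq_len(ncell), function(i) {
      s <- sims[[i]]
      if (is.null(s)) return(FALSE)
      pop_cv <- function(x) sqrt(mean((x - mean(x))^2)) / mean(x)
      cu <- pop_cv(s$up); cd <- pop_cv(s$down)
      rt <- mean(s$up) / mean(s$down)
      abs(cu - exp_stats$cv_up) <= n_sd * exp_stats$cv_up_sd &&
        abs(cd - exp_stats$cv_down) <= n_sd * exp_stats$cv_down_sd &&
        abs(rt - exp_stats$ratio) <= n_sd * exp_stats$ratio_sd
    }, logical(1))
  }
  cells <- cbind(grid, mean_s = mean_s, no_alternation = no_alt,
                 in_constraint = in_constraint)
  structure(list(cells = cells, per_recording = smat,
                 best_cells = best_cells,
                 best_taus = tmat[cbind(best_cells,
                                        seq_along(recordings))]),
            class = "similarity_map")
}
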