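# Deterministic analysis of the r-a model: fixed points, stability,
# effective I/O curves and classification into UP/DOWN regimes.

# scalar fixed-point residual g(r) = r - R_inf(w r - b A_inf(r) + I)
ra_residual <- function(params, r) {
  a <- transfer_eval(params$a_inf, r)
  r - transfer_eval(params$r_inf, params$w * r - params$b * a + params$I)
}

# 2x2 Jacobian of the deterministic flow at (r, a)
ra_jacobian <- function(params, r, a) {
  u <- params$w * r - params$b * a + params$I
  Rp <- transfer_deriv(params$r_inf, u)
  Ap <- transfer_deriv(params$a_inf, r)
  matrix(c((-1 + Rp * params$w) / params$tau_r, -Rp * params$b / params$tau_r,
           Ap / params$tau_a, -1 / params$tau_a),
         2, 2, byrow = TRUE)
}

stability_label <- function(ev) {
  re <- Re(ev)
  cplx <- any(abs(Im(ev)) > 1e-12)
  if (all(re < 0)) if (cplx) "stable_spiral" else "stable_node"
  else if (all(re > 0)) if (cplx) "unstable_spiral" else "unstable_node"
  else "saddle"
}

#' Fold rates of the r-nullcline
#'
#' For a logistic rate transfer the r-nullcline `a(r)` is S-shaped whenever
#' `w * gain * max > 4`; its two folds sit at the rates where the effective
#' recurrent slope equals one, `w R_inf'(u) = 1`, which on the nullcline
#' reduces to a quadratic in `r`. The left (low-rate) and right (high-rate)
#' branches outside the folds carry the DOWN and UP states.
#'
#' @param params a [rate_pop_params()] object.
#' @return Numeric vector `c(lower, upper)` of fold rates, or `NULL` when the
#'   nullcline is unfolded.
#' @export
nullcline_folds <- function(params) {
  g <- params$r_inf$gain
  m <- params$r_inf$max
  disc <- m^2 - 4 * m / (params$w * g)
  if (!is.finite(disc) || disc <= 0) return(NULL)
  c((m - sqrt(disc)) / 2, (m + sqrt(disc)) / 2)
}

branch_of <- function(r, folds) {
  if (is.null(folds)) return(NA_character_)
  if (r < folds[1]) "DOWN" else if (r > folds[2]) "UP" else "middle"
}

#' Fixed points of the adapting recurrent population
#'
#' Finds every steady state of the deterministic model, i.e. every solution
#' of \eqn{r = R_\infty(w r - b A_\infty(r) + I)} in the admissible rate range
#' `[0, max(R_inf)]`. Roots are bracketed by sign changes of the residual on
#' a dense grid and refined by bisection; each is classified by the
#' eigenvalues of the full 2D Jacobian and assigned to the DOWN, middle or
#' UP branch of the r-nullcline.
#'
#' @param params a [rate_pop_params()] object.
#' @param n_grid grid resolution for the bracketing scan.
#' @param tol root refinement tolerance.
#' @return A data frame with one row per fixed point (sorted by `r_star`):
#'   columns `r_star`, `a_star`, `branch`, `stability`, `eig1`, `eig2`
#'   (complex).
#' @export
steady_states <- function(params, n_grid = 2000, tol = 1e-8) {
  stopifnot(inherits(params, "rate_pop_params"))
  rmax <- params$r_inf$max
  grid <- seq(0, rmax, length.out = n_grid + 1)
  gv <- ra_residual(params, grid)
  roots <- numeric(0)
  for (i in seq_len(n_grid)) {
    if (gv[i] == 0) {
      roots <- c(roots, grid[i])
    } else if (gv[i] * gv[i + 1] < 0) {
      roots <- c(roots, uniroot(function(r) ra_residual(params, r),
                                c(grid[i], grid[i + 1]), tol = tol)$root)
    }
  }
  if (gv[n_grid + 1] == 0) roots <- c(roots, rmax)
  roots <- sort(roots)
  # drop duplicates from roots landing exactly on grid nodes
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > 10 * tol)]
  folds <- nullcline_folds(params)
  rows <- lapply(roots, function(r) {
    a <- transfer_eval(params$a_inf, r)
    ev <- eigen(ra_jacobian(params, r, a), only.values = TRUE)$values
    ev <- as.complex(ev)
    data.frame(r_star = r, a_star = a,
               branch = branch_of(r, folds),
               stability = stability_label(ev),
               eig1 = ev[1], eig2 = ev[2])
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(r_star = numeric(0), a_star = numeric(0),
               branch = character(0), stability = character(0),
               eig1 = complex(0), eig2 = complex(0))
  attr(out, "folds") <- folds
  out
}

regime_labels <- c("oscillatory", "bistable", "excitable_up",
                   "excitable_down", "monostable_no_alternations")

# Noise-free limit-cycle probe: simulate from a perturbed start and look for
# >= 5 consecutive inter-peak intervals agreeing within 5%. The window must
# hold >= 10 cycles of the slow relaxation oscillation, whose period can
# reach ~8 tau_a.
limit_cycle_probe <- function(params, dt = 0.05) {
  dur <- 120 * params$tau_a
  n <- ceiling(dur / dt)
  rmax <- params$r_inf$max
  fps <- steady_states(params)
  r0 <- if (nrow(fps)) min(rmax, fps$r_star[1] + 0.3 * rmax) else 0.8 * rmax
  a0 <- if (nrow(fps)) fps$a_star[1] else 0.5 * params$a_inf$max
  tr <- cpp_simulate_ra(numeric(n), rep(params$I, n), dt,
                        params$w, params$b, params$tau_r, params$tau_a,
                        params$r_inf$gain, params$r_inf$half, params$r_inf$max,
                        params$a_inf$gain, params$a_inf$half, params$a_inf$max,
                        r0, a0)
  r <- tr[, 1]
  tail_r <- r[(length(r) %/% 2):length(r)]
  if (diff(range(tail_r)) < 0.05 * rmax) return(FALSE)
  thr <- mean(range(tail_r))
  pk <- which(diff(sign(diff(r))) == -2) + 1
  pk <- pk[r[pk] > thr & pk > length(r) %/% 4]
  if (length(pk) < 7) return(FALSE)
  ipi <- diff(pk) * dt
  ipi <- tail(ipi, 10)
  ok <- abs(ipi - median(ipi)) <= 0.05 * median(ipi)
  runs <- rle(ok)
  any(runs$lengths[runs$values] >= 5)
}

#' Classify the dynamical regime of the population model
#'
#' Assigns one of five regimes from the fixed-point structure:
#' `bistable` (a stable fixed point on each outer nullcline branch separated
#' by a saddle), `excitable_up` / `excitable_down` (a single stable fixed
#' point on the UP / DOWN branch of a folded nullcline), `oscillatory` (no
#' stable fixed point but a sustained limit cycle, confirmed by a noise-free
#' simulation probe), and `monostable_no_alternations` otherwise (including
#' every unfolded, weak-recurrence configuration).
#'
#' @param params a [rate_pop_params()] object.
#' @return An object of class `nrem_regime`: a list with `label`, the
#'   `fixed_points` table and the fold rates.
#' @examples
#' classify_regime(rate_pop_params(w = 6.3, b = 1, I = 2.35))$label # bistable
#' @export
classify_regime <- function(params) {
  fps <- steady_states(params)
  folds <- attr(fps, "folds")
  stable <- fps[startsWith(fps$stability, "stable"), , drop = FALSE]
  ns <- nrow(stable)
  label <-
    if (is.null(folds)) {
      "monostable_no_alternations"
    } else if (ns >= 2 && any(stable$branch == "DOWN") &&
               any(stable$branch == "UP")) {
      "bistable"
    } else if (ns == 1 && stable$branch == "DOWN") {
      "excitable_down"
    } else if (ns == 1 && stable$branch == "UP") {
      "excitable_up"
    } else if (ns == 0 && limit_cycle_probe(params)) {
      "oscillatory"
    } else {
      "monostable_no_alternations"
    }
  structure(list(label = label, fixed_points = fps, folds = folds),
            class = "nrem_regime")
}

#' @export
print.nrem_regime <- function(x, ...) {
  cat("regime:", x$label, "with", nrow(x$fixed_points), "fixed point(s)\n")
  invisible(x)
}

#' Effective input/output curve of the population
#'
#' Traces the steady-state population rate `r_ss` against tonic drive,
#' recording every fixed-point branch with its stability, locating
#' saddle-node bifurcations (drives where the fixed-point count changes,
#' reported at the bracketing grid-cell edge) and Hopf bifurcations (sign
#' changes of the real part of a complex eigenvalue pair along a branch).
#' The curve shape is labelled `monotonic_stable`, `oscillatory_centered`
#' (a drive interval with no stable fixed point) or `bistable_centered`
#' (a drive interval with two stable fixed points).
#'
#' @param params a [rate_pop_params()] object; its `I` field is ignored.
#' @param drive_range length-2 numeric interval of drives.
#' @param n_points number of drive grid points (>= 2).
#' @return A list of class `io_curve`: `branches` (data frame `drive`,
#'   `r_ss`, `branch`, `stability`, `stable`), `bifurcations` (data frame
#'   `drive`, `type`), `shape`, and the drive grid.
#' @export
io_curve <- function(params, drive_range, n_points = 201) {
  stopifnot(length(drive_range) == 2, n_points >= 2)
  drives <- seq(drive_range[1], drive_range[2], length.out = n_points)
  per <- lapply(drives, function(I) {
    p <- params; p$I <- I
    fp <- steady_states(p)
    if (nrow(fp)) cbind(drive = I, fp) else NULL
  })
  counts <- vapply(per, function(x) if (is.null(x)) 0L else nrow(x), 0L)
  branches <- do.call(rbind, per)
  if (is.null(branches))
    stop("no fixed points found anywhere in the drive range")
  branches$stable <- startsWith(branches$stability, "stable")
  # saddle-node points: fixed-point count changes between adjacent drives
  sn <- drives[which(diff(counts) != 0)] +
    diff(drives[1:2]) / 2
  # Hopf points: stability flip with complex eigenvalues along a branch
  hopf <- numeric(0)
  for (br in unique(branches$branch)) {
    bb <- branches[branches$branch %in% br, ]
    bb <- bb[order(bb$drive), ]
    if (nrow(bb) < 2) next
    cplx <- abs(Im(bb$eig1)) > 1e-12
    flip <- which(diff(bb$stable) != 0 & (cplx[-1] | cplx[-nrow(bb)]))
    if (length(flip))
      hopf <- c(hopf, (bb$drive[flip] + bb$drive[flip + 1]) / 2)
  }
  bif <- rbind(
    if (length(sn)) data.frame(drive = sn, type = "saddle_node"),
    if (length(hopf)) data.frame(drive = hopf, type = "hopf"))
  if (is.null(bif)) bif <- data.frame(drive = numeric(0), type = character(0))
  n_stable <- vapply(split(branches$stable, branches$drive), sum, 0L)
  shape <- if (any(n_stable >= 2)) "bistable_centered"
  else if (any(n_stable == 0)) "oscillatory_centered"
  else "monotonic_stable"
  structure(list(drives = drives, branches = branches, bifurcations = bif,
                 shape = shape),
            class = "io_curve")
}

#' @export
print.io_curve <- function(x, ...) {
  cat(sprintf("effective I/O curve over [%g, %g]: shape %s, %d bifurcation(s)\n",
              min(x$drives), max(x$drives), x$shape, nrow(x$bifurcations)))
  invisible(x)
}

#' Map dynamical regimes over a parameter plane
#'
#' Classifies the regime on a grid spanned by two of `I`, `w`, `b`.
#'
#' @param base a [rate_pop_params()] object providing the fixed parameters.
#' @param axis1,axis2 lists `list(name = "I", values = <numeric>)`; names
#'   must be chosen from `I`, `w`, `b`.
#' @return A data frame with columns `axis1`, `axis2` (named after the swept
#'   parameters) and `regime`; axis metadata in attributes.
#' @export
regime_map <- function(base, axis1, axis2) {
  for (ax in list(axis1, axis2)) {
    if (!is.list(ax) || !ax$name %in% c("I", "w", "b"))
      stop("axis name must be one of 'I', 'w', 'b'")
    if (!length(ax$values)) stop("empty axis grid for ", ax$name)
  }
  grid <- expand.grid(v1 = axis1$values, v2 = axis2$values,
                      KEEP.OUT.ATTRS = FALSE)
  lab <- vapply(seq_len(nrow(grid)), function(k) {
    p <- base
    p[[axis1$name]] <- grid$v1[k]
    p[[axis2$name]] <- grid$v2[k]
    classify_regime(p)$label
  }, character(1))
  out <- data.frame(grid$v1, grid$v2, regime = lab)
  names(out)[1:2] <- c(axis1$name, axis2$name)
  attr(out, "axes") <- c(axis1$name, axis2$name)
  out
}
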