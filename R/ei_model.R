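# Analysis of the adapting inhibition-stabilized network: frozen-adaptation
# phase plane, effective I/O curve, separatrix, and regime classification.

# inhibitory rate nullcline: unique r_i solving
#   r_i = R_i(w_ie r_e - w_ii r_i + I_i)
# The residual is strictly increasing in r_i, so elementwise bisection over
# a vector of r_e values converges unconditionally.
ei_ri_of_re <- function(params, r_e) {
  f <- function(ri, re) ri - transfer_eval(params$io_i,
                                           params$w_ie * re -
                                             params$w_ii * ri + params$I_i)
  hi <- pmax(params$r_cap,
             transfer_eval(params$io_i, params$w_ie * r_e + params$I_i)) + 1
  lo <- numeric(length(r_e))
  at_zero <- f(0, r_e) >= 0
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    up <- f(mid, r_e) >= 0
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
  }
  out <- (lo + hi) / 2
  out[at_zero] <- 0
  out
}

ei_residual <- function(params, r_e, a) {
  ri <- ei_ri_of_re(params, r_e)
  r_e - transfer_eval(params$io_e,
                      params$w_ee * r_e - params$w_ei * ri - params$b * a +
                        params$I_e)
}

ei_jacobian2 <- function(params, re, ri, a) {
  ue <- params$w_ee * re - params$w_ei * ri - params$b * a + params$I_e
  ui <- params$w_ie * re - params$w_ii * ri + params$I_i
  Rep <- transfer_deriv(params$io_e, ue)
  Rip <- transfer_deriv(params$io_i, ui)
  matrix(c((-1 + Rep * params$w_ee) / params$tau_e,
           -Rep * params$w_ei / params$tau_e,
           Rip * params$w_ie / params$tau_i,
           (-1 - Rip * params$w_ii) / params$tau_i),
         2, 2, byrow = TRUE)
}

#' Fixed points of the E-I network with frozen adaptation
#'
#' Treating the slow adaptation variable as a constant, finds all fixed
#' points of the fast `r_e`-`r_i` subsystem (by scanning the excitatory
#' residual along the inhibitory nullcline), with 2D Jacobian stability and
#' a spiral flag for complex eigenvalue pairs.
#'
#' @param params an [ei_params()] object.
#' @param a_frozen frozen adaptation level (>= 0).
#' @param n_grid scan resolution in `r_e`.
#' @return An object of class `ei_phase_portrait`: `a_frozen` and a
#'   `fixed_points` data frame (`r_e`, `r_i`, `stability`, `spiral`,
#'   `eig1`, `eig2`).
#' @export
ei_fixed_points <- function(params, a_frozen = 0, n_grid = 1200) {
  stopifnot(inherits(params, "ei_params"), a_frozen >= 0)
  grid <- seq(0, params$r_cap, length.out = n_grid + 1)
  gv <- ei_residual(params, grid, a_frozen)
  roots <- numeric(0)
  for (i in seq_len(n_grid)) {
    if (gv[i] == 0) roots <- c(roots, grid[i])
    else if (gv[i] * gv[i + 1] < 0)
      roots <- c(roots, uniroot(function(r) ei_residual(params, r, a_frozen),
                                c(grid[i], grid[i + 1]), tol = 1e-10)$root)
  }
  if (gv[n_grid + 1] == 0) roots <- c(roots, params$r_cap)
  roots <- sort(roots)
  if (length(roots) > 1) roots <- roots[c(TRUE, diff(roots) > 1e-8)]
  rows <- lapply(roots, function(re) {
    ri <- ei_ri_of_re(params, re)
    ev <- as.complex(eigen(ei_jacobian2(params, re, ri, a_frozen),
                           only.values = TRUE)$values)
    data.frame(r_e = re, r_i = ri, stability = stability_label(ev),
               spiral = any(abs(Im(ev)) > 1e-12), eig1 = ev[1], eig2 = ev[2])
  })
  fp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(r_e = numeric(0), r_i = numeric(0), stability = character(0),
               spiral = logical(0), eig1 = complex(0), eig2 = complex(0))
  structure(list(a_frozen = a_frozen, fixed_points = fp),
            class = "ei_phase_portrait")
}

#' @export
print.ei_phase_portrait <- function(x, ...) {
  cat(sprintf("E-I phase portrait (a frozen at %g): %d fixed point(s)\n",
              x$a_frozen, nrow(x$fixed_points)))
  if (nrow(x$fixed_points)) print(x$fixed_points[, 1:4])
  invisible(x)
}

#' Effective I/O curve of the E-I network
#'
#' Steady-state excitatory rate against drive to the E population with
#' adaptation frozen, traced as in [io_curve()]: saddle-node points where
#' the fixed-point count changes and a shape label
#' (`monotonic_stable` / `oscillatory_centered` / `bistable_centered`).
#'
#' @param params an [ei_params()] object (its `I_e` is ignored).
#' @param drive_range interval of drives to E; defaults to a window around
#'   `I_e`.
#' @param n_points drive grid size.
#' @param a_frozen frozen adaptation level.
#' @return An `io_curve` object (branches use `r_ss` = fixed-point `r_e`).
#' @export
ei_effective_io <- function(params, drive_range = params$I_e + c(-3, 3),
                            n_points = 121, a_frozen = 0) {
  drives <- seq(drive_range[1], drive_range[2], length.out = n_points)
  per <- lapply(drives, function(Ie) {
    p <- params; p$I_e <- Ie
    fp <- ei_fixed_points(p, a_frozen)$fixed_points
    if (!nrow(fp)) return(NULL)
    data.frame(drive = Ie, r_ss = fp$r_e, stability = fp$stability,
               spiral = fp$spiral)
  })
  counts <- vapply(per, function(x) if (is.null(x)) 0L else nrow(x), 0L)
  branches <- do.call(rbind, per)
  if (is.null(branches)) stop("no fixed points in the drive range")
  branches$stable <- startsWith(branches$stability, "stable")
  branches$branch <- NA_character_
  for (d in unique(branches$drive)) {
    ix <- which(branches$drive == d)
    if (length(ix) >= 3) {
      ord <- order(branches$r_ss[ix])
      branches$branch[ix[ord]] <-
        c("DOWN", rep("middle", length(ix) - 2), "UP")
    }
  }
  sn <- drives[which(diff(counts) != 0)] + diff(drives[1:2]) / 2
  bif <- if (length(sn)) data.frame(drive = sn, type = "saddle_node")
  else data.frame(drive = numeric(0), type = character(0))
  n_stable <- vapply(split(branches$stable, branches$drive), sum, 0L)
  shape <- if (any(n_stable >= 2)) "bistable_centered"
  else if (any(n_stable == 0)) "oscillatory_centered"
  else "monotonic_stable"
  structure(list(drives = drives, branches = branches, bifurcations = bif,
                 shape = shape, a_frozen = a_frozen),
            class = "io_curve")
}

ei_flow2 <- function(params, a_frozen) {
  function(t, y, parms) {
    ue <- params$w_ee * y[1] - params$w_ei * y[2] - params$b * a_frozen +
      params$I_e
    ui <- params$w_ie * y[1] - params$w_ii * y[2] + params$I_i
    list(c((-y[1] + transfer_eval(params$io_e, ue)) / params$tau_e,
           (-y[2] + transfer_eval(params$io_i, ui)) / params$tau_i))
  }
}

#' Separatrix of the bistable frozen-adaptation E-I system
#'
#' Computes the basin boundary between the UP and DOWN fixed points as the
#' stable manifold of the saddle, by reverse-time integration from small
#' offsets (1e-6) along the saddle's stable eigendirection, terminated at
#' the phase-plane bounding box.
#'
#' @param params an [ei_params()] object.
#' @param a_frozen frozen adaptation level; the frozen system must be
#'   bistable.
#' @param t_max reverse-time integration horizon (ms).
#' @return A two-column matrix (`r_e`, `r_i`) polyline of class
#'   `ei_separatrix`, with the saddle and the stable fixed points in
#'   attributes.
#' @export
ei_separatrix <- function(params, a_frozen = 0, t_max = 60 * params$tau_e) {
  pp <- ei_fixed_points(params, a_frozen)
  fp <- pp$fixed_points
  sad <- fp[fp$stability == "saddle", , drop = FALSE]
  if (!nrow(sad))
    stop("no saddle at frozen a = ", a_frozen,
         "; fixed-point structure is not bistable (",
         paste(fp$stability, collapse = ", "), ")")
  sad <- sad[1, ]
  J <- ei_jacobian2(params, sad$r_e, sad$r_i, a_frozen)
  eg <- eigen(J)
  stable_dir <- Re(eg$vectors[, which.min(Re(eg$values))])
  stable_dir <- stable_dir / sqrt(sum(stable_dir^2))
  box <- c(-0.02 * params$r_cap, 1.05 * params$r_cap)
  run_branch <- function(sign) {
    y0 <- c(sad$r_e, sad$r_i) + sign * 1e-6 * stable_dir
    flow <- ei_flow2(params, a_frozen)
    rev_flow <- function(t, y, parms) {
      d <- flow(t, y, parms)[[1]]
      list(-d)
    }
    sol <- deSolve::ode(y0, times = seq(0, t_max, length.out = 4000),
                        func = rev_flow, parms = NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-10)
    xy <- sol[, 2:3, drop = FALSE]
    inside <- xy[, 1] >= box[1] & xy[, 1] <= box[2] &
      xy[, 2] >= box[1] & xy[, 2] <= box[2]
    cut <- which(!inside)[1]
    if (!is.na(cut)) xy <- xy[seq_len(cut), , drop = FALSE]
    xy
  }
  b1 <- run_branch(1)
  b2 <- run_branch(-1)
  poly <- rbind(b2[rev(seq_len(nrow(b2))), ], c(sad$r_e, sad$r_i), b1)
  colnames(poly) <- c("r_e", "r_i")
  stable <- fp[startsWith(fp$stability, "stable"), , drop = FALSE]
  up_fp <- stable[which.max(stable$r_e), c("r_e", "r_i")]
  dn_fp <- stable[which.min(stable$r_e), c("r_e", "r_i")]
  structure(poly, class = c("ei_separatrix", "matrix"),
            saddle = c(sad$r_e, sad$r_i),
            up_fp = as.numeric(up_fp), down_fp = as.numeric(dn_fp))
}

# count crossings of segment p->q with the polyline
segment_crossings <- function(poly, p, q) {
  x1 <- poly[-nrow(poly), 1]; y1 <- poly[-nrow(poly), 2]
  x2 <- poly[-1, 1]; y2 <- poly[-1, 2]
  d1 <- (x2 - x1) * (p[2] - y1) - (y2 - y1) * (p[1] - x1)
  d2 <- (x2 - x1) * (q[2] - y1) - (y2 - y1) * (q[1] - x1)
  d3 <- (q[1] - p[1]) * (y1 - p[2]) - (q[2] - p[2]) * (x1 - p[1])
  d4 <- (q[1] - p[1]) * (y2 - p[2]) - (q[2] - p[2]) * (x2 - p[1])
  sum(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Which side of the separatrix a point lies on
#'
#' Classifies phase-plane points into the UP or DOWN basin by the parity of
#' crossings of the straight segment from the point to the UP fixed point
#' with the separatrix polyline: an even count places the point in the UP
#' basin.
#'
#' @param sep an [ei_separatrix()] result.
#' @param points two-column matrix of (`r_e`, `r_i`) test points.
#' @return Character vector `"UP"` / `"DOWN"` per point.
#' @export
separatrix_side <- function(sep, points) {
  up <- attr(sep, "up_fp")
  points <- matrix(points, ncol = 2)
  vapply(seq_len(nrow(points)), function(i) {
    k <- segment_crossings(unclass(sep), points[i, ], up)
    if (k %% 2 == 0) "UP" else "DOWN"
  }, character(1))
}

#' Basin of attraction by forward simulation
#'
#' Integrates the frozen-adaptation E-I system forward from given initial
#' points and reports which stable fixed point attracts each.
#'
#' @param params an [ei_params()] object.
#' @param points two-column matrix of initial (`r_e`, `r_i`) points.
#' @param a_frozen frozen adaptation level.
#' @param t_end forward horizon (ms).
#' @return Character vector `"UP"` / `"DOWN"` per point.
#' @export
ei_forward_basin <- function(params, points, a_frozen = 0,
                             t_end = 100 * params$tau_e) {
  pp <- ei_fixed_points(params, a_frozen)
  st <- pp$fixed_points[startsWith(pp$fixed_points$stability, "stable"), ]
  if (nrow(st) < 2) stop("frozen system is not bistable")
  up <- st$r_e[which.max(st$r_e)]; dn <- st$r_e[which.min(st$r_e)]
  flow <- ei_flow2(params, a_frozen)
  points <- matrix(points, ncol = 2)
  vapply(seq_len(nrow(points)), function(i) {
    sol <- deSolve::ode(points[i, ], times = c(0, t_end), func = flow,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-8, atol = 1e-10)
    re_end <- sol[nrow(sol), 2]
    if (abs(re_end - up) < abs(re_end - dn)) "UP" else "DOWN"
  }, character(1))
}

# fold rates of the effective I/O curve, for branch labeling
ei_fold_rates <- function(params, a_frozen = 0,
                          drive_range = params$I_e + c(-3, 3)) {
  eio <- ei_effective_io(params, drive_range, n_points = 121,
                         a_frozen = a_frozen)
  mid <- eio$branches[eio$branches$branch %in% "middle", , drop = FALSE]
  if (!nrow(mid)) return(NULL)
  range(mid$r_ss)
}

# noise-free limit-cycle probe for the full three-variable system
ei_limit_cycle_probe <- function(params, dt = 0.2) {
  dur <- 120 * params$tau_a
  n <- ceiling(dur / dt)
  tr <- cpp_simulate_ei(numeric(n), numeric(n),
                        rep(params$I_e, n), rep(params$I_i, n), dt,
                        params$w_ee, params$w_ei, params$w_ie, params$w_ii,
                        params$b, params$tau_e, params$tau_i, params$tau_a,
                        params$io_e$gain, params$io_e$thresh, params$io_e$expo,
                        params$io_i$gain, params$io_i$thresh, params$io_i$expo,
                        params$a_inf$gain, params$a_inf$half, params$a_inf$max,
                        0.6 * params$r_cap, 0, 0, params$r_cap)
  re <- tr[, 1]
  tail_r <- re[(length(re) %/% 2):length(re)]
  if (diff(range(tail_r)) < 0.02 * max(re)) return(FALSE)
  thr <- mean(range(tail_r))
  pk <- which(diff(sign(diff(re))) == -2) + 1
  pk <- pk[re[pk] > thr & pk > length(re) %/% 4]
  if (length(pk) < 7) return(FALSE)
  ipi <- tail(diff(pk) * dt, 10)
  ok <- abs(ipi - median(ipi)) <= 0.05 * median(ipi)
  runs <- rle(ok)
  any(runs$lengths[runs$values] >= 5)
}

#' Regime of the full adapting E-I network
#'
#' Classifies the three-variable system by the same rules as
#' [classify_regime()]: fixed points of the full system (the intersection
#' of the effective I/O curve with the steady-state adaptation relation),
#' branch membership relative to the folds of the effective curve, and a
#' noise-free limit-cycle probe when no fixed point is stable.
#'
#' @param params an [ei_params()] object.
#' @return An object of class `nrem_regime`.
#' @export
ei_regime <- function(params) {
  g3 <- function(re) {
    a <- transfer_eval(params$a_inf, re)
    ei_residual(params, re, a)
  }
  grid <- seq(0, params$r_cap, length.out = 1201)
  gv <- vapply(grid, g3, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(length(grid) - 1)) {
    if (gv[i] == 0) roots <- c(roots, grid[i])
    else if (gv[i] * gv[i + 1] < 0)
      roots <- c(roots, uniroot(g3, c(grid[i], grid[i + 1]), tol = 1e-10)$root)
  }
  roots <- sort(roots)
  if (length(roots) > 1) roots <- roots[c(TRUE, diff(roots) > 1e-8)]
  jac3 <- function(re) {
    ri <- ei_ri_of_re(params, re)
    a <- transfer_eval(params$a_inf, re)
    ue <- params$w_ee * re - params$w_ei * ri - params$b * a + params$I_e
    ui <- params$w_ie * re - params$w_ii * ri + params$I_i
    Rep <- transfer_deriv(params$io_e, ue)
    Rip <- transfer_deriv(params$io_i, ui)
    Ap <- transfer_deriv(params$a_inf, re)
    matrix(c((-1 + Rep * params$w_ee) / params$tau_e,
             -Rep * params$w_ei / params$tau_e, -Rep * params$b / params$tau_e,
             Rip * params$w_ie / params$tau_i,
             (-1 - Rip * params$w_ii) / params$tau_i, 0,
             Ap / params$tau_a, 0, -1 / params$tau_a),
           3, 3, byrow = TRUE)
  }
  # effective drive seen by the frozen system spans I_e - b * [0, a_max]
  folds <- ei_fold_rates(params,
                         drive_range = c(params$I_e - params$b *
                                           params$a_inf$max - 1,
                                         params$I_e + 1))
  rows <- lapply(roots, function(re) {
    ev <- eigen(jac3(re), only.values = TRUE)$values
    stable <- all(Re(ev) < 0)
    branch <- if (is.null(folds)) NA_character_
    else if (re < folds[1]) "DOWN" else if (re > folds[2]) "UP" else "middle"
    data.frame(r_star = re, a_star = transfer_eval(params$a_inf, re),
               branch = branch, stable = stable)
  })
  fps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(r_star = numeric(0), a_star = numeric(0),
               branch = character(0), stable = logical(0))
  st <- fps[fps$stable, , drop = FALSE]
  ns <- nrow(st)
  label <-
    if (is.null(folds)) "monostable_no_alternations"
    else if (ns >= 2 && any(st$branch == "DOWN") && any(st$branch == "UP"))
      "bistable"
    else if (ns == 1 && identical(st$branch, "DOWN")) "excitable_down"
    else if (ns == 1 && identical(st$branch, "UP")) "excitable_up"
    else if (ns == 0 && ei_limit_cycle_probe(params)) "oscillatory"
    else "monostable_no_alternations"
  structure(list(label = label, fixed_points = fps, folds = folds),
            class = "nrem_regime")
}
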