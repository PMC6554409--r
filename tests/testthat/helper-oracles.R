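# Independent oracles and shared fixtures for the test suite.

# brute-force fixed-point oracle: dense sign-change scan of the steady-state
# residual g(r) = r - R_inf(w r - b A_inf(r) + I) at fixed resolution,
# refined by bisection on each bracket
oracle_fixed_points <- function(params, resolution = 1e-4) {
  logis <- function(x, s) s$max / (1 + exp(-s$gain * (x - s$half)))
  g <- function(r) r - logis(params$w * r -
                               params$b * logis(r, params$a_inf) +
                               params$I, params$r_inf)
  grid <- seq(0, params$r_inf$max, by = resolution)
  gv <- g(grid)
  roots <- grid[gv == 0]
  br <- which(gv[-1] * gv[-length(gv)] < 0)
  for (i in br) {
    lo <- grid[i]; hi <- grid[i + 1]
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  sort(roots)
}

# brute-force two-sample KS oracle: evaluate both ECDFs just after every
# pooled point
oracle_ks <- function(a, b) {
  pts <- sort(c(a, b))
  max(vapply(pts, function(x)
    abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

# dense-grid nullcline-intersection oracle for the frozen-a E-I system
oracle_ei_fixed_points <- function(params, a_frozen, resolution = 2e-3) {
  tev <- function(s, x) {
    u <- pmax(x - s$thresh, 0)
    s$gain * u^s$expo
  }
  ri_of <- function(re) {
    f <- function(ri) ri - tev(params$io_i,
                               params$w_ie * re - params$w_ii * ri + params$I_i)
    lo <- 0
    hi <- max(params$r_cap,
              tev(params$io_i, params$w_ie * re + params$I_i)) + 1
    if (f(lo) >= 0) return(0)
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) >= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  g <- function(re) re - tev(params$io_e,
                             params$w_ee * re - params$w_ei * ri_of(re) -
                               params$b * a_frozen + params$I_e)
  grid <- seq(0, params$r_cap, by = resolution)
  gv <- vapply(grid, g, numeric(1))
  roots <- grid[gv == 0]
  br <- which(gv[-1] * gv[-length(gv)] < 0)
  for (i in br) {
    lo <- grid[i]; hi <- grid[i + 1]
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  sort(roots)
}

# random but valid two-variable parameter draws spanning folded and
# unfolded configurations
random_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    rate_pop_params(w = runif(1, 0, 8), b = runif(1, 0, 2),
                    I = runif(1, 0, 5)))
}

# matching of detected events against truth intervals by midpoint
# containment, with optional tolerance
event_precision_recall <- function(detected, truth, tol = 0) {
  if (!nrow(detected) || !nrow(truth)) return(c(precision = 0, recall = 0))
  hit_d <- vapply(seq_len(nrow(detected)), function(i) {
    m <- (detected$start[i] + detected$stop[i]) / 2
    any(truth$start - tol <= m & truth$stop + tol >= m)
  }, logical(1))
  hit_t <- vapply(seq_len(nrow(truth)), function(i) {
    m <- (truth$start[i] + truth$stop[i]) / 2
    any(detected$start - tol <= m & detected$stop + tol >= m)
  }, logical(1))
  c(precision = mean(hit_d), recall = mean(hit_t))
}
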