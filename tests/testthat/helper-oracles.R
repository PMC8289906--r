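# Independent reference implementations used to cross-check the package.
# These are written directly from the closed forms and never call the
# functions they verify.

# bi-exponential concentration, literal formula
oracle_cp <- function(ka, ke, F, D0, Vd, t) {
  F * D0 * ka / (Vd * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

# bisection root of log(ka/ke)/(ka-ke) = Tmax on (ke, hi]
oracle_ka_bisect <- function(Tmax, ke, hi = 10, iters = 200) {
  f <- function(ka) log(ka / ke) / (ka - ke) - Tmax
  lo <- ke * (1 + 1e-9)
  stopifnot(f(lo) > 0, f(hi) < 0)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# partial correlation through the inverse of the joint correlation matrix
oracle_pcor <- function(x, y, z) {
  P <- solve(stats::cor(cbind(x, y, z)))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# dense grid search for the least-squares release estimate
oracle_grid_D0 <- function(t, y, params, Vd, grid = seq(0, 1e7, by = 100)) {
  s <- shape_at(params, Vd, t)
  rss <- vapply(grid, function(d0) sum((y - d0 * s)^2), numeric(1))
  grid[which.min(rss)]
}

gfap_params <- function() kinetic_params(ka = 0.08, ke = 0.0193, F = 0.8)
nominal_scenario <- function() injury_scenario(D0 = 400000, Vd = 5000)
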