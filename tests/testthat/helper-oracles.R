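# Independent oracles, deliberately implemented apart from the package's
# own code paths.

# Saturation mole fraction of the regular-solution model by dense
# bracketing scan plus bisection on h(x) = ln x + A (1 - x)^2 + g_rt,
# where g_rt = max(0, dGfus)/RT.  Returns the smallest root in (0, 1].
oracle_regular_root <- function(A, g_rt, n_grid = 1e6) {
  h <- function(x) log(x) + A * (1 - x)^2 + g_rt
  xs <- seq(1e-8, 1, length.out = n_grid)
  hs <- h(xs)
  sgn <- sign(hs)
  flip <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (!length(flip)) return(if (abs(h(1)) < 1e-9) 1 else NA_real_)
  lo <- xs[flip[1]]; hi <- xs[flip[1] + 1]
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (h(lo) * h(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Mean pair interaction energies by an explicit O(n^2) double loop over
# all grid pairs, weights p(s, s') ~ P(s) P(s') exp{[a_eff (mu_s + mu_s')
# - E_mf - E_hb] / RT}.
oracle_mean_energies <- function(profile, potential, params) {
  grid <- profile$grid
  pw <- profile$p / sum(profile$p)
  rt <- solvscreen::gas_constant() * potential$temperature
  n <- length(grid)
  w <- matrix(0, n, n); emf <- matrix(0, n, n); ehb <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    emf[i, j] <- misfit_energy(grid[i], grid[j], params)
    ehb[i, j] <- hbond_energy(grid[i], grid[j], params)
    w[i, j] <- pw[i] * pw[j] *
      exp((params$a_eff * (potential$mu[i] + potential$mu[j]) -
             emf[i, j] - ehb[i, j]) / rt)
  }
  w <- w / sum(w)
  c(e_misfit = sum(w * emf), e_hb = sum(w * ehb))
}

# Leverages of a two-point, one-feature design by explicit 2x2 inversion
# of X'X with X = [1, x].
oracle_hat_2pt <- function(x_train, x_query) {
  X <- cbind(1, x_train)
  xtx <- t(X) %*% X
  inv <- solve(xtx)
  sapply(x_query, function(q) {
    v <- c(1, q)
    drop(t(v) %*% inv %*% v)
  })
}
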