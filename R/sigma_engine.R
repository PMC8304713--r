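# Toy COSMO-RS segment thermodynamics.
#
# Surface contacts between screening-charge segments carry a misfit
# (electrostatic) penalty, a hydrogen-bond gain for sufficiently polar
# opposite-sign pairs, and an element-specific dispersion term.  A
# self-consistent sigma-potential over the solvent's sigma-profile gives
# residual chemical potentials; averaging the pair energies over the
# equilibrium contact distribution yields the per-component mean
# interaction energies used as model descriptors.  The engine is
# residual-only: the combinatorial contribution is deliberately omitted.

#' Discretized sigma-profile
#'
#' @param grid Strictly increasing, uniformly spaced screening charge
#'   densities (e/A^2).
#' @param p Nonnegative surface area per bin (A^2), total area positive.
#' @param elements Optional named numeric vector of area-weighted element
#'   composition (fractions summing to 1), used for the dispersion term.
#' @return An object of class `"sigma_profile"`.
#' @export
sigma_profile <- function(grid, p, elements = NULL) {
  grid <- as.numeric(grid); p <- as.numeric(p)
  if (length(grid) < 2L || length(grid) != length(p))
    stop("grid and p must have equal length >= 2")
  d <- diff(grid)
  if (any(d <= 0) || max(abs(d - d[1L])) > 1e-9 * abs(d[1L]))
    stop("grid must be strictly increasing and uniform")
  if (any(p < 0) || sum(p) <= 0)
    stop("bin areas must be nonnegative with positive total")
  if (!is.null(elements)) {
    if (is.null(names(elements)) || any(elements < 0))
      stop("elements must be a named nonnegative vector")
    elements <- elements / sum(elements)
  }
  structure(list(grid = grid, p = p, elements = elements),
            class = "sigma_profile")
}

#' Default sigma grid
#'
#' 61 uniform bins on \[-0.03, 0.03\] e/A^2, the conventional screening
#' charge density range.
#'
#' @param n Number of bins.
#' @param range Grid endpoints (e/A^2).
#' @return Numeric vector of bin centres.
#' @export
default_sigma_grid <- function(n = 61L, range = c(-0.03, 0.03)) {
  seq(range[1L], range[2L], length.out = n)
}

#' Contact interaction parameters
#'
#' @param a_eff Effective contact area (A^2).
#' @param alpha_prime Misfit coefficient (kcal/mol A^2 per (e/A^2)^2).
#' @param c_hb Hydrogen-bond coefficient (same units); the adopted sign
#'   convention makes the hydrogen-bond energy attractive (<= 0) for
#'   `c_hb > 0`.
#' @param sigma_hb Hydrogen-bond polarity threshold (e/A^2).
#' @param tau_vdw Named numeric vector of per-element dispersion
#'   coefficients (kcal/mol/A^2).
#' @param c_vdw Overall dispersion multiplier (dimensionless).
#' @return An object of class `"contact_params"`.
#' @export
contact_params <- function(a_eff = 6.25, alpha_prime = 5950, c_hb = 35000,
                           sigma_hb = 0.0084,
                           tau_vdw = c(H = -0.01, C = -0.03, N = -0.04,
                                       O = -0.05, S = -0.06),
                           c_vdw = 1) {
  if (a_eff <= 0) stop("a_eff must be positive")
  if (sigma_hb < 0) stop("sigma_hb must be nonnegative")
  structure(list(a_eff = a_eff, alpha_prime = alpha_prime, c_hb = c_hb,
                 sigma_hb = sigma_hb, tau_vdw = tau_vdw, c_vdw = c_vdw),
            class = "contact_params")
}

#' Misfit (electrostatic) pair energy
#'
#' `a_eff * (alpha'/2) * (sigma + sigma')^2`: the penalty for imperfect
#' mutual screening of two contacting segments; zero for a perfectly
#' screening pair (`sigma = -sigma'`), never negative.
#'
#' @param sigma,sigma_prime Screening charge densities (e/A^2);
#'   vectorized.
#' @param params A [contact_params()].
#' @return Energy, kcal/mol.
#' @export
misfit_energy <- function(sigma, sigma_prime, params = contact_params()) {
  params$a_eff * (params$alpha_prime / 2) * (sigma + sigma_prime)^2
}

#' Hydrogen-bond pair energy
#'
#' Nonzero only when the more negative segment (donor side) is below
#' `-sigma_hb` and the more positive (acceptor side) above `+sigma_hb`;
#' then attractive and increasingly negative for more polar opposite
#' pairs.
#'
#' @inheritParams misfit_energy
#' @return Energy, kcal/mol (<= 0 for `c_hb > 0`).
#' @export
hbond_energy <- function(sigma, sigma_prime, params = contact_params()) {
  s_don <- pmin(sigma, sigma_prime)
  s_acc <- pmax(sigma, sigma_prime)
  params$a_eff * params$c_hb *
    pmin(0, pmin(0, s_don + params$sigma_hb) * pmax(0, s_acc - params$sigma_hb))
}

#' Van der Waals pair energy for an element pair
#'
#' Depends only on the element types of the contacting atoms:
#' `a_eff * c_vdw * (tau + tau')`.
#'
#' @param element,element_prime Element symbols present in
#'   `params$tau_vdw`.
#' @param params A [contact_params()].
#' @return Energy, kcal/mol.
#' @export
vdw_energy <- function(element, element_prime, params = contact_params()) {
  tau <- params$tau_vdw
  unknown <- setdiff(unique(c(element, element_prime)), names(tau))
  if (length(unknown))
    stop("unknown element(s) in tau table: ", paste(unknown, collapse = ", "))
  params$a_eff * params$c_vdw * (tau[element] + tau[element_prime])
}

pair_energy_matrix <- function(grid, params, vdw_shift = 0) {
  s <- outer(grid, grid, "+") # only the sum enters the misfit term
  e_mf <- params$a_eff * (params$alpha_prime / 2) * s^2
  e_hb <- outer(grid, grid, hbond_energy, params = params)
  list(misfit = e_mf, hbond = e_hb, total = e_mf + e_hb + vdw_shift)
}

#' Solve the self-consistent sigma-potential of a solvent
#'
#' Damped fixed-point iteration of the discrete segment free-energy
#' equation
#' `mu(s) = -(RT/a_eff) log sum_s' P(s') exp{[a_eff mu(s') - E_mf(s,s') -
#' E_hb(s,s')] / RT}`
#' over the normalized profile `P` (bin areas rescaled to sum to one).
#' When all pair energies vanish the fixed point is `mu == 0`.
#'
#' @param profile A [sigma_profile()] of the (mixture) solvent.
#' @param params A [contact_params()].
#' @param temperature Temperature, K.
#' @param damping Update damping factor in `(0, 1]`.
#' @param tol Convergence tolerance on the max update (kcal/mol/A^2).
#' @param max_iter Iteration cap; hitting it flags `converged = FALSE`
#'   (with a warning) rather than failing silently.  Strongly
#'   hydrogen-bonding profiles converge geometrically but slowly at room
#'   temperature, hence the generous default.
#' @return An object of class `"sigma_potential"` with fields `grid`,
#'   `mu` (kcal/mol/A^2), `temperature`, `converged`, `iterations`.
#' @export
solve_sigma_potential <- function(profile, params = contact_params(),
                                  temperature = 298.15, damping = 0.4,
                                  tol = 1e-8, max_iter = 3000L) {
  stopifnot(inherits(profile, "sigma_profile"))
  if (temperature <= 0) stop("temperature must be positive")
  grid <- profile$grid
  pw <- profile$p / sum(profile$p)
  rt <- R_KCAL * temperature
  em <- pair_energy_matrix(grid, params)
  e_tot <- em$misfit + em$hbond # n x n, rows: sigma, cols: sigma'
  mu <- numeric(length(grid))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # log-sum-exp over sigma' for numerical stability
    z <- sweep(-e_tot / rt, 2L, params$a_eff * mu / rt, "+")
    zmax <- apply(z, 1L, max)
    lse <- zmax + log((exp(z - zmax) %*% pw)[, 1L])
    mu_new <- -(rt / params$a_eff) * lse
    delta <- max(abs(mu_new - mu))
    mu <- mu + damping * (mu_new - mu)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("sigma-potential iteration did not converge in ", max_iter,
            " steps (last update ", format(delta), ")")
  structure(list(grid = grid, mu = mu, temperature = temperature,
                 converged = converged, iterations = iter,
                 params = params),
            class = "sigma_potential")
}

#' Residual chemical potential of a solute in a solvent
#'
#' Integrates the solvent's sigma-potential over the solute's surface:
#' `sum_s p_solute(s) * mu_solvent(s)` (area times energy-per-area).
#' Zero in the ideal limit `mu == 0`.
#'
#' @param solute_profile A [sigma_profile()]; its bin areas are taken as
#'   absolute areas (A^2).
#' @param solvent_potential A [sigma_potential][solve_sigma_potential]
#'   on the same grid.
#' @return Energy, kcal/mol.
#' @export
residual_chemical_potential <- function(solute_profile, solvent_potential) {
  stopifnot(inherits(solute_profile, "sigma_profile"),
            inherits(solvent_potential, "sigma_potential"))
  if (length(solute_profile$grid) != length(solvent_potential$grid) ||
      max(abs(solute_profile$grid - solvent_potential$grid)) > 1e-12)
    stop("solute and solvent grids do not match")
  sum(solute_profile$p * solvent_potential$mu)
}

#' Mean interaction energies of a pure component
#'
#' Expectation of each pair-energy term over the equilibrium contact
#' distribution `p(s, s') ~ P(s) P(s') exp{[a_eff(mu(s) + mu(s')) -
#' E_tot(s, s')] / RT}`.  The dispersion term is a constant per contact,
#' computed from the area-weighted element composition.
#'
#' @param profile A [sigma_profile()] of the pure component (with
#'   `elements` set if a dispersion mean is wanted).
#' @param potential Its converged [sigma_potential][solve_sigma_potential].
#' @param params A [contact_params()].
#' @return Named numeric `c(e_misfit, e_hb, e_vdw)`, kcal/mol.
#' @export
mean_interaction_energies <- function(profile, potential,
                                      params = contact_params()) {
  stopifnot(inherits(profile, "sigma_profile"),
            inherits(potential, "sigma_potential"))
  if (!potential$converged)
    stop("refusing to average over an unconverged sigma-potential")
  grid <- profile$grid
  pw <- profile$p / sum(profile$p)
  rt <- R_KCAL * potential$temperature
  em <- pair_energy_matrix(grid, params)
  e_tot <- em$misfit + em$hbond
  lw <- outer(params$a_eff * potential$mu, params$a_eff * potential$mu, "+") / rt -
    e_tot / rt + log(outer(pw, pw))
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  e_vdw <- 0
  if (!is.null(profile$elements)) {
    tau <- params$tau_vdw
    unknown <- setdiff(names(profile$elements), names(tau))
    if (length(unknown))
      stop("unknown element(s) in tau table: ", paste(unknown, collapse = ", "))
    # E[tau + tau'] over independent element draws = 2 * sum w_el tau_el
    e_vdw <- 2 * params$a_eff * params$c_vdw *
      sum(profile$elements * tau[names(profile$elements)])
  }
  c(e_misfit = sum(w * em$misfit), e_hb = sum(w * em$hbond), e_vdw = e_vdw)
}

#' Residual log activity coefficient from the sigma engine
#'
#' `ln gamma = [mu_solute(in mixture) - mu_solute(in pure solute)] / RT`,
#' where the mixture profile blends the solute and solvent profiles at
#' the current solute mole fraction.  Tends to zero as the solute profile
#' approaches the solvent profile.
#'
#' @param x Solute mole fraction in `(0, 1]`.
#' @param solute_profile,solvent_profile [sigma_profile()]s on a shared
#'   grid.
#' @param params A [contact_params()].
#' @param temperature Temperature, K.
#' @return `ln gamma` (dimensionless).
#' @export
sigma_ln_gamma <- function(x, solute_profile, solvent_profile,
                           params = contact_params(), temperature = 298.15) {
  mix_p <- x * solute_profile$p / sum(solute_profile$p) +
    (1 - x) * solvent_profile$p / sum(solvent_profile$p)
  mix <- sigma_profile(solute_profile$grid, mix_p)
  pot_mix <- solve_sigma_potential(mix, params, temperature)
  pure <- sigma_profile(solute_profile$grid,
                        solute_profile$p / sum(solute_profile$p))
  pot_self <- solve_sigma_potential(pure, params, temperature)
  rt <- R_KCAL * temperature
  (residual_chemical_potential(pure, pot_mix) -
      residual_chemical_potential(pure, pot_self)) / rt
}
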