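test_that("pair energies follow the segment-contact formulas", {
  p <- contact_params(a_eff = 1, alpha_prime = 2, c_hb = 1,
                      sigma_hb = 0.008)
  # misfit: perfectly screening contact, direct arithmetic, symmetry
  expect_equal(misfit_energy(0.013, -0.013, p), 0)
  expect_equal(misfit_energy(0.01, 0.01, p), 4e-4)
  expect_gte(min(misfit_energy(runif(20, -0.03, 0.03),
                               runif(20, -0.03, 0.03), p)), 0)
  expect_equal(misfit_energy(0.004, -0.011, p),
               misfit_energy(-0.011, 0.004, p))

  # hydrogen bond: apolar and threshold-boundary contacts give zero,
  # polar opposite pair matches the adopted form, attractive sign
  expect_equal(hbond_energy(0, 0, p), 0)
  expect_equal(hbond_energy(-0.008, 0.02, p), 0)
  expect_equal(hbond_energy(-0.02, 0.005, p), 0)
  expect_equal(hbond_energy(-0.02, 0.02, p), -1.44e-4)
  expect_equal(hbond_energy(-0.02, 0.02, p), hbond_energy(0.02, -0.02, p))
  # more polar opposite pair => more negative
  expect_lt(hbond_energy(-0.025, 0.025, p), hbond_energy(-0.015, 0.015, p))

  # dispersion: tau-sum form, element symmetry, unknown elements named
  pv <- contact_params(a_eff = 1, tau_vdw = c(C = -0.01, O = -0.02, X = 0))
  expect_equal(unname(vdw_energy("X", "X", pv)), 0)
  expect_equal(unname(vdw_energy("C", "O", pv)), -0.03)
  expect_equal(unname(vdw_energy("C", "O", pv)),
               unname(vdw_energy("O", "C", pv)))
  expect_error(vdw_energy("C", "Zr", pv), "Zr")
})

test_that("sigma-potential solver finds the self-consistent fixed point", {
  profiles <- generate_toy_sigma_profiles(3, seed = 2)
  zero <- contact_params(alpha_prime = 0, c_hb = 0)

  # zero pair energies: mu identically zero at any temperature
  for (temp in c(298.15, 596.3)) {
    pot <- solve_sigma_potential(profiles$apolar, zero, temperature = temp)
    expect_true(pot$converged)
    expect_lt(max(abs(pot$mu)), 1e-12)
  }

  # misfit-only params with a sigma-symmetric profile: mu is even
  mf_only <- contact_params(c_hb = 0)
  sym <- profiles$polar # built from mirrored Gaussians
  expect_equal(sym$p, rev(sym$p))
  pot <- solve_sigma_potential(sym, mf_only)
  expect_true(pot$converged)
  expect_equal(pot$mu, rev(pot$mu), tolerance = 1e-6)

  # idempotence: re-solving a converged potential moves nothing
  full <- contact_params()
  pot1 <- solve_sigma_potential(profiles$random2, full)
  expect_true(pot1$converged)
  pot2 <- solve_sigma_potential(profiles$random2, full)
  expect_equal(pot1$mu, pot2$mu)

  # non-convergence is flagged, not silent
  expect_warning(
    pot_nc <- solve_sigma_potential(profiles$polar, full, max_iter = 2L),
    "did not converge")
  expect_false(pot_nc$converged)
  expect_error(mean_interaction_energies(profiles$polar, pot_nc),
               "unconverged")
})

test_that("residual chemical potential integrates the solute surface", {
  profiles <- generate_toy_sigma_profiles(2, seed = 5)
  zero <- contact_params(alpha_prime = 0, c_hb = 0)
  pot0 <- solve_sigma_potential(profiles$polar, zero)
  expect_equal(residual_chemical_potential(profiles$apolar, pot0), 0)

  # narrow solute collapsed onto one bin picks out that bin's mu
  pot <- solve_sigma_potential(profiles$polar, contact_params())
  grid <- profiles$polar$grid
  onebin <- rep(0, length(grid)); onebin[20] <- 2.5
  narrow <- sigma_profile(grid, onebin)
  expect_equal(residual_chemical_potential(narrow, pot), 2.5 * pot$mu[20])

  other <- sigma_profile(default_sigma_grid(31), rep(1, 31))
  expect_error(residual_chemical_potential(other, pot), "grid")
})

test_that("mean interaction energies match the O(n^2) double-sum oracle", {
  profiles <- generate_toy_sigma_profiles(3, seed = 9,
                                          grid = default_sigma_grid(41))
  params <- contact_params()
  for (nm in c("polar", "random2")) {
    pr <- profiles[[nm]]
    pr$elements <- c(C = 0.5, O = 0.3, H = 0.2)
    pot <- solve_sigma_potential(pr, params)
    got <- mean_interaction_energies(pr, pot, params)
    want <- oracle_mean_energies(pr, pot, params)
    expect_equal(got[["e_misfit"]], want[["e_misfit"]], tolerance = 1e-10)
    expect_equal(got[["e_hb"]], want[["e_hb"]], tolerance = 1e-10)
    # sign conventions: misfit repulsive, hydrogen bond attractive
    expect_gte(got[["e_misfit"]], 0)
    expect_lte(got[["e_hb"]], 0)
    # dispersion from area-weighted element composition
    expect_equal(got[["e_vdw"]],
                 2 * params$a_eff * sum(pr$elements *
                                          params$tau_vdw[names(pr$elements)]))
  }
  # zero-energy params give a zero triple; misfit-only kills the HB term
  pr <- profiles$polar
  pot0 <- solve_sigma_potential(pr, contact_params(alpha_prime = 0, c_hb = 0))
  e0 <- mean_interaction_energies(pr, pot0,
                                  contact_params(alpha_prime = 0, c_hb = 0))
  expect_equal(unname(e0[c("e_misfit", "e_hb")]), c(0, 0))
  mf <- contact_params(c_hb = 0)
  emf <- mean_interaction_energies(pr, solve_sigma_potential(pr, mf), mf)
  expect_equal(emf[["e_hb"]], 0)
})

test_that("residual ln gamma vanishes as solute approaches solvent", {
  profiles <- generate_toy_sigma_profiles(2, seed = 13)
  params <- contact_params()
  lg_self <- sigma_ln_gamma(0.3, profiles$polar, profiles$polar, params)
  expect_equal(lg_self, 0, tolerance = 1e-6)
  lg <- sigma_ln_gamma(0.05, profiles$apolar, profiles$polar, params)
  expect_true(is.finite(lg))
})
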