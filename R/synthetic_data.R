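# Seeded synthetic data with the statistical structure the analysis
# assumes: a component pool with interaction-energy triples, a record
# table shaped like the experimental campaign (neat solvents, aqueous
# binary series, neat eutectics and water-diluted eutectics; 160 records
# at the defaults), and log10 solubilities from a known nonlinear
# response plus Gaussian noise, with the ground truth stored alongside
# for recovery tests.

#' Specification for the synthetic-data generator
#'
#' Defaults emulate the experimental campaign: 12 neat solvents (water
#' included, once repeated at 287.65 K as the cold-water record), 5
#' aqueous binary pairs at 12 compositions, 7 neat ChCl eutectics, and
#' water-diluted eutectic records filling the table to 160 rows.
#'
#' @param n_neat Number of neat solvent components.
#' @param n_binary_pairs Number of aqueous binary pairs.
#' @param n_binary_fracs Compositions per binary series.
#' @param n_nades Number of eutectic (hydrogen-bond donor) candidates.
#' @param n_total Total number of records.
#' @param noise_sd Gaussian noise on log10 x (log10 units).
#' @param seed Integer seed.
#' @param truth Coefficients `(b0, b1, b2, b3, b4)` of the ground-truth
#'   response (see [generate_records()]).
#' @param temperature_jitter_sd SD of the kelvin-scale jitter emulating
#'   bath-temperature variation between measurement series.
#' @return A list of class `"generator_spec"`.
#' @export
generator_spec <- function(n_neat = 12L, n_binary_pairs = 5L,
                           n_binary_fracs = 12L, n_nades = 7L,
                           n_total = 160L, noise_sd = 0.03, seed = 1L,
                           truth = c(b0 = -3.0, b1 = 1.2, b2 = 0.6,
                                     b3 = -0.15, b4 = 0.3),
                           temperature_jitter_sd = 0.3) {
  stopifnot(noise_sd >= 0, n_neat >= 2L, n_binary_pairs >= 0L,
            n_binary_fracs >= 0L, n_nades >= 0L, length(truth) == 5L)
  structure(list(n_neat = as.integer(n_neat),
                 n_binary_pairs = as.integer(n_binary_pairs),
                 n_binary_fracs = as.integer(n_binary_fracs),
                 n_nades = as.integer(n_nades),
                 n_total = as.integer(n_total),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 truth = truth,
                 temperature_jitter_sd = temperature_jitter_sd),
            class = "generator_spec")
}

#' Generate the synthetic component pool
#'
#' Energy triples are drawn as `E_misfit ~ U(0.1, 3.0)`,
#' `E_hb ~ U(-4.0, 0)`, `E_vdw ~ U(-3.0, -0.5)` kcal/mol (misfit
#' repulsive, hydrogen bonding and dispersion attractive); draws are
#' rejected until the triple sum is at most -0.5 kcal/mol.  A net
#' attractive total is what condensing liquids require, it guarantees
#' well-defined relative contributions, and it keeps the relative
#' descriptors on a common sign convention across the pool (a
#' near-zero or sign-flipping denominator would make them unbounded and
#' physically meaningless).  Deterministic per seed.  The pool comprises
#' water, `n_neat - 1` organic solvents, the ChCl acceptor salt and
#' `n_nades` donor candidates.
#'
#' @param spec A [generator_spec()].
#' @return A component data frame.
#' @export
generate_components <- function(spec = generator_spec()) {
  draw_triple <- function(nm, role) {
    repeat {
      tr <- c(runif(1, 0.1, 3.0), runif(1, -4.0, 0), runif(1, -3.0, -0.5))
      if (sum(tr) <= -0.5) break
    }
    component(nm, tr[1L], tr[2L], tr[3L], role = role)
  }
  withr::with_seed(spec$seed, {
    out <- list(draw_triple("water", "water"))
    for (i in seq_len(spec$n_neat - 1L))
      out[[length(out) + 1L]] <- draw_triple(sprintf("solv%02d", i), "solvent")
    out[[length(out) + 1L]] <- draw_triple("ChCl", "hba")
    for (i in seq_len(spec$n_nades))
      out[[length(out) + 1L]] <- draw_triple(sprintf("hbd%02d", i), "hbd")
    do.call(component_table, out)
  })
}

truth_response <- function(desc, truth) {
  unname(truth[1L] + truth[2L] * desc["e_hb"] +
           truth[3L] * tanh(2 * desc["e_misfit"] - 1) +
           truth[4L] * desc["E_vdw"] +
           truth[5L] * (desc["T_K"] - 298.15) / 100)
}

#' Evaluate the generator's ground-truth response on descriptors
#'
#' `log10 x = b0 + b1 e_hb + b2 tanh(2 e_misfit - 1) + b3 E_vdw +
#' b4 (T - 298.15)/100`, clipped so `x` stays within `(1e-6, 0.5)`;
#' nonlinear in exactly the descriptors the model sees.
#'
#' @param features Descriptor matrix (columns as in
#'   [build_feature_matrix()]) or a single descriptor vector.
#' @param truth Coefficient vector `(b0, b1, b2, b3, b4)`.
#' @return Noise-free log10 mole-fraction solubilities.
#' @export
truth_surface <- function(features, truth = generator_spec()$truth) {
  if (is.null(dim(features)))
    features <- matrix(features, nrow = 1L,
                       dimnames = list(NULL, names(features)))
  vals <- apply(features, 1L, truth_response, truth = truth)
  unname(pmin(pmax(vals, log10(1e-6)), log10(0.5)))
}

#' Generate synthetic solubility records
#'
#' Builds the system roster (neat solvents incl. one cold-water repeat,
#' aqueous binary series, neat 1:1 eutectics, then water-diluted
#' eutectics until `n_total` records exist), evaluates the ground truth
#' on each system's mixture descriptor, adds `N(0, noise_sd)` noise on
#' the log10 scale and clips the mole fraction to `(1e-6, 0.5)`.
#'
#' @param spec A [generator_spec()].
#' @param components Component pool (default regenerated from `spec`).
#' @return List: `records` (long-format data frame), `components`,
#'   `truth` (data frame `system_id`, `log10x_true`), `spec`.
#' @export
generate_records <- function(spec = generator_spec(),
                             components = generate_components(spec)) {
  systems <- list()
  add <- function(sys) systems[[length(systems) + 1L]] <<- sys
  organics <- components$name[components$role == "solvent"]
  hbds <- components$name[components$role == "hbd"]
  for (nm in c("water", organics)) add(solvent_system(nm, 1, "neat"))
  add(solvent_system("water", 1, "neat", temperature = 287.65,
                     id = "water@287.65K"))
  fr_grid <- seq_len(spec$n_binary_fracs) / (spec$n_binary_fracs + 1L)
  for (nm in utils::head(organics, spec$n_binary_pairs)) for (f in fr_grid)
    add(solvent_system(c(nm, "water"), c(f, 1 - f), "binary"))
  for (nm in hbds)
    add(solvent_system(c("ChCl", nm), c(0.5, 0.5), "nades",
                       id = paste0("ChCl+", nm)))
  dilution <- expand.grid(hbd = hbds, f = fr_grid,
                          stringsAsFactors = FALSE)
  i <- 0L
  while (length(systems) < spec$n_total && i < nrow(dilution)) {
    i <- i + 1L
    f <- dilution$f[i]
    add(solvent_system(c("ChCl", dilution$hbd[i], "water"),
                       c(f / 2, f / 2, 1 - f), "nades_water",
                       id = paste0("ChCl+", dilution$hbd[i], "+water@",
                                   format(f))))
  }
  systems <- systems[seq_len(min(length(systems), spec$n_total))]
  withr::with_seed(spec$seed + 1L, {
    jit <- rnorm(length(systems), 0, spec$temperature_jitter_sd)
    eps <- rnorm(length(systems), 0, spec$noise_sd)
  })
  records <- vector("list", length(systems))
  truth_log <- numeric(length(systems))
  for (k in seq_along(systems)) {
    sys <- systems[[k]]
    if (sys$id != "water@287.65K") sys$temperature <- sys$temperature + jit[k]
    desc <- mixture_descriptor(sys, components)
    truth_log[k] <- truth_surface(desc, spec$truth)
    x_obs <- 10^(truth_log[k] + eps[k])
    x_obs <- min(max(x_obs, 1e-6), 0.5)
    records[[k]] <- solubility_record(sys, x_obs)
  }
  records <- do.call(rbind, records)
  list(records = validate_records(records), components = components,
       truth = data.frame(system_id = vapply(systems, `[[`, character(1), "id"),
                          log10x_true = truth_log),
       spec = spec)
}

#' Generate toy sigma-profiles
#'
#' Mixtures of one to three Gaussians on the default sigma grid,
#' area-normalized.  Every batch starts with one symmetric apolar
#' profile (single Gaussian at zero) and one polar donor/acceptor
#' profile (Gaussians at -0.015 and +0.015 e/A^2); the rest are random.
#' Deterministic per seed.
#'
#' @param n Number of profiles (>= 1).
#' @param seed Integer seed.
#' @param grid Sigma grid (default [default_sigma_grid()]).
#' @return List of [sigma_profile()]s.
#' @export
generate_toy_sigma_profiles <- function(n, seed = 1L,
                                        grid = default_sigma_grid()) {
  stopifnot(n >= 1L)
  gauss <- function(mu, s) exp(-(grid - mu)^2 / (2 * s^2))
  normalize <- function(p) sigma_profile(grid, p / sum(p))
  withr::with_seed(seed, {
    out <- list(apolar = normalize(gauss(0, 0.004)))
    if (n >= 2L)
      out$polar <- normalize(gauss(-0.015, 0.004) + gauss(0.015, 0.004))
    while (length(out) < n) {
      k <- sample(1:3, 1L)
      p <- Reduce(`+`, lapply(seq_len(k), function(i)
        runif(1, 0.3, 1) * gauss(runif(1, -0.02, 0.02), runif(1, 0.002, 0.008))))
      out[[paste0("random", length(out))]] <- normalize(p)
    }
    out
  })
}
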