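# Seven-descriptor feature construction.
#
# Each record is described by the absolute mean interaction-energy triple
# (misfit, H-bond, van der Waals), the same triple as relative fractions
# of their sum, and the temperature.  Multicomponent solvents mix every
# energy-derived descriptor linearly with solute-free mole fraction.

DESCRIPTOR_NAMES <- c("E_misfit", "E_hb", "E_vdw",
                      "e_misfit", "e_hb", "e_vdw", "T_K")

#' Relative interaction-energy contributions of a component
#'
#' Each term of the energy triple divided by the triple's sum, so the
#' three relative descriptors always sum to one.
#'
#' @param comp A one-row component data frame (or any list with
#'   `e_misfit`, `e_hb`, `e_vdw`).
#' @return Named numeric `c(e_misfit_rel, e_hb_rel, e_vdw_rel)`.
#' @export
relative_contributions <- function(comp) {
  triple <- c(comp$e_misfit[1L], comp$e_hb[1L], comp$e_vdw[1L])
  tot <- sum(triple)
  if (!is.finite(tot) || tot == 0)
    stop("degenerate component: interaction-energy triple sums to zero")
  setNames(triple / tot, c("e_misfit_rel", "e_hb_rel", "e_vdw_rel"))
}

component_descriptors <- function(comp) {
  rel <- relative_contributions(comp)
  c(E_misfit = comp$e_misfit[1L], E_hb = comp$e_hb[1L], E_vdw = comp$e_vdw[1L],
    e_misfit = unname(rel[1L]), e_hb = unname(rel[2L]), e_vdw = unname(rel[3L]))
}

#' Descriptor vector of a (possibly multicomponent) solvent system
#'
#' The six energy-derived descriptors of each component are combined as a
#' mole-fraction-weighted sum; the temperature is appended as the seventh
#' descriptor.  Linear mixing preserves the unit sum of the relative
#' descriptors.
#'
#' @param system A [solvent_system()], or a data frame of record rows for
#'   a single system.
#' @param components Component table supplying the energy triples.
#' @return Named numeric vector of length 7
#'   (`E_misfit,E_hb,E_vdw,e_misfit,e_hb,e_vdw,T_K`).
#' @export
mixture_descriptor <- function(system, components) {
  if (is.data.frame(system)) {
    comp_names <- system$component
    fracs <- system$frac
    temperature <- system$temperature_K[1L]
  } else {
    stopifnot(inherits(system, "solvent_system"))
    comp_names <- system$components
    fracs <- system$fractions
    temperature <- system$temperature
  }
  if (abs(sum(fracs) - 1) > 1e-9)
    stop("solute-free mole fractions must sum to 1")
  missing_comp <- setdiff(comp_names, components$name)
  if (length(missing_comp))
    stop("missing component energies for: ",
         paste(missing_comp, collapse = ", "))
  acc <- numeric(6L)
  for (k in seq_along(comp_names)) {
    row <- components[match(comp_names[k], components$name), , drop = FALSE]
    acc <- acc + fracs[k] * component_descriptors(row)
  }
  c(acc, T_K = temperature)
}

#' Feature matrix and log-solubility targets for a record table
#'
#' @param records Long-format record data frame (see [read_records()]);
#'   row/system order is preserved.
#' @param components Component table supplying the energy triples.
#' @return List with `x` (n_systems x 7 matrix, columns
#'   `E_misfit,E_hb,E_vdw,e_misfit,e_hb,e_vdw,T_K`), `y` (log10
#'   mole-fraction solubility), and `system_id`.
#' @export
build_feature_matrix <- function(records, components) {
  validate_records(records)
  ids <- unique(records$system_id)
  missing_comp <- setdiff(unique(records$component), components$name)
  if (length(missing_comp))
    stop("missing component energies for: ",
         paste(missing_comp, collapse = ", "))
  x <- matrix(NA_real_, nrow = length(ids), ncol = 7L,
              dimnames = list(ids, DESCRIPTOR_NAMES))
  y <- numeric(length(ids))
  for (i in seq_along(ids)) {
    rows <- records[records$system_id == ids[i], , drop = FALSE]
    x[i, ] <- mixture_descriptor(rows, components)
    y[i] <- log10(rows$x_exp[1L])
  }
  list(x = x, y = y, system_id = ids)
}

#' Export a feature matrix with targets as CSV
#'
#' @param fm Result of [build_feature_matrix()].
#' @param path Output CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(system_id = fm$system_id, fm$x, log10_x = fm$y,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
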