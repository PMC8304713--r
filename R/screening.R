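# Candidate enumeration and ranked screening.
#
# Candidates are neat solvents, aqueous binary mixtures on a composition
# grid, or deep-eutectic (ChCl + hydrogen-bond donor, 1:1) formulations
# carrying 0.2 mole fraction of water -- the experimentally optimal
# dilution.  Each candidate system is converted to its descriptor
# vector, predicted with the range-filtered ensemble mean, flagged
# against the applicability domain, and ranked.

#' Enumerate neat-solvent candidates
#'
#' @param components Component table; one neat system per row.
#' @param temperature Temperature, K.
#' @param class_labels Optional named character vector of solvent-class
#'   tags (opaque labels carried into the ranking).
#' @return A list of [solvent_system()]s of class `"candidate_set"`.
#' @export
enumerate_neat <- function(components, temperature = 298.15,
                           class_labels = NULL) {
  validate_components(components)
  systems <- lapply(components$name, function(nm)
    solvent_system(nm, 1, "neat", temperature))
  names(systems) <- vapply(systems, `[[`, character(1), "id")
  structure(list(category = "neat", systems = systems,
                 class_labels = class_labels),
            class = "candidate_set")
}

#' Enumerate aqueous binary-mixture candidates
#'
#' One system per (cosolvent, grid fraction): the cosolvent at
#' solute-free fraction `f` with water at `1 - f`.  Duplicate cosolvent
#' names are collapsed; water itself is skipped.
#'
#' @param components Component table of cosolvents.
#' @param fractions Cosolvent mole-fraction grid, strictly inside
#'   `(0, 1)`.
#' @param water_name Name of the water component.
#' @param temperature Temperature, K.
#' @return A `"candidate_set"` of binary systems.
#' @export
enumerate_binary <- function(components, fractions, water_name = "water",
                             temperature = 298.15) {
  validate_components(components)
  if (length(fractions) && any(fractions <= 0 | fractions >= 1))
    stop("binary grid fractions must lie strictly inside (0, 1)")
  solvents <- setdiff(unique(components$name), water_name)
  systems <- list()
  for (nm in solvents) for (f in fractions) {
    sys <- solvent_system(c(nm, water_name), c(f, 1 - f), "binary",
                          temperature)
    systems[[sys$id]] <- sys
  }
  structure(list(category = "binary", systems = systems,
                 class_labels = NULL),
            class = "candidate_set")
}

#' Enumerate deep-eutectic (NADES) candidates
#'
#' Each hydrogen-bond-donor candidate is formulated as the ternary
#' system ChCl : HBD : water = 0.4 : 0.4 : 0.2 -- a 1:1 eutectic
#' carrying the experimentally optimal 0.2 mole fraction of water.
#' Candidates missing from the component table are skipped with a
#' message; duplicate names are deduplicated.
#'
#' @param hbd_names Character vector of candidate donor names.
#' @param components Component table that must also contain `hba_name`
#'   and `water_name`.
#' @param water_fraction Overall water mole fraction (default 0.2).
#' @param hba_name,water_name Names of the acceptor salt and water.
#' @param temperature Temperature, K.
#' @return A `"candidate_set"` of ternary systems; skipped candidates
#'   are recorded in `$skipped`.
#' @export
enumerate_nades <- function(hbd_names, components, water_fraction = 0.2,
                            hba_name = "ChCl", water_name = "water",
                            temperature = 298.15) {
  validate_components(components)
  for (req in c(hba_name, water_name))
    if (!req %in% components$name)
      stop("component table lacks required component '", req, "'")
  hbd_names <- unique(as.character(hbd_names))
  known <- hbd_names %in% components$name
  if (any(!known))
    message("skipping ", sum(!known), " candidate(s) without energy triples: ",
            paste(utils::head(hbd_names[!known], 5L), collapse = ", "))
  half <- (1 - water_fraction) / 2
  systems <- list()
  for (nm in hbd_names[known]) {
    sys <- solvent_system(c(hba_name, nm, water_name),
                          c(half, half, water_fraction), "nades_water",
                          temperature,
                          id = paste0(hba_name, "+", nm, "+water@",
                                      format(1 - water_fraction)))
    systems[[sys$id]] <- sys
  }
  structure(list(category = "nades", systems = systems,
                 class_labels = NULL, skipped = hbd_names[!known]),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set [%s] with %d system(s)>\n",
              x$category, length(x$systems)))
  invisible(x)
}

#' Screen candidates with a fitted ensemble
#'
#' Computes the mixture descriptor of every candidate, predicts with the
#' range-filtered ensemble mean, flags each candidate against the
#' leverage-based applicability domain, and ranks by predicted
#' solubility (descending; ties broken by system id).  Candidates whose
#' predictions are all discarded are dropped from the ranking and
#' counted.
#'
#' @param candidates A `"candidate_set"` (or plain list of
#'   [solvent_system()]s).
#' @param ensemble A fitted [sann_ensemble][build_ensemble].
#' @param components Component table with energy triples for all
#'   candidate components.
#' @return Data frame of class `"screening_result"`: `rank`, `system`,
#'   `category`, `mean_log10x`, `x_pred`, `n_valid`, `inside_AD`, with
#'   the number of dropped candidates in `attr(, "n_dropped")` and the
#'   count of discarded member predictions in
#'   `attr(, "n_discarded_predictions")`.
#' @export
screen <- function(candidates, ensemble, components) {
  systems <- if (inherits(candidates, "candidate_set")) candidates$systems
             else candidates
  if (!length(systems))
    return(structure(data.frame(rank = integer(), system = character(),
                                category = character(),
                                mean_log10x = numeric(), x_pred = numeric(),
                                n_valid = integer(), inside_AD = logical()),
                     n_dropped = 0L, n_discarded_predictions = 0L,
                     class = c("screening_result", "data.frame")))
  feats <- t(vapply(systems, mixture_descriptor, numeric(7L),
                    components = components))
  pred <- predict(ensemble, feats)
  ad <- williams_report(ensemble, feats, targets = NULL)
  out <- data.frame(system = vapply(systems, `[[`, character(1), "id"),
                    category = vapply(systems, `[[`, character(1), "category"),
                    mean_log10x = pred$mean_log10x, x_pred = pred$x_pred,
                    n_valid = pred$n_used, inside_AD = ad$inside_domain,
                    stringsAsFactors = FALSE)
  dropped <- !pred$valid
  out <- out[!dropped, , drop = FALSE]
  out <- out[order(-out$mean_log10x, out$system), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", "system", "category", "mean_log10x", "x_pred",
                 "n_valid", "inside_AD")]
  rownames(out) <- NULL
  structure(out, n_dropped = sum(dropped),
            n_discarded_predictions = sum(pred$n_discarded),
            class = c("screening_result", "data.frame"))
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("Screening of %d candidate(s) (%d dropped, %d member predictions discarded)\n",
              nrow(x) + attr(x, "n_dropped"), attr(x, "n_dropped"),
              attr(x, "n_discarded_predictions")))
  print.data.frame(utils::head(x, 10L), row.names = FALSE, digits = 4)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}
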