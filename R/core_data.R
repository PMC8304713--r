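# Domain types and tabular I/O.
#
# Components and solubility records are carried as plain data frames so
# they round-trip losslessly through CSV; solvent systems are small S3
# objects.  Units: energies kcal/mol, temperature K, solubility mole
# fraction (log10 transform happens only in the model layer).

COMPONENT_ROLES <- c("solute", "solvent", "hba", "hbd", "water")
SYSTEM_CATEGORIES <- c("neat", "binary", "nades", "nades_water")

COMPONENT_COLUMNS <- c("name", "cas", "role", "e_misfit", "e_hb", "e_vdw",
                       "fusion_gibbs", "t_melt", "h_fus")
RECORD_COLUMNS <- c("system_id", "category", "component", "frac",
                    "temperature_K", "x_exp", "sd")

#' Create a component with its mean interaction-energy triple
#'
#' A component is a named chemical species (solute, solvent, hydrogen-bond
#' acceptor/donor, or water) characterised by its mean misfit,
#' hydrogen-bond and van der Waals interaction energies in the pure
#' liquid, plus optional fusion properties for solutes.
#'
#' @param name Component name (nonempty string).
#' @param e_misfit,e_hb,e_vdw Mean interaction energies, kcal/mol.
#' @param role One of `"solute"`, `"solvent"`, `"hba"`, `"hbd"`, `"water"`.
#' @param cas Optional CAS registry number.
#' @param fusion_gibbs Optional Gibbs energy of fusion, kcal/mol.
#' @param t_melt,h_fus Optional melting temperature (K) and enthalpy of
#'   fusion (kcal/mol), used when `fusion_gibbs` is not given.
#' @return A one-row data frame with the standard component columns.
#' @export
component <- function(name, e_misfit, e_hb, e_vdw, role = "solvent",
                      cas = NA_character_, fusion_gibbs = NA_real_,
                      t_melt = NA_real_, h_fus = NA_real_) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name) || is.na(name))
    stop("component 'name' must be a nonempty string")
  role <- match.arg(role, COMPONENT_ROLES)
  triple <- c(e_misfit, e_hb, e_vdw)
  if (length(triple) != 3L || any(!is.finite(triple)))
    stop("component '", name, "': energy triple must be finite")
  if (!is.na(t_melt) && t_melt <= 0)
    stop("component '", name, "': t_melt must be positive")
  data.frame(name = name, cas = as.character(cas), role = role,
             e_misfit = e_misfit, e_hb = e_hb, e_vdw = e_vdw,
             fusion_gibbs = as.numeric(fusion_gibbs),
             t_melt = as.numeric(t_melt), h_fus = as.numeric(h_fus),
             stringsAsFactors = FALSE)
}

#' Bind components into a component table
#'
#' @param ... One-row data frames from [component()], or data frames with
#'   the standard component columns.
#' @return A data frame, one row per component.
#' @export
component_table <- function(...) {
  out <- do.call(rbind, list(...))
  validate_components(out)
}

validate_components <- function(df) {
  missing_cols <- setdiff(COMPONENT_COLUMNS, names(df))
  if (length(missing_cols))
    stop("component table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(is.na(df$name) | !nzchar(df$name))
  if (length(bad))
    stop("component row ", bad[1L], ": blank name (column 'name')")
  for (col in c("e_misfit", "e_hb", "e_vdw")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop("component row ", bad[1L], ": non-finite value in column '", col, "'")
  }
  bad <- which(!is.na(df$t_melt) & df$t_melt <= 0)
  if (length(bad))
    stop("component row ", bad[1L], ": t_melt must be positive (column 't_melt')")
  df
}

#' Define a solvent system from components and solute-free mole fractions
#'
#' Compositions are always solute-free: fractions describe the solvent
#' phase only (the `x2*` / `xNADES*` convention for binary and
#' NADES-water series).
#'
#' @param components Character vector of component names.
#' @param fractions Numeric vector of solute-free mole fractions, summing
#'   to one.
#' @param category One of `"neat"`, `"binary"`, `"nades"`, `"nades_water"`.
#' @param temperature Temperature in kelvin (default 298.15).
#' @param id Optional system identifier; a default is derived from the
#'   composition.
#' @return An object of class `"solvent_system"`.
#' @export
solvent_system <- function(components, fractions, category,
                           temperature = 298.15, id = NULL) {
  category <- match.arg(category, SYSTEM_CATEGORIES)
  components <- as.character(components)
  fractions <- as.numeric(fractions)
  if (length(components) != length(fractions))
    stop("components and fractions differ in length")
  if (any(fractions < 0 | fractions > 1))
    stop("mole fractions must lie in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("solute-free mole fractions must sum to 1 (got ",
         format(sum(fractions)), ")")
  if (category == "neat" && length(components) != 1L)
    stop("a neat system has exactly one component")
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive (kelvin)")
  if (is.null(id)) {
    id <- paste(components, collapse = "+")
    if (length(components) > 1L)
      id <- paste0(id, "@", format(fractions[1L], trim = TRUE))
  }
  structure(list(id = id, components = components, fractions = fractions,
                 category = category, temperature = temperature),
            class = "solvent_system")
}

#' @export
print.solvent_system <- function(x, ...) {
  comp <- paste(sprintf("%s (%.3g)", x$components, x$fractions), collapse = ", ")
  cat(sprintf("<solvent_system %s [%s] %s at %.2f K>\n",
              x$id, x$category, comp, x$temperature))
  invisible(x)
}

#' Convert a solvent system to long-format record rows
#'
#' @param system A [solvent_system()].
#' @param x_exp Measured solute mole fraction in `(0, 1)`.
#' @param sd Optional standard deviation of `x_exp`.
#' @return A data frame in the long record layout (one row per solvent
#'   component).
#' @export
solubility_record <- function(system, x_exp, sd = NA_real_) {
  stopifnot(inherits(system, "solvent_system"))
  if (!is.finite(x_exp) || x_exp <= 0 || x_exp >= 1)
    stop("x_exp must be a mole fraction strictly inside (0, 1)")
  if (!is.na(sd) && sd < 0) stop("sd must be nonnegative")
  data.frame(system_id = system$id, category = system$category,
             component = system$components, frac = system$fractions,
             temperature_K = system$temperature,
             x_exp = x_exp, sd = as.numeric(sd),
             stringsAsFactors = FALSE)
}

validate_records <- function(df) {
  missing_cols <- setdiff(RECORD_COLUMNS, names(df))
  if (length(missing_cols))
    stop("record table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(df$x_exp) | df$x_exp <= 0 | df$x_exp >= 1)
  if (length(bad))
    stop("record row ", bad[1L], ": x_exp outside (0, 1) (column 'x_exp')")
  bad <- which(!is.na(df$sd) & df$sd < 0)
  if (length(bad))
    stop("record row ", bad[1L], ": negative sd (column 'sd')")
  fs <- tapply(df$frac, df$system_id, sum)
  off <- names(fs)[abs(fs - 1) > 1e-9]
  if (length(off))
    stop("system '", off[1L], "': solute-free fractions do not sum to 1")
  df
}

#' Rebuild solvent systems from a long record table
#'
#' @param records Long-format record data frame.
#' @return A named list of [solvent_system()] objects keyed by system id.
#' @export
systems_from_records <- function(records) {
  validate_records(records)
  ids <- unique(records$system_id)
  out <- lapply(ids, function(sid) {
    rows <- records[records$system_id == sid, , drop = FALSE]
    solvent_system(rows$component, rows$frac, rows$category[1L],
                   rows$temperature_K[1L], id = sid)
  })
  names(out) <- ids
  out
}

# ---- packaged experimental fixture ---------------------------------------

#' Experimental theophylline solubility fixture
#'
#' Mole-fraction solubilities of theophylline at 25 degrees C in seven
#' neat solvents, five aqueous binary mixtures at their unimolar optimum
#' (x2* = 0.5), five neat choline chloride (ChCl) deep eutectics in 1:1
#' proportion, and four NADES-water mixtures at the xNADES* = 0.8
#' optimum, with reported standard deviations.  Values are the
#' experimental mole fractions (e.g. DMSO 70.96e-4, water 6.10e-4,
#' ChCl+glycerol+water at 0.8 146.57e-4).
#'
#' @return A long-format record data frame (one row per solvent
#'   component of each system).
#' @export
build_fixture <- function() {
  t25 <- 298.15
  neat <- function(name, x, s, role = "solvent")
    solubility_record(solvent_system(name, 1, "neat", t25), x * 1e-4, s * 1e-4)
  binw <- function(name, x, s) {
    sys <- solvent_system(c(name, "water"), c(0.5, 0.5), "binary", t25)
    solubility_record(sys, x * 1e-4, s * 1e-4)
  }
  nades <- function(hbd, x, s) {
    sys <- solvent_system(c("ChCl", hbd), c(0.5, 0.5), "nades", t25,
                          id = paste0("ChCl+", hbd))
    solubility_record(sys, x * 1e-4, s * 1e-4)
  }
  nadesw <- function(hbd, x, s) {
    sys <- solvent_system(c("ChCl", hbd, "water"), c(0.4, 0.4, 0.2),
                          "nades_water", t25,
                          id = paste0("ChCl+", hbd, "+water@0.8"))
    solubility_record(sys, x * 1e-4, s * 1e-4)
  }
  out <- rbind(
    neat("DMSO", 70.96, 0.28),
    neat("DMF", 59.21, 0.43),
    neat("1,4-dioxane", 31.67, 0.58),
    neat("methanol", 13.64, 0.04),
    neat("1-propanol", 13.39, 0.13),
    neat("1-butanol", 10.23, 0.11),
    neat("water", 6.10, 0.12),
    binw("DMSO", 90.13, 0.56),
    binw("DMF", 76.41, 0.58),
    binw("1,4-dioxane", 62.37, 0.45),
    binw("1-butanol", 43.47, 0.22),
    binw("1-propanol", 35.03, 0.08),
    nades("glycerol", 128.17, 0.68),
    nades("sorbitol", 103.63, 1.20),
    nades("xylitol", 92.61, 0.94),
    nades("glucose", 73.45, 0.75),
    nades("fructose", 67.79, 0.72),
    nadesw("glycerol", 146.57, 0.72),
    nadesw("sorbitol", 123.83, 0.70),
    nadesw("xylitol", 113.94, 0.31),
    nadesw("glucose", 93.76, 0.96))
  validate_records(out)
}

#' Look up one solubility record by system id
#'
#' @param records Long-format record data frame (default the packaged
#'   fixture).
#' @param system_id System identifier, e.g. `"DMSO"`, `"DMSO+water@0.5"`,
#'   `"ChCl+glycerol"`, `"ChCl+glycerol+water@0.8"`.
#' @return A one-row data frame with `system_id`, `x_exp`, `sd`.
#' @export
fixture_lookup <- function(system_id, records = build_fixture()) {
  rows <- records[records$system_id == system_id, , drop = FALSE]
  if (!nrow(rows)) stop("no record with system id '", system_id, "'")
  unique(rows[, c("system_id", "category", "temperature_K", "x_exp", "sd")])
}

#' Solubility enhancement ratio between two records
#'
#' @param a,b One-row record data frames (anything with an `x_exp`
#'   column) or plain mole fractions.
#' @return `x_a / x_b`, dimensionless.
#' @export
enhancement_ratio <- function(a, b) {
  xa <- if (is.data.frame(a)) a$x_exp[1L] else as.numeric(a)
  xb <- if (is.data.frame(b)) b$x_exp[1L] else as.numeric(b)
  if (!is.finite(xb) || xb == 0) stop("reference solubility is zero")
  xa / xb
}

# ---- CSV I/O -------------------------------------------------------------

#' Read a component table from CSV
#'
#' Expects header `name,cas,role,e_misfit,e_hb,e_vdw,fusion_gibbs,t_melt,h_fus`;
#' extra columns are preserved.
#'
#' @param path CSV file path.
#' @return A validated component data frame.
#' @export
read_components <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  # all-NA columns come back logical; restore the declared types
  for (col in c("e_misfit", "e_hb", "e_vdw", "fusion_gibbs", "t_melt",
                "h_fus"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  if ("cas" %in% names(df)) df$cas <- as.character(df$cas)
  validate_components(df)
}

#' @rdname read_components
#' @param components Component data frame.
#' @export
write_components <- function(components, path) {
  validate_components(components)
  write.csv(components, path, row.names = FALSE)
  invisible(path)
}

#' Read and write long-format solubility record tables
#'
#' The long format has one row per solvent component of each system, with
#' header `system_id,category,component,frac,temperature_K,x_exp,sd`.
#' Round-trips are lossless; unknown columns are preserved.
#'
#' @param path CSV file path.
#' @return A validated record data frame.
#' @export
read_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("frac", "temperature_K", "x_exp", "sd"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  validate_records(df)
}

#' @rdname read_records
#' @param records Record data frame.
#' @export
write_records <- function(records, path) {
  validate_records(records)
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
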