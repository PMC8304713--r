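# Iterative solid-liquid-equilibrium solubility.
#
# At saturation the solute's chemical potential in the solid equals that
# in solution, giving ln(gamma x) = -max(0, dGfus)/RT with the pure
# supercooled melt as reference; the clamp keeps the activity of the
# solid at 1 above the melting point.  Solubility follows from a damped
# fixed point x <- x_ideal / gamma(x) with a pluggable activity model.

#' Gibbs energy of fusion from melting properties
#'
#' Standard approximation `dGfus = dHfus * (1 - T/Tm)` (heat-capacity
#' terms omitted).  Zero at the melting point, negative above it (later
#' clamped by the solver).
#'
#' @param t_melt Melting temperature, K.
#' @param h_fus Enthalpy of fusion, kcal/mol.
#' @param temperature Temperature of interest, K.
#' @return Energy, kcal/mol.
#' @export
fusion_gibbs_from_melting <- function(t_melt, h_fus, temperature) {
  if (t_melt <= 0 || h_fus <= 0) stop("t_melt and h_fus must be positive")
  h_fus * (1 - temperature / t_melt)
}

#' Ideal solubility from the Gibbs energy of fusion
#'
#' `x = exp(-max(0, dGfus)/RT)`: unity at (and above, via the clamp) the
#' melting point.
#'
#' @param fusion_gibbs Gibbs energy of fusion, kcal/mol.
#' @param temperature Temperature, K.
#' @return Mole fraction in `(0, 1]`.
#' @export
ideal_solubility <- function(fusion_gibbs, temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  exp(-max(0, fusion_gibbs) / (R_KCAL * temperature))
}

#' Activity-coefficient models for the SLE solver
#'
#' An activity model is a function `gamma(x, temperature)` returning a
#' positive finite activity coefficient on `(0, 1]`.
#'
#' * `ideal_activity()`: `gamma == 1`.
#' * `regular_solution_activity(A)`: one-parameter model
#'   `ln gamma = A (1 - x)^2`.
#' * `sigma_activity(...)`: residual model backed by the sigma engine
#'   ([sigma_ln_gamma()]); a structural stand-in, not a parametrized
#'   reproduction of any reference software.
#'
#' @return A function of class `"activity_model"`.
#' @export
ideal_activity <- function() {
  structure(function(x, temperature) rep(1, length(x)),
            class = c("activity_model", "function"))
}

#' @rdname ideal_activity
#' @param A Dimensionless interaction parameter.
#' @export
regular_solution_activity <- function(A) {
  structure(function(x, temperature) exp(A * (1 - x)^2),
            class = c("activity_model", "function"))
}

#' @rdname ideal_activity
#' @param solute_profile,solvent_profile [sigma_profile()]s on a shared
#'   grid.
#' @param params A [contact_params()].
#' @export
sigma_activity <- function(solute_profile, solvent_profile,
                           params = contact_params()) {
  structure(function(x, temperature)
    exp(sigma_ln_gamma(x, solute_profile, solvent_profile, params,
                       temperature)),
    class = c("activity_model", "function"))
}

#' Solve for the saturation mole fraction
#'
#' Damped fixed-point iteration on `ln x`:
#' `x_{k+1} = exp(-max(0, dGfus)/RT) / gamma(x_k)`, starting from the
#' ideal value, with `x` clipped to `(0, 1]` each step.  Convergence is
#' declared when the update of `ln x` drops below `tol`.
#'
#' @param fusion_gibbs Gibbs energy of fusion of the solute, kcal/mol
#'   (clamped at zero from below).
#' @param activity_model An [activity model][ideal_activity].
#' @param temperature Temperature, K.
#' @param tol Convergence tolerance on `|ln x_{k+1} - ln x_k|`.
#' @param max_iter Iteration cap; exceeding it flags `converged = FALSE`
#'   with a warning rather than failing silently.
#' @param damping Damping factor on the `ln x` update.
#' @param x_start Optional starting mole fraction (default: ideal value).
#' @return List of class `"sle_result"`: `x_sat`, `gamma_sat`,
#'   `iterations`, `converged`, `clamped`.
#' @export
solve_solubility <- function(fusion_gibbs, activity_model = ideal_activity(),
                             temperature = 298.15, tol = 1e-8,
                             max_iter = 200L, damping = 0.5, x_start = NULL) {
  if (temperature <= 0) stop("temperature must be positive")
  clamped <- fusion_gibbs < 0
  x_ideal <- ideal_solubility(fusion_gibbs, temperature)
  ln_x_ideal <- log(x_ideal)
  ln_x <- log(if (is.null(x_start)) x_ideal else x_start)
  if (ln_x > 0) stop("x_start must lie in (0, 1]")
  converged <- FALSE
  iter <- 0L
  gam <- 1
  for (iter in seq_len(max_iter)) {
    gam <- activity_model(exp(ln_x), temperature)
    if (!is.finite(gam) || gam <= 0)
      stop("activity model returned a non-positive gamma at x = ",
           format(exp(ln_x)))
    ln_x_new <- min(0, ln_x_ideal - log(gam))
    delta <- ln_x_new - ln_x
    ln_x <- ln_x + damping * delta
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("SLE iteration did not converge in ", max_iter, " steps")
  x_sat <- exp(ln_x)
  structure(list(x_sat = x_sat,
                 gamma_sat = as.numeric(activity_model(x_sat, temperature)),
                 iterations = iter, converged = converged,
                 clamped = clamped),
            class = "sle_result")
}

#' @export
print.sle_result <- function(x, ...) {
  cat(sprintf("<sle_result x_sat = %.6g, gamma_sat = %.6g, %s in %d iterations%s>\n",
              x$x_sat, x$gamma_sat,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, if (x$clamped) ", dGfus clamped at 0" else ""))
  invisible(x)
}
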