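# Ensemble of small single-hidden-layer regressors.
#
# Each candidate network has 6-12 hidden units and hidden/output transfer
# functions drawn from {identity, logistic, tanh, exponential, sine}, is
# trained by BFGS on the sum-of-squares error of the training subset
# with early stopping monitored on the test subset, and is accepted into
# the ensemble only if its whole-set RMSD (log10 mole-fraction scale) is
# below 0.04 with at most four outliers (|standardized residual| > 3).
# Ensemble predictions discard members implying mole fractions outside
# (0, 1) and average the survivors in log10 space.

ACTIVATIONS <- c("identity", "logistic", "tanh", "exponential", "sine")

act_fun <- function(name) {
  switch(name,
         identity = function(z) z,
         logistic = function(z) 1 / (1 + exp(-z)),
         tanh = tanh,
         exponential = function(z) exp(pmin(z, 30)),
         sine = sin,
         stop("unknown activation '", name, "'"))
}

act_grad <- function(name) {
  # derivative expressed through the pre-activation z
  switch(name,
         identity = function(z) rep(1, length(z)),
         logistic = function(z) { s <- 1 / (1 + exp(-z)); s * (1 - s) },
         tanh = function(z) 1 - tanh(z)^2,
         exponential = function(z) exp(pmin(z, 30)),
         sine = cos,
         stop("unknown activation '", name, "'"))
}

#' Split records into training / test / validation subsets
#'
#' Random 70/15/15 partition: `round(0.70 n)` training, `round(0.15 n)`
#' test, remainder validation.  Deterministic for a fixed seed.
#'
#' @param n Number of records (>= 10), or something with a length/row
#'   count.
#' @param seed Integer seed.
#' @return List of integer index vectors `train`, `test`, `validation`.
#' @export
split_dataset <- function(n, seed) {
  if (is.data.frame(n) || is.matrix(n)) n <- nrow(n)
  else if (length(n) > 1L) n <- length(n)
  n <- as.integer(n)
  if (n < 10L) stop("need at least 10 records to split 70/15/15")
  perm <- withr::with_seed(seed, sample.int(n))
  n_train <- round(0.70 * n)
  n_test <- round(0.15 * n)
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[n_train + seq_len(n_test)]),
       validation = sort(perm[(n_train + n_test + 1L):n]))
}

feature_scaler <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2L, sd)
  sdev[!is.finite(sdev) | sdev < 1e-12] <- 1
  list(center = mu, scale = sdev)
}

apply_scaler <- function(x, scaler) {
  scale(x, center = scaler$center, scale = scaler$scale)[, , drop = FALSE]
}

mlp_forward <- function(theta, x, h, act) {
  p <- ncol(x)
  w1 <- matrix(theta[seq_len(p * h)], p, h)
  b1 <- theta[p * h + seq_len(h)]
  w2 <- theta[p * h + h + seq_len(h)]
  b2 <- theta[p * h + 2L * h + 1L]
  z1 <- sweep(x %*% w1, 2L, b1, "+")
  a1 <- act_fun(act[1L])(z1)
  z2 <- drop(a1 %*% w2) + b2
  list(z1 = z1, a1 = a1, z2 = z2, yhat = act_fun(act[2L])(z2),
       w1 = w1, w2 = w2)
}

mlp_sos <- function(theta, x, y, h, act) {
  sum((mlp_forward(theta, x, h, act)$yhat - y)^2)
}

mlp_sos_grad <- function(theta, x, y, h, act) {
  fw <- mlp_forward(theta, x, h, act)
  dy <- 2 * (fw$yhat - y) * act_grad(act[2L])(fw$z2)     # n
  g_w2 <- drop(crossprod(fw$a1, dy))                     # h
  g_b2 <- sum(dy)
  d1 <- (dy %o% fw$w2) * act_grad(act[1L])(fw$z1)        # n x h
  g_w1 <- crossprod(x, d1)                               # p x h
  g_b1 <- colSums(d1)
  c(as.vector(g_w1), g_b1, g_w2, g_b2)
}

target_affine <- function(y_train, act_out) {
  # Affine target scaling matched to the output transfer function's
  # range (as automated network builders do): identity gets a z-score,
  # bounded transfers a min-max map into their comfortably reachable
  # band, exponential a positive band.  Stored as (center, scale) with
  # y_scaled = (y - center) / scale.
  rng <- switch(act_out,
                identity = NULL,
                logistic = c(0.15, 0.85),
                tanh = c(-0.7, 0.7),
                sine = c(-0.7, 0.7),
                exponential = c(0.5, 1.5))
  if (is.null(rng)) {
    sc <- sd(y_train)
    if (!is.finite(sc) || sc < 1e-12) sc <- 1
    return(list(center = mean(y_train), scale = sc))
  }
  lo <- min(y_train); hi <- max(y_train)
  if (hi - lo < 1e-12) return(list(center = lo - rng[1L], scale = 1))
  sc <- (hi - lo) / (rng[2L] - rng[1L])
  list(center = lo - rng[1L] * sc, scale = sc)
}

#' Train one single-hidden-layer network
#'
#' Minimizes the sum-of-squares error on the training subset by BFGS with
#' analytic gradients, in short bouts between which the test-subset error
#' is monitored; training stops once the test error has not improved for
#' `patience` bouts and the weights with the best test error are kept.
#' Features are expected standardized; targets are rescaled internally
#' into the output transfer function's range (predictions are mapped
#' back to the log10 mole-fraction scale).
#'
#' @param x Standardized feature matrix.
#' @param y Targets, log10 mole-fraction scale.
#' @param hidden_units Number of hidden units, 6 to 12.
#' @param activations Length-2 character vector, hidden and output
#'   transfer functions from `identity`, `logistic`, `tanh`,
#'   `exponential`, `sine`.
#' @param seed Integer seed for the weight initialization.
#' @param train_idx,test_idx Row indices of the training and test
#'   subsets.
#' @param maxit_bout,max_bouts,patience Early-stopping schedule.
#' @return An object of class `"sann"` (weights, architecture, target
#'   scaling, training diagnostics); `rmsd`, `n_outliers` and `accepted`
#'   are filled in by [evaluate_network()] / [build_ensemble()].
#' @export
train_network <- function(x, y, hidden_units, activations, seed,
                          train_idx = seq_along(y), test_idx = integer(),
                          maxit_bout = 40L, max_bouts = 25L, patience = 5L) {
  if (hidden_units < 6L || hidden_units > 12L)
    stop("hidden_units must lie in [6, 12]")
  activations <- as.character(activations)
  if (length(activations) != 2L || !all(activations %in% ACTIVATIONS))
    stop("activations must be two of: ", paste(ACTIVATIONS, collapse = ", "))
  x <- as.matrix(x)
  p <- ncol(x)
  h <- as.integer(hidden_units)
  xt <- x[train_idx, , drop = FALSE]
  aff <- target_affine(y[train_idx], activations[2L])
  y_center <- aff$center
  y_scale <- aff$scale
  yt <- (y[train_idx] - y_center) / y_scale
  has_test <- length(test_idx) > 0L
  if (has_test) {
    xv <- x[test_idx, , drop = FALSE]
    yv <- (y[test_idx] - y_center) / y_scale
  }
  n_par <- p * h + 2L * h + 1L
  theta <- withr::with_seed(seed, runif(n_par, -0.5, 0.5))
  best_theta <- theta
  best_test <- Inf
  stale <- 0L
  diverged <- FALSE
  for (bout in seq_len(max_bouts)) {
    fit <- tryCatch(
      optim(theta, mlp_sos, mlp_sos_grad, x = xt, y = yt, h = h,
            act = activations, method = "BFGS",
            control = list(maxit = maxit_bout)),
      error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$par))) { diverged <- TRUE; break }
    theta <- fit$par
    score <- if (has_test) mlp_sos(theta, xv, yv, h, activations)
             else fit$value
    if (is.finite(score) && score < best_test - 1e-12) {
      best_test <- score
      best_theta <- theta
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  structure(list(theta = best_theta, hidden_units = h,
                 activations = activations, seed = as.integer(seed),
                 y_center = y_center, y_scale = y_scale, p = p,
                 diverged = diverged, rmsd = NA_real_,
                 n_outliers = NA_integer_, accepted = FALSE),
            class = "sann")
}

#' Predict with a single network
#'
#' @param object A fitted `"sann"`.
#' @param x Standardized feature matrix.
#' @param ... Unused.
#' @return Predicted log10 mole-fraction solubilities.
#' @export
predict.sann <- function(object, x, ...) {
  fw <- mlp_forward(object$theta, as.matrix(x), object$hidden_units,
                    object$activations)
  fw$yhat * object$y_scale + object$y_center
}

#' Whole-set accuracy and outlier count of a network
#'
#' RMSD on the log10 mole-fraction scale over all supplied records;
#' outliers are records with |standardized residual| > 3 (residuals
#' divided by their own standard deviation, the Williams-plot
#' convention).
#'
#' @param model A fitted `"sann"`.
#' @param x Standardized feature matrix (all records).
#' @param y Targets.
#' @return Named list `rmsd`, `n_outliers`.
#' @export
evaluate_network <- function(model, x, y) {
  res <- y - predict(model, x)
  s <- sd(res)
  n_out <- if (!is.finite(s) || s < 1e-15) 0L else sum(abs(res / s) > 3)
  list(rmsd = sqrt(mean(res^2)), n_outliers = as.integer(n_out))
}

#' The network acceptance predicate
#'
#' A network joins the ensemble iff its RMSD is below `rmsd_max`
#' (default 0.04 log10 units, strict) and it has at most `max_outliers`
#' outliers (default 4, inclusive).
#'
#' @param rmsd Whole-set RMSD, log10 scale.
#' @param n_outliers Outlier count.
#' @param rmsd_max,max_outliers Thresholds.
#' @return Logical.
#' @export
network_accepted <- function(rmsd, n_outliers, rmsd_max = 0.04,
                             max_outliers = 4L) {
  is.finite(rmsd) && rmsd < rmsd_max && n_outliers <= max_outliers
}

#' Build an ensemble of accepted networks
#'
#' Trains candidate networks with randomized hidden-unit counts,
#' transfer-function pairs and weight seeds until `n_target` candidates
#' pass the acceptance predicate or `max_attempts` have been tried, then
#' sorts the accepted networks by increasing RMSD.
#'
#' @param x Raw feature matrix (n x 7); standardization parameters are
#'   estimated from the training subset.
#' @param y Targets, log10 mole-fraction scale.
#' @param n_target Number of accepted networks wanted (default 40).
#' @param max_attempts Cap on candidate trainings.
#' @param seed Integer seed driving the split and all candidate draws.
#' @param rmsd_max,max_outliers Acceptance thresholds.
#' @param hidden_range Candidate hidden-unit range (within `[6, 12]`).
#' @return An object of class `"sann_ensemble"`: accepted `networks`
#'   (RMSD-ascending), `scaler`, `split`, per-attempt `log`, and the
#'   training design (`x`, `y`) for applicability-domain diagnostics.
#' @export
build_ensemble <- function(x, y, n_target = 40L, max_attempts = 20L * n_target,
                           seed = 1L, rmsd_max = 0.04, max_outliers = 4L,
                           hidden_range = c(6L, 12L)) {
  if (n_target < 1L) stop("n_target must be at least 1")
  x <- as.matrix(x)
  split <- split_dataset(nrow(x), seed)
  scaler <- feature_scaler(x[split$train, , drop = FALSE])
  xs <- apply_scaler(x, scaler)
  draws <- withr::with_seed(seed + 1L, data.frame(
    hidden = sample(seq.int(hidden_range[1L], hidden_range[2L]),
                    max_attempts, replace = TRUE),
    act_hidden = sample(ACTIVATIONS, max_attempts, replace = TRUE),
    act_output = sample(ACTIVATIONS, max_attempts, replace = TRUE),
    seed = sample.int(2^30, max_attempts)))
  networks <- list()
  log <- vector("list", max_attempts)
  n_tried <- 0L
  for (k in seq_len(max_attempts)) {
    n_tried <- k
    net <- train_network(xs, y, draws$hidden[k],
                         c(draws$act_hidden[k], draws$act_output[k]),
                         draws$seed[k], train_idx = split$train,
                         test_idx = split$test)
    ev <- evaluate_network(net, xs, y)
    net$rmsd <- ev$rmsd
    net$n_outliers <- ev$n_outliers
    net$accepted <- !net$diverged &&
      network_accepted(ev$rmsd, ev$n_outliers, rmsd_max, max_outliers)
    log[[k]] <- data.frame(attempt = k, hidden = draws$hidden[k],
                           act_hidden = draws$act_hidden[k],
                           act_output = draws$act_output[k],
                           rmsd = ev$rmsd, n_outliers = ev$n_outliers,
                           accepted = net$accepted)
    if (net$accepted) networks[[length(networks) + 1L]] <- net
    if (length(networks) >= n_target) break
  }
  log <- do.call(rbind, log[seq_len(n_tried)])
  if (!length(networks))
    stop("no network passed the acceptance criteria in ", n_tried,
         " attempts (best RMSD ", format(min(log$rmsd), digits = 3), ")")
  networks <- networks[order(vapply(networks, `[[`, numeric(1), "rmsd"))]
  structure(list(networks = networks, scaler = scaler, split = split,
                 rmsd_max = rmsd_max, max_outliers = max_outliers,
                 x = x, y = y, log = log, seed = as.integer(seed)),
            class = "sann_ensemble")
}

#' @export
print.sann_ensemble <- function(x, ...) {
  r <- vapply(x$networks, `[[`, numeric(1), "rmsd")
  cat(sprintf("<sann_ensemble of %d accepted networks (%d attempts); RMSD %.4f-%.4f, mean %.4f>\n",
              length(r), nrow(x$log), min(r), max(r), mean(r)))
  invisible(x)
}

ensemble_member_predictions <- function(ensemble, x) {
  xs <- apply_scaler(as.matrix(x), ensemble$scaler)
  vapply(ensemble$networks, predict, numeric(nrow(xs)), x = xs)
}

filtered_mean <- function(preds) {
  # discard members implying x outside (0, 1), i.e. log10 x >= 0
  valid <- is.finite(preds) & preds < 0
  list(mean = if (any(valid)) mean(preds[valid]) else NA_real_,
       n_used = sum(valid), n_discarded = sum(!valid))
}

#' Range-filtered ensemble prediction
#'
#' Each member predicts log10 x; members implying a mole fraction outside
#' the physically meaningful range (0, 1) are discarded and the rest
#' averaged in log10 space.  A query for which every member is discarded
#' is flagged (`valid = FALSE`, mean `NA`) rather than propagating NaN.
#'
#' @param object A `"sann_ensemble"`.
#' @param x Feature matrix of queries (raw descriptor scale), or a
#'   single descriptor vector.
#' @param ... Unused.
#' @return Data frame with one row per query: `mean_log10x`, `x_pred`,
#'   `n_used`, `n_discarded`, `valid`; per-member predictions in
#'   `attr(, "per_network")`.
#' @export
predict.sann_ensemble <- function(object, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L,
                                   dimnames = list(NULL, names(x)))
  per <- ensemble_member_predictions(object, x)
  if (is.null(dim(per))) per <- matrix(per, nrow = nrow(x))
  stats <- apply(per, 1L, filtered_mean)
  out <- data.frame(
    mean_log10x = vapply(stats, `[[`, numeric(1), "mean"),
    n_used = vapply(stats, `[[`, integer(1), "n_used"),
    n_discarded = vapply(stats, `[[`, integer(1), "n_discarded"))
  out$x_pred <- 10^out$mean_log10x
  out$valid <- out$n_used > 0L
  attr(out, "per_network") <- per
  out
}

#' Prediction as a function of ensemble size
#'
#' Cumulative range-filtered mean over the `k` lowest-RMSD members, for
#' `k = 1 .. K`; diagnostic for how many networks the averaged
#' prediction needs before it stabilizes.
#'
#' @param ensemble A `"sann_ensemble"` (members are RMSD-sorted).
#' @param descriptor Descriptor vector (or one-row matrix) of the query.
#' @return Data frame with columns `k`, `mean_log10x`.
#' @export
convergence_curve <- function(ensemble, descriptor) {
  if (is.null(dim(descriptor)))
    descriptor <- matrix(descriptor, nrow = 1L,
                         dimnames = list(NULL, names(descriptor)))
  per <- drop(ensemble_member_predictions(ensemble, descriptor))
  means <- vapply(seq_along(per), function(k)
    filtered_mean(per[seq_len(k)])$mean, numeric(1))
  data.frame(k = seq_along(per), mean_log10x = means)
}

# ---- JSON bundle serialization -------------------------------------------

#' Save or load an ensemble as a JSON bundle
#'
#' The bundle stores every member's architecture and weights, the
#' feature scaler, the split, the acceptance thresholds and the training
#' design, so predictions reload exactly.
#'
#' @param ensemble A `"sann_ensemble"`.
#' @param path Output (input) JSON path.
#' @return `write_ensemble()` the path, invisibly; `read_ensemble()` the
#'   restored `"sann_ensemble"`.
#' @export
write_ensemble <- function(ensemble, path) {
  nets <- lapply(ensemble$networks, function(nt)
    list(theta = nt$theta, hidden_units = nt$hidden_units,
         activations = nt$activations, seed = nt$seed,
         y_center = nt$y_center, y_scale = nt$y_scale, p = nt$p,
         rmsd = nt$rmsd, n_outliers = nt$n_outliers,
         accepted = nt$accepted, diverged = nt$diverged))
  bundle <- list(format = "solvscreen-sann-ensemble", version = 1L,
                 networks = nets,
                 scaler = ensemble$scaler, split = ensemble$split,
                 rmsd_max = ensemble$rmsd_max,
                 max_outliers = ensemble$max_outliers,
                 x = as.data.frame(ensemble$x), y = ensemble$y,
                 seed = ensemble$seed)
  jsonlite::write_json(bundle, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(b$format, "solvscreen-sann-ensemble"))
    stop("not a solvscreen ensemble bundle: ", path)
  nets <- lapply(seq_len(nrow(b$networks)), function(i) {
    row <- b$networks[i, ]
    structure(list(theta = row$theta[[1L]],
                   hidden_units = as.integer(row$hidden_units),
                   activations = row$activations[[1L]],
                   seed = as.integer(row$seed),
                   y_center = row$y_center, y_scale = row$y_scale,
                   p = as.integer(row$p), diverged = row$diverged,
                   rmsd = row$rmsd,
                   n_outliers = as.integer(row$n_outliers),
                   accepted = row$accepted),
              class = "sann")
  })
  x <- as.matrix(b$x)
  scaler <- list(center = unlist(b$scaler$center),
                 scale = unlist(b$scaler$scale))
  structure(list(networks = nets, scaler = scaler,
                 split = lapply(b$split, as.integer),
                 rmsd_max = b$rmsd_max,
                 max_outliers = as.integer(b$max_outliers),
                 x = x, y = b$y, log = NULL, seed = as.integer(b$seed)),
            class = "sann_ensemble")
}
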