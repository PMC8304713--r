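# Leverage-based applicability domain (Williams plot data).
#
# Leverages are the hat values of the intercept-augmented descriptor
# design; a query is interpolative when its leverage stays below the
# warning leverage h* = 3(p+1)/n and its standardized residual within
# +/- 3.  The domain is a property of the shared descriptor design, not
# of individual ensemble members.

#' Hat values (leverages) of query rows against a training design
#'
#' `h_q = x_q (X'X)^{-1} x_q'` with an intercept column prepended to both
#' the training design and the queries.
#'
#' @param train_features Training feature matrix (n x p, no intercept).
#' @param query_features Query feature matrix (defaults to the training
#'   rows, giving the self-leverages whose sum is `p + 1`).
#' @return Numeric vector of leverages.
#' @export
hat_values <- function(train_features, query_features = train_features) {
  x <- cbind(1, as.matrix(train_features))
  q <- cbind(1, as.matrix(query_features))
  xtx <- crossprod(x)
  r <- tryCatch(chol(xtx), error = function(e) NULL)
  if (is.null(r) || any(abs(diag(r)) < 1e-10 * sqrt(max(diag(xtx)))))
    stop("training design is rank-deficient; check descriptors for collinearity")
  # h_q = || R^{-T} q' ||^2 columnwise
  v <- backsolve(r, t(q), transpose = TRUE)
  colSums(v^2)
}

# Leverages on the independent column space of the training design.
# The seven-descriptor design is structurally rank-deficient (the three
# relative energies sum to one, collinear with the intercept), so the
# ensemble-level report projects onto the pivoted-QR column basis; the
# generalized warning threshold 3 * rank / n reduces to 3(p+1)/n for a
# full-rank design.
design_leverages <- function(train_features, query_features) {
  x <- cbind(1, as.matrix(train_features))
  q <- cbind(1, as.matrix(query_features))
  dec <- qr(x)
  keep <- dec$pivot[seq_len(dec$rank)]
  r <- chol(crossprod(x[, keep, drop = FALSE]))
  v <- backsolve(r, t(q[, keep, drop = FALSE]), transpose = TRUE)
  list(h = colSums(v^2), rank = dec$rank)
}

#' Warning leverage
#'
#' The conventional threshold `h* = 3 (p + 1) / n`.
#'
#' @param n Number of training records.
#' @param p Number of descriptors (default 7).
#' @return Numeric threshold.
#' @export
warning_leverage <- function(n, p = 7L) 3 * (p + 1) / n

#' Williams-plot report for an ensemble
#'
#' Residuals of the range-filtered ensemble mean, standardized by their
#' own standard deviation, against leverages of each record on the
#' ensemble's training-subset design.  A record is inside the domain iff
#' `h <= h*` and `|standardized residual| <= 3`.  Leverages are computed
#' on the design's independent column space (the relative-energy
#' descriptors sum to one, so the intercept-augmented design is
#' structurally rank-deficient) with the generalized threshold
#' `h* = 3 rank / n`.
#'
#' @param ensemble A fitted [sann_ensemble][build_ensemble].
#' @param features Feature matrix to diagnose (default: the ensemble's
#'   full design).
#' @param targets Matching log10 solubilities (default: the ensemble's
#'   targets; pass `NULL` for prediction-only queries, which are judged
#'   on leverage alone).
#' @return Data frame of class `"ad_report"` with columns `leverage`,
#'   `std_residual`, `inside_domain`, plus the threshold in
#'   `attr(, "warning_leverage")`.
#' @export
williams_report <- function(ensemble, features = ensemble$x,
                            targets = ensemble$y) {
  stopifnot(inherits(ensemble, "sann_ensemble"))
  train <- ensemble$x[ensemble$split$train, , drop = FALSE]
  if (is.null(dim(features)))
    features <- matrix(features, nrow = 1L,
                       dimnames = list(NULL, names(features)))
  lev <- design_leverages(train, features)
  h <- lev$h
  h_star <- 3 * lev$rank / nrow(train)
  if (!is.null(targets)) {
    res <- targets - predict(ensemble, features)$mean_log10x
    s <- sd(res)
    std_res <- if (!is.finite(s) || s < 1e-15) res * 0 else res / s
  } else {
    std_res <- rep(NA_real_, nrow(features))
  }
  inside <- h <= h_star & (is.na(std_res) | abs(std_res) <= 3)
  out <- data.frame(record = seq_len(nrow(features)), leverage = h,
                    std_residual = std_res, inside_domain = inside)
  if (!is.null(rownames(features))) out$record <- rownames(features)
  attr(out, "warning_leverage") <- h_star
  class(out) <- c("ad_report", class(out))
  out
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("Williams report: %d record(s), h* = %.4f, %d outside domain\n",
              nrow(x), attr(x, "warning_leverage"), sum(!x$inside_domain)))
  print.data.frame(utils::head(x, 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}
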