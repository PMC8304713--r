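test_that("70/15/15 split is a deterministic disjoint cover", {
  sp <- split_dataset(160, seed = 3)
  expect_equal(lengths(sp), c(train = 112L, test = 24L, validation = 24L))
  all_idx <- c(sp$train, sp$test, sp$validation)
  expect_equal(sort(all_idx), 1:160)
  expect_equal(split_dataset(160, seed = 3), sp)
  expect_false(identical(split_dataset(160, seed = 4), sp))
  # other sizes still cover disjointly
  for (n in c(10, 37, 101)) {
    s <- split_dataset(n, seed = 1)
    expect_equal(sort(c(s$train, s$test, s$validation)), seq_len(n))
    expect_equal(length(s$train), round(0.7 * n))
    expect_equal(length(s$test), round(0.15 * n))
  }
  expect_error(split_dataset(9, seed = 1), "at least 10")
})

test_that("trainer fits representable targets and is seed-deterministic", {
  withr::with_seed(5, {
    x <- matrix(rnorm(120 * 7), 120, 7)
    beta <- runif(7, -1, 1)
  })
  y_lin <- drop(x %*% beta) - 2
  sp <- split_dataset(120, seed = 5)
  net <- train_network(x, y_lin, hidden_units = 6,
                       activations = c("identity", "identity"), seed = 42,
                       train_idx = sp$train, test_idx = sp$test)
  ev <- evaluate_network(net, x, y_lin)
  expect_lt(ev$rmsd, 1e-3)
  # constant targets are reproduced exactly enough
  y_const <- rep(-2.5, 120)
  netc <- train_network(x, y_const, 6, c("tanh", "identity"), seed = 1,
                        train_idx = sp$train, test_idx = sp$test)
  expect_lt(evaluate_network(netc, x, y_const)$rmsd, 1e-6)
  # same seed, same result; different seed, different weights
  net2 <- train_network(x, y_lin, 6, c("identity", "identity"), seed = 42,
                        train_idx = sp$train, test_idx = sp$test)
  expect_identical(net$theta, net2$theta)
  expect_equal(evaluate_network(net2, x, y_lin)$rmsd, ev$rmsd)
  expect_error(train_network(x, y_lin, 5, c("identity", "identity"), 1),
               "\\[6, 12\\]")
  expect_error(train_network(x, y_lin, 6, c("relu", "identity"), 1),
               "activations")
})

test_that("acceptance predicate has the stated strict/inclusive boundaries", {
  expect_true(network_accepted(0.039, 4L))
  expect_false(network_accepted(0.041, 0L))
  expect_false(network_accepted(0.02, 5L))
  expect_false(network_accepted(0.04, 0L))   # strict on RMSD
  expect_true(network_accepted(0.0399, 4L))  # inclusive on outliers
  # property: predicate is exactly (rmsd < max) && (outliers <= max)
  withr::with_seed(6, {
    for (i in 1:50) {
      r <- runif(1, 0, 0.08); k <- sample(0:8, 1)
      expect_identical(network_accepted(r, k), r < 0.04 && k <= 4)
    }
  })
})

test_that("outlier counting uses |standardized residual| > 3", {
  withr::with_seed(12, {
    x <- matrix(rnorm(120 * 7), 120, 7)
    beta <- runif(7, -1, 1)
  })
  y <- drop(x %*% beta)
  sp <- split_dataset(120, seed = 12)
  net <- train_network(x, y, 6, c("identity", "identity"), seed = 2,
                       train_idx = sp$train, test_idx = sp$test)
  ev <- evaluate_network(net, x, y)
  expect_lt(ev$rmsd, 1e-3)
  expect_equal(ev$n_outliers, 0L)
  # two grossly perturbed records become the only standardized outliers
  y_out <- y
  y_out[c(5, 80)] <- y_out[c(5, 80)] + c(1, -1)
  ev2 <- evaluate_network(net, x, y_out)
  expect_equal(ev2$n_outliers, 2L)
})

test_that("ensemble accumulates accepted networks sorted by RMSD", {
  ens <- shared_ensemble()
  expect_s3_class(ens, "sann_ensemble")
  rmsds <- vapply(ens$networks, `[[`, numeric(1), "rmsd")
  expect_equal(length(rmsds), 10L)
  expect_true(all(diff(rmsds) >= 0))
  expect_true(all(vapply(ens$networks, `[[`, logical(1), "accepted")))
  expect_true(all(rmsds < ens$rmsd_max))
  expect_true(all(vapply(ens$networks, `[[`, integer(1), "n_outliers") <= 4L))
  # an impossible threshold raises an informative error
  fm <- shared_features()
  expect_error(build_ensemble(fm$x, fm$y, n_target = 1, max_attempts = 3,
                              seed = 1, rmsd_max = 1e-9),
               "no network passed")
})

test_that("range-filtered prediction discards unphysical members", {
  # direct check of the filter rule on a synthetic member spread
  preds <- c(-2.0, -1.5, 0.3)
  fm <- solvscreen:::filtered_mean(preds)
  expect_equal(fm$mean, -1.75)
  expect_equal(fm$n_used, 2L)
  expect_equal(fm$n_discarded, 1L)
  expect_equal(fm$n_used + fm$n_discarded, length(preds))
  agree <- solvscreen:::filtered_mean(rep(-3, 7))
  expect_equal(agree$mean, -3)
  expect_equal(agree$n_discarded, 0L)
  allbad <- solvscreen:::filtered_mean(c(0.2, 1.3))
  expect_true(is.na(allbad$mean))
  expect_equal(allbad$n_used, 0L)

  # through the ensemble: means over members, no NaN propagation
  ens <- shared_ensemble()
  fm <- shared_features()
  pr <- predict(ens, fm$x[1:5, ])
  expect_equal(nrow(pr), 5L)
  expect_true(all(pr$valid))
  expect_equal(pr$n_used + pr$n_discarded, rep(10L, 5))
  per <- attr(pr, "per_network")
  expect_equal(pr$mean_log10x[1],
               mean(per[1, per[1, ] < 0]))
})

test_that("ensemble mean is invariant under member permutation", {
  ens <- shared_ensemble()
  fm <- shared_features()
  shuffled <- ens
  shuffled$networks <- withr::with_seed(9, sample(ens$networks))
  p1 <- predict(ens, fm$x[3:6, ])
  p2 <- predict(shuffled, fm$x[3:6, ])
  expect_equal(p1$mean_log10x, p2$mean_log10x)
})

test_that("convergence curve ends at the full-ensemble mean", {
  ens <- shared_ensemble()
  fm <- shared_features()
  cc <- convergence_curve(ens, fm$x[2, ])
  expect_equal(nrow(cc), length(ens$networks))
  expect_equal(cc$mean_log10x[nrow(cc)],
               predict(ens, fm$x[2, , drop = FALSE])$mean_log10x)
  # identical members give a flat curve
  clone <- ens
  clone$networks <- rep(ens$networks[1], 5)
  ccf <- convergence_curve(clone, fm$x[2, ])
  expect_equal(diff(range(ccf$mean_log10x)), 0)
})

test_that("JSON bundle round-trips ensemble predictions exactly", {
  ens <- shared_ensemble()
  fm <- shared_features()
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_equal(length(back$networks), length(ens$networks))
  p1 <- predict(ens, fm$x[1:8, ])
  p2 <- predict(back, fm$x[1:8, ])
  expect_equal(p2$mean_log10x, p1$mean_log10x, tolerance = 1e-12)
  expect_error(read_ensemble(withr::local_tempfile(lines = "{}",
                                                   fileext = ".json")),
               "bundle")
})
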