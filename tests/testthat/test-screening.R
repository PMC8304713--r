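make_pool <- function() {
  gen <- shared_gen()
  gen$components
}

test_that("binary enumeration counts pairs times fractions", {
  comps <- make_pool()
  organics <- comps[comps$role == "solvent", ][1:5, ]
  grid9 <- seq(0.1, 0.9, by = 0.1)
  cand <- enumerate_binary(organics, grid9)
  expect_equal(length(cand$systems), 45L)
  # the unimolar system is present when 0.5 is on the grid
  ids <- names(cand$systems)
  expect_true(any(grepl("@0.5$", ids)))
  sys <- cand$systems[[grep("@0.5$", ids)[1]]]
  expect_equal(sys$fractions, c(0.5, 0.5))
  expect_equal(sys$components[2], "water")
  # empty grid, duplicate rows, invalid fractions
  expect_equal(length(enumerate_binary(organics, numeric())$systems), 0L)
  expect_equal(length(enumerate_binary(rbind(organics, organics),
                                       grid9)$systems), 45L)
  expect_error(enumerate_binary(organics, c(0.5, 1)), "inside")
})

test_that("NADES enumeration builds 0.4/0.4/0.2 ternaries and skips unknowns", {
  comps <- make_pool()
  hbds <- comps$name[comps$role == "hbd"]
  cand <- enumerate_nades(hbds, comps)
  expect_equal(length(cand$systems), length(hbds))
  sys <- cand$systems[[1]]
  expect_equal(sys$fractions, c(0.4, 0.4, 0.2))
  expect_equal(sys$components[1], "ChCl")
  expect_equal(sys$components[3], "water")
  # duplicates deduplicated, unknowns skipped with a message
  expect_equal(length(enumerate_nades(rep(hbds[1], 3), comps)$systems), 1L)
  expect_message(c2 <- enumerate_nades(c(hbds[1], "mystery"), comps),
                 "skipping")
  expect_equal(length(c2$systems), 1L)
  expect_equal(c2$skipped, "mystery")
  expect_error(enumerate_nades(hbds, comps[comps$name != "ChCl", ]),
               "ChCl")
})

test_that("screening ranks by predicted solubility and conserves counts", {
  gen <- shared_gen()
  ens <- shared_ensemble()
  comps <- gen$components
  neat <- enumerate_neat(comps[comps$role %in% c("solvent", "water"), ])
  res <- screen(neat, ens, comps)
  expect_s3_class(res, "screening_result")
  expect_equal(nrow(res) + attr(res, "n_dropped"), length(neat$systems))
  expect_true(all(diff(res$mean_log10x) <= 0))
  expect_equal(res$rank, seq_len(nrow(res)))
  # ranking is invariant to candidate input order
  rev_cand <- rev(neat$systems)
  res2 <- screen(rev_cand, ens, comps)
  expect_equal(res2$system, res$system)
  expect_equal(res2$mean_log10x, res$mean_log10x)
  # screening reproduces the predict() code path on the same descriptor
  sys_id <- res$system[1]
  d <- mixture_descriptor(neat$systems[[sys_id]], comps)
  expect_equal(res$mean_log10x[1],
               predict(ens, matrix(d, 1, dimnames = list(NULL, names(d))))$mean_log10x)
  # empty candidate set yields an empty, well-formed result
  empty <- screen(list(), ens, comps)
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_dropped"), 0L)
})

test_that("screening recovers the known best candidate on synthetic truth", {
  gen <- shared_gen()
  ens <- shared_ensemble()
  comps <- gen$components
  neat <- enumerate_neat(comps[comps$role %in% c("solvent", "water"), ])
  feats <- t(sapply(neat$systems, mixture_descriptor, components = comps))
  truth <- truth_surface(feats, gen$spec$truth)
  best_true <- names(neat$systems)[which.max(truth)]
  res <- screen(neat, ens, comps)
  # the ground-truth optimum sits at the top of the ranking
  expect_true(best_true %in% res$system[1:2])
  # and predicted values track the truth ordering closely
  expect_gt(cor(res$mean_log10x, truth[match(res$system,
                                             names(neat$systems))],
                method = "spearman"), 0.9)
})
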