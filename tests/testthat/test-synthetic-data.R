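test_that("component generator is seeded and non-degenerate", {
  spec <- generator_spec(seed = 31)
  c1 <- generate_components(spec)
  c2 <- generate_components(spec)
  expect_identical(c1, c2)
  c3 <- generate_components(generator_spec(seed = 32))
  expect_false(identical(c1$e_hb, c3$e_hb))
  # 12 neat solvent components (water + organics) by default
  expect_equal(sum(c1$role %in% c("water", "solvent")), 12L)
  # energy signs and non-degenerate triples for every component
  expect_true(all(c1$e_misfit > 0))
  expect_true(all(c1$e_hb <= 0))
  expect_true(all(c1$e_vdw < 0))
  for (i in seq_len(nrow(c1)))
    expect_equal(sum(relative_contributions(c1[i, ])), 1)
})

test_that("record generator emulates the 160-record campaign", {
  gen <- shared_gen()
  rec <- gen$records
  ids <- unique(rec$system_id)
  expect_equal(length(ids), 160L)
  cat_of <- rec$category[match(ids, rec$system_id)]
  expect_equal(sum(cat_of == "neat"), 13L)   # 12 solvents + cold water
  expect_equal(sum(cat_of == "binary"), 60L) # 5 pairs x 12 fractions
  expect_equal(sum(cat_of == "nades"), 7L)
  expect_equal(sum(cat_of == "nades_water"), 80L)
  # generated table passes all record invariants
  expect_silent(solvscreen:::validate_records(rec))
  # determinism and truth bookkeeping
  gen2 <- generate_records(gen$spec)
  expect_identical(gen2$records, rec)
  expect_equal(gen2$truth$system_id, ids)
})

test_that("zero noise puts records exactly on the truth surface", {
  gen0 <- generate_records(generator_spec(noise_sd = 0, seed = 33))
  fm <- build_feature_matrix(gen0$records, gen0$components)
  expect_equal(fm$y, truth_surface(fm$x, gen0$spec$truth),
               tolerance = 1e-12)
  # noisy targets deviate with roughly the requested spread
  gen <- generate_records(generator_spec(noise_sd = 0.05, seed = 33))
  fm2 <- build_feature_matrix(gen$records, gen$components)
  dev <- fm2$y - truth_surface(fm2$x, gen$spec$truth)
  expect_gt(sd(dev), 0.03)
  expect_lt(sd(dev), 0.07)
})

test_that("binary series follow the truth along the composition line", {
  gen0 <- generate_records(generator_spec(noise_sd = 0,
                                          temperature_jitter_sd = 0,
                                          seed = 34))
  rec <- gen0$records
  comps <- gen0$components
  bin_ids <- unique(rec$system_id[rec$category == "binary"])
  pair <- sub("@.*", "", bin_ids)[1]
  series <- bin_ids[startsWith(bin_ids, paste0(pair, "@"))]
  first_rows <- rec[match(series, rec$system_id), ]
  fr <- first_rows$frac # fraction of the organic component
  fm <- build_feature_matrix(rec[rec$system_id %in% series, ], comps)
  y <- fm$y[match(series, fm$system_id)][order(fr)]
  # independently mix the endpoint descriptors and evaluate the truth
  nm <- strsplit(pair, "+", fixed = TRUE)[[1]]
  d_org <- mixture_descriptor(solvent_system(nm[1], 1, "neat"), comps)
  d_wat <- mixture_descriptor(solvent_system("water", 1, "neat"), comps)
  f_sorted <- sort(fr)
  y_line <- vapply(f_sorted, function(f)
    truth_surface(f * d_org + (1 - f) * d_wat, gen0$spec$truth),
    numeric(1))
  expect_equal(y, y_line, tolerance = 1e-12)
  # and when the dense truth line is monotone, so is the series
  f_dense <- seq(0, 1, length.out = 201)
  t_dense <- vapply(f_dense, function(f)
    truth_surface(f * d_org + (1 - f) * d_wat, gen0$spec$truth),
    numeric(1))
  if (all(diff(t_dense) >= 0) || all(diff(t_dense) <= 0))
    expect_true(all(diff(y) >= -1e-12) || all(diff(y) <= 1e-12))
})

test_that("toy sigma-profile batches are normalized, tagged and seeded", {
  pr <- generate_toy_sigma_profiles(5, seed = 35)
  expect_equal(length(pr), 5L)
  for (p in pr) expect_equal(sum(p$p), 1)
  # the symmetric apolar profile mirrors exactly
  expect_equal(pr$apolar$p, rev(pr$apolar$p))
  expect_equal(pr$polar$p, rev(pr$polar$p))
  pr2 <- generate_toy_sigma_profiles(5, seed = 35)
  expect_identical(pr, pr2)
})
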