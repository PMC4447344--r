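noise_dh <- estimate_noise(dh$design)
cfg_small <- sim_config(n_sims = 50, step_length = 0.1, n_repeats = 2,
                        seed = 404)
ens_small <- fit_ensemble(dh$design, noise_dh, cfg_small)

test_that("ensembles are reproducible and degenerate correctly", {
  ens2 <- fit_ensemble(dh$design, noise_dh, cfg_small)
  expect_identical(ens_small$coefficients, ens2$coefficients)
  expect_identical(ens_small$sse, ens2$sse)
  # zero noise, one simulation: the ensemble is the point-estimate fits
  noise0 <- noise_model(dh$design$cqa_names,
                        noise_dh$table$center_mean, rsd = 0,
                        replicate_runs = c(5, 12, 14))
  ens0 <- fit_ensemble(dh$design, noise0,
                       sim_config(n_sims = 1, seed = 1))
  d0 <- dh$design
  d0$responses[c(5, 12, 14), ] <- rep(noise_dh$table$center_mean,
                                      each = 3)
  fits0 <- stepwise_fit_all(d0, alpha = 0.35)
  for (j in seq_along(fits0)) {
    dense <- ens0$coefficients[, j, 1]
    expect_equal(dense[c("(Intercept)", fits0[[j]]$terms)],
                 coef(fits0[[j]]), tolerance = 1e-10)
    expect_equal(sum(dense != 0), length(fits0[[j]]$terms) + 1)
  }
})

test_that("probability cells equal brute-force counting, bit for bit", {
  map <- probability_map(ens_small, dh$cqas,
                         slice = c(extraction_number = 0))
  limits <- dh$cqas[match(dh$design$cqa_names, dh$cqas$name), ]
  idx <- rbind(c(1, 1), c(6, 11), c(21, 21), c(11, 18))
  tm <- quad_terms(dh$factors)
  for (r in seq_len(nrow(idx))) {
    x1 <- map$axes[[1]][idx[r, 1]]; x2 <- map$axes[[2]][idx[r, 2]]
    coded <- matrix(c(x1, x2, 0), 1,
                    dimnames = list(NULL, dh$factors$name))
    g <- design_matrix(coded, tm)
    hits <- 0L
    for (s in seq_len(ens_small$n_sims)) {
      ok <- TRUE
      for (j in seq_along(dh$design$cqa_names)) {
        p <- sum(g * ens_small$coefficients[, j, s])
        if (p < limits$lower[j] || p > limits$upper[j]) ok <- FALSE
      }
      hits <- hits + ok
    }
    expect_identical(map$prob[idx[r, 1], idx[r, 2]],
                     hits / ens_small$n_sims)
  }
})

test_that("unbounded limits give probability one everywhere", {
  wide <- cqa_spec(dh$cqas$name, "", rep(-Inf, 6), rep(Inf, 6))
  map <- probability_map(ens_small, wide, slice = c(extraction_number = 0))
  expect_true(all(map$prob == 1))
})

test_that("zero-noise ensembles give 0/1 indicator maps", {
  noise0 <- noise_model(dh$design$cqa_names,
                        noise_dh$table$center_mean, rsd = 0,
                        replicate_runs = c(5, 12, 14))
  ens0 <- fit_ensemble(dh$design, noise0,
                       sim_config(n_sims = 3, step_length = 0.1, seed = 2))
  map <- probability_map(ens0, dh$cqas, slice = c(extraction_number = 0))
  expect_true(all(map$prob %in% c(0, 1)))
})

test_that("threshold masks are monotone and sized correctly", {
  map <- probability_map(ens_small, dh$cqas,
                         slice = c(extraction_number = 0))
  ds90 <- design_space(map, threshold = 0.90)
  ds95 <- design_space(map, threshold = 0.95)
  expect_true(all(ds95$mask <= ds90$mask))
  expect_equal(ds95$dss, mean(map$prob >= 0.95))
  # threshold 1 keeps only certain cells; above 1 empties the mask
  ds100 <- design_space(map, threshold = 1)
  expect_equal(ds100$dss, mean(map$prob == 1))
  expect_warning(dsover <- design_space(map, threshold = 1.01),
                 "empty design space")
  expect_equal(dsover$dss, 0)
  wide <- cqa_spec(dh$cqas$name, "", rep(-Inf, 6), rep(Inf, 6))
  expect_equal(design_space(probability_map(ens_small, wide,
                                            slice = c(extraction_number = 0)),
                            threshold = 0.95)$dss, 1)
})

test_that("repeated design-space computations report ADSS and RSDDSS", {
  cfg <- sim_config(n_sims = 100, step_length = 0.1, n_repeats = 3,
                    seed = 7)
  ds <- design_space(dh$design, dh$cqas, cfg = cfg,
                     slice = c(extraction_number = 0))
  expect_length(ds$dss, 3)
  expect_equal(ds$adss, mean(ds$dss))
  expect_equal(ds$rsddss, 100 * sd(ds$dss) / mean(ds$dss))
  # byte-identical under the same master seed
  ds2 <- design_space(dh$design, dh$cqas, cfg = cfg,
                      slice = c(extraction_number = 0))
  expect_identical(ds$dss, ds2$dss)
  expect_identical(ds$map$prob, ds2$map$prob)
})

test_that("verification reports point, ensemble and joint quantities", {
  v <- verify_point(ens_small, verification_point, dh$cqas)
  fits <- stepwise_fit_all(dh$design, alpha = 0.35)
  for (j in seq_along(fits))
    expect_equal(v$table$predicted[j],
                 unname(predict(fits[[j]], verification_point)))
  # joint probability by explicit counting over the stored ensemble
  g <- design_matrix(code_factors(verification_point, dh$factors),
                     quad_terms(dh$factors))
  limits <- dh$cqas[match(dh$design$cqa_names, dh$cqas$name), ]
  hits <- 0
  for (s in seq_len(ens_small$n_sims)) {
    p <- drop(g %*% ens_small$coefficients[, , s])
    hits <- hits + all(p >= limits$lower & p <= limits$upper)
  }
  expect_identical(v$joint_prob, hits / ens_small$n_sims)
  expect_warning(verify_point(ens_small,
                              c(extraction_time = 2.3, wm_ratio = 8,
                                extraction_number = 2), dh$cqas),
                 "outside")
})

test_that("ensemble means recover the point-estimate model under noise", {
  cfg <- sim_config(n_sims = 1000, seed = 31)
  ens <- fit_ensemble(dh$design, noise_dh, cfg)
  point <- rsm_fit(dh$design, "danshensu", danhong_term_sets()$danshensu)
  ints <- ens$coefficients["(Intercept)", "danshensu", ]
  se <- sd(ints) / sqrt(length(ints))
  expect_lt(abs(mean(ints) - coef(point)[1]), 3 * se + 1e-8)
})

test_that("synthetic truth is recovered within Monte-Carlo error", {
  truth <- list(y = c("(Intercept)" = 300, "extraction_time" = 30,
                      "wm_ratio" = -40, "extraction_number" = 50))
  syn <- generate_synthetic(synthetic_spec(dh$factors, truth,
                                           noise_rsd = 0.05), seed = 3)
  noise <- noise_model("y", center_mean = 300, rsd = 0.05,
                       replicate_runs = c(5, 12, 14))
  ens <- fit_ensemble(syn, noise, sim_config(n_sims = 800, seed = 17))
  for (term in c("extraction_time", "wm_ratio", "extraction_number")) {
    sel <- ens$coefficients[term, 1, ]
    expect_true(all(sel != 0))   # strong effects are always selected
    # the ensemble SD estimates the Monte-Carlo standard error of one
    # refit; the ensemble mean must sit within 3 of them from the truth
    expect_lt(abs(mean(sel) - truth$y[[term]]), 3 * sd(sel))
  }
})

test_that("distribution families are compared on common random numbers", {
  cmp <- compare_distributions(dh$design, dh$cqas,
                               cfg = sim_config(n_sims = 120,
                                                step_length = 0.1,
                                                seed = 5),
                               families = c("normal", "lognormal"),
                               slice = c(extraction_number = 0))
  expect_equal(cmp$summary$family, c("normal", "lognormal"))
  expect_true(all(cmp$summary$dss >= 0 & cmp$summary$dss <= 1))
  single <- design_space(probability_map(
    fit_ensemble(dh$design, noise_dh, sim_config(n_sims = 120,
                                                 step_length = 0.1,
                                                 seed = 5)),
    dh$cqas, slice = c(extraction_number = 0)), threshold = 0.95)
  expect_equal(cmp$summary$dss[1], single$dss)
})
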