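test_that("design_matrix builds the quadratic basis columns", {
  fs <- dh$factors
  tm <- quad_terms(fs)
  expect_length(tm, 9)
  coded <- matrix(c(1, -1, 0), 1, dimnames = list(NULL, fs$name))
  X <- design_matrix(coded, tm)
  expect_equal(drop(X), c("(Intercept)" = 1, extraction_time = 1,
                          wm_ratio = -1, extraction_number = 0,
                          "extraction_time:wm_ratio" = -1,
                          "extraction_time:extraction_number" = 0,
                          "wm_ratio:extraction_number" = 0,
                          "extraction_time^2" = 1, "wm_ratio^2" = 1,
                          "extraction_number^2" = 0))
  # empty term set: just the intercept column
  expect_equal(design_matrix(coded), matrix(1, 1, 1,
               dimnames = list(NULL, "(Intercept)")))
  # study run 4 codes to (-1/3, 1, 1)
  X4 <- design_matrix(coded_settings(dh$design), tm)[4, ]
  expect_equal(unname(X4["wm_ratio:extraction_number"]), 1)
  expect_equal(unname(X4["extraction_time:extraction_number"]), -1 / 3)
})

test_that("least-squares fits equal the normal-equations oracle", {
  set.seed(31)
  tm <- quad_terms(dh$factors)
  for (i in 1:10) {
    terms <- sample(tm, sample(3:7, 1))
    cqa <- sample(dh$design$cqa_names, 1)
    fit <- rsm_fit(dh$design, cqa, terms)
    X <- design_matrix(coded_settings(dh$design), terms)
    o <- oracle_ols(X, dh$design$responses[[cqa]])
    expect_lt(max(abs(coef(fit) - o$beta)), 1e-8)
    expect_equal(fit$sse, o$sse, tolerance = 1e-8)
    expect_lt(max(abs(fit$p.value - o$p)), 1e-8)
  }
})

test_that("a hand-solved single-factor fit is reproduced", {
  fs <- unit_factor()
  design <- design_table(data.frame(x = c(-1, 0, 0, 1)),
                         data.frame(y = c(1, 2, 2.2, 3)), fs)
  fit <- rsm_fit(design, "y", "x")
  expect_equal(unname(coef(fit)), c(2.05, 1.0))
})

test_that("noiseless synthetic responses are interpolated exactly", {
  syn <- make_synthetic(noise_rsd = 0)
  truth <- attr(syn, "true_coefficients")$y
  fit <- rsm_fit(syn, "y", setdiff(names(truth), "(Intercept)"))
  expect_lt(max(abs(coef(fit) - truth)), 1e-10)
  expect_equal(unname(model_criteria(fit)["R2"]), 1)
  expect_lt(fit$sse, 1e-16)
})

test_that("model criteria behave at the extremes and match the study", {
  syn <- make_synthetic(noise_rsd = 0)
  perfect <- rsm_fit(syn, "y",
                     setdiff(names(attr(syn, "true_coefficients")$y),
                             "(Intercept)"))
  expect_equal(unname(model_criteria(perfect)[c("R2", "R2adj")]), c(1, 1))
  onlyint <- rsm_fit(dh$design, "danshensu", character(0))
  expect_equal(unname(model_criteria(onlyint)["R2"]), 0)
  dsu <- rsm_fit(dh$design, "danshensu", danhong_term_sets()$danshensu)
  expect_equal(unname(round(model_criteria(dsu)["R2adj"], 3)), 0.987)
})

test_that("PRESS via the hat matrix equals explicit leave-one-out", {
  for (cqa in c("danshensu", "dry_matter")) {
    fit <- rsm_fit(dh$design, cqa, danhong_term_sets()[[cqa]])
    X <- design_matrix(coded_settings(dh$design), fit$terms)
    expect_equal(fit$press, oracle_press(X, dh$design$responses[[cqa]]),
                 tolerance = 1e-8)
    expect_equal(unname(model_criteria(fit)["R2pred"]),
                 1 - fit$press / fit$sst)
  }
})

test_that("rank deficiency is reported with the collinear terms", {
  fs <- unit_factor()
  design <- design_table(data.frame(x = c(-1, 0, 0.5, 1)),
                         data.frame(y = c(1, 2, 2.2, 3)), fs)
  # duplicate information: x entered twice is impossible, so square the
  # settings to create an exactly collinear pair on a two-level design
  d2 <- design_table(data.frame(x = c(-1, -1, 1, 1)),
                     data.frame(y = c(1, 1.1, 3, 3.2)), fs)
  expect_error(rsm_fit(d2, "y", c("x", "x^2")), "collinear")
  expect_error(rsm_fit(design, "y", rep("x", 2)), "duplicate")
})

test_that("prediction codes uncoded input and matches direct evaluation", {
  fit <- rsm_fit(dh$design, "danshensu", danhong_term_sets()$danshensu)
  co <- coef(fit)
  x1 <- 0.35 / 0.75; x2 <- 0.15; x3 <- 0
  manual <- co["(Intercept)"] + co["extraction_time"] * x1 +
    co["wm_ratio"] * x2 + co["extraction_number"] * x3 +
    co["extraction_time:extraction_number"] * x1 * x3 +
    co["wm_ratio:extraction_number"] * x2 * x3 +
    co["extraction_number^2"] * x3^2
  expect_equal(unname(predict(fit, verification_point)), unname(manual))
  expect_equal(predict(fit, c(extraction_time = 0.35 / 0.75,
                              wm_ratio = 0.15, extraction_number = 0),
                       coded = TRUE),
               predict(fit, verification_point))
})

test_that("stepwise selection matches the reference procedure", {
  C <- design_matrix(coded_settings(dh$design),
                     quad_terms(dh$factors))[, -1]
  for (cqa in dh$design$cqa_names) {
    for (alpha in c(0.15, 0.35)) {
      sel <- stepwise_select(dh$design, cqa, alpha)
      ref <- oracle_stepwise(C, dh$design$responses[[cqa]], alpha)
      expect_equal(sel$terms, quad_terms(dh$factors)[ref],
                   info = paste(cqa, alpha))
    }
  }
})

test_that("stepwise keeps everything at alpha 1 and finds pure signals", {
  all9 <- stepwise_select(dh$design, "danshensu", alpha_enter = 1)
  expect_setequal(all9$terms, quad_terms(dh$factors))
  # noiseless y linear in time only (intercept large enough to keep the
  # surface positive over the whole design)
  syn <- make_synthetic(noise_rsd = 0,
                        coefs = list(y = c("(Intercept)" = 5,
                                           "extraction_time" = 3)))
  for (alpha in c(0.05, 0.35, 0.5))
    expect_equal(stepwise_select(syn, "y", alpha)$terms, "extraction_time")
})

test_that("stepwise reproduces the study's Danshensu term set at 0.35", {
  sel <- stepwise_select(dh$design, "danshensu", 0.35)
  expect_setequal(sel$terms, danhong_term_sets()$danshensu)
})

test_that("stepwise solutions are fixed points of the add/remove rules", {
  C <- design_matrix(coded_settings(dh$design), quad_terms(dh$factors))[, -1]
  alpha <- 0.35
  for (cqa in dh$design$cqa_names) {
    sel <- stepwise_select(dh$design, cqa, alpha)
    inc <- match(sel$terms, quad_terms(dh$factors))
    # no included term is removable
    expect_true(all(sel$p.value[-1] <= alpha))
    # no excluded candidate is addable
    for (j in setdiff(seq_len(ncol(C)), inc)) {
      trial <- sort(c(inc, j))
      o <- oracle_ols(cbind(1, C[, trial]),
                      dh$design$responses[[cqa]])
      expect_gte(o$p[which(trial == j) + 1], alpha)
    }
  }
})

test_that("degenerate stepwise results keep the intercept-only model", {
  # pure noise around a constant: tiny alpha leaves nothing significant
  syn <- make_synthetic(noise_rsd = 0.05, seed = 99,
                        coefs = list(y = c("(Intercept)" = 100)))
  sel <- stepwise_select(syn, "y", alpha_enter = 0.001)
  expect_length(sel$terms, 0)
  expect_equal(unname(predict(sel, verification_point)),
               unname(coef(sel)[1]))
})
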