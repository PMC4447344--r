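test_that("center-replicate noise estimation matches hand statistics", {
  noise <- estimate_noise(dh$design)
  tab <- noise$table
  dsu <- c(1.934, 1.715, 1.834)
  expect_equal(tab$center_mean[tab$cqa == "danshensu"], mean(dsu))
  expect_equal(round(100 * tab$rsd[tab$cqa == "danshensu"], 1), 6.0)
  dm <- c(479.9, 437.6, 485.2)
  expect_equal(round(tab$center_mean[tab$cqa == "dry_matter"], 1), 467.6)
  expect_equal(tab$center_sd[tab$cqa == "dry_matter"], sd(dm))
  expect_false(any(tab$degenerate))
})

test_that("degenerate and missing replicate groups are handled", {
  fs <- unit_factor()
  d <- design_table(data.frame(x = c(0, 0, 0, 1)),
                    data.frame(y = c(2, 2, 2, 3)), fs)
  expect_warning(noise <- estimate_noise(d), "identical replicate")
  expect_true(noise$table$degenerate)
  d2 <- design_table(data.frame(x = c(-1, 0, 1)),
                     data.frame(y = c(1, 2, 3)), fs)
  expect_error(estimate_noise(d2), "replicate")
})

test_that("moment matching hits the target mean and SD in every family", {
  for (fam in c("normal", "lognormal", "sqrt-normal",
                "reciprocal-normal")) {
    par <- match_moments(fam, mean = 2, sd = 0.12)
    # numeric moments of the transformed draw as an independent check
    z <- seq(par$mu - 8 * par$sigma, par$mu + 8 * par$sigma,
             length.out = 40001)
    w <- dnorm(z, par$mu, par$sigma); w <- w / sum(w)
    x <- switch(fam, "normal" = z, "lognormal" = exp(z),
                "sqrt-normal" = z^2, "reciprocal-normal" = 1 / z)
    m <- sum(w * x); s <- sqrt(sum(w * (x - m)^2))
    expect_equal(m, 2, tolerance = 1e-4)
    expect_equal(s, 0.12, tolerance = 1e-3)
  }
})

test_that("large normal and lognormal samples match the targets", {
  set.seed(2024)
  fs <- unit_factor()
  d <- design_table(data.frame(x = c(0, 0, 0)),
                    data.frame(y = c(1.9, 2.0, 2.1)), fs)
  for (fam in c("normal", "lognormal")) {
    noise <- noise_model("y", center_mean = 2, rsd = 0.06,
                         replicate_runs = 1:3, family = fam)
    draws <- draw_responses(d, noise, n_sims = 34000)
    x <- as.vector(draws)   # every run draws from the center distribution
    expect_equal(mean(x), 2, tolerance = 0.002 / 2)
    expect_equal(sd(x), 0.12, tolerance = 0.002 / 0.12)
    if (fam != "normal") expect_true(all(x > 0))
  }
})

test_that("zero RSD makes draws deterministic at the target means", {
  noise0 <- noise_model(dh$design$cqa_names,
                        center_mean = estimate_noise(dh$design)$table$center_mean,
                        rsd = 0, replicate_runs = c(5, 12, 14))
  drawn <- draw_responses(dh$design, noise0)
  nonrep <- setdiff(1:15, c(5, 12, 14))
  expect_equal(as.matrix(drawn)[nonrep, ],
               as.matrix(dh$design$responses)[nonrep, ])
  # replicate rows collapse onto the center mean, their shared target
  for (i in c(5, 12, 14))
    expect_equal(unname(unlist(drawn[i, ])),
                 noise0$table$center_mean, ignore_attr = TRUE)
})

test_that("non-center runs scale their SD with the measured value", {
  set.seed(5)
  fs <- unit_factor()
  d <- design_table(data.frame(x = c(0, 0, 0, 1)),
                    data.frame(y = c(1.9, 2.0, 2.1, 8)), fs)
  noise <- estimate_noise(d)
  draws <- draw_responses(d, noise, n_sims = 20000)
  expect_equal(mean(draws[4, 1, ]), 8, tolerance = 0.01)
  expect_equal(sd(draws[4, 1, ]), noise$table$rsd * 8, tolerance = 0.01)
})
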