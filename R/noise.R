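#' Estimate the measurement-noise model from center replicates
#'
#' The Monte-Carlo procedure regenerates every response from a "given
#' distribution" whose dispersion is anchored at the design's replicated
#' run.  Per CQA, the sample mean and sample standard deviation (n-1
#' denominator) of the largest replicate group give the center mean and SD;
#' their ratio is the relative standard deviation (RSD).  Non-replicated
#' runs are assumed to share that RSD, so their SD is `rsd * measured
#' value`.
#'
#' @param design a [design_table()] containing a replicate group of at
#'   least 3 runs.
#' @param family distribution family used when drawing: one of
#'   `"normal"`, `"lognormal"`, `"sqrt-normal"`, `"reciprocal-normal"`.
#' @return A `noise_model` object: `family`, `replicate_runs` (row
#'   indices), and a data frame `table` with per-CQA `center_mean`,
#'   `center_sd`, `rsd` and a `degenerate` flag (identical replicates).
#' @examples
#' dh <- danhong_fixture()
#' estimate_noise(dh$design)
#' @export
estimate_noise <- function(design, family = c("normal", "lognormal",
                                              "sqrt-normal",
                                              "reciprocal-normal")) {
  stopifnot(inherits(design, "design_table"))
  family <- match.arg(family)
  groups <- replicate_groups(design, min_size = 3)
  if (!length(groups))
    stop("no replicate group with >= 3 runs; cannot estimate noise")
  idx <- groups[[1]]
  tab <- do.call(rbind, lapply(design$cqa_names, function(cc) {
    v <- design$responses[[cc]][idx]
    m <- mean(v); s <- stats::sd(v)
    data.frame(cqa = cc, center_mean = m, center_sd = s, rsd = s / m,
               degenerate = s == 0, stringsAsFactors = FALSE)
  }))
  if (any(tab$degenerate))
    warning("identical replicate values for: ",
            paste(tab$cqa[tab$degenerate], collapse = ", "),
            " (rsd = 0; draws are deterministic)")
  structure(list(family = family, replicate_runs = idx, table = tab),
            class = "noise_model")
}

#' Build a noise model from known per-CQA means and RSDs
#'
#' Bypasses replicate-based estimation when the center means and relative
#' standard deviations are known (from historical data, or forced to zero
#' to make the Monte-Carlo draws degenerate).
#'
#' @param cqa character vector of CQA names.
#' @param center_mean,rsd numeric vectors per CQA (`center_sd` is
#'   `rsd * center_mean`).
#' @param replicate_runs integer row indices of the center-point runs.
#' @param family distribution family (see [estimate_noise()]).
#' @return A `noise_model` object.
#' @export
noise_model <- function(cqa, center_mean, rsd, replicate_runs,
                        family = "normal") {
  stopifnot(length(cqa) == length(center_mean), all(center_mean > 0),
            all(rsd >= 0))
  rsd <- rep_len(rsd, length(cqa))
  structure(list(family = family, replicate_runs = as.integer(replicate_runs),
                 table = data.frame(cqa = cqa, center_mean = center_mean,
                                    center_sd = rsd * center_mean,
                                    rsd = rsd, degenerate = rsd == 0,
                                    stringsAsFactors = FALSE)),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("Noise model (%s family), center replicates at runs %s\n",
              x$family, paste(x$replicate_runs, collapse = ", ")))
  tab <- x$table
  tab$rsd_pct <- 100 * tab$rsd
  print(tab[c("cqa", "center_mean", "center_sd", "rsd_pct")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Moment-matched parameters of the sampling distributions
#'
#' Each family draws a positive response whose *distribution-level* mean
#' and standard deviation equal the targets.  For `normal` the parameters
#' are the targets themselves.  For `lognormal` (`log X` normal) the
#' closed-form inversion is `sigma^2 = log(1 + cv^2)`,
#' `mu = log(mean) - sigma^2/2`.  For `sqrt-normal` (`sqrt(X)` normal,
#' i.e. `X = Z^2`, `Z ~ N(mu, sigma)`) the moments
#' `E X = mu^2 + sigma^2`, `Var X = 4 mu^2 sigma^2 + 2 sigma^4` invert in
#' closed form.  For `reciprocal-normal` (`1/X` normal) no closed form
#' exists; the coefficient of variation of `1/Z` is scale-free in the CV of
#' `Z`, so a one-dimensional root search on numerically integrated moments
#' finds the CV of `Z`, and the mean fixes its location.  Reciprocal
#' moments are taken over `Z` within 8 SDs of its mean, which requires a
#' modest target CV (< 0.1); at that level the probability of `Z` straying
#' near zero is negligible.
#'
#' @param family distribution family (see [estimate_noise()]).
#' @param mean,sd target mean (> 0) and SD (>= 0) of the drawn value.
#' @return List with elements `mu` and `sigma` on the transformed
#'   (normal) scale; vectorized over `mean` and `sd`.
#' @export
match_moments <- function(family, mean, sd) {
  stopifnot(all(mean > 0), all(sd >= 0))
  n <- max(length(mean), length(sd))
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  cv <- sd / mean
  switch(family,
    "normal" = list(mu = mean, sigma = sd),
    "lognormal" = {
      s2 <- log(1 + cv^2)
      list(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
    },
    "sqrt-normal" = {
      v <- sd^2
      s2 <- mean - sqrt(mean^2 - v / 2)   # real because cv < sqrt(2) always here
      list(mu = sqrt(mean - s2), sigma = sqrt(s2))
    },
    "reciprocal-normal" = {
      cvz <- vapply(cv, reciprocal_cvz, 0.0)
      m1 <- vapply(cvz, function(c1) reciprocal_moments(c1)[1], 0.0)
      muz <- m1 / mean                    # E[1/Z] scales as 1/location
      list(mu = muz, sigma = muz * cvz)
    },
    stop("unknown family: '", family, "'"))
}

# mean and sd of 1/Z for Z ~ N(1, cvz), integrated over +/- 8 SD.
reciprocal_moments <- function(cvz) {
  if (cvz == 0) return(c(1, 0))
  if (cvz >= 0.1)
    stop("reciprocal-normal family needs target CV < 0.1 (got ",
         signif(cvz, 3), ")")
  lo <- 1 - 8 * cvz; hi <- 1 + 8 * cvz
  m1 <- stats::integrate(function(z) stats::dnorm(z, 1, cvz) / z,
                         lo, hi, rel.tol = 1e-10)$value
  m2 <- stats::integrate(function(z) stats::dnorm(z, 1, cvz) / z^2,
                         lo, hi, rel.tol = 1e-10)$value
  c(m1, sqrt(max(m2 - m1^2, 0)))
}

# CV of Z such that 1/Z has coefficient of variation cv_target.
reciprocal_cvz <- function(cv_target) {
  if (cv_target == 0) return(0)
  f <- function(c1) { m <- reciprocal_moments(c1); m[2] / m[1] - cv_target }
  stats::uniroot(f, lower = cv_target / 4, upper = min(cv_target * 2, 0.099),
                 tol = 1e-12)$root
}

# Per-run target means/SDs: replicate-group runs draw from the center
# distribution; other runs centre on their measured value with SD
# rsd * value.
noise_targets <- function(design, noise) {
  R <- as.matrix(design$responses)
  tab <- noise$table[match(colnames(R), noise$table$cqa), ]
  mu <- R
  mu[noise$replicate_runs, ] <- rep(tab$center_mean,
                                    each = length(noise$replicate_runs))
  sd <- sweep(mu, 2, tab$rsd, "*")
  list(mean = mu, sd = sd)
}

#' Draw regenerated response tables
#'
#' Draws each run-by-CQA response independently from the noise model's
#' family, moment-matched so the drawn value has the target mean and SD:
#' replicate-group runs use the center mean/SD, other runs their measured
#' value with SD `rsd * value`.  Draws under the `normal` family are kept
#' as-is even if negative (at the RSD levels of replicated designs such
#' draws are vanishingly rare, and truncation would bias the moments); the
#' transformed families are positive by construction.
#'
#' @param design a [design_table()].
#' @param noise a [estimate_noise()] result.
#' @param n_sims number of regenerated tables.
#' @return For `n_sims = 1` a data frame shaped like `design$responses`;
#'   otherwise a 3-d array (run x CQA x simulation).  Uses the current RNG
#'   state; call `set.seed()` beforehand for reproducibility.
#' @export
draw_responses <- function(design, noise, n_sims = 1) {
  stopifnot(inherits(noise, "noise_model"), n_sims >= 1)
  Y <- draw_response_matrix(design, noise, n_sims)
  n <- nrow(Y); ncqa <- length(design$cqa_names)
  if (n_sims == 1) {
    out <- as.data.frame(Y)
    names(out) <- design$cqa_names
    return(out)
  }
  array(Y, dim = c(n, ncqa, n_sims),
        dimnames = list(NULL, design$cqa_names, NULL))
}

# Flat draw matrix: n_runs x (n_sims * ncqa), CQA index fastest
# (column (s-1)*ncqa + j).  Optionally seeds the RNG.
draw_response_matrix <- function(design, noise, n_sims, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tg <- noise_targets(design, noise)
  n <- nrow(tg$mean); ncqa <- ncol(tg$mean)
  par <- match_moments(noise$family, as.numeric(tg$mean), as.numeric(tg$sd))
  mu <- matrix(par$mu, n, ncqa); sg <- matrix(par$sigma, n, ncqa)
  Z <- array(stats::rnorm(n * ncqa * n_sims), dim = c(n, ncqa, n_sims))
  Z <- sweep(sweep(Z, c(1, 2), sg, "*"), c(1, 2), mu, "+")
  X <- switch(noise$family,
              "normal" = Z,
              "lognormal" = exp(Z),
              "sqrt-normal" = Z^2,
              "reciprocal-normal" = 1 / Z)
  # (n, ncqa, n_sims) flattens so column (s-1)*ncqa + j is CQA j of sim s
  matrix(X, n, n_sims * ncqa)
}
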