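#' Simulation configuration
#'
#' Collects the tunable settings of a Monte-Carlo design-space run.
#' Defaults are the optimized settings of the worked example: 10000
#' simulations, 0.01 coded-unit step length, stepwise significance 0.35,
#' probability threshold 0.95, and 10 repeats for stability metrics.
#'
#' @param n_sims number of regenerated data sets per computation (>= 1).
#' @param step_length grid spacing in coded units; the grid spans
#'   `[-1, 1]` per free factor with `round(2/step_length) + 1` points per
#'   axis, endpoints included.
#' @param alpha stepwise significance level for adding and removing terms.
#' @param threshold acceptance probability defining the design space,
#'   in (0, 1).
#' @param n_repeats independent full recomputations for the ADSS/RSDDSS
#'   stability metrics.
#' @param seed master integer seed; all per-repeat and per-simulation
#'   randomness derives from it deterministically.
#' @param max_sweeps stepwise sweep limit.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sims = 10000, step_length = 0.01, alpha = 0.35,
                       threshold = 0.95, n_repeats = 10, seed = 1,
                       max_sweeps = 50) {
  # thresholds >= 1 are tolerated: they simply empty the mask (with warning)
  stopifnot(n_sims >= 1, step_length > 0, step_length <= 2,
            alpha > 0, alpha <= 1, threshold > 0, n_repeats >= 1)
  structure(list(n_sims = as.integer(n_sims), step_length = step_length,
                 alpha = alpha, threshold = threshold,
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed),
                 max_sweeps = as.integer(max_sweeps)),
            class = "sim_config")
}

# Deterministic substream seeds from the master seed (kept below 2^31).
derive_seeds <- function(master, n) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Fit the Monte-Carlo model ensemble
#'
#' Regenerates the full response table `n_sims` times from the noise model
#' and stepwise-fits every CQA on each regenerated table, giving `n_sims`
#' complete model sets.  Simulations where any CQA's selection fails are
#' dropped and counted; more than 1% failures abort the run.
#'
#' @param design a [design_table()].
#' @param noise a [estimate_noise()] result.
#' @param cfg a [sim_config()]; `cfg$seed` fixes the draws.
#' @return An `rsm_ensemble` object: dense coefficient array
#'   (coefficient x CQA x simulation, unselected terms zero), per-fit SSE /
#'   PRESS / coefficient counts, term-selection frequencies, the inputs,
#'   and the failed-simulation count.
#' @examples
#' dh <- danhong_fixture()
#' ens <- fit_ensemble(dh$design, estimate_noise(dh$design),
#'                     sim_config(n_sims = 50, seed = 7))
#' @export
fit_ensemble <- function(design, noise, cfg = sim_config()) {
  stopifnot(inherits(design, "design_table"),
            inherits(noise, "noise_model"), inherits(cfg, "sim_config"))
  C <- candidate_matrix(coded_settings(design), design$factors)
  ncqa <- length(design$cqa_names)
  Y <- draw_response_matrix(design, noise, cfg$n_sims, seed = cfg$seed)
  res <- cpp_fit_ensemble(C, Y, cfg$alpha, cfg$alpha, cfg$max_sweeps)
  bad_cols <- which(res$status != 0L)
  bad_sims <- unique((bad_cols - 1L) %/% ncqa + 1L)
  if (length(bad_sims) > 0.01 * cfg$n_sims)
    stop("stepwise selection failed in ", length(bad_sims), " of ",
         cfg$n_sims, " simulations (> 1%)")
  keep_sims <- setdiff(seq_len(cfg$n_sims), bad_sims)
  keep <- rep((keep_sims - 1L) * ncqa, each = ncqa) + seq_len(ncqa)
  sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
  structure(list(
    coefficients = array(res$coefficients[, keep, drop = FALSE],
                         dim = c(nrow(res$coefficients), ncqa,
                                 length(keep_sims)),
                         dimnames = list(c("(Intercept)",
                                           quad_terms(design$factors)),
                                         design$cqa_names, NULL)),
    selected = res$selected[, keep, drop = FALSE],
    sse = res$sse[keep], press = res$press[keep], ncoef = res$ncoef[keep],
    sst = sst[keep],
    n_sims = length(keep_sims), n_failed = length(bad_sims),
    design = design, noise = noise, cfg = cfg),
    class = "rsm_ensemble")
}

#' @export
print.rsm_ensemble <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo model ensemble: %d simulations (%d failed), %s family, alpha %.2f\n",
    x$n_sims, x$n_failed, x$noise$family, x$cfg$alpha))
  freq <- matrix(rowMeans(array(x$selected,
                                dim = c(nrow(x$selected),
                                        dim(x$coefficients)[2], x$n_sims)),
                          dims = 1), ncol = 1)
  cat("Overall term-selection frequency:\n")
  print(round(stats::setNames(drop(freq),
                              quad_terms(x$design$factors)), 3))
  invisible(x)
}

#' Per-simulation model criteria of an ensemble
#'
#' @param ensemble an [fit_ensemble()] result.
#' @return Data frame of mean `R2`, `R2adj`, `R2pred`, `AIC`, `BIC` per
#'   CQA over the ensemble.
#' @export
ensemble_criteria <- function(ensemble) {
  stopifnot(inherits(ensemble, "rsm_ensemble"))
  n <- nrow(ensemble$design$settings)
  crit <- criteria_from_sums(ensemble$sse, ensemble$press, ensemble$sst,
                             n, ensemble$ncoef)
  crit <- matrix(crit, ncol = 5,
                 dimnames = list(NULL,
                                 c("R2", "R2adj", "R2pred", "AIC", "BIC")))
  cqa_of <- rep_len(ensemble$design$cqa_names, nrow(crit))
  means <- apply(crit, 2, function(v) tapply(v, cqa_of, mean))
  means <- means[ensemble$design$cqa_names, , drop = FALSE]
  data.frame(cqa = rownames(means), means, row.names = NULL,
             check.names = FALSE)
}

# Ensemble predictions at arbitrary coded points: list(pred = ncqa x nsims
# matrix for a single point, or G %*% coefs handling), used by verify_point.
ensemble_coef_matrix <- function(ensemble) {
  d <- dim(ensemble$coefficients)
  matrix(ensemble$coefficients, d[1], d[2] * d[3])
}

#' Joint-acceptance probability map over a coded factor grid
#'
#' For every node of a regular grid over `[-1, 1]^2` in the two free
#' (non-sliced) factors, with the remaining factor fixed at a coded slice
#' value, evaluates all CQA models of every simulation and reports the
#' fraction of simulations whose predictions jointly lie inside all CQA
#' limits.  Probabilities are exact empirical fractions with resolution
#' `1 / n_sims`.
#'
#' @param ensemble an [fit_ensemble()] result.
#' @param cqas a [cqa_spec()] with the acceptance limits (order must cover
#'   the design's CQAs).
#' @param slice named coded value(s) of the factor(s) held fixed; by
#'   default every `discrete` factor at coded 0.
#' @param step_length grid spacing in coded units (default from the
#'   ensemble's configuration).
#' @return A `probability_map`: free-factor axes (coded), the probability
#'   matrix, the slice, and metadata.
#' @export
probability_map <- function(ensemble, cqas, slice = NULL,
                            step_length = ensemble$cfg$step_length) {
  stopifnot(inherits(ensemble, "rsm_ensemble"), inherits(cqas, "cqa_spec"))
  design <- ensemble$design
  if (is.null(slice)) {
    dn <- design$factors$name[design$factors$discrete]
    slice <- stats::setNames(rep(0, length(dn)), dn)
  }
  if (is.null(names(slice)) || !all(names(slice) %in% design$factors$name))
    stop("slice must be a named coded value of known factor(s)")
  free <- setdiff(design$factors$name, names(slice))
  if (length(free) != 2)
    stop("need exactly 2 free factors for a map (got ",
         length(free), ")")
  limits <- cqas[match(design$cqa_names, cqas$name), ]
  if (anyNA(limits$name))
    stop("cqas lacks limits for: ",
         paste(setdiff(design$cqa_names, cqas$name), collapse = ", "))
  npts <- round(2 / step_length) + 1
  ax <- seq(-1, 1, length.out = npts)
  grid <- expand.grid(ax, ax, KEEP.OUT.ATTRS = FALSE)  # free[1] fastest
  coded <- matrix(0, nrow(grid), nrow(design$factors),
                  dimnames = list(NULL, design$factors$name))
  coded[, free[1]] <- grid[[1]]
  coded[, free[2]] <- grid[[2]]
  for (nm in names(slice)) coded[, nm] <- slice[[nm]]
  G <- design_matrix(coded, quad_terms(design$factors))
  prob <- cpp_joint_prob(G, ensemble_coef_matrix(ensemble),
                         length(design$cqa_names),
                         limits$lower, limits$upper)
  structure(list(axes = stats::setNames(list(ax, ax), free),
                 prob = matrix(prob, npts, npts,
                               dimnames = stats::setNames(list(NULL, NULL),
                                                          free)),
                 slice = slice, free = free, factors = design$factors,
                 n_sims = ensemble$n_sims, step_length = step_length),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf(
    "Probability map: %s grid over %s, slice %s, %d simulations\n",
    paste(dim(x$prob), collapse = " x "), paste(x$free, collapse = " / "),
    paste(names(x$slice), "=", x$slice, collapse = ", "), x$n_sims))
  cat(sprintf("probability range: %.3f - %.3f\n",
              min(x$prob), max(x$prob)))
  invisible(x)
}

#' @export
as.data.frame.probability_map <- function(x, ...) {
  grid <- expand.grid(x$axes[[1]], x$axes[[2]], KEEP.OUT.ATTRS = FALSE)
  fs <- x$factors[match(x$free, x$factors$name), ]
  out <- data.frame(grid[[1]], grid[[2]],
                    fs$center[1] + fs$half_range[1] * grid[[1]],
                    fs$center[2] + fs$half_range[2] * grid[[2]],
                    as.vector(x$prob))
  names(out) <- c(paste0(x$free, "_coded"), paste0(x$free, "_uncoded"),
                  "probability")
  out
}

#' Plot a probability map with the design-space iso-contour
#'
#' @param x a [probability_map()].
#' @param threshold probability level of the drawn iso-contour.
#' @param uncoded draw axes in physical units?
#' @param ... passed to [graphics::image()].
#' @export
plot.probability_map <- function(x, threshold = 0.95, uncoded = TRUE, ...) {
  fs <- x$factors[match(x$free, x$factors$name), ]
  a1 <- x$axes[[1]]; a2 <- x$axes[[2]]
  if (uncoded) {
    a1 <- fs$center[1] + fs$half_range[1] * a1
    a2 <- fs$center[2] + fs$half_range[2] * a2
  }
  lab <- paste0(fs$name, ifelse(nzchar(fs$unit), paste0(" (", fs$unit, ")"),
                                ""))
  graphics::image(a1, a2, x$prob, col = grDevices::hcl.colors(64, "Blues",
                                                              rev = TRUE),
                  xlab = lab[1], ylab = lab[2], ...)
  graphics::contour(a1, a2, x$prob, levels = threshold, lwd = 2,
                    col = "white", add = TRUE)
  invisible(x)
}

#' Extract the design space and its stability metrics
#'
#' The design space is the set of grid cells whose joint-acceptance
#' probability is at least the threshold.  Its dimensionless size (DSS) is
#' the fraction of grid cells in the mask over the coded `[-1, 1]^2`
#' slice.  Applied to a full design table, the computation is repeated
#' `n_repeats` times with independent derived seeds to give the average
#' size (ADSS) and its relative standard deviation (RSDDSS, in %), the
#' stability diagnostics of the simulation settings.
#'
#' @param x a [probability_map()] (single mask and size) or a
#'   [design_table()] (full repeated pipeline).
#' @param ... method arguments.
#' @return A `design_space` object: the (first-repeat) map, logical mask,
#'   `threshold`, per-repeat `dss`, `adss` and `rsddss`.
#' @examples
#' dh <- danhong_fixture()
#' ds <- design_space(dh$design, dh$cqas,
#'                    cfg = sim_config(n_sims = 100, step_length = 0.05,
#'                                     n_repeats = 2, seed = 1),
#'                    slice = c(extraction_number = 0))
#' ds$adss
#' @export
design_space <- function(x, ...) UseMethod("design_space")

#' @rdname design_space
#' @param threshold acceptance probability defining the mask.
#' @export
design_space.probability_map <- function(x, threshold = 0.95, ...) {
  mask <- x$prob >= threshold
  if (!any(mask)) warning("empty design space at threshold ", threshold)
  structure(list(map = x, mask = mask, threshold = threshold,
                 dss = mean(mask), adss = mean(mask), rsddss = NA_real_),
            class = "design_space")
}

#' @rdname design_space
#' @param cqas a [cqa_spec()] of acceptance limits.
#' @param cfg a [sim_config()].
#' @param slice named coded value(s) of the fixed factor(s).
#' @param noise optional [estimate_noise()] result; estimated from the
#'   design with the given `family` when omitted.
#' @param family distribution family when `noise` is omitted.
#' @export
design_space.design_table <- function(x, cqas, cfg = sim_config(),
                                      slice = NULL, noise = NULL,
                                      family = "normal", ...) {
  if (is.null(noise)) noise <- estimate_noise(x, family)
  seeds <- derive_seeds(cfg$seed, cfg$n_repeats)
  dss <- numeric(cfg$n_repeats)
  n_failed <- integer(cfg$n_repeats)
  first <- NULL
  for (r in seq_len(cfg$n_repeats)) {
    cfg_r <- cfg; cfg_r$seed <- seeds[r]
    ens <- fit_ensemble(x, noise, cfg_r)
    map <- probability_map(ens, cqas, slice = slice)
    if (r == 1) first <- map
    dss[r] <- mean(map$prob >= cfg$threshold)
    n_failed[r] <- ens$n_failed
  }
  adss <- mean(dss)
  if (adss == 0)
    stop("design space empty in every repeat; RSDDSS undefined")
  structure(list(map = first, mask = first$prob >= cfg$threshold,
                 threshold = cfg$threshold, dss = dss, adss = adss,
                 rsddss = 100 * stats::sd(dss) / adss,
                 n_failed = n_failed, repeat_seeds = seeds,
                 cfg = cfg, noise = noise),
            class = "design_space")
}

#' @export
print.design_space <- function(x, ...) {
  cat(sprintf("Design space at threshold %.2f\n", x$threshold))
  cat(sprintf("  DSS per repeat: %s\n",
              paste(signif(x$dss, 4), collapse = ", ")))
  cat(sprintf("  ADSS %.4f", x$adss))
  if (is.finite(x$rsddss)) cat(sprintf("  RSDDSS %.3f%%", x$rsddss))
  cat("\n")
  invisible(x)
}

#' @export
plot.design_space <- function(x, ...) {
  plot.probability_map(x$map, threshold = x$threshold, ...)
}

#' Verify a candidate operating point
#'
#' Reports, for a given uncoded operating point: the point-estimate
#' prediction of every CQA (stepwise fits of the measured data), the
#' ensemble-mean prediction, whether the point estimate lies within the
#' CQA limits, and the joint probability of meeting all limits (fraction
#' of ensemble simulations whose predictions are all inside the limits).
#'
#' @param ensemble an [fit_ensemble()] result.
#' @param point named numeric vector of uncoded factor settings.
#' @param cqas a [cqa_spec()] of limits.
#' @return A `verification` object with the per-CQA table and
#'   `joint_prob`.
#' @export
verify_point <- function(ensemble, point, cqas) {
  stopifnot(inherits(ensemble, "rsm_ensemble"), inherits(cqas, "cqa_spec"))
  design <- ensemble$design
  coded <- code_factors(point, design$factors)
  if (any(abs(coded) > 1 + 1e-12))
    warning("point lies outside the coded [-1, 1] design region")
  fits <- stepwise_fit_all(design, alpha = ensemble$cfg$alpha,
                           max_sweeps = ensemble$cfg$max_sweeps)
  limits <- cqas[match(design$cqa_names, cqas$name), ]
  if (anyNA(limits$name)) stop("cqas lacks limits for some design CQAs")
  point_pred <- vapply(fits, function(f) predict(f, coded, coded = TRUE),
                       0.0)
  g <- design_matrix(coded, quad_terms(design$factors))
  pred <- matrix(drop(g %*% ensemble_coef_matrix(ensemble)),
                 nrow = length(design$cqa_names))
  ens_mean <- rowMeans(pred)
  ok <- pred >= limits$lower & pred <= limits$upper
  joint <- mean(colSums(ok) == nrow(ok))
  tab <- data.frame(cqa = design$cqa_names,
                    predicted = point_pred,
                    ensemble_mean = ens_mean,
                    lower = limits$lower, upper = limits$upper,
                    within = point_pred >= limits$lower &
                             point_pred <= limits$upper,
                    row.names = NULL)
  structure(list(point = point, coded = drop(coded), table = tab,
                 joint_prob = joint, n_sims = ensemble$n_sims),
            class = "verification")
}

#' @export
print.verification <- function(x, digits = 4, ...) {
  cat("Operating-point verification at",
      paste(names(x$point), "=", x$point, collapse = ", "), "\n")
  tab <- x$table
  tab$within <- ifelse(tab$within, "Yes", "No")
  print(tab, digits = digits, row.names = FALSE)
  cat(sprintf("Joint probability of meeting all limits: %.4f (%d sims)\n",
              x$joint_prob, x$n_sims))
  invisible(x)
}

#' Compare noise-distribution families
#'
#' Runs the full ensemble + design-space computation once per distribution
#' family with the *same* master seed (paired underlying normal draws), so
#' family effects are compared on common random numbers.  Reports the mean
#' model criteria and the design-space size per family.
#'
#' @param design a [design_table()].
#' @param cqas a [cqa_spec()].
#' @param cfg a [sim_config()].
#' @param families subset of the four supported family names.
#' @param slice named coded value(s) of the fixed factor(s).
#' @return List with a `summary` data frame (family, dss, mean criteria)
#'   and the per-family `design_space` results.
#' @export
compare_distributions <- function(design, cqas, cfg = sim_config(),
                                  families = c("normal", "lognormal",
                                               "sqrt-normal",
                                               "reciprocal-normal"),
                                  slice = NULL) {
  results <- list()
  rows <- list()
  for (fam in families) {
    noise <- estimate_noise(design, fam)
    ens <- fit_ensemble(design, noise, cfg)
    map <- probability_map(ens, cqas, slice = slice)
    ds <- design_space(map, threshold = cfg$threshold)
    crit <- ensemble_criteria(ens)
    results[[fam]] <- ds
    rows[[fam]] <- data.frame(family = fam, dss = ds$dss,
                              t(colMeans(crit[-1])),
                              check.names = FALSE)
  }
  list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
       results = results)
}
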