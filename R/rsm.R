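#' The full quadratic candidate basis
#'
#' Canonical term order for a k-factor quadratic response surface: all
#' linear terms in factor order, then all pairwise interactions
#' (`"a:b"`, first-factor major), then all pure quadratics (`"a^2"`).
#' The intercept is implicit and always included.
#'
#' @param factors a [factor_spec()].
#' @return Character vector of term labels.
#' @examples
#' quad_terms(factor_spec(c("t", "r"), "", c(1, 8), c(1, 2)))
#' @export
quad_terms <- function(factors) {
  fn <- factors$name
  k <- length(fn)
  inter <- character(0)
  if (k >= 2)
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
      inter <- c(inter, paste0(fn[i], ":", fn[j]))
  c(fn, inter, paste0(fn, "^2"))
}

# Evaluate one term label on a coded settings matrix.
term_column <- function(coded, term) {
  fn <- colnames(coded)
  if (term %in% fn) return(coded[, term])
  if (grepl(":", term, fixed = TRUE)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2 && all(parts %in% fn))
      return(coded[, parts[1]] * coded[, parts[2]])
  }
  if (grepl("^2", term, fixed = TRUE)) {
    base <- sub("\\^2$", "", term)
    if (base %in% fn) return(coded[, base]^2)
  }
  stop("unknown model term: '", term, "'")
}

#' Model matrix for a quadratic term set
#'
#' Builds the regression matrix for a set of quadratic-basis terms on coded
#' factor settings: an all-ones intercept column followed by one column per
#' term (interaction columns are elementwise products, quadratic columns
#' elementwise squares).
#'
#' @param coded numeric matrix of coded settings, columns named for factors.
#' @param terms character vector of term labels (subset of [quad_terms()]);
#'   may be empty for the intercept-only model.
#' @return Numeric matrix, `nrow(coded)` x `(1 + length(terms))`.
#' @export
design_matrix <- function(coded, terms = character(0)) {
  coded <- as.matrix(coded)
  if (any(!is.finite(coded))) stop("coded values must be finite")
  if (anyDuplicated(terms)) stop("duplicate model terms")
  X <- matrix(1, nrow(coded), 1 + length(terms),
              dimnames = list(NULL, c("(Intercept)", terms)))
  for (j in seq_along(terms))
    X[, j + 1] <- term_column(coded, terms[j])
  X
}

# Candidate matrix: all quad_terms columns, no intercept.
candidate_matrix <- function(coded, factors) {
  terms <- quad_terms(factors)
  design_matrix(coded, terms)[, -1, drop = FALSE]
}

#' Fit a quadratic response-surface model by least squares
#'
#' Fits the selected quadratic-basis terms (plus intercept) to one CQA of a
#' design table by ordinary least squares on the coded factor scale, with
#' two-sided t tests per coefficient and the usual model-quality criteria
#' (see [model_criteria()]).
#'
#' @param design a [design_table()].
#' @param cqa name of the response column to fit.
#' @param terms character vector of term labels; default the full quadratic
#'   basis.
#' @return An object of class `rsm_fit` with components `coefficients`,
#'   `se`, `t`, `p.value`, `fitted.values`, `residuals`, `sse`, `sst`,
#'   `df.residual`, `press`, `criteria`, `terms`, `cqa`, `factors`.
#' @seealso [stepwise_select()], [predict.rsm_fit()]
#' @examples
#' dh <- danhong_fixture()
#' fit <- rsm_fit(dh$design, "danshensu",
#'                c("extraction_time", "wm_ratio", "extraction_number"))
#' coef(fit)
#' @export
rsm_fit <- function(design, cqa, terms = quad_terms(design$factors)) {
  stopifnot(inherits(design, "design_table"))
  if (!cqa %in% design$cqa_names) stop("unknown CQA: '", cqa, "'")
  y <- design$responses[[cqa]]
  X <- design_matrix(coded_settings(design), terms)
  fit_ols_matrix(X, y, terms, cqa, design$factors)
}

# Shared OLS engine on a prepared model matrix (intercept first).
fit_ols_matrix <- function(X, y, terms, cqa, factors) {
  n <- nrow(X); p <- ncol(X)
  if (n <= p)
    stop("need more runs (", n, ") than coefficients (", p, ")")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1, p)]]
    stop("rank-deficient model matrix; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  df <- n - p
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(sse / df * diag(XtXinv), 0))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  h <- rowSums((X %*% XtXinv) * X)
  press <- if (any(h > 1 - 1e-10)) NA_real_ else sum((resid / (1 - h))^2)
  structure(list(coefficients = beta, se = se, t = tval, p.value = pval,
                 fitted.values = fitted, residuals = resid,
                 sse = sse, sst = sst, df.residual = df,
                 leverage = h, press = press,
                 criteria = criteria_from_sums(sse, press, sst, n, p),
                 terms = terms, cqa = cqa, factors = factors,
                 nobs = n),
            class = "rsm_fit")
}

#' Model-quality criteria
#'
#' For a model with `p` coefficients (intercept included) on `n` runs:
#' `R2 = 1 - SSE/SST` (SST about the response mean),
#' `R2adj = 1 - (SSE/(n-p)) / (SST/(n-1))`,
#' `R2pred = 1 - PRESS/SST` with PRESS the leave-one-out prediction error
#' sum of squares computed through the hat matrix,
#' `AIC = n log(SSE/n) + 2p` and `BIC = n log(SSE/n) + p log(n)`.
#'
#' @param fit an [rsm_fit()].
#' @return Named numeric vector `c(R2, R2adj, R2pred, AIC, BIC)`.
#' @export
model_criteria <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  fit$criteria
}

criteria_from_sums <- function(sse, press, sst, n, p) {
  if (any(n - p < 1)) stop("criteria undefined: no residual degrees of freedom")
  r2 <- 1 - sse / sst
  r2adj <- 1 - (sse / (n - p)) / (sst / (n - 1))
  r2pred <- 1 - press / sst
  # guard log(0) for exact interpolation
  ll <- n * log(pmax(sse, .Machine$double.xmin) / n)
  c(R2 = r2, R2adj = r2adj, R2pred = r2pred,
    AIC = ll + 2 * p, BIC = ll + p * log(n))
}

#' @export
print.rsm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Quadratic response-surface fit: %s (coded units)\n", x$cqa))
  print(round(x$coefficients, digits))
  cat(sprintf("R2 %.4f  R2adj %.4f  R2pred %.4f\n",
              x$criteria["R2"], x$criteria["R2adj"], x$criteria["R2pred"]))
  invisible(x)
}

#' @export
summary.rsm_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients,
                    std.error = object$se,
                    t.value = object$t,
                    p.value = object$p.value)
  structure(list(cqa = object$cqa, table = tab, criteria = object$criteria,
                 df.residual = object$df.residual, press = object$press),
            class = "summary.rsm_fit")
}

#' @export
print.summary.rsm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Response: %s\n", x$cqa))
  print(round(x$table, digits))
  cat(sprintf("Residual df %d; PRESS %.4g\n", x$df.residual, x$press))
  print(round(x$criteria, digits))
  invisible(x)
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' @export
residuals.rsm_fit <- function(object, ...) object$residuals

#' @export
fitted.rsm_fit <- function(object, ...) object$fitted.values

#' Predict from a response-surface fit
#'
#' Evaluates `intercept + sum(coefficient * term value)` at new factor
#' settings.  Settings are given in uncoded physical units by default and
#' coded internally; pass `coded = TRUE` to supply coded values directly.
#'
#' @param object an [rsm_fit()].
#' @param newdata named numeric vector, matrix or data frame of factor
#'   settings (one column per factor).
#' @param coded logical; is `newdata` already on the coded scale?
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.rsm_fit <- function(object, newdata, coded = FALSE, ...) {
  x <- as_factor_matrix(newdata, object$factors$name)
  if (!coded) x <- code_factors(x, object$factors)
  X <- design_matrix(x, object$terms)
  drop(X %*% object$coefficients)
}

#' Bidirectional p-value stepwise term selection
#'
#' Selects a quadratic-basis term set for one CQA by the classical
#' p-value criterion, starting from the intercept-only model.  Each sweep
#' first adds the candidate term with the smallest coefficient p-value if
#' it is below `alpha_enter` (ties go to the earlier term in canonical
#' order), then removes the included term with the largest p-value if it
#' exceeds `alpha_remove` (ties go to the later term); sweeps repeat until
#' no change.  No model hierarchy is enforced: a quadratic or interaction
#' term may be kept while its parent linear term is dropped.  The procedure
#' is deterministic given the data and may legitimately return the
#' intercept-only model, whose predictions are constant.
#'
#' @param design a [design_table()].
#' @param cqa name of the response column.
#' @param alpha_enter significance level to add a term, in (0, 1].
#' @param alpha_remove significance level to remove a term; defaults to
#'   `alpha_enter` (equal add/remove levels).
#' @param max_sweeps sweep limit before declaring non-convergence.
#' @return An [rsm_fit()] on the selected term set, with the selection
#'   recorded in `$selection`.
#' @examples
#' dh <- danhong_fixture()
#' stepwise_select(dh$design, "danshensu", alpha_enter = 0.35)$terms
#' @export
stepwise_select <- function(design, cqa, alpha_enter = 0.35,
                            alpha_remove = alpha_enter, max_sweeps = 50) {
  stopifnot(inherits(design, "design_table"),
            alpha_enter > 0, alpha_enter <= 1,
            alpha_remove > 0, alpha_remove <= 1)
  if (!cqa %in% design$cqa_names) stop("unknown CQA: '", cqa, "'")
  C <- candidate_matrix(coded_settings(design), design$factors)
  y <- design$responses[[cqa]]
  res <- cpp_fit_ensemble(C, matrix(y, ncol = 1),
                          alpha_enter, alpha_remove, as.integer(max_sweeps))
  if (res$status[1] == 1L)
    stop("stepwise selection for '", cqa, "' did not converge within ",
         max_sweeps, " sweeps (cycling among: ",
         paste(colnames(C)[res$selected[, 1] == 1], collapse = ", "), ")")
  if (res$status[1] == 2L)
    stop("stepwise selection for '", cqa, "' hit a singular fit")
  sel <- quad_terms(design$factors)[res$selected[, 1] == 1]
  fit <- rsm_fit(design, cqa, sel)
  fit$selection <- list(alpha_enter = alpha_enter,
                        alpha_remove = alpha_remove)
  fit
}

#' Stepwise fits for every CQA of a design
#'
#' @param design a [design_table()].
#' @param alpha significance level for adding and removing terms.
#' @param ... passed to [stepwise_select()].
#' @return Named list of [rsm_fit()] objects, one per CQA.
#' @export
stepwise_fit_all <- function(design, alpha = 0.35, ...) {
  fits <- lapply(design$cqa_names, function(cc)
    stepwise_select(design, cc, alpha_enter = alpha, ...))
  names(fits) <- design$cqa_names
  fits
}

#' Average model criteria across a grid of significance levels
#'
#' Regenerates the response table `n_sims` times from the noise model,
#' stepwise-fits every CQA at each significance level on the *same* set of
#' regenerated tables (paired across levels), and averages each quality
#' criterion over simulations.  Used to pick the stepwise significance
#' level: R2 increases with the level while R2adj, R2pred, AIC and BIC
#' turn over where overfitting sets in.
#'
#' @param design a [design_table()].
#' @param alphas numeric vector of significance levels in (0, 1].
#' @param n_sims simulations per level.
#' @param noise a [noise_model()]; default estimated from `design` with a
#'   normal family.
#' @param seed integer seed for the response regeneration.
#' @return Data frame (class `alpha_sweep`) with columns `alpha`, `cqa`,
#'   `R2`, `R2adj`, `R2pred`, `AIC`, `BIC` (means over simulations).
#' @export
alpha_sweep <- function(design, alphas, n_sims = 1000,
                        noise = estimate_noise(design), seed = 1) {
  stopifnot(all(alphas > 0), all(alphas <= 1), n_sims >= 1)
  C <- candidate_matrix(coded_settings(design), design$factors)
  ncqa <- length(design$cqa_names)
  Y <- draw_response_matrix(design, noise, n_sims, seed = seed)
  n <- nrow(C)
  sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
  out <- vector("list", length(alphas))
  for (a in seq_along(alphas)) {
    res <- cpp_fit_ensemble(C, Y, alphas[a], alphas[a], 50L)
    if (any(res$status != 0L))
      stop("stepwise failure at alpha = ", alphas[a], " in simulation ",
           which(res$status != 0L)[1])
    crit <- criteria_from_sums(res$sse, res$press, sst, n, res$ncoef)
    crit <- matrix(crit, ncol = 5,
                   dimnames = list(NULL, c("R2", "R2adj", "R2pred",
                                           "AIC", "BIC")))
    cqa_of <- rep_len(design$cqa_names, ncol(Y))
    means <- apply(crit, 2, function(v) tapply(v, cqa_of, mean))
    out[[a]] <- data.frame(alpha = alphas[a],
                           cqa = rownames(means), means,
                           row.names = NULL, check.names = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("alpha_sweep", "data.frame")
  res
}

#' @export
plot.alpha_sweep <- function(x, criterion = "R2adj", ...) {
  stopifnot(criterion %in% c("R2", "R2adj", "R2pred", "AIC", "BIC"))
  cqas <- unique(x$cqa)
  cols <- grDevices::hcl.colors(length(cqas), "Dark 3")
  graphics::matplot(
    x = unique(x$alpha),
    y = sapply(cqas, function(cc) x[[criterion]][x$cqa == cc]),
    type = "b", pch = 1, lty = 1, col = cols,
    xlab = "stepwise significance level", ylab = paste("mean", criterion),
    ...)
  graphics::legend("bottomright", legend = cqas, col = cols, lty = 1,
                   cex = 0.7, bty = "n")
  invisible(x)
}
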