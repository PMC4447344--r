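# Shared fixtures and independent reference implementations used as
# oracles.  The oracles deliberately take the dumbest correct route
# (normal equations, explicit leave-one-out refits, per-entry counting
# loops) so they stay independent of the package's code paths.

dh <- danhong_fixture()

verification_point <- c(extraction_time = 1.6, wm_ratio = 8.3,
                        extraction_number = 2)

# Plain normal-equations OLS: coefficients, SSE, per-coefficient p-values.
oracle_ols <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  sse <- sum(resid^2)
  df <- nrow(X) - ncol(X)
  se <- sqrt(diag(solve(XtX)) * sse / df)
  p <- 2 * pt(abs(beta / se), df, lower.tail = FALSE)
  list(beta = drop(beta), sse = sse, p = drop(p))
}

# PRESS by explicit leave-one-out refitting.
oracle_press <- function(X, y) {
  sum(vapply(seq_len(nrow(X)), function(i) {
    b <- qr.coef(qr(X[-i, , drop = FALSE]), y[-i])
    (y[i] - sum(X[i, ] * b))^2
  }, 0.0))
}

# Reference bidirectional p-value stepwise in plain R, mirroring the
# documented procedure (add smallest p < alpha, then drop largest
# p > alpha, ties to earlier/later canonical term respectively).
oracle_stepwise <- function(C, y, alpha, max_sweeps = 50) {
  inc <- integer(0)
  n <- nrow(C)
  for (s in seq_len(max_sweeps)) {
    changed <- FALSE
    best_p <- 2; best_j <- NA_integer_
    for (j in setdiff(seq_len(ncol(C)), inc)) {
      if (n - (length(inc) + 2) < 1) break
      trial <- sort(c(inc, j))
      X <- cbind(1, C[, trial, drop = FALSE])
      o <- oracle_ols(X, y)
      pj <- unname(o$p[which(trial == j) + 1])
      if (!is.na(pj) && pj < best_p) { best_p <- pj; best_j <- j }
    }
    if (!is.na(best_j) && best_p < alpha) {
      inc <- sort(c(inc, best_j))
      changed <- TRUE
    }
    if (length(inc)) {
      o <- oracle_ols(cbind(1, C[, inc, drop = FALSE]), y)
      pin <- o$p[-1]
      worst <- max(pin)
      if (worst > alpha) {
        inc <- inc[-max(which(pin == worst))]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  inc
}

# A small single-factor factor spec centred at 0.
unit_factor <- function(name = "x") factor_spec(name, "", 0, 1)

# Synthetic three-factor table on the worked example's layout.
make_synthetic <- function(noise_rsd = 0, seed = 1,
                           coefs = list(y = c("(Intercept)" = 100,
                                              "extraction_time" = 10,
                                              "wm_ratio" = -5,
                                              "extraction_number^2" = -8))) {
  generate_synthetic(
    synthetic_spec(dh$factors, coefs, noise_rsd = noise_rsd),
    seed = seed)
}
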