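#' Specify a synthetic designed experiment with known ground truth
#'
#' Synthetic data sets emulate the structure of the worked example: a
#' three-level design over coded `[-1, 1]`, responses generated from a
#' known quadratic surface, and multiplicative normal noise of a stated
#' relative standard deviation (mirroring the RSD-proportional noise model
#' used for the Monte-Carlo regeneration).  They exist so that parameter
#' recovery and selection power can be tested against a known truth.
#'
#' @param factors a [factor_spec()]; default the worked example's factors.
#' @param true_coefficients named list (one element per CQA) of named
#'   numeric vectors: an `"(Intercept)"` entry plus values for any subset
#'   of [quad_terms()] labels.
#' @param noise_rsd relative standard deviation of the multiplicative
#'   noise (>= 0).
#' @param design_coded optional matrix of coded run settings (columns =
#'   factors); default the worked example's 15-run layout.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(factors = danhong_fixture()$factors,
                           true_coefficients, noise_rsd = 0.05,
                           design_coded = NULL) {
  stopifnot(inherits(factors, "factor_spec"), noise_rsd >= 0,
            is.list(true_coefficients), length(true_coefficients) >= 1,
            !is.null(names(true_coefficients)))
  if (is.null(design_coded)) {
    dh <- danhong_fixture()
    design_coded <- coded_settings(dh$design)[, factors$name, drop = FALSE]
  }
  ok_terms <- c("(Intercept)", quad_terms(factors))
  for (cc in names(true_coefficients)) {
    b <- true_coefficients[[cc]]
    if (is.null(names(b)) || !all(names(b) %in% ok_terms))
      stop("true_coefficients[['", cc,
           "']] must be named with '(Intercept)' and quad_terms() labels")
  }
  structure(list(factors = factors,
                 true_coefficients = true_coefficients,
                 noise_rsd = noise_rsd,
                 design_coded = as_factor_matrix(design_coded,
                                                 factors$name)),
            class = "synthetic_spec")
}

#' Generate a synthetic design table
#'
#' Evaluates the true quadratic surface at the coded run settings and
#' multiplies by `1 + noise`, `noise ~ N(0, noise_rsd)`.  Draws that come
#' out non-positive are redrawn (responses are yields and must be
#' positive); the redraw count is recorded in the `regenerated` attribute.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; equal seeds give identical tables.
#' @return A [design_table()] carrying the truth in attribute
#'   `true_coefficients`.
#' @examples
#' sp <- synthetic_spec(
#'   factor_spec("x", "", 0, 1),
#'   list(y = c("(Intercept)" = 10, x = 3)),
#'   noise_rsd = 0, design_coded = matrix(c(-1, 0, 1), ncol = 1))
#' generate_synthetic(sp, seed = 1)$responses$y   # exactly 7, 10, 13
#' @export
generate_synthetic <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  X <- design_matrix(spec$design_coded, quad_terms(spec$factors))
  n <- nrow(X)
  resp <- list()
  redraws <- 0L
  for (cc in names(spec$true_coefficients)) {
    b <- spec$true_coefficients[[cc]]
    beta <- stats::setNames(numeric(ncol(X)), colnames(X))
    beta[names(b)] <- b
    truth <- drop(X %*% beta)
    if (any(truth <= 0))
      stop("true surface for '", cc, "' is non-positive at a design point")
    y <- truth * (1 + stats::rnorm(n, 0, spec$noise_rsd))
    while (any(y <= 0)) {
      bad <- y <= 0
      redraws <- redraws + sum(bad)
      y[bad] <- truth[bad] * (1 + stats::rnorm(sum(bad), 0, spec$noise_rsd))
    }
    resp[[cc]] <- y
  }
  design <- design_table(decode_factors(spec$design_coded, spec$factors),
                         as.data.frame(resp, check.names = FALSE),
                         spec$factors)
  attr(design, "true_coefficients") <- spec$true_coefficients
  attr(design, "regenerated") <- redraws
  design
}
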