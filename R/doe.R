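#' Define the factors of a designed experiment
#'
#' A factor specification records, for every critical process parameter
#' (CPP), the affine map between uncoded (physical) units and the coded
#' scale used for all modelling: `coded = (uncoded - center) / half_range`,
#' so that the design's extreme levels map to -1 and +1.  Factors whose
#' physical settings can only take the design levels (such as an extraction
#' number) are flagged `discrete`; they are still carried as reals in the
#' models, but design-space slices are taken at their coded levels only.
#'
#' @param name character vector of factor names.
#' @param unit character vector of physical units ("" if dimensionless).
#' @param center numeric vector, uncoded value mapping to coded 0.
#' @param half_range numeric vector (> 0), uncoded distance from the center
#'   to the coded +1 level.
#' @param discrete logical vector, `TRUE` for level-restricted factors.
#' @return A `factor_spec` data frame with one row per factor.
#' @examples
#' factor_spec(c("time", "ratio"), c("h", "g/g"), c(1.25, 8), c(0.75, 2))
#' @export
factor_spec <- function(name, unit = "", center, half_range,
                        discrete = FALSE) {
  n <- length(name)
  stopifnot(is.character(name), n >= 1, !anyDuplicated(name))
  spec <- data.frame(name = name,
                     unit = rep_len(as.character(unit), n),
                     center = as.numeric(center),
                     half_range = as.numeric(half_range),
                     discrete = rep_len(as.logical(discrete), n),
                     stringsAsFactors = FALSE)
  if (any(!is.finite(spec$center)) || any(!is.finite(spec$half_range)))
    stop("factor centers and half-ranges must be finite")
  if (any(spec$half_range <= 0))
    stop("factor half_range must be > 0")
  class(spec) <- c("factor_spec", "data.frame")
  spec
}

#' Define acceptance limits for critical quality attributes
#'
#' Each critical quality attribute (CQA) carries a lower and an upper
#' acceptance limit; a point of the process meets the specification only
#' when every CQA prediction lies inside its limits.  The optional `basis`
#' labels which raw-material mass a per-gram yield is expressed against
#' (used by the yield calculators, see [ingredient_yield()]).
#'
#' @param name character vector of CQA names.
#' @param unit character vector of units.
#' @param lower,upper numeric vectors of acceptance limits, `lower < upper`.
#' @param basis optional character vector naming the denominator basis mass.
#' @return A `cqa_spec` data frame with one row per CQA.
#' @export
cqa_spec <- function(name, unit = "", lower, upper, basis = NA_character_) {
  n <- length(name)
  stopifnot(is.character(name), n >= 1, !anyDuplicated(name))
  spec <- data.frame(name = name,
                     unit = rep_len(as.character(unit), n),
                     lower = as.numeric(lower),
                     upper = as.numeric(upper),
                     basis = rep_len(as.character(basis), n),
                     stringsAsFactors = FALSE)
  if (any(!(spec$lower < spec$upper)))
    stop("every CQA must satisfy lower < upper")
  class(spec) <- c("cqa_spec", "data.frame")
  spec
}

#' Assemble a design table
#'
#' Bundles the run-by-run uncoded factor settings and the measured CQA
#' responses of a designed experiment together with the factor
#' specification.  Responses must be finite and positive (they are yields).
#'
#' @param settings data frame or matrix of uncoded factor settings, one row
#'   per run, columns named for the factors.
#' @param responses data frame or matrix of measured responses, one row per
#'   run, columns named for the CQAs.
#' @param factors a [factor_spec()].
#' @param run optional integer run-order labels (default `1:n`).
#' @return A `design_table` object.
#' @export
design_table <- function(settings, responses, factors, run = NULL) {
  settings <- as.data.frame(settings)
  responses <- as.data.frame(responses)
  stopifnot(inherits(factors, "factor_spec"),
            nrow(settings) == nrow(responses))
  missing_f <- setdiff(factors$name, names(settings))
  if (length(missing_f))
    stop("settings lack factor column(s): ", paste(missing_f, collapse = ", "))
  settings <- settings[, factors$name, drop = FALSE]
  if (!all(vapply(responses, is.numeric, TRUE)))
    stop("all response columns must be numeric")
  rmat <- as.matrix(responses)
  if (any(!is.finite(rmat)) || any(rmat <= 0))
    stop("responses must be finite and > 0")
  if (is.null(run)) run <- seq_len(nrow(settings))
  structure(list(run = as.integer(run),
                 factors = factors,
                 settings = settings,
                 responses = responses,
                 cqa_names = names(responses)),
            class = "design_table")
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("Design table: %d runs, %d factors, %d CQAs\n",
              nrow(x$settings), nrow(x$factors), length(x$cqa_names)))
  cat("Factors:", paste(x$factors$name, collapse = ", "), "\n")
  cat("CQAs:   ", paste(x$cqa_names, collapse = ", "), "\n")
  print(cbind(run = x$run, x$settings, x$responses), ...)
  invisible(x)
}

#' @export
dim.design_table <- function(x) c(nrow(x$settings), nrow(x$factors),
                                  length(x$cqa_names))

as_factor_matrix <- function(x, fnames) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (!is.null(names(x))) {
      unknown <- setdiff(names(x), fnames)
      if (length(unknown))
        stop("unknown factor name(s): ", paste(unknown, collapse = ", "))
      x <- x[fnames]
    } else if (length(x) != length(fnames)) {
      stop("expected one value per factor (", length(fnames), ")")
    }
    x <- matrix(x, nrow = 1, dimnames = list(NULL, fnames))
  } else {
    if (!is.null(colnames(x))) {
      unknown <- setdiff(colnames(x), fnames)
      if (length(unknown))
        stop("unknown factor name(s): ", paste(unknown, collapse = ", "))
      x <- x[, fnames, drop = FALSE]
    } else if (ncol(x) != length(fnames)) {
      stop("expected one column per factor (", length(fnames), ")")
    } else colnames(x) <- fnames
  }
  storage.mode(x) <- "double"
  x
}

#' Code and decode factor settings
#'
#' `code_factors()` applies the affine map `(uncoded - center) / half_range`
#' per factor; `decode_factors()` is its exact inverse.  Inputs may be a
#' named numeric vector (one point), or a matrix / data frame with one
#' column per factor.
#'
#' @param uncoded,coded numeric vector, matrix or data frame of settings.
#' @param factors a [factor_spec()].
#' @return A numeric matrix of the same shape (a 1-row matrix for vector
#'   input) on the other scale.
#' @examples
#' fs <- factor_spec("time", "h", 1.25, 0.75)
#' code_factors(c(time = 0.5), fs)    # -1
#' decode_factors(c(time = 1), fs)    # 2
#' @export
code_factors <- function(uncoded, factors) {
  x <- as_factor_matrix(uncoded, factors$name)
  if (any(!is.finite(x))) stop("uncoded factor values must be finite")
  sweep(sweep(x, 2, factors$center, "-"), 2, factors$half_range, "/")
}

#' @rdname code_factors
#' @export
decode_factors <- function(coded, factors) {
  x <- as_factor_matrix(coded, factors$name)
  if (any(!is.finite(x))) stop("coded factor values must be finite")
  sweep(sweep(x, 2, factors$half_range, "*"), 2, factors$center, "+")
}

#' Coded settings of a design table
#'
#' @param design a [design_table()].
#' @return Matrix of coded factor settings, one row per run.
#' @export
coded_settings <- function(design) {
  stopifnot(inherits(design, "design_table"))
  code_factors(design$settings, design$factors)
}

#' Replicate groups of a design
#'
#' Runs with identical uncoded factor settings (exact equality) form a
#' replicate group; groups are used to estimate measurement noise.
#'
#' @param design a [design_table()].
#' @param min_size smallest group size to report (default 2).
#' @return A list of integer row-index vectors, one per group, largest first.
#' @export
replicate_groups <- function(design, min_size = 2) {
  stopifnot(inherits(design, "design_table"))
  key <- apply(design$settings, 1, paste, collapse = "\r")
  idx <- split(seq_along(key), key)
  idx <- idx[lengths(idx) >= min_size]
  unname(idx[order(-lengths(idx))])
}

# ---- CSV interfaces ---------------------------------------------------------

#' Read and write the package's CSV formats
#'
#' Factor specifications use columns `name,unit,center,half_range,discrete`;
#' CQA specifications `name,unit,lower,upper[,basis]`; design tables
#' `run,<factor names...>,<cqa names...>` with uncoded factor values.
#'
#' @param path file path.
#' @param factors a [factor_spec()] identifying the factor columns of a
#'   design CSV; remaining non-`run` columns are taken as CQAs.
#' @return `read_factor_csv()` a `factor_spec`; `read_cqa_csv()` a
#'   `cqa_spec`; `read_design_csv()` a `design_table`.
#' @export
read_factor_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "unit", "center", "half_range", "discrete")
  if (!all(need %in% names(df)))
    stop("factor CSV must have columns: ", paste(need, collapse = ", "))
  factor_spec(df$name, df$unit, df$center, df$half_range, df$discrete)
}

#' @rdname read_factor_csv
#' @export
read_cqa_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "unit", "lower", "upper")
  if (!all(need %in% names(df)))
    stop("CQA CSV must have columns: ", paste(need, collapse = ", "))
  cqa_spec(df$name, df$unit, df$lower, df$upper,
           if ("basis" %in% names(df)) df$basis else NA_character_)
}

#' @rdname read_factor_csv
#' @export
read_design_csv <- function(path, factors) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"run" %in% names(df)) stop("design CSV must have a 'run' column")
  missing_f <- setdiff(factors$name, names(df))
  if (length(missing_f))
    stop("design CSV lacks factor column(s): ",
         paste(missing_f, collapse = ", "))
  cqa_cols <- setdiff(names(df), c("run", factors$name))
  if (!length(cqa_cols)) stop("design CSV has no response columns")
  for (cc in cqa_cols)
    if (!is.numeric(df[[cc]]) || anyNA(df[[cc]]))
      stop("non-numeric or missing values in response column '", cc, "'")
  design_table(df[factors$name], df[cqa_cols], factors, run = df$run)
}

#' @rdname read_factor_csv
#' @param design a [design_table()] to write.
#' @export
write_design_csv <- function(design, path) {
  out <- cbind(run = design$run, design$settings, design$responses)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
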