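# Report writers and the thin run_* entry points behind the command-line
# script.  CSV numerics are fixed at 6 significant digits so repeated runs
# hash identically across platforms; JSON keeps full precision.

fmt6 <- function(x) {
  if (is.numeric(x)) formatC(signif(x, 6), format = "g", digits = 6) else x
}

write_csv6 <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt6), check.names = FALSE,
                       stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tabular fit report for a set of models
#'
#' One row per coefficient (`cqa, term, estimate, std_error, p_value`)
#' followed by one row per quality criterion, mirroring the layout of a
#' published coefficient table.
#'
#' @param fits named list of [rsm_fit()] objects (e.g. from
#'   [stepwise_fit_all()]).
#' @return Data frame; `write_fit_report()` writes it as CSV (6
#'   significant digits) and returns the path.
#' @export
fit_report <- function(fits) {
  rows <- lapply(fits, function(f) {
    co <- data.frame(cqa = f$cqa,
                     term = names(f$coefficients),
                     estimate = unname(f$coefficients),
                     std_error = unname(f$se),
                     p_value = unname(f$p.value))
    cr <- data.frame(cqa = f$cqa, term = names(f$criteria),
                     estimate = unname(f$criteria),
                     std_error = NA_real_, p_value = NA_real_)
    rbind(co, cr)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' @rdname fit_report
#' @param path output CSV path.
#' @export
write_fit_report <- function(fits, path) {
  write_csv6(fit_report(fits), path)
}

#' Write a probability map as long-format CSV
#'
#' Columns: coded and uncoded coordinates of the two free factors, the
#' joint-acceptance probability, and an `in_design_space` flag at the
#' given threshold.
#'
#' @param map a [probability_map()].
#' @param path output CSV path.
#' @param threshold mask threshold for the flag column.
#' @export
write_probability_map <- function(map, path, threshold = 0.95) {
  df <- as.data.frame(map)
  df$in_design_space <- df$probability >= threshold
  write_csv6(df, path)
}

#' Write design-space metrics as JSON
#'
#' Full-precision JSON with the per-repeat sizes, ADSS, RSDDSS, the
#' stepwise failure counts per repeat, and an echo of the configuration
#' and seed.
#'
#' @param ds a [design_space()] result.
#' @param path output JSON path.
#' @export
write_metrics <- function(ds, path) {
  stopifnot(inherits(ds, "design_space"))
  payload <- list(dss = ds$dss, adss = ds$adss, rsddss = ds$rsddss,
                  threshold = ds$threshold,
                  n_failed = ds$n_failed,
                  slice = as.list(ds$map$slice),
                  config = unclass(ds$cfg))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

write_manifest <- function(path, ...) {
  jsonlite::write_json(list(...), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

load_inputs <- function(design, factors, limits = NULL) {
  fs <- read_factor_csv(factors)
  list(design = read_design_csv(design, fs), factors = fs,
       cqas = if (!is.null(limits)) read_cqa_csv(limits))
}

#' Run a stepwise fit of every CQA and write the report
#'
#' File-path entry point used by the command-line script: reads the design
#' and factor CSVs, stepwise-fits every CQA, and writes the coefficient /
#' criteria report plus a manifest echoing the configuration.
#'
#' @param design,factors paths to the design and factor-specification
#'   CSVs.
#' @param alpha stepwise significance level.
#' @param out output CSV path.
#' @param verbose print progress?
#' @return Invisibly, the named list of fits.
#' @export
run_fit <- function(design, factors, alpha = 0.35, out = "fit_report.csv",
                    verbose = TRUE) {
  inp <- load_inputs(design, factors)
  fits <- stepwise_fit_all(inp$design, alpha = alpha)
  write_fit_report(fits, out)
  write_manifest(paste0(tools::file_path_sans_ext(out), "_manifest.json"),
                 command = "fit", design = design, factors = factors,
                 alpha = alpha, out = out)
  if (verbose)
    for (f in fits)
      message(sprintf("%-28s R2 %.4f (%d terms)", f$cqa,
                      f$criteria["R2"], length(f$terms)))
  invisible(fits)
}

#' Run the full design-space computation and write its artifacts
#'
#' Reads the input CSVs, runs the repeated Monte-Carlo design-space
#' computation at each requested slice of the discrete factor, and writes
#' per-slice probability-map CSVs, a metrics JSON, an optional PNG contour
#' plot, and a manifest.
#'
#' @param design,factors,limits input CSV paths.
#' @param out_dir output directory (created if missing).
#' @param slices named list or vector of coded slice values for the fixed
#'   factor; default all coded levels `-1, 0, 1` of the first discrete
#'   factor.
#' @param family noise-distribution family.
#' @param cfg a [sim_config()].
#' @param png also write contour PNGs? (excluded from determinism
#'   guarantees)
#' @param verbose print progress?
#' @return Invisibly, the list of per-slice [design_space()] results.
#' @export
run_designspace <- function(design, factors, limits, out_dir = ".",
                            slices = NULL, family = "normal",
                            cfg = sim_config(), png = FALSE,
                            verbose = TRUE) {
  inp <- load_inputs(design, factors, limits)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(slices)) {
    dn <- inp$factors$name[inp$factors$discrete][1]
    if (is.na(dn)) stop("no discrete factor; pass `slices` explicitly")
    slices <- stats::setNames(list(c(-1, 0, 1)), dn)
  }
  sname <- names(slices)[1]
  out <- list()
  for (sv in slices[[1]]) {
    tag <- gsub("-", "m", paste0(sname, "_", sv))
    ds <- design_space(inp$design, inp$cqas, cfg = cfg,
                       slice = stats::setNames(sv, sname), family = family)
    write_probability_map(ds$map, file.path(out_dir,
                                            paste0("map_", tag, ".csv")),
                          threshold = cfg$threshold)
    write_metrics(ds, file.path(out_dir, paste0("metrics_", tag, ".json")))
    if (png) {
      grDevices::png(file.path(out_dir, paste0("map_", tag, ".png")),
                     width = 900, height = 760)
      plot(ds)
      grDevices::dev.off()
    }
    if (verbose)
      message(sprintf("slice %s = %g: ADSS %.4f, RSDDSS %.3f%%, %s",
                      sname, sv, ds$adss, ds$rsddss,
                      paste0("failures ",
                             paste(ds$n_failed, collapse = "/"))))
    out[[tag]] <- ds
  }
  write_manifest(file.path(out_dir, "manifest.json"),
                 command = "designspace", design = design,
                 factors = factors, limits = limits, family = family,
                 slices = slices, config = unclass(cfg))
  invisible(out)
}

#' Verify an operating point from the command line
#'
#' Reads the inputs, builds the ensemble, and writes a per-CQA
#' verification report (predicted value, limits, within/outside flag) and
#' the joint acceptance probability.
#'
#' @param design,factors,limits input CSV paths.
#' @param point named numeric vector of uncoded factor settings.
#' @param family noise-distribution family.
#' @param cfg a [sim_config()].
#' @param out output JSON path.
#' @param verbose print the report?
#' @return Invisibly, the [verify_point()] result.
#' @export
run_verify <- function(design, factors, limits, point, family = "normal",
                       cfg = sim_config(), out = "verification.json",
                       verbose = TRUE) {
  inp <- load_inputs(design, factors, limits)
  noise <- estimate_noise(inp$design, family)
  ens <- fit_ensemble(inp$design, noise, cfg)
  v <- verify_point(ens, point, inp$cqas)
  payload <- list(point = as.list(point), table = v$table,
                  joint_probability = v$joint_prob,
                  n_sims = v$n_sims, config = unclass(cfg))
  jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (verbose) print(v)
  invisible(v)
}
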