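#' The Danhong injection extraction study
#'
#' The packaged worked example: a 15-run, three-level designed experiment
#' on the water extraction of mixed Danshen (Salviae miltiorrhizae Radix
#' et Rhizoma) and Honghua (Carthami Flos), the raw materials of Danhong
#' injection.  Three critical process parameters are varied -- extraction
#' time (0.5-2 h, coded center 1.25 h), water-to-material mass ratio
#' (6-10 g/g) and extraction number (1-3) -- and six critical quality
#' attributes are measured per run: the yields of Danshensu,
#' hydroxysafflor yellow A, rosmarinic acid, lithospermic acid and
#' salvianolic acid B, and the dry-matter yield.  Runs 5, 12 and 14
#' replicate the center point and anchor the noise model.  The CQA
#' specification carries the registered acceptance limits (e.g. dry matter
#' 400-550 mg/g material).
#'
#' Values are transcribed at their published precision; an embedded
#' checksum guards the packaged files against corruption.
#'
#' @return A list with elements `design` (a [design_table()]), `factors`
#'   (a [factor_spec()]) and `cqas` (a [cqa_spec()]).
#' @examples
#' dh <- danhong_fixture()
#' dim(dh$design)   # 15 runs, 3 factors, 6 CQAs
#' @export
danhong_fixture <- function() {
  files <- c(factors = "danhong_factors.csv",
             cqas = "danhong_cqa_limits.csv",
             design = "danhong_design.csv")
  paths <- vapply(files, function(f)
    system.file("extdata", f, package = "mcdspace", mustWork = TRUE), "")
  want <- c(factors = "a43ab111c01b28b53bebaffa418659f4",
            cqas = "6e60c62e1c2ac8d4b3831b6e2cf1e458",
            design = "c11c826814b891684a998c8a30f6ac5f")
  got <- tools::md5sum(paths)
  if (any(got != want))
    stop("packaged fixture checksum mismatch for: ",
         paste(names(files)[got != want], collapse = ", "))
  factors <- read_factor_csv(paths["factors"])
  cqas <- read_cqa_csv(paths["cqas"])
  design <- read_design_csv(paths["design"], factors)
  stopifnot(nrow(design$settings) == 15, length(design$cqa_names) == 6,
            nrow(factors) == 3)
  list(design = design, factors = factors, cqas = cqas)
}

#' The published model term sets of the worked example
#'
#' The stepwise-selected quadratic term set of each CQA model of the
#' Danhong study, as reported with the study; refitting these sets on the
#' design table reproduces the reported coefficients.
#'
#' @return Named list of term-label vectors, one per CQA.
#' @export
danhong_term_sets <- function() {
  t1 <- "extraction_time"; t2 <- "wm_ratio"; t3 <- "extraction_number"
  i12 <- paste0(t1, ":", t2); i13 <- paste0(t1, ":", t3)
  i23 <- paste0(t2, ":", t3)
  q1 <- paste0(t1, "^2"); q2 <- paste0(t2, "^2"); q3 <- paste0(t3, "^2")
  list(danshensu = c(t1, t2, t3, i13, i23, q3),
       hydroxysafflor_yellow_A = c(t2, t3, i12, q1, q2, q3),
       rosmarinic_acid = c(t2, t3, q1, q2, q3),
       lithospermic_acid = c(t1, t2, t3, i23, q1, q2, q3),
       salvianolic_acid_B = c(t1, t2, t3, i13, i23, q2, q3),
       dry_matter = c(t1, t2, t3, i12, i13, i23, q2, q3))
}
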