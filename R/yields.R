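#' Yields from raw extract measurements
#'
#' The process CQAs are per-gram yields computed from raw measurements of
#' the pooled extract: `yield = content * extract_mass / basis_mass`, where
#' `content` is the dry-matter or active-ingredient content of the extract
#' in mg per g extract, `extract_mass` the mass of pooled extract in g, and
#' `basis_mass` the raw-material mass the yield is expressed against in g.
#' Different CQAs may use different basis masses: ingredient yields are
#' conventionally reported per gram of the herb the ingredient originates
#' from, while dry-matter yield uses the total material mass.
#'
#' @param content dry-matter or ingredient content of the extract,
#'   mg per g extract (>= 0).
#' @param extract_mass mass of the pooled extract, g (> 0).
#' @param basis_mass raw-material basis mass, g (> 0).
#' @return Yield in mg per g basis material; vectorized.
#' @examples
#' dry_matter_yield(50, 500, 60)   # 416.7 mg/g material
#' @export
dry_matter_yield <- function(content, extract_mass, basis_mass) {
  check_yield_args(content, extract_mass, basis_mass)
  content * extract_mass / basis_mass
}

#' @rdname dry_matter_yield
#' @export
ingredient_yield <- function(content, extract_mass, basis_mass) {
  check_yield_args(content, extract_mass, basis_mass)
  content * extract_mass / basis_mass
}

check_yield_args <- function(content, extract_mass, basis_mass) {
  if (any(!is.finite(content)) || any(content < 0))
    stop("content must be finite and >= 0")
  if (any(!is.finite(extract_mass)) || any(extract_mass <= 0))
    stop("extract_mass must be finite and > 0")
  if (any(!is.finite(basis_mass)) || any(basis_mass <= 0))
    stop("basis_mass must be finite and > 0")
  invisible(TRUE)
}

#' Compute all CQA yields for a set of runs
#'
#' Applies [ingredient_yield()] (or [dry_matter_yield()]) to a table of raw
#' measurements, resolving each CQA's basis mass through the `basis` column
#' of the CQA specification.
#'
#' @param measurements data frame with a column `extract_mass_g` and one
#'   content column per CQA (mg per g extract), named as in `cqas`.
#' @param cqas a [cqa_spec()] whose `basis` column names entries of
#'   `basis_masses`.
#' @param basis_masses named numeric vector of basis masses in g, e.g.
#'   `c(danshen = 45, honghua = 15, material = 60)`.
#' @return Data frame of yields, one column per CQA, mg per g basis.
#' @export
compute_yields <- function(measurements, cqas, basis_masses) {
  stopifnot(inherits(cqas, "cqa_spec"))
  if (!"extract_mass_g" %in% names(measurements))
    stop("measurements must have an 'extract_mass_g' column")
  missing_c <- setdiff(cqas$name, names(measurements))
  if (length(missing_c))
    stop("missing content column(s): ", paste(missing_c, collapse = ", "))
  missing_b <- setdiff(cqas$basis, names(basis_masses))
  if (length(missing_b))
    stop("missing basis mass(es): ", paste(missing_b, collapse = ", "))
  out <- lapply(seq_len(nrow(cqas)), function(i) {
    ingredient_yield(measurements[[cqas$name[i]]],
                     measurements$extract_mass_g,
                     basis_masses[[cqas$basis[i]]])
  })
  names(out) <- cqas$name
  as.data.frame(out, check.names = FALSE)
}
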