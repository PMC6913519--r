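#' Lipid constants
#'
#' `mgdl_per_mmol()` returns the conversion constant between mg/dL and
#' mmol/L for LDL and non-HDL cholesterol (38.67 mg/dL per mmol/L).
#' `treatment_inflation_factor()` returns the multiplicative correction
#' (1.30) applied to measured non-HDL cholesterol of subjects on
#' lipid-lowering medication, undoing the average on-treatment reduction.
#' `nonhdl_breaks_mmol()` returns the guideline-derived non-HDL category
#' boundaries in mmol/L: 2.6, 3.7, 4.8 and 5.7 (the second boundary uses
#' the 145 mg/dL low-risk treatment goal rather than the 130 mg/dL
#' guideline value).
#'
#' @return A numeric scalar (or vector of boundaries).
#' @export
mgdl_per_mmol <- function() 38.67

#' @rdname mgdl_per_mmol
#' @export
treatment_inflation_factor <- function() 1.30

#' @rdname mgdl_per_mmol
#' @export
nonhdl_breaks_mmol <- function() c(2.6, 3.7, 4.8, 5.7)

#' Convert lipid concentrations between mg/dL and mmol/L
#'
#' @param value Non-negative lipid concentration(s).
#' @param direction `"mg_to_mmol"` divides by 38.67, `"mmol_to_mg"`
#'   multiplies.
#' @return Converted concentration(s), unrounded.
#' @examples
#' convert_units(100, "mg_to_mmol") # 2.586 mmol/L
#' @export
convert_units <- function(value, direction = c("mg_to_mmol", "mmol_to_mg")) {
  direction <- match.arg(direction)
  if (any(value < 0, na.rm = TRUE)) {
    stop("lipid concentrations must be non-negative", call. = FALSE)
  }
  if (direction == "mg_to_mmol") value / mgdl_per_mmol()
  else value * mgdl_per_mmol()
}

#' Derive non-HDL cholesterol
#'
#' Non-HDL cholesterol is total cholesterol minus HDL cholesterol, the sum
#' of all apoB-containing atherogenic lipoprotein cholesterol.
#'
#' @param total_chol,hdl_chol Concentrations in mmol/L; requires
#'   `total_chol > hdl_chol >= 0` elementwise.
#' @return Non-HDL cholesterol in mmol/L.
#' @export
derive_non_hdl <- function(total_chol, hdl_chol) {
  if (any(hdl_chol < 0, na.rm = TRUE)) {
    stop("HDL cholesterol must be non-negative", call. = FALSE)
  }
  bad <- which(hdl_chol >= total_chol)
  if (length(bad) > 0L) {
    stop(sprintf(
      "HDL cholesterol >= total cholesterol for %d record(s) (first at index %d)",
      length(bad), bad[1L]), call. = FALSE)
  }
  total_chol - hdl_chol
}

#' Inflate non-HDL cholesterol for treated subjects
#'
#' Measured baseline non-HDL cholesterol of subjects on lipid-lowering
#' medication is inflated by 30% to approximate the untreated
#' concentration; untreated values pass through unchanged.
#'
#' @param non_hdl Non-HDL cholesterol, mmol/L (non-negative).
#' @param on_lipid_lowering Logical/0-1 indicator of lipid-lowering use.
#' @return Adjusted non-HDL cholesterol, mmol/L.
#' @export
adjust_for_treatment <- function(non_hdl, on_lipid_lowering) {
  if (any(non_hdl < 0, na.rm = TRUE)) {
    stop("non-HDL cholesterol must be non-negative", call. = FALSE)
  }
  ifelse(as.logical(on_lipid_lowering),
         non_hdl * treatment_inflation_factor(), non_hdl)
}

#' Guideline non-HDL cholesterol categories
#'
#' `lipid_categories()` tabulates the five half-open categories
#' `[lower, upper)` partitioning `[0, Inf)`; `assign_category()` maps
#' concentrations to category indices 1..5. A value exactly at a boundary
#' falls in the higher category (boundaries are written as "<upper" on the
#' category below).
#'
#' @param breaks Interior boundaries in mmol/L (default
#'   [nonhdl_breaks_mmol()]).
#' @param non_hdl Non-negative concentration(s) in mmol/L; `NA`/`NaN` is an
#'   error.
#' @return `lipid_categories()`: a data frame with columns `index`,
#'   `lower_mmol`, `upper_mmol`, `label`. `assign_category()`: integer
#'   category indices.
#' @examples
#' assign_category(c(2.59, 3.7, 5.7)) # 1, 3, 5
#' @export
lipid_categories <- function(breaks = nonhdl_breaks_mmol()) {
  stopifnot(length(breaks) >= 1L, !is.unsorted(breaks, strictly = TRUE),
            all(breaks > 0))
  lower <- c(0, breaks)
  upper <- c(breaks, Inf)
  k <- length(lower)
  label <- c(sprintf("<%.1f", breaks[1L]),
             if (k > 2L) sprintf("%.1f to <%.1f", lower[2:(k - 1L)],
                                 upper[2:(k - 1L)]),
             sprintf(">=%.1f", breaks[k - 1L]))
  data.frame(index = seq_len(k), lower_mmol = lower, upper_mmol = upper,
             label = label)
}

#' @rdname lipid_categories
#' @export
assign_category <- function(non_hdl, breaks = nonhdl_breaks_mmol()) {
  if (any(is.na(non_hdl))) {
    stop("non-HDL cholesterol contains missing values", call. = FALSE)
  }
  if (any(non_hdl < 0)) {
    stop("non-HDL cholesterol must be non-negative", call. = FALSE)
  }
  # findInterval with default openness gives [lower, upper): a boundary
  # value joins the higher category.
  findInterval(non_hdl, breaks) + 1L
}

#' Prepare a cohort table for analysis
#'
#' Derives non-HDL cholesterol from total and HDL cholesterol, applies the
#' 30% inflation for subjects on lipid-lowering medication, assigns the
#' guideline category, and attaches the baseline age group and
#' risk-factor-burden classification used by the lifetime-risk model.
#'
#' @param records Subject table as produced by [generate_cohort()] or
#'   [read_cohort()].
#' @param breaks Category boundaries, mmol/L.
#' @return `records` with columns `non_hdl`, `non_hdl_adj`, `non_hdl_cat`,
#'   `age_group` and `rf_burden` appended.
#' @export
prepare_cohort <- function(records, breaks = nonhdl_breaks_mmol()) {
  check_records(records)
  records$non_hdl <- derive_non_hdl(records$total_chol, records$hdl_chol)
  records$non_hdl_adj <- adjust_for_treatment(records$non_hdl,
                                              records$lipid_lowering_med)
  records$non_hdl_cat <- assign_category(records$non_hdl_adj, breaks)
  records$age_group <- age_group_of(records$age_baseline)
  records$rf_burden <- rf_burden_of(records)
  records
}
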