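# FLM classifiers: the summed-intensity L/S ratio and the lamellar body
# count, with confusion-matrix evaluation against Apgar-derived outcomes.

#' Lecithin/sphingomyelin ratio for one sample
#'
#' Sum of intensities over the library's lecithin species (diacyl PCs)
#' divided by the sum over its sphingomyelin species. Because the ratio is
#' a quotient of sums from the same sample it is invariant to any global
#' scaling of the row, including TIC normalization.
#'
#' @param intensities Named numeric vector of species intensities (one row
#'   of an intensity matrix; names are species names).
#' @param library The \code{lipid_library}.
#' @param sample_id Optional id used in error messages.
#' @return The L/S ratio (non-negative scalar).
#' @export
ls_ratio <- function(intensities, library, sample_id = NULL) {
  stopifnot(inherits(library, "lipid_library"))
  lec <- library$name[library$is_lecithin]
  sm <- library$name[library$is_sphingomyelin]
  num <- sum(intensities[names(intensities) %in% lec])
  den <- sum(intensities[names(intensities) %in% sm])
  if (den <= 0)
    stop("zero sphingomyelin signal", if (!is.null(sample_id))
      paste0(" in sample ", sample_id), "; L/S ratio undefined")
  num / den
}

#' L/S ratios for every row of an intensity matrix
#'
#' @param matrix An \code{intensity_matrix}.
#' @inheritParams ls_ratio
#' @return Named numeric vector of ratios, one per sample.
#' @export
ls_ratios <- function(matrix, library) {
  vapply(rownames(matrix), function(id)
    ls_ratio(matrix[id, ], library, sample_id = id), numeric(1))
}

#' Classify fetal lung maturity from the L/S ratio
#'
#' Ratios strictly below the cutoff are called premature; values at or
#' above it (including exactly at it) are called mature, mirroring the
#' strict "< cutoff" convention of the clinical partition.
#'
#' @param ratio Numeric vector of L/S ratios (>= 0).
#' @param cutoff Decision threshold; default 10.0.
#' @return Character vector, \code{"premature"} or \code{"mature"}.
#' @export
classify_ls <- function(ratio, cutoff = 10.0) {
  if (any(ratio < 0, na.rm = TRUE)) stop("L/S ratio cannot be negative")
  ifelse(ratio < cutoff, "premature", "mature")
}

#' Classify fetal lung maturity from the lamellar body count
#'
#' @param count LBC in units of 1e9/L (>= 0).
#' @param cutoff Decision threshold; default 50 (x 1e9/L). Counts strictly
#'   below it are premature; at or above, mature.
#' @return Character vector, \code{"premature"} or \code{"mature"}.
#' @export
classify_lbc <- function(count, cutoff = 50) {
  if (any(count < 0, na.rm = TRUE)) stop("lamellar body count cannot be negative")
  ifelse(count < cutoff, "premature", "mature")
}

# round-half-up to whole percent (10/11 -> 91)
.pct <- function(num, den) if (den == 0) NA_real_ else floor(100 * num / den + 0.5)

#' Evaluate a maturity classifier against outcomes
#'
#' Premature is the positive class (the condition being screened for).
#' Records with outcome \code{"control_18gw"} count as premature outcomes:
#' an 18-gestational-week fetus cannot have mature lungs. Sensitivity and
#' specificity are reported as whole percents, rounded half-up.
#'
#' @param records data.frame with columns \code{sample_id},
#'   \code{flm_outcome} (\code{premature}, \code{mature} or
#'   \code{control_18gw}) and, depending on \code{method}, \code{ls_ratio}
#'   or \code{lbc}.
#' @param method \code{"ls"} or \code{"lbc"}.
#' @param cutoff Decision threshold; defaults to 10.0 for \code{"ls"} and
#'   50 for \code{"lbc"}.
#' @return A \code{confusion_summary} list: \code{tp}, \code{fn}, \code{tn},
#'   \code{fp}, \code{sensitivity} (\%), \code{specificity} (\%),
#'   \code{method}, \code{cutoff}, \code{n}.
#' @export
evaluate_classifier <- function(records, method = c("ls", "lbc"),
                                cutoff = NULL) {
  method <- match.arg(method)
  if (is.null(cutoff)) cutoff <- if (method == "ls") 10.0 else 50
  need <- c("sample_id", "flm_outcome",
            if (method == "ls") "ls_ratio" else "lbc")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "))
  value <- records[[if (method == "ls") "ls_ratio" else "lbc"]]
  bad <- records$sample_id[is.na(value) | is.na(records$flm_outcome)]
  if (length(bad))
    stop("records missing ", method, " value or outcome for sample(s): ",
         paste(bad, collapse = ", "))
  ok_outcomes <- c("premature", "mature", "control_18gw")
  if (!all(records$flm_outcome %in% ok_outcomes))
    stop("flm_outcome must be one of: ", paste(ok_outcomes, collapse = ", "))

  truth <- ifelse(records$flm_outcome == "mature", "mature", "premature")
  pred <- if (method == "ls") classify_ls(value, cutoff) else
    classify_lbc(value, cutoff)
  tp <- sum(pred == "premature" & truth == "premature")
  fn <- sum(pred == "mature" & truth == "premature")
  tn <- sum(pred == "mature" & truth == "mature")
  fp <- sum(pred == "premature" & truth == "mature")
  structure(list(
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = .pct(tp, tp + fn),
    specificity = .pct(tn, tn + fp),
    method = method, cutoff = cutoff, n = nrow(records)
  ), class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(
    "FLM classifier [%s, cutoff %s] on %d samples\n", x$method, x$cutoff, x$n))
  cat(sprintf("  premature called premature (TP): %d\n", x$tp))
  cat(sprintf("  premature called mature    (FN): %d\n", x$fn))
  cat(sprintf("  mature called mature       (TN): %d\n", x$tn))
  cat(sprintf("  mature called premature    (FP): %d\n", x$fp))
  cat(sprintf("  sensitivity %d%%, specificity %d%%\n",
              x$sensitivity, x$specificity))
  invisible(x)
}
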