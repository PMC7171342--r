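# Targeted quantification: accurate-mass / retention-time matching of peak
# lists against the lipid library, TIC normalization, QC precision, PCA.

#' Signed parts-per-million mass error
#'
#' @param observed_mz Observed ion m/z (Da); may be a vector.
#' @param reference_mz Reference (theoretical) m/z (Da), > 0.
#' @return \code{(observed - reference) / reference * 1e6}, signed.
#' @export
ppm_error <- function(observed_mz, reference_mz) {
  if (any(!is.finite(reference_mz)) || any(reference_mz <= 0))
    stop("reference_mz must be positive")
  (observed_mz - reference_mz) / reference_mz * 1e6
}

#' Extract the intensity of one library species from a peak list
#'
#' Candidate peaks are those with absolute ppm error within \code{ppm_tol}
#' of the species' adduct m/z target and retention time within
#' \code{rt_window} of its expected RT. With \code{multiple = "max"}
#' (default) the most intense candidate is reported, which is robust to
#' noise shoulders; \code{"sum"} totals all candidates. Absence of any
#' candidate is an intensity of 0, not an error.
#'
#' @param peaks data.frame with columns \code{mz}, \code{rt},
#'   \code{intensity}.
#' @param species One row of a \code{lipid_library} (needs \code{mz} and
#'   \code{expected_rt}).
#' @param ppm_tol Mass tolerance in ppm; matching is inclusive
#'   (|ppm| <= tol). Default 5.
#' @param rt_window RT half-window in minutes. Default 0.2.
#' @param multiple How to resolve multiple candidates: \code{"max"} or
#'   \code{"sum"}.
#' @return A single non-negative intensity.
#' @export
extract_intensity <- function(peaks, species, ppm_tol = 5, rt_window = 0.2,
                              multiple = c("max", "sum")) {
  multiple <- match.arg(multiple)
  stopifnot(ppm_tol > 0, rt_window > 0)
  if (nrow(peaks) == 0L) return(0)
  hit <- abs(ppm_error(peaks$mz, species$mz)) <= ppm_tol &
    abs(peaks$rt - species$expected_rt) <= rt_window
  if (!any(hit)) return(0)
  if (multiple == "max") max(peaks$intensity[hit]) else sum(peaks$intensity[hit])
}

#' Build the samples-by-species intensity matrix
#'
#' Runs \code{\link{extract_intensity}} for every (sample, library species)
#' pair. Column order is the library order; row order follows the input
#' sample order.
#'
#' @param peaklists Named list of peak-list data.frames (names are sample
#'   ids), each with columns \code{mz}, \code{rt}, \code{intensity}.
#' @param library A \code{lipid_library}.
#' @inheritParams extract_intensity
#' @return An \code{intensity_matrix}: numeric matrix, samples x species,
#'   with attribute \code{normalized = FALSE}.
#' @export
build_matrix <- function(peaklists, library, ppm_tol = 5, rt_window = 0.2,
                         multiple = c("max", "sum")) {
  multiple <- match.arg(multiple)
  stopifnot(inherits(library, "lipid_library"))
  if (length(peaklists) == 0L) stop("need at least one sample")
  ids <- names(peaklists)
  if (is.null(ids) || any(ids == ""))
    stop("peaklists must be a named list (names are sample ids)")
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ", paste(unique(ids[duplicated(ids)]),
                                           collapse = ", "))
  mat <- matrix(0, nrow = length(ids), ncol = nrow(library),
                dimnames = list(ids, library$name))
  for (i in seq_along(peaklists)) {
    pl <- peaklists[[i]]
    for (j in seq_len(nrow(library))) {
      mat[i, j] <- extract_intensity(pl, library[j, ], ppm_tol = ppm_tol,
                                     rt_window = rt_window, multiple = multiple)
    }
  }
  attr(mat, "normalized") <- FALSE
  class(mat) <- c("intensity_matrix", class(mat))
  mat
}

#' Is an intensity matrix TIC-normalized?
#' @param matrix An \code{intensity_matrix}.
#' @export
is_normalized <- function(matrix) isTRUE(attr(matrix, "normalized"))

#' Total-ion-count normalization
#'
#' Divides each sample row by its own total over the library-matched
#' species, so rows sum to 1 and samples are comparable regardless of
#' injection amount. Idempotent.
#'
#' @param matrix A raw \code{intensity_matrix}.
#' @return The normalized matrix (attribute \code{normalized = TRUE}).
#' @export
tic_normalize <- function(matrix) {
  sums <- rowSums(matrix)
  bad <- which(sums <= 0)
  if (length(bad))
    stop("cannot TIC-normalize sample(s) with zero total intensity: ",
         paste(rownames(matrix)[bad], collapse = ", "))
  out <- matrix / sums
  attr(out, "normalized") <- TRUE
  class(out) <- class(matrix)
  dimnames(out) <- dimnames(matrix)
  out
}

#' QC replicate precision report
#'
#' Per-species coefficient of variation over replicate injections
#' (sd with n-1 denominator / mean * 100), averaged per lipid class.
#' Species with zero mean across replicates are reported as \code{NA} and
#' excluded from class averages. The lecithin and sphingomyelin subset
#' averages are reported separately because they are the two halves of the
#' L/S ratio.
#'
#' @param replicates An \code{intensity_matrix} whose rows are QC replicate
#'   injections (>= 2).
#' @param library The \code{lipid_library} the matrix columns follow.
#' @return A list of class \code{qc_report}: \code{per_species_cv} (named,
#'   \%), \code{class_average_cv} (named, \%), \code{lecithin_average_cv},
#'   \code{sphingomyelin_average_cv}, \code{n_replicates}.
#' @export
qc_cv <- function(replicates, library) {
  stopifnot(inherits(library, "lipid_library"))
  if (nrow(replicates) < 2L)
    stop("need at least 2 QC replicates to estimate CV")
  means <- colMeans(replicates)
  sds <- apply(replicates, 2, stats::sd)
  cv <- ifelse(means > 0, sds / means * 100, NA_real_)
  names(cv) <- colnames(replicates)
  cls <- library$class[match(colnames(replicates), library$name)]
  class_avg <- tapply(cv, cls, mean, na.rm = TRUE)
  lec <- library$name[library$is_lecithin]
  sm <- library$name[library$is_sphingomyelin]
  structure(list(
    per_species_cv = cv,
    class_average_cv = class_avg,
    lecithin_average_cv = mean(cv[names(cv) %in% lec], na.rm = TRUE),
    sphingomyelin_average_cv = mean(cv[names(cv) %in% sm], na.rm = TRUE),
    n_replicates = nrow(replicates)
  ), class = "qc_report")
}

#' PCA scores for an intensity matrix
#'
#' Mean-centered (always) and optionally unit-variance scaled principal
#' component analysis, the standard overview plot for run stability:
#' QC replicate injections should cluster tightly relative to the biological
#' samples. Columns that are zero across all samples are dropped first with
#' a warning (they carry no information and break scaling).
#'
#' @param matrix An \code{intensity_matrix}.
#' @param n_components Number of components to return; at most
#'   \code{min(n_samples - 1, n_species)}.
#' @param scaling \code{"unit_variance"} (center + scale, the default) or
#'   \code{"center"} (center only).
#' @return List with \code{scores} (samples x components),
#'   \code{explained_variance} (fraction per returned component) and
#'   \code{loadings}.
#' @export
pca_scores <- function(matrix, n_components = 2,
                       scaling = c("unit_variance", "center")) {
  scaling <- match.arg(scaling)
  x <- unclass(matrix)
  attr(x, "normalized") <- NULL
  allzero <- colSums(x != 0) == 0
  if (any(allzero)) {
    warning("dropping ", sum(allzero), " all-zero species column(s) before PCA")
    x <- x[, !allzero, drop = FALSE]
  }
  if (n_components > min(nrow(x) - 1L, ncol(x)))
    stop("n_components exceeds min(n_samples - 1, n_species)")
  if (scaling == "unit_variance") {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0))
      stop("constant column(s) under unit-variance scaling: ",
           paste(colnames(x)[sds == 0], collapse = ", "))
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = (scaling == "unit_variance"))
  keep <- seq_len(n_components)
  list(
    scores = fit$x[, keep, drop = FALSE],
    explained_variance = (fit$sdev^2 / sum(fit$sdev^2))[keep],
    loadings = fit$rotation[, keep, drop = FALSE]
  )
}
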