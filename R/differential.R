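# Biomarker discovery between mature and premature groups: Welch t-tests,
# fold changes, a NIPALS PLS-DA with VIP scores, and the
# p < 0.05 / VIP > 1.1 / FC > 2 selection rule.

#' Welch unequal-variance two-sample t-test
#'
#' Thin wrapper over \code{stats::t.test(var.equal = FALSE)} returning the
#' statistic, the Welch-Satterthwaite degrees of freedom and the two-sided
#' p-value. When both groups have zero variance and equal means the test is
#' degenerate and \code{t = 0, p = 1} by convention.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 observations")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    if (mean(group_a) == mean(group_b)) return(list(t = 0, df = Inf, p = 1))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf, df = Inf, p = 0))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Fold change of mature over premature group means
#'
#' Ratio of arithmetic group means of TIC-normalized intensities, unlogged.
#' A non-positive premature mean makes the ratio undefined and is an error
#' surfaced to the user rather than patched with a pseudo-count.
#'
#' @param mean_mature,mean_premature Group means (premature mean > 0).
#' @return \code{mean_mature / mean_premature}.
#' @export
fold_change <- function(mean_mature, mean_premature) {
  if (!is.finite(mean_premature) || mean_premature <= 0)
    stop("premature group mean must be positive to form a fold change")
  mean_mature / mean_premature
}

#' Two-class PLS-DA by NIPALS with deflation
#'
#' Fits a univariate-response PLS (PLS1) model to the class membership:
#' X is mean-centered and (by default) unit-variance scaled; y is the 0/1
#' class indicator, centered. Each component's weight vector is
#' \code{X'y} normalized to unit length; X and y are deflated by the
#' extracted score before the next component. Successive score vectors are
#' orthogonal. Columns constant across samples are dropped with a warning.
#'
#' @param X Numeric matrix, samples x species (e.g. a TIC-normalized
#'   \code{intensity_matrix}).
#' @param y Binary group labels: logical, 0/1, or a two-level
#'   factor/character vector. Both classes must be present.
#' @param n_components Number of latent components (default 2).
#' @param scale Unit-variance scale the columns (default TRUE).
#' @return A \code{pls_model} list: \code{weights}, \code{loadings},
#'   \code{scores} (one column per component), \code{ssy} (y-variance
#'   explained per component, absolute), \code{y_total_ss},
#'   \code{y_variance_explained} (fractions), \code{species} (column
#'   names kept), \code{n_components}.
#' @export
fit_plsda <- function(X, y, n_components = 2, scale = TRUE) {
  X <- as.matrix(unclass(X))
  if (is.character(y)) y <- factor(y)
  if (is.factor(y)) {
    if (nlevels(droplevels(y)) != 2L) stop("y must have exactly two classes")
    y <- as.numeric(droplevels(y)) - 1
  }
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("y must have exactly two classes")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")

  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant species column(s) before PLS")
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  Xc <- sweep(X, 2, colMeans(X))
  if (scale) Xc <- sweep(Xc, 2, sds, "/")
  yc <- y - mean(y)
  y_total_ss <- sum(yc^2)

  p <- ncol(Xc)
  n_components <- min(n_components, p, nrow(Xc) - 1L)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(Xc), n_components)
  ssy <- numeric(n_components)
  Xd <- Xc; yd <- yc
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5) { n_components <- a - 1L; break }
    w <- w / nw
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(Xd, t_)) / tt
    q_ <- sum(yd * t_) / tt
    Xd <- Xd - tcrossprod(t_, p_)
    yd <- yd - q_ * t_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_
    ssy[a] <- q_^2 * tt
  }
  if (n_components < 1L) stop("no predictive component could be extracted")
  keep <- seq_len(n_components)
  structure(list(
    weights = W[, keep, drop = FALSE],
    loadings = P[, keep, drop = FALSE],
    scores = Tm[, keep, drop = FALSE],
    ssy = ssy[keep],
    y_total_ss = y_total_ss,
    y_variance_explained = ssy[keep] / y_total_ss,
    species = colnames(Xc),
    n_components = n_components
  ), class = "pls_model")
}

#' Variable importance for the projection (VIP)
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{aj}/\lVert w_a \rVert)^2 / \sum_a SSY_a}}
#' where p is the number of species and SSY_a the y-variance explained by
#' component a. The squared VIPs always sum to p.
#'
#' @param model A fitted \code{pls_model}.
#' @return Named numeric vector of VIP scores over the model's species.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (sum(model$ssy) <= 0)
    stop("no y-variance explained by any component; VIP undefined")
  W <- model$weights
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")  # (w_aj / ||w_a||)^2
  p <- nrow(W)
  v <- sqrt(p * drop(wn2 %*% model$ssy) / sum(model$ssy))
  names(v) <- model$species
  v
}

#' Per-species differential statistics between mature and premature samples
#'
#' Computes, for every library species, the Welch t-test p-value, the
#' mature/premature fold change of group means and the PLS-DA VIP score,
#' then applies the strict selection rule
#' p < \code{p_max} and VIP > \code{vip_min} and FC > \code{fc_min}.
#'
#' @param matrix TIC-normalized \code{intensity_matrix}.
#' @param groups Character vector over rows of \code{matrix} with values
#'   \code{"mature"} / \code{"premature"}.
#' @param n_components PLS components for the VIP model (default 2).
#' @param p_max,vip_min,fc_min Selection thresholds (defaults 0.05, 1.1, 2).
#' @return data.frame of class \code{biomarker_table} with columns
#'   \code{species_name}, \code{fold_change}, \code{vip}, \code{p_value},
#'   \code{selected}, in library column order. Species dropped from the
#'   PLS model (constant columns) get VIP \code{NA} and are never selected.
#' @export
biomarker_stats <- function(matrix, groups, n_components = 2,
                            p_max = 0.05, vip_min = 1.1, fc_min = 2.0) {
  stopifnot(length(groups) == nrow(matrix))
  if (!all(groups %in% c("mature", "premature")))
    stop("groups must be 'mature' or 'premature'")
  mat_rows <- groups == "mature"
  if (!any(mat_rows) || all(mat_rows)) stop("both groups must be present")

  pvals <- apply(matrix, 2, function(x)
    welch_t(x[mat_rows], x[!mat_rows])$p)
  fcs <- apply(matrix, 2, function(x)
    fold_change(mean(x[mat_rows]), mean(x[!mat_rows])))
  model <- fit_plsda(matrix, ifelse(mat_rows, 1, 0),
                     n_components = n_components)
  vips <- vip(model)[colnames(matrix)]

  out <- data.frame(
    species_name = colnames(matrix),
    fold_change = unname(fcs),
    vip = unname(vips),
    p_value = unname(pvals),
    stringsAsFactors = FALSE
  )
  out$selected <- !is.na(out$vip) &
    out$p_value < p_max & out$vip > vip_min & out$fold_change > fc_min
  class(out) <- c("biomarker_table", "data.frame")
  out
}

#' Apply the biomarker selection rule and rank the hits
#'
#' Strict thresholds, exactly as printed in the selection rule: p < p_max,
#' VIP > vip_min, fold change > fc_min. The result is sorted by fold change
#' descending, species name ascending on ties, and is invariant to the
#' input row order.
#'
#' @param records A \code{biomarker_table} (or data.frame with columns
#'   \code{species_name}, \code{fold_change}, \code{vip}, \code{p_value}).
#' @inheritParams biomarker_stats
#' @return The selected subset, re-ranked.
#' @export
select_biomarkers <- function(records, p_max = 0.05, vip_min = 1.1,
                              fc_min = 2.0) {
  stopifnot(p_max > 0, vip_min > 0, fc_min > 0)
  keep <- !is.na(records$vip) &
    records$p_value < p_max & records$vip > vip_min &
    records$fold_change > fc_min
  sel <- records[keep, , drop = FALSE]
  sel <- sel[order(-sel$fold_change, sel$species_name), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}
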