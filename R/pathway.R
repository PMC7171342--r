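# Metabolite-set enrichment (one-sided hypergeometric, Holm-Bonferroni
# family-wise adjustment) and pathway topology impact via relative
# betweenness centrality.

#' Construct and validate a pathway definition
#'
#' @param name Pathway name.
#' @param compounds Character vector of member compound ids (unique).
#' @param edges Two-column matrix / data.frame (or list of length-2
#'   vectors) of undirected edges over \code{compounds}; no self-loops.
#'   May be empty.
#' @return A \code{pathway} list with elements \code{name},
#'   \code{compounds}, \code{edges} (2-column character matrix).
#' @export
pathway <- function(name, compounds, edges = NULL) {
  compounds <- as.character(compounds)
  if (anyDuplicated(compounds)) stop("duplicate compounds in pathway ", name)
  if (is.null(edges) || length(edges) == 0L) {
    em <- matrix(character(0), ncol = 2)
  } else {
    if (is.list(edges) && !is.data.frame(edges))
      edges <- do.call(rbind, edges)
    em <- as.matrix(edges)
    storage.mode(em) <- "character"
    if (ncol(em) != 2L) stop("edges must be pairs")
    if (any(!c(em) %in% compounds))
      stop("edge references non-member compound in pathway ", name, ": ",
           paste(setdiff(c(em), compounds), collapse = ", "))
    if (any(em[, 1] == em[, 2]))
      stop("self-loop in pathway ", name)
  }
  structure(list(name = name, compounds = compounds, edges = em),
            class = "pathway")
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' P(X >= overlap_k) where X counts how many of \code{hits_n} compounds
#' drawn without replacement from a background of \code{background_n} fall
#' into a pathway of size \code{pathway_k}.
#'
#' @param background_n Background universe size.
#' @param pathway_k Pathway compounds inside the background.
#' @param hits_n Number of hit compounds drawn.
#' @param overlap_k Observed pathway/hit overlap.
#' @return The one-sided p-value.
#' @export
hypergeom_p <- function(background_n, pathway_k, hits_n, overlap_k) {
  if (pathway_k > background_n || hits_n > background_n ||
      overlap_k > min(pathway_k, hits_n) || overlap_k < 0 ||
      min(background_n, pathway_k, hits_n) < 0)
    stop("inconsistent hypergeometric counts")
  if (overlap_k == 0) return(1.0)
  stats::phyper(overlap_k - 1, pathway_k, background_n - pathway_k, hits_n,
                lower.tail = FALSE)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p_values Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values in the input order (elementwise >= raw).
#' @export
holm_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "holm")
}

#' Relative betweenness centrality of pathway compounds
#'
#' Betweenness centrality normalized by (n-1)(n-2)/2, n = number of
#' compounds, so values lie in [0, 1]. Disconnected graphs are allowed:
#' unreachable pairs simply contribute no shortest paths. Pathways with
#' fewer than 3 compounds have no possible intermediary and return zeros.
#'
#' @param pw A \code{pathway}.
#' @return Named numeric vector over all member compounds.
#' @export
relative_betweenness <- function(pw) {
  stopifnot(inherits(pw, "pathway"))
  n <- length(pw$compounds)
  if (n < 1L) stop("pathway has no compounds")
  out <- stats::setNames(numeric(n), pw$compounds)
  if (n < 3L || nrow(pw$edges) == 0L) return(out)
  g <- igraph::graph_from_data_frame(
    as.data.frame(pw$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = pw$compounds, stringsAsFactors = FALSE))
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  out[names(b)] <- b / ((n - 1) * (n - 2) / 2)
  out
}

#' Pathway topology impact of a matched compound set
#'
#' Sum of relative betweenness centralities over the matched compounds
#' divided by the sum over all pathway compounds; 0 when the pathway has
#' no centrality mass at all (complete graphs, <= 2 nodes), which still
#' flags "a little association" rather than none.
#'
#' @param pw A \code{pathway}.
#' @param matched Character vector, subset of \code{pw$compounds}.
#' @return Impact in [0, 1].
#' @export
pathway_impact <- function(pw, matched) {
  stopifnot(inherits(pw, "pathway"))
  matched <- as.character(matched)
  if (!all(matched %in% pw$compounds))
    stop("matched compounds not in pathway ", pw$name, ": ",
         paste(setdiff(matched, pw$compounds), collapse = ", "))
  cent <- relative_betweenness(pw)
  tot <- sum(cent)
  if (tot == 0) return(0)
  sum(cent[matched]) / tot
}

#' Metabolite-set enrichment with topology impact
#'
#' For each pathway, computes the one-sided hypergeometric p-value for the
#' overlap of \code{hits} with the pathway's compounds (restricted to the
#' background), the Holm-Bonferroni adjusted p across the tested pathways,
#' \code{-log(p)} of the raw p, and the topology impact of the matched
#' compounds.
#'
#' @param pathways List of \code{pathway} objects.
#' @param hits Character vector of significant compounds (subset of
#'   \code{background}).
#' @param background Character vector: the compound universe.
#' @param log_base Base for \code{-log(p)}: \code{"e"} (default) or
#'   \code{"10"}.
#' @return data.frame sorted by raw p ascending with columns
#'   \code{pathway}, \code{pathway_size}, \code{overlap}, \code{raw_p},
#'   \code{holm_p}, \code{neg_log_p}, \code{impact}, \code{hits}
#'   (comma-joined matched compounds).
#' @export
enrich <- function(pathways, hits, background, log_base = c("e", "10")) {
  log_base <- match.arg(log_base)
  hits <- unique(as.character(hits))
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("background compound set is empty")
  if (!all(hits %in% background))
    stop("hits must be a subset of the background: ",
         paste(setdiff(hits, background), collapse = ", "))
  rows <- lapply(pathways, function(pw) {
    members <- intersect(pw$compounds, background)
    overlap <- intersect(members, hits)
    p <- hypergeom_p(length(background), length(members), length(hits),
                     length(overlap))
    data.frame(
      pathway = pw$name,
      pathway_size = length(members),
      overlap = length(overlap),
      raw_p = p,
      impact = pathway_impact(pw, intersect(pw$compounds, hits)),
      hits = paste(overlap, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$holm_p <- holm_adjust(out$raw_p)
  base <- if (log_base == "e") exp(1) else 10
  out$neg_log_p <- -log(out$raw_p, base = base)
  out <- out[order(out$raw_p, out$pathway),
             c("pathway", "pathway_size", "overlap", "raw_p", "holm_p",
               "neg_log_p", "impact", "hits")]
  rownames(out) <- NULL
  out
}
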