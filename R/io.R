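# Plain-text I/O for the pipeline's tabular formats: peak lists, intensity
# matrices, cohort metadata, pathway JSON.

#' Read peak lists from a long-format CSV
#'
#' Format: header \code{sample_id,mz,rt,intensity}, one row per peak.
#'
#' @param path CSV path.
#' @return Named list of per-sample data.frames (\code{mz,rt,intensity}).
#' @export
read_peaklists <- function(path) {
  if (!file.exists(path)) stop("peak list file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "mz", "rt", "intensity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("peak list file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  split(df[, c("mz", "rt", "intensity")], factor(df$sample_id,
                                                 levels = unique(df$sample_id)))
}

#' Write peak lists to a long-format CSV
#'
#' @param peaklists Named list of per-sample data.frames.
#' @param path Output path.
#' @export
write_peaklists <- function(peaklists, path) {
  rows <- lapply(names(peaklists), function(id)
    cbind(sample_id = id, peaklists[[id]][, c("mz", "rt", "intensity")]))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write an intensity matrix to TSV
#'
#' Samples as rows, a header of species names, and a
#' \code{#normalized=true|false} comment line recording the matrix state.
#'
#' @param matrix An \code{intensity_matrix}.
#' @param path Output path.
#' @export
write_matrix <- function(matrix, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#normalized=%s",
                     if (is_normalized(matrix)) "true" else "false"), con)
  df <- data.frame(sample_id = rownames(matrix),
                   format(unclass(matrix), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an intensity matrix written by \code{\link{write_matrix}}
#'
#' @param path TSV path.
#' @return An \code{intensity_matrix} with its normalized flag restored.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  first <- readLines(path, n = 1)
  normalized <- identical(first, "#normalized=true")
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df$sample_id)
  as_intensity_matrix(mat, normalized = normalized)
}

#' Read a cohort metadata CSV
#'
#' Expected columns: \code{sample_id}, \code{flm_outcome} and any of
#' \code{ls_ratio}, \code{lbc}, \code{gw}, \code{group}.
#'
#' @param path CSV path.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "flm_outcome") %in% names(df)))
    stop("cohort file needs sample_id and flm_outcome columns")
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Read pathway definitions from a JSON file
#'
#' One JSON array of objects \code{{name, compounds: [], edges: [[a,b],...]}}.
#'
#' @param path JSON path.
#' @return Named list of \code{\link{pathway}} objects.
#' @export
read_pathways <- function(path) {
  if (!file.exists(path)) stop("pathway file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  out <- lapply(seq_along(raw), function(i) {
    pw <- raw[[i]]
    edges <- pw$edges
    if (is.list(edges) && length(edges) == 1L) edges <- edges[[1]]
    pathway(pw$name, unlist(pw$compounds), edges)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Write pathway definitions to JSON
#'
#' @param pathways Named list of \code{\link{pathway}} objects.
#' @param path Output path.
#' @export
write_pathways <- function(pathways, path) {
  payload <- lapply(unname(pathways), function(pw)
    list(name = pw$name, compounds = pw$compounds,
         edges = if (nrow(pw$edges)) unname(apply(pw$edges, 1, c,
                                                  simplify = FALSE))
         else list()))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
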