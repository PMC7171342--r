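# Lipid catalogue: species annotation from shorthand nomenclature, library
# validation and I/O, adduct m/z arithmetic.

#' Monoisotopic proton mass in Da, used for [M+H]+ / [M-H]- arithmetic
#' @export
PROTON_MASS <- 1.007276466

.LIPID_CLASSES <- c("PC", "PE", "SM", "Cer", "PG")
.LINKAGES <- c("diacyl", "ether_O", "ether_P", "lyso", "n_acyl")

# The shorthand dialect mixes hyphen-like glyphs (the typography of printed
# tables is inconsistent); normalize them all to ASCII '-'.
.normalize_dashes <- function(x) {
  gsub("[‐‑‒–—−]", "-", x)
}

#' Annotate a lipid species from its shorthand name
#'
#' Parses names of the form \code{Class(chain1/chain2)} -- e.g.
#' \code{"PC(20:4/14:0)"}, \code{"SM(d16:1/17:0)"}, \code{"PC(O-16:0/18:1)"} --
#' and derives the lipid class, the linkage type and the two diagnostic
#' membership flags. Lecithin (the L/S ratio numerator) is defined as
#' diacyl phosphatidylcholine: ether-linked (O-, P-) and lyso PCs are
#' excluded. Every sphingomyelin belongs to the ratio denominator.
#'
#' @param name Shorthand lipid name, e.g. \code{"PC(16:0/18:1)"}. Hyphen-like
#'   unicode dashes in O-/P- prefixes are accepted.
#' @return A list with elements \code{lipid_class}, \code{linkage},
#'   \code{is_lecithin} and \code{is_sphingomyelin}.
#' @examples
#' annotate_species("PC(20:4/14:0)")  # diacyl PC -> lecithin
#' annotate_species("PC(20:4/0:0)")   # lyso PC -> not lecithin
#' @export
annotate_species <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  nm <- .normalize_dashes(trimws(name))
  m <- regmatches(nm, regexec("^([A-Za-z]+)\\((.+)\\)$", nm))[[1]]
  if (length(m) != 3L)
    stop("cannot parse lipid name ", sQuote(name), ": expected Class(chain/chain)")
  cls <- m[2]
  if (!cls %in% .LIPID_CLASSES)
    stop("cannot parse lipid name ", sQuote(name), ": unknown class token ",
         sQuote(cls))
  chains <- strsplit(m[3], "/", fixed = TRUE)[[1]]
  if (length(chains) != 2L)
    stop("cannot parse lipid name ", sQuote(name),
         ": expected two /-separated chains, got ", sQuote(m[3]))
  parse_chain <- function(ch) {
    prefix <- ""
    body <- ch
    if (grepl("^[OP]-", ch)) {
      prefix <- substr(ch, 1, 1)
      body <- substring(ch, 3)
    } else if (grepl("^d", ch)) {
      prefix <- "d"
      body <- substring(ch, 2)
    }
    if (!grepl("^[0-9]+:[0-9]+$", body))
      stop("cannot parse lipid name ", sQuote(name), ": bad chain token ",
           sQuote(ch))
    cd <- as.integer(strsplit(body, ":", fixed = TRUE)[[1]])
    list(prefix = prefix, carbons = cd[1], doubles = cd[2])
  }
  c1 <- parse_chain(chains[1])
  c2 <- parse_chain(chains[2])

  linkage <- if (cls %in% c("SM", "Cer")) {
    "n_acyl"
  } else if (c1$carbons == 0L || c2$carbons == 0L) {
    "lyso"
  } else if (c1$prefix == "O" || c2$prefix == "O") {
    "ether_O"
  } else if (c1$prefix == "P" || c2$prefix == "P") {
    "ether_P"
  } else {
    "diacyl"
  }
  list(
    lipid_class = cls,
    linkage = linkage,
    is_lecithin = (cls == "PC" && linkage == "diacyl"),
    is_sphingomyelin = (cls == "SM")
  )
}

#' Construct a validated lipid library
#'
#' @param df data.frame with columns \code{name}, \code{class},
#'   \code{linkage}, \code{neutral_mass} (Da), \code{adduct}
#'   (\code{"[M+H]+"} or \code{"[M-H]-"}), \code{expected_rt} (minutes).
#' @return An object of class \code{lipid_library}: the input data.frame with
#'   derived logical columns \code{is_lecithin}, \code{is_sphingomyelin} and
#'   a numeric \code{mz} column (the adduct ion target).
#' @export
lipid_library <- function(df) {
  required <- c("name", "class", "linkage", "neutral_mass", "adduct", "expected_rt")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("library table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("library table is empty")
  df$name <- .normalize_dashes(as.character(df$name))
  df$adduct <- .normalize_dashes(as.character(df$adduct))
  dup <- df$name[duplicated(df$name)]
  if (length(dup))
    stop("duplicate species name(s) in library: ",
         paste(unique(dup), collapse = ", "))
  if (!all(df$class %in% .LIPID_CLASSES))
    stop("unknown lipid class in library: ",
         paste(setdiff(unique(df$class), .LIPID_CLASSES), collapse = ", "))
  if (!all(df$linkage %in% .LINKAGES))
    stop("unknown linkage in library: ",
         paste(setdiff(unique(df$linkage), .LINKAGES), collapse = ", "))
  if (any(!is.finite(df$neutral_mass)) || any(df$neutral_mass <= 0))
    stop("neutral_mass must be positive and finite")
  if (any(!is.finite(df$expected_rt)) || any(df$expected_rt < 0))
    stop("expected_rt must be non-negative")
  df$is_lecithin <- df$class == "PC" & df$linkage == "diacyl"
  df$is_sphingomyelin <- df$class == "SM"
  df$mz <- mapply(mz_for_adduct, df$neutral_mass, df$adduct)
  rownames(df) <- NULL
  class(df) <- c("lipid_library", "data.frame")
  df
}

#' Load a lipid library from a CSV file
#'
#' File format: UTF-8 CSV with header
#' \code{name,class,linkage,neutral_mass,adduct,expected_rt}, dot decimal
#' separator. Lines starting with \code{#} are treated as comments.
#'
#' @param path Path to the library CSV.
#' @return A \code{\link{lipid_library}} with row order preserved.
#' @export
load_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  lipid_library(df)
}

#' Save a lipid library to CSV
#'
#' Writes the six canonical columns plus a comment header recording the
#' proton mass constant used for adduct m/z targets, so that saved and
#' reloaded libraries round-trip exactly.
#'
#' @param library A \code{lipid_library}.
#' @param path Output path.
#' @export
save_library <- function(library, path) {
  stopifnot(inherits(library, "lipid_library"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# lipid library; adduct m/z computed with proton mass %.9f Da",
                     PROTON_MASS), con)
  cols <- c("name", "class", "linkage", "neutral_mass", "adduct", "expected_rt")
  utils::write.csv(format(library[, cols], digits = 15, trim = TRUE,
                          scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tally library species by lipid class
#'
#' @param library A \code{lipid_library}.
#' @return Named integer vector over the classes present, plus the derived
#'   \code{lecithin} and \code{sphingomyelin} subset counts.
#' @export
counts_by_class <- function(library) {
  stopifnot(inherits(library, "lipid_library"))
  tab <- table(factor(library$class, levels = .LIPID_CLASSES))
  out <- c(as.integer(tab),
           sum(library$is_lecithin), sum(library$is_sphingomyelin))
  names(out) <- c(.LIPID_CLASSES, "lecithin", "sphingomyelin")
  out
}

#' Ion m/z for a neutral mass under a protonation adduct
#'
#' @param neutral_mass Monoisotopic neutral mass in Da (> 0).
#' @param adduct \code{"[M+H]+"} (adds one proton mass) or \code{"[M-H]-"}
#'   (subtracts it). Unicode minus glyphs are accepted.
#' @return The ion m/z in Da.
#' @export
mz_for_adduct <- function(neutral_mass, adduct) {
  stopifnot(is.numeric(neutral_mass), length(neutral_mass) == 1L)
  if (!is.finite(neutral_mass) || neutral_mass <= 0)
    stop("neutral_mass must be positive")
  ad <- .normalize_dashes(adduct)
  if (ad == "[M+H]+") neutral_mass + PROTON_MASS
  else if (ad == "[M-H]-") neutral_mass - PROTON_MASS
  else stop("unsupported adduct label: ", sQuote(adduct))
}

#' Neutral mass from an observed adduct ion m/z (inverse of mz_for_adduct)
#'
#' @param mz Ion m/z in Da.
#' @param adduct Adduct label as in \code{\link{mz_for_adduct}}.
#' @export
neutral_from_mz <- function(mz, adduct) {
  ad <- .normalize_dashes(adduct)
  if (ad == "[M+H]+") mz - PROTON_MASS
  else if (ad == "[M-H]-") mz + PROTON_MASS
  else stop("unsupported adduct label: ", sQuote(adduct))
}
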