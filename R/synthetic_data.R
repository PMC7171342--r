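# Synthetic-data generators: a structured lipid catalogue, gestational-age-
# structured cohorts of peak lists, QC replicate injections, and toy pathway
# graphs. All generators are deterministic given their seed.

#' Coerce a plain matrix to an intensity_matrix
#'
#' @param mat Numeric matrix, samples x species, with dimnames.
#' @param normalized Whether rows are already TIC-normalized.
#' @export
as_intensity_matrix <- function(mat, normalized = FALSE) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  attr(mat, "normalized") <- normalized
  if (!inherits(mat, "intensity_matrix"))
    class(mat) <- c("intensity_matrix", class(mat))
  mat
}

# unique chain-pair names like "PC(16:0/18:1)"; prefix decorates sn-1
.make_names <- function(cls, n, sn1_prefix = "", sn2 = NULL, rng_order = TRUE) {
  grid <- expand.grid(c1 = seq(14, 22, by = 2), d1 = 0:4,
                      c2 = seq(14, 22, by = 2), d2 = 0:4)
  nm <- sprintf("%s(%s%d:%d/%s)", cls, sn1_prefix, grid$c1, grid$d1,
                if (is.null(sn2)) sprintf("%d:%d", grid$c2, grid$d2) else sn2)
  nm <- unique(nm)
  if (rng_order) nm <- sample(nm)
  nm[seq_len(n)]
}

#' Generate a structured synthetic lipid library
#'
#' Produces a catalogue with the composition of a targeted amniotic-fluid
#' polar lipid panel: 151 species = 88 PC (64 diacyl, 12 ether-O, 6
#' ether-P, 6 lyso) + 27 PE + 23 SM + 13 Cer, so that exactly 64 species
#' are lecithins and 23 are sphingomyelins. Neutral masses are drawn
#' uniformly in [400, 900] Da, unique to 4 decimals; expected retention
#' times uniformly in [1, 13] minutes. PEs are assigned the deprotonated
#' adduct, all other classes the protonated one. The species identities
#' are synthetic: only the catalogue's structure mirrors the targeted
#' panel, not its actual membership.
#'
#' @param seed Integer RNG seed (mandatory).
#' @return A \code{\link{lipid_library}} of 151 species.
#' @export
generate_library <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(seed)
  names <- c(
    .make_names("PC", 64),
    .make_names("PC", 12, sn1_prefix = "O-"),
    .make_names("PC", 6, sn1_prefix = "P-"),
    .make_names("PC", 6, sn2 = "0:0"),
    .make_names("PE", 27),
    .make_names("SM", 23, sn1_prefix = "d"),
    .make_names("Cer", 13, sn1_prefix = "d")
  )
  ann <- lapply(names, annotate_species)
  cls <- vapply(ann, `[[`, "", "lipid_class")
  linkage <- vapply(ann, `[[`, "", "linkage")
  n <- length(names)
  mass <- round(stats::runif(n, 400, 900), 4)
  while (anyDuplicated(mass)) {
    dup <- duplicated(mass)
    mass[dup] <- round(stats::runif(sum(dup), 400, 900), 4)
  }
  lipid_library(data.frame(
    name = names,
    class = cls,
    linkage = linkage,
    neutral_mass = mass,
    adduct = ifelse(cls == "PE", "[M-H]-", "[M+H]+"),
    expected_rt = round(stats::runif(n, 1, 13), 2),
    stringsAsFactors = FALSE
  ))
}

#' Specify a synthetic amniotic-fluid cohort
#'
#' Encodes the statistical structure the generator plants: log-normal
#' species intensities around per-species baselines; a logistic
#' gestational-week multiplier on lecithin species of mature-outcome
#' samples (lecithin synthesis accelerates sharply around 36 weeks, while
#' sphingomyelin stays flat through late pregnancy, so the L/S ratio rises
#' with maturity); optional planted fold changes on chosen species in the
#' mature groups; lamellar body counts drawn around 2 (18-week controls)
#' or near the 50 x 1e9/L decision boundary with a deliberate overlap.
#'
#' @param n_per_group Samples per group (>= 2); default 10.
#' @param groups Subset of \code{control_18gw}, \code{premature},
#'   \code{mature_lt37}, \code{mature_gt38}.
#' @param lecithin_rise List \code{midpoint} (gestational week, default
#'   36), \code{steepness} (per week, default 0.8), \code{max_mult}
#'   (ceiling multiplier over the 18-week baseline, default 20). Set
#'   \code{max_mult = 1} for a flat lecithin trajectory.
#' @param planted_biomarkers Named numeric vector: species name ->
#'   true fold change applied in mature-outcome samples. Default none.
#' @param noise_cv Biological + technical coefficient of variation per
#'   species, percent (> 0); default 30.
#' @param baseline_ls Expected L/S ratio of the immature baseline;
#'   default 1.8 (the 18-week controls of the reference cohort sit near
#'   1.3-2.3).
#' @param seed Integer RNG seed (mandatory).
#' @return A validated \code{cohort_spec} list.
#' @export
cohort_spec <- function(n_per_group = 10,
                        groups = c("control_18gw", "premature",
                                   "mature_lt37", "mature_gt38"),
                        lecithin_rise = list(midpoint = 36, steepness = 0.8,
                                             max_mult = 20),
                        planted_biomarkers = NULL,
                        noise_cv = 30,
                        baseline_ls = 1.8,
                        seed) {
  if (missing(seed)) stop("cohort_spec requires an explicit seed")
  stopifnot(n_per_group >= 2, noise_cv > 0, baseline_ls > 0)
  groups <- match.arg(groups, several.ok = TRUE)
  stopifnot(all(c("midpoint", "steepness", "max_mult") %in%
                  names(lecithin_rise)), lecithin_rise$max_mult >= 1)
  structure(list(
    n_per_group = as.integer(n_per_group), groups = groups,
    lecithin_rise = lecithin_rise, planted_biomarkers = planted_biomarkers,
    noise_cv = noise_cv, baseline_ls = baseline_ls,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# log-normal draw with arithmetic mean `m` and coefficient of variation cv (%)
.rlnorm_cv <- function(n, m, cv) {
  sdlog <- sqrt(log(1 + (cv / 100)^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# logistic gestational multiplier for lecithin synthesis
.lecithin_mult <- function(gw, rise) {
  1 + (rise$max_mult - 1) / (1 + exp(-rise$steepness * (gw - rise$midpoint)))
}

# peak list for one sample: library species with small m/z and RT jitter,
# plus uniform decoy noise peaks that mostly fall outside every window
.peaks_for_sample <- function(intensities, library, n_decoys = 100) {
  ppm_jitter <- pmin(pmax(stats::rnorm(nrow(library), 0, 1.2), -4.5), 4.5)
  rt_jitter <- pmin(pmax(stats::rnorm(nrow(library), 0, 0.05), -0.15), 0.15)
  signal <- data.frame(
    mz = library$mz * (1 + ppm_jitter * 1e-6),
    rt = library$expected_rt + rt_jitter,
    intensity = intensities
  )
  decoys <- data.frame(
    mz = stats::runif(n_decoys, 100, 1500),
    rt = stats::runif(n_decoys, 0, 15),
    intensity = stats::rlnorm(n_decoys, log(200), 0.8)
  )
  out <- rbind(signal, decoys)
  out[sample(nrow(out)), , drop = FALSE]
}

#' Generate a gestational-age-structured synthetic cohort
#'
#' Draws per-species baselines (log-normal, with the lecithin pool scaled
#' so the immature L/S ratio sits at \code{baseline_ls}), applies the
#' lecithin logistic rise to mature-outcome samples and the planted fold
#' changes, then emits per-sample peak lists (with m/z and RT jitter and
#' decoy noise peaks) plus a metadata table.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param library A \code{\link{lipid_library}}.
#' @return List with \code{peaklists} (named list of data.frames
#'   \code{mz,rt,intensity}) and \code{records} (data.frame
#'   \code{sample_id, gw, group, flm_outcome, lbc}).
#' @export
generate_cohort <- function(spec, library) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(library, "lipid_library"))
  planted <- spec$planted_biomarkers
  if (!is.null(planted)) {
    absent <- setdiff(names(planted), library$name)
    if (length(absent))
      stop("planted biomarker(s) absent from library: ",
           paste(absent, collapse = ", "))
  }
  set.seed(spec$seed)

  base <- stats::rlnorm(nrow(library), meanlog = log(1e5), sdlog = 1)
  lec <- library$is_lecithin
  sm <- library$is_sphingomyelin
  base[lec] <- base[lec] * spec$baseline_ls * sum(base[sm]) / sum(base[lec])

  gw_pool <- list(control_18gw = 18L, premature = 30:36,
                  mature_lt37 = 35:36, mature_gt38 = 38:40)
  records <- do.call(rbind, lapply(spec$groups, function(g) {
    data.frame(
      sample_id = sprintf("%s_%02d", g, seq_len(spec$n_per_group)),
      gw = sample(rep(gw_pool[[g]], length.out = spec$n_per_group * 3),
                  spec$n_per_group),
      group = g,
      flm_outcome = switch(g, control_18gw = "control_18gw",
                           premature = "premature", "mature"),
      stringsAsFactors = FALSE
    )
  }))
  lbc_mean <- c(control_18gw = 2, premature = 38,
                mature_lt37 = 58, mature_gt38 = 58)
  lbc_sd <- c(control_18gw = 1, premature = 10,
              mature_lt37 = 7, mature_gt38 = 7)
  records$lbc <- round(pmax(
    stats::rnorm(nrow(records), lbc_mean[records$group],
                 lbc_sd[records$group]), 0), 1)

  peaklists <- vector("list", nrow(records))
  names(peaklists) <- records$sample_id
  for (i in seq_len(nrow(records))) {
    m <- base
    if (records$flm_outcome[i] == "mature") {
      m[lec] <- m[lec] * .lecithin_mult(records$gw[i], spec$lecithin_rise)
      if (!is.null(planted)) {
        idx <- match(names(planted), library$name)
        m[idx] <- m[idx] * planted
      }
    }
    intensities <- .rlnorm_cv(length(m), m, spec$noise_cv)
    peaklists[[i]] <- .peaks_for_sample(intensities, library)
  }
  list(peaklists = peaklists, records = records)
}

#' Generate QC replicate injections
#'
#' Replicate peak lists of one pooled sample whose intensities vary with
#' class-specific target CVs, emulating instrument precision runs: the
#' class-average CVs of the extracted matrix converge to the targets as
#' the number of replicates grows.
#'
#' @param library A \code{\link{lipid_library}}.
#' @param n_reps Number of replicate injections (>= 2); default 6.
#' @param cv_target_pc Target CV (\%) for PC species (also applied to PE
#'   and Cer); default 3.8.
#' @param cv_target_sm Target CV (\%) for SM species; default 3.4.
#' @param seed Integer RNG seed (mandatory).
#' @return Named list of peak-list data.frames (\code{QC_1} ...).
#' @export
generate_qc <- function(library, n_reps = 6, cv_target_pc = 3.8,
                        cv_target_sm = 3.4, seed) {
  stopifnot(inherits(library, "lipid_library"), n_reps >= 2)
  if (cv_target_pc <= 0 || cv_target_sm <= 0)
    stop("CV targets must be positive")
  set.seed(seed)
  base <- stats::rlnorm(nrow(library), meanlog = log(1e5), sdlog = 1)
  cv <- ifelse(library$is_sphingomyelin, cv_target_sm, cv_target_pc)
  out <- lapply(seq_len(n_reps), function(r) {
    intensities <- .rlnorm_cv(length(base), base, cv)
    .peaks_for_sample(intensities, library, n_decoys = 50)
  })
  names(out) <- sprintf("QC_%d", seq_len(n_reps))
  out
}

#' The 33-sample reference cohort (clinical comparison fixture)
#'
#' The bundled cohort of 33 amniotic-fluid samples with their measured L/S
#' ratio, lamellar body count, sampling gestational week and Apgar-derived
#' FLM outcome; seven 18-week amniocentesis samples carry the outcome
#' label \code{control_18gw} and count as premature during evaluation.
#'
#' @return data.frame with columns \code{sample_id}, \code{ls_ratio},
#'   \code{lbc}, \code{gw}, \code{flm_outcome} (33 rows).
#' @export
clinical_cohort <- function() {
  path <- system.file("extdata", "clinical_cohort.csv", package = "amniolipids")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Toy pathway bundle for topology tests
#'
#' Four synthetic pathway graphs with analytically known centralities:
#' a 5-node star (the hub carries all centrality), a 3-node path, a
#' complete 4-node graph (no centrality mass at all), and an 8-node tree
#' whose relative betweenness table ships alongside the package
#' (\code{extdata/toy_tree8_centralities.csv}).
#'
#' @param seed Accepted for interface uniformity with the other
#'   generators; the bundle is fully deterministic.
#' @return Named list of \code{\link{pathway}} objects:
#'   \code{star}, \code{path3}, \code{complete4}, \code{tree8}.
#' @export
generate_toy_pathways <- function(seed = 1) {
  set.seed(seed)
  list(
    star = pathway("star",
                   c("hub", "leaf1", "leaf2", "leaf3", "leaf4"),
                   cbind("hub", c("leaf1", "leaf2", "leaf3", "leaf4"))),
    path3 = pathway("path3", c("pa", "pb", "pc"),
                    rbind(c("pa", "pb"), c("pb", "pc"))),
    complete4 = pathway("complete4", paste0("k", 1:4),
                        t(utils::combn(paste0("k", 1:4), 2))),
    tree8 = pathway("tree8", paste0("n", 1:8),
                    rbind(c("n1", "n2"), c("n2", "n3"), c("n3", "n4"),
                          c("n4", "n5"), c("n3", "n6"), c("n6", "n7"),
                          c("n6", "n8")))
  )
}
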