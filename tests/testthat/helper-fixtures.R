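# Shared fixtures: a hand-sized library and peak-list builders.

tiny_library <- function() {
  names <- c("PC(16:0/18:1)", "PC(18:0/20:4)", "PC(O-16:0/18:1)",
             "PC(20:4/0:0)", "SM(d18:1/16:0)", "SM(d16:1/17:0)",
             "PE(16:0/16:0)", "Cer(d18:1/16:0)")
  ann <- lapply(names, annotate_species)
  lipid_library(data.frame(
    name = names,
    class = vapply(ann, `[[`, "", "lipid_class"),
    linkage = vapply(ann, `[[`, "", "linkage"),
    neutral_mass = c(759.5778, 809.5935, 745.5985, 543.3325,
                     702.5676, 688.5519, 691.5152, 537.5121),
    adduct = c(rep("[M+H]+", 6), "[M-H]-", "[M+H]+"),
    expected_rt = c(8.1, 8.9, 8.5, 3.2, 7.4, 7.0, 7.8, 9.5),
    stringsAsFactors = FALSE
  ))
}

# a peak list containing exactly the library species at given intensities,
# with optional ppm / rt offsets
peaks_at <- function(library, intensities, ppm_offset = 0, rt_offset = 0) {
  data.frame(
    mz = library$mz * (1 + ppm_offset * 1e-6),
    rt = library$expected_rt + rt_offset,
    intensity = intensities
  )
}

empty_peaks <- function() {
  data.frame(mz = numeric(0), rt = numeric(0), intensity = numeric(0))
}
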