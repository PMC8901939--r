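#' The 42-feature registry
#'
#' Fixed registry of the 42 radiomic features produced by [extract_all()]:
#' four shape features, six first-order (discretized-histogram) statistics,
#' seven gray-level co-occurrence matrix (GLCM) features, eleven gray-level
#' run-length matrix (GLRLM) features, three neighborhood gray-level
#' difference matrix (NGLDM) features and eleven gray-level zone-length
#' matrix (GLZLM) features. Names follow the LIFEx naming convention
#' (`GROUP_Feature`).
#'
#' @return A tibble with columns `name` and `group`, 42 rows.
#' @examples
#' feature_registry()
#' table(feature_registry()$group)
#' @export
feature_registry <- function() {
  reg <- list(
    SHAPE = c("Volume_mL", "Volume_voxels", "Sphericity", "Compacity"),
    DISCRETIZED_HISTO = c("Skewness", "Kurtosis", "ExcessKurtosis",
                          "Entropy_log10", "Entropy_log2", "Energy"),
    GLCM = c("Homogeneity", "Energy", "Contrast", "Correlation",
             "Entropy_log10", "Entropy_log2", "Dissimilarity"),
    GLRLM = c("SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE",
              "LRLGE", "LRHGE", "GLNU", "RLNU", "RP"),
    NGLDM = c("Coarseness", "Contrast", "Busyness"),
    GLZLM = c("SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE",
              "LZLGE", "LZHGE", "GLNU", "ZLNU", "ZP")
  )
  tibble::tibble(
    name = unlist(lapply(names(reg), function(g) paste(g, reg[[g]], sep = "_")),
                  use.names = FALSE),
    group = rep(names(reg), lengths(reg))
  )
}

#' Reference CT acquisition-protocol profile
#'
#' Frequency profile of (convolution kernel, kVp) acquisition protocols
#' observed in a multi-center lung-cancer CT radiomics cohort: 15 protocols
#' over 10 kernels and 4 tube voltages, with frequencies counting malignant
#' lesion images per protocol. One protocol has frequency 1 and is dropped by
#' the default minimum-frequency filter, leaving 14 harmonization batches
#' (124 observations). This profile is the default batch-size design of the
#' synthetic generator.
#'
#' @return A tibble with columns `protocol`, `kernel`, `kvp`, `frequency`.
#' @examples
#' ct_protocol_profile()
#' sum(ct_protocol_profile()$frequency)
#' @export
ct_protocol_profile <- function() {
  tibble::tibble(
    protocol = 1:15,
    kernel = c("B", "B10f", "B20f", "B30f", "B30f", "B30f", "B31f", "B31s",
               "B31f", "B40f", "B40f", "FC08", "FC08", "FC17", "STANDARD"),
    kvp = c(120, 120, 120, 100, 120, 140, 100, 130, 120, 100, 120,
            100, 120, 100, 120),
    frequency = c(5L, 17L, 12L, 25L, 2L, 1L, 19L, 9L, 9L, 4L, 7L, 11L, 2L, 2L, 2L)
  )
}

# scanner manufacturer implied by the reconstruction kernel family
kernel_scanner <- function(kernel) {
  dplyr::case_when(
    kernel == "B" ~ "Philips",
    grepl("^B[0-9]", kernel) ~ "Siemens",
    grepl("^FC", kernel) ~ "Toshiba",
    kernel == "STANDARD" ~ "GE",
    TRUE ~ "Siemens"
  )
}
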