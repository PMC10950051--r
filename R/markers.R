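#' Canonical biomarker registry
#'
#' The panel analysed by this package consists of 27 Alzheimer's disease
#' biomarkers spanning PET, MRI, CSF mass-spectrometry and immunoassay
#' measures, plasma assays, clinical scores and a polygenic risk score. The
#' registry is shipped as a versioned text resource and records, for each
#' marker, a display name, its modality, the correlation block it belongs to
#' in the reference clustering solution (`core`, `neurodegeneration`, `at8`,
#' `dysfunction`, or `none` for markers outside the main clusters) and
#' whether it is log-transformed before z-scoring.
#'
#' @return A tibble with columns `marker`, `display`, `modality`, `block`
#'   and `log_transform`.
#' @export
#' @examples
#' marker_registry()
marker_registry <- function() {
  path <- system.file("extdata", "markers.tsv", package = "admarkers")
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  reg$log_transform <- as.logical(reg$log_transform)
  tibble::as_tibble(reg)
}

#' @rdname marker_registry
#' @export
ad_marker_names <- function() marker_registry()$marker

#' Marker columns present in a panel data frame
#'
#' @param data A data frame holding a biomarker panel.
#' @param schema Character vector of canonical marker names.
#' @return Character vector: the schema markers present in `data`, in
#'   registry order.
#' @export
panel_markers <- function(data, schema = ad_marker_names()) {
  intersect(schema, names(data))
}

# label (non-marker) columns understood by the reader
label_columns <- function() {
  c("subject_id", "cdr_group", "centiloid", "amyloid_positive",
    "age", "sex", "apoe4_carrier", "education", "race_nhw", "group")
}

# markers log-transformed before z-scoring (skewed NfL measures)
default_log_markers <- function() {
  reg <- marker_registry()
  reg$marker[reg$log_transform]
}
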