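#' Read a biomarker panel from CSV/TSV
#'
#' Reads a subject-by-marker table with a header row. Empty cells denote
#' missing values; all marker values must otherwise be numeric. Recognised
#' label columns (`subject_id`, `cdr_group`, `centiloid`,
#' `amyloid_positive`, `age`, `sex`, `apoe4_carrier`, `education`,
#' `race_nhw`, `group`) are parsed alongside the markers; any other column
#' not in `schema` is an error. Amyloid positivity is defined by the
#' Centiloid threshold: a Centiloid value of 16.4 or greater is positive
#' (the threshold is inclusive). Cognitively impaired (`cdr_group ==
#' "CDRgt0"`) subjects who are amyloid negative are dropped with a warning,
#' since the analysis cohort requires impaired subjects to be on the
#' amyloid pathway.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param schema Character vector of marker column names expected in the
#'   file (default: the full 27-marker registry). Markers absent from the
#'   file are allowed; unknown columns are not.
#' @return A tibble with label columns followed by marker columns; `NA`
#'   marks missing biomarker measurements. Row order is preserved.
#' @export
read_panel <- function(path, schema = ad_marker_names()) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  header <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  dup <- unique(header[duplicated(header)])
  if (length(dup) > 0)
    abort_stage("read_panel", paste0("duplicated column(s): ",
                                     paste(dup, collapse = ", ")))
  unknown <- setdiff(header, c(schema, label_columns()))
  if (length(unknown) > 0)
    abort_stage("read_panel", paste0("unknown marker column(s): ",
                                     paste(unknown, collapse = ", ")))
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE)
  out <- tibble::tibble(.rows = nrow(raw))
  parse_num <- function(col) {
    v <- raw[[col]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad) > 0)
      abort_stage("read_panel", sprintf(
        "non-numeric value '%s' at row %d, column '%s'", v[bad[1]], bad[1], col))
    num
  }
  parse_lgl <- function(col) {
    v <- tolower(raw[[col]])
    v[v == ""] <- NA_character_
    out <- rep(NA, length(v))
    out[v %in% c("true", "t", "1", "yes")] <- TRUE
    out[v %in% c("false", "f", "0", "no")] <- FALSE
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad) > 0)
      abort_stage("read_panel", sprintf(
        "non-logical value '%s' at row %d, column '%s'", raw[[col]][bad[1]],
        bad[1], col))
    out
  }
  for (col in intersect(c("subject_id", "cdr_group", "sex", "group"), header))
    out[[col]] <- dplyr::na_if(raw[[col]], "")
  for (col in intersect(c("centiloid", "age", "education"), header))
    out[[col]] <- parse_num(col)
  for (col in intersect(c("amyloid_positive", "apoe4_carrier", "race_nhw"), header))
    out[[col]] <- parse_lgl(col)
  for (col in intersect(schema, header)) out[[col]] <- parse_num(col)

  if ("centiloid" %in% names(out)) {
    apos <- out$centiloid >= 16.4
    if ("amyloid_positive" %in% names(out)) {
      bad <- which(!is.na(out$amyloid_positive) & !is.na(apos) &
                     out$amyloid_positive != apos)
      if (length(bad) > 0)
        abort_stage("read_panel", sprintf(
          "amyloid_positive inconsistent with the 16.4 Centiloid threshold at row %d",
          bad[1]))
    }
    out$amyloid_positive <- apos
  }
  if (all(c("cdr_group", "amyloid_positive") %in% names(out))) {
    drop <- !is.na(out$cdr_group) & out$cdr_group == "CDRgt0" &
      !is.na(out$amyloid_positive) & !out$amyloid_positive
    if (any(drop)) {
      warning(sprintf(
        "dropped %d cognitively impaired, amyloid-negative subject(s)",
        sum(drop)), call. = FALSE)
      out <- out[!drop, , drop = FALSE]
    }
  }
  attr(out, "ad_transforms") <- character()
  out
}

#' Write a panel to CSV with a sidecar JSON of applied transforms
#'
#' @param data Panel tibble.
#' @param path Output CSV path.
#' @param sidecar Path for the JSON sidecar recording the transforms applied
#'   so far and the generating seed (if any); default `<path>.json`.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_panel <- function(data, path, sidecar = paste0(path, ".json"),
                        seed = attr(data, "ad_seed")) {
  readr::write_csv(data, path, na = "", progress = FALSE)
  meta <- list(transforms = as.list(attr(data, "ad_transforms") %||% character()),
               seed = seed, n_subjects = nrow(data),
               markers = panel_markers(data))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Preprocess a panel: log-transform skewed markers, then z-score
#'
#' Applies a natural-log transform to the listed markers (by default the
#' skewed CSF and plasma NfL measures) and then z-scores every marker over
#' its non-missing entries, using the population (n-divisor) standard
#' deviation. Missing entries are untouched: preprocessing never creates or
#' destroys missingness. Downstream analyses are rank- and split-based, so
#' the log base and the z-score divisor have no effect on results; they are
#' fixed here for reproducibility.
#'
#' @param data Panel tibble.
#' @param log_markers Markers to log-transform first; must be present in the
#'   panel and strictly positive where observed.
#' @param markers Marker columns to process (default: all registry markers
#'   present).
#' @return The panel with transformed marker columns.
#' @export
preprocess <- function(data, log_markers = default_log_markers(),
                       markers = panel_markers(data)) {
  log_markers <- intersect(log_markers, markers)
  bad <- setdiff(log_markers, names(data))
  if (length(bad) > 0)
    abort_stage("preprocess", paste0("log marker not in panel: ",
                                     paste(bad, collapse = ", ")))
  for (m in log_markers) {
    v <- data[[m]]
    if (any(v[!is.na(v)] <= 0))
      abort_stage("preprocess", sprintf(
        "non-positive value in log-transformed marker '%s'", m))
    data[[m]] <- log(v)
  }
  for (m in markers) {
    v <- data[[m]]
    obs <- !is.na(v)
    if (sum(obs) == 0) next
    mu <- mean(v[obs])
    sdev <- sqrt(mean((v[obs] - mu)^2))
    if (sdev < 1e-12)
      abort_stage("preprocess", sprintf(
        "marker '%s' is constant: z-score undefined", m))
    data[[m]] <- (v - mu) / sdev
  }
  attr(data, "ad_transforms") <- c(attr(data, "ad_transforms") %||% character(),
                                   paste0("log:", paste(log_markers, collapse = "+")),
                                   "zscore:population-sd")
  data
}

#' Exclude subjects missing too many biomarkers
#'
#' Subjects missing strictly more than `fraction` of the marker columns are
#' removed; the order of survivors is preserved.
#'
#' @param data Panel tibble.
#' @param fraction Maximum tolerated missing fraction, in (0, 1); default
#'   0.5 (subjects missing more than 50% of the biomarkers are excluded).
#' @param markers Marker columns considered.
#' @return The filtered panel.
#' @export
exclude_sparse_subjects <- function(data, fraction = 0.5,
                                    markers = panel_markers(data)) {
  stopifnot(fraction > 0, fraction < 1)
  miss <- rowMeans(is.na(as.matrix(data[, markers, drop = FALSE])))
  out <- data[miss <= fraction, , drop = FALSE]
  attr(out, "ad_transforms") <- c(attr(data, "ad_transforms") %||% character(),
                                  sprintf("exclude_sparse:>%g", fraction))
  out
}

#' Subset a panel to an analysis cohort
#'
#' Cohorts follow the clinical grouping: `entire` keeps everyone,
#' `preclinical` keeps cognitively normal (CDR 0) amyloid-positive subjects,
#' `impaired` keeps cognitively impaired (CDR > 0) amyloid-positive
#' subjects, and `amyloid_positive` keeps everyone at or above the 16.4
#' Centiloid threshold regardless of cognitive status.
#'
#' @param data Panel tibble with `cdr_group` and `amyloid_positive` columns.
#' @param which One of `"entire"`, `"preclinical"`, `"impaired"`,
#'   `"amyloid_positive"`.
#' @return The subset panel; an empty subset is an error.
#' @export
subset_cohort <- function(data, which = c("entire", "preclinical", "impaired",
                                          "amyloid_positive")) {
  which <- match.arg(which)
  keep <- switch(which,
    entire = rep(TRUE, nrow(data)),
    preclinical = data$cdr_group == "CDR0" & data$amyloid_positive,
    impaired = data$cdr_group == "CDRgt0" & data$amyloid_positive,
    amyloid_positive = data$amyloid_positive)
  keep[is.na(keep)] <- FALSE
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0)
    abort_stage("subset_cohort", paste0("empty cohort: ", which))
  attr(out, "ad_transforms") <- c(attr(data, "ad_transforms") %||% character(),
                                  paste0("subset:", which))
  out
}
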