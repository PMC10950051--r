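#' Specify a synthetic cohort
#'
#' The generator emulates the statistical structure the analysis pipeline
#' assumes: a Gaussian factor model with four correlated biomarker blocks
#' (core pathology, neurodegeneration, AT8-associated phospho-tau sites,
#' neuronal dysfunction/inflammation; three markers belong to no block and
#' are pure noise), group-dependent mean shifts on the block factors and on
#' individual markers, and per-marker missingness. For subject `s` in group
#' `g` and marker `m` in block `b` with within-block loading `l`:
#' \deqn{x_{sm} = l (f_{sb} + \delta_{bg}) + \sqrt{1 - l^2}\,\sigma
#' \epsilon_{sm} + \gamma_{mg}} with standard-normal `f` and `eps`, block
#' shift `delta`, marker shift `gamma` and noise scale `sigma`. Missingness
#' is applied per marker (MCAR), after which a fraction of subjects is
#' forced above 50% missingness to exercise the exclusion rule.
#'
#' @param group_sizes Named integer vector `(cn_aneg, cn_apos, ci)`;
#'   default the study sizes 211/228/88.
#' @param blocks Named list of blocks, each `list(members =, loading =)`.
#'   Members must partition a subset of the 27 markers.
#' @param effect_matrix Numeric matrix, blocks x groups: mean shift of the
#'   block factor per group (z units).
#' @param marker_shifts Numeric matrix, markers x groups: additional
#'   per-marker mean shifts (z units); zero by default.
#' @param satellite_loadings Named list `marker = list(block =, loading =)`
#'   giving markers outside every block a weak coupling to a block factor.
#'   Satellites keep planted block `"none"`: they emulate markers that are
#'   disease-related but too loosely coupled to sit inside a main cluster.
#' @param noise_sd Scale of the idiosyncratic noise.
#' @param missing_rates Named numeric vector of per-marker MCAR missingness
#'   probabilities (default 0.10 everywhere).
#' @param sparse_subject_rate Fraction of subjects forced to miss more than
#'   half the markers.
#' @param seed Seed; a fixed seed gives a byte-identical cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(cn_aneg = 211L, cn_apos = 228L, ci = 88L),
                        blocks = default_blocks(),
                        effect_matrix = default_effect_matrix(),
                        marker_shifts = default_marker_shifts(),
                        satellite_loadings = default_satellites(),
                        noise_sd = 1,
                        missing_rates = NULL,
                        sparse_subject_rate = 0.02,
                        seed = 1L) {
  markers <- ad_marker_names()
  members <- unlist(lapply(blocks, `[[`, "members"), use.names = FALSE)
  if (anyDuplicated(members) > 0)
    abort_stage("cohort_spec", "block members must not overlap")
  if (!all(members %in% markers))
    abort_stage("cohort_spec", "unknown marker in block membership")
  for (b in blocks)
    if (b$loading <= 0 || b$loading > 1)
      abort_stage("cohort_spec", "loadings must lie in (0, 1]")
  missing_rates <- missing_rates %||%
    stats::setNames(rep(0.10, length(markers)), markers)
  if (any(missing_rates >= 1) || any(missing_rates < 0))
    abort_stage("cohort_spec", "missing rates must lie in [0, 1)")
  if (is.null(marker_shifts)) {
    marker_shifts <- matrix(0, length(markers), 3,
                            dimnames = list(markers, names(group_sizes)))
  }
  for (s in names(satellite_loadings)) {
    if (s %in% members)
      abort_stage("cohort_spec", "satellite markers must lie outside blocks")
    if (!satellite_loadings[[s]]$block %in% names(blocks))
      abort_stage("cohort_spec", "unknown satellite block")
  }
  structure(list(group_sizes = group_sizes, blocks = blocks,
                 satellite_loadings = satellite_loadings,
                 effect_matrix = effect_matrix, marker_shifts = marker_shifts,
                 noise_sd = noise_sd, missing_rates = missing_rates,
                 sparse_subject_rate = sparse_subject_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# default four-block structure following the reference clustering solution;
# loadings are chosen inversely to block size so each block contributes a
# comparable leading eigenvalue and the scree kinks at the block count
default_blocks <- function(loadings = c(core = 0.45, neurodegeneration = 0.92,
                                        at8 = 0.95, dysfunction = 0.86)) {
  reg <- marker_registry()
  out <- list()
  for (b in names(loadings)) {
    out[[b]] <- list(members = reg$marker[reg$block == b],
                     loading = unname(loadings[b]))
  }
  # the MRI cortical signature couples to the neurodegeneration factor more
  # weakly than the NfL measures (it detaches in the preclinical subset)
  out$neurodegeneration$member_loadings <-
    stats::setNames(c(0.92, 0.92, 0.66),
                    c("nfl_csf", "nfl_plasma", "cortical_signature"))
  out
}

# markers outside the main blocks couple weakly to a block factor: MMSE and
# the polygenic risk score to core pathology, pT175 to the AT8 sites
default_satellites <- function() {
  list(mmse = list(block = "core", loading = 0.42),
       prs = list(block = "core", loading = 0.40),
       pt175 = list(block = "at8", loading = 0.45))
}

# block-factor mean shifts (z units) per group: core pathology tracks
# amyloid status, neurodegeneration tracks cognitive impairment, AT8 and
# dysfunction blocks are weakly informative
default_effect_matrix <- function() {
  m <- rbind(core = c(-0.35, 0.30, 0.50),
             neurodegeneration = c(-0.15, 0.00, 1.50),
             at8 = c(0.00, 0.00, 0.25),
             dysfunction = c(0.00, 0.00, 0.30))
  colnames(m) <- c("cn_aneg", "cn_apos", "ci")
  m
}

# per-marker extra shifts: five core markers strongly separate amyloid
# groups (the planted strong amyloid predictors); tau PET and t-tau/Abeta40
# additionally separate cognitive groups; clinical scores track impairment
default_marker_shifts <- function() {
  markers <- ad_marker_names()
  m <- matrix(0, length(markers), 3,
              dimnames = list(markers, c("cn_aneg", "cn_apos", "ci")))
  strong <- strong_amyloid_markers()
  m[strong, ] <- rep(c(-0.65, 0.60, 0.60), each = length(strong))
  m["tau_pet", ] <- c(0.00, 0.00, 1.40)
  m["ttau_ab40_csf", ] <- c(0.00, 0.00, 1.10)
  m["cdr_sb", ] <- c(0.00, 0.00, 2.50)
  m["mmse", ] <- c(0.00, 0.00, -1.20)
  m
}

#' @rdname cohort_spec
#' @export
strong_amyloid_markers <- function() {
  c("pt217", "pt111", "ptau181_ab40_csf", "ab42_ab40_csf", "pt231")
}

#' Named cohort presets
#'
#' `entire_cohort` is the default four-block cohort with group-dependent
#' effects; `preclinical_only` and `impaired_only` restrict the group sizes
#' to a single group; `null_panel` has no correlation structure and no
#' effects (every marker is pure noise); `single_separator` makes one marker
#' (`pt217`) deterministically equal to amyloid status with all other
#' markers pure noise.
#'
#' @param name Preset name.
#' @param seed Seed passed through to the spec.
#' @return A `cohort_spec`.
#' @export
cohort_preset <- function(name = c("entire_cohort", "preclinical_only",
                                   "impaired_only", "null_panel",
                                   "single_separator"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    entire_cohort = cohort_spec(seed = seed),
    preclinical_only = cohort_spec(
      group_sizes = c(cn_aneg = 0L, cn_apos = 228L, ci = 0L), seed = seed),
    impaired_only = cohort_spec(
      group_sizes = c(cn_aneg = 0L, cn_apos = 0L, ci = 88L), seed = seed),
    null_panel = {
      blocks <- lapply(default_blocks(), function(b) {
        b$loading <- 1e-8; b$member_loadings <- NULL; b
      })
      cohort_spec(blocks = blocks, satellite_loadings = list(),
                  effect_matrix = default_effect_matrix() * 0,
                  marker_shifts = NULL, seed = seed)
    },
    single_separator = {
      blocks <- lapply(default_blocks(), function(b) {
        b$loading <- 1e-8; b$member_loadings <- NULL; b
      })
      mr <- stats::setNames(rep(0.10, 27), ad_marker_names())
      mr["pt217"] <- 0
      cohort_spec(blocks = blocks, satellite_loadings = list(),
                  effect_matrix = default_effect_matrix() * 0,
                  marker_shifts = NULL, missing_rates = mr,
                  sparse_subject_rate = 0, seed = seed)
    })
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [cohort_spec()]: exact group sizes, factor-model
#' marker values, demographics with the published group moments, a Centiloid
#' value rank-matched within group to the amyloid-PET marker (so amyloid
#' positivity is exactly the 16.4-Centiloid rule), per-marker MCAR
#' missingness and forced sparse subjects. For the `single_separator` preset
#' the `pt217` column is set equal to amyloid status after the factor draw.
#'
#' @param spec A `cohort_spec`.
#' @return A list of class `synthetic_cohort` with `panel` (tibble of labels
#'   plus the 27 markers) and `truth` (planted block assignment and the
#'   planted informative markers per outcome).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  markers <- ad_marker_names()
  gs <- spec$group_sizes
  n <- sum(gs)
  group <- rep(names(gs), times = gs)
  gidx <- match(group, colnames(spec$effect_matrix))

  x <- matrix(NA_real_, n, length(markers), dimnames = list(NULL, markers))
  block_of <- stats::setNames(rep("none", length(markers)), markers)
  factors <- list()
  for (b in names(spec$blocks)) {
    bl <- spec$blocks[[b]]
    factors[[b]] <- rnorm(n) + spec$effect_matrix[b, gidx]
    if (length(bl$members) == 0) next
    block_of[bl$members] <- b
    for (m in bl$members) {
      l <- (bl$member_loadings %||% numeric())[m]
      l <- if (is.null(l) || is.na(l)) bl$loading else unname(l)
      x[, m] <- l * factors[[b]] + sqrt(1 - l^2) * spec$noise_sd * rnorm(n)
    }
  }
  for (m in markers[block_of == "none"]) {
    sat <- spec$satellite_loadings[[m]]
    x[, m] <- if (is.null(sat)) spec$noise_sd * rnorm(n)
              else sat$loading * factors[[sat$block]] +
                sqrt(1 - sat$loading^2) * spec$noise_sd * rnorm(n)
  }
  x <- x + t(spec$marker_shifts[markers, gidx, drop = FALSE])

  # NfL markers are log-transformed downstream: exponentiate so the stored
  # raw values are positive and skewed, as measured concentrations are
  for (m in default_log_markers()) x[, m] <- exp(x[, m])

  amyloid_positive <- group %in% c("cn_apos", "ci")
  if (spec$missing_rates["pt217"] == 0 &&
      all(abs(spec$effect_matrix) < 1e-6) &&
      all(vapply(spec$blocks, function(b) b$loading, 0) < 1e-6)) {
    # single-separator regime: pt217 equals the outcome exactly
    x[, "pt217"] <- as.numeric(amyloid_positive)
  }

  centiloid <- numeric(n)
  for (g in names(gs)) {
    idx <- which(group == g)
    if (length(idx) == 0) next
    u <- sort(runif(length(idx)))
    cl <- if (g == "cn_aneg") -6 + 22.3 * qbeta(u, 2, 4)
          else 16.4 + 95 * qbeta(u, 1.6, 3)
    # rank-match to the amyloid-PET marker within group
    centiloid[idx[order(x[idx, "amyloid_pet"])]] <- cl
  }

  demo <- generate_demographics(gs)

  # MCAR missingness, then forced sparse subjects
  for (m in markers) {
    r <- spec$missing_rates[m]
    if (r > 0) x[runif(n) < r, m] <- NA
  }
  n_sparse <- floor(spec$sparse_subject_rate * n)
  if (n_sparse > 0) {
    sparse_idx <- sample.int(n, n_sparse)
    k_miss <- ceiling(0.52 * length(markers))
    for (i in sparse_idx) x[i, sample(markers, k_miss)] <- NA
  }

  panel <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = group,
    cdr_group = ifelse(group == "ci", "CDRgt0", "CDR0"),
    centiloid = centiloid,
    amyloid_positive = amyloid_positive,
    age = demo$age, sex = demo$sex, apoe4_carrier = demo$apoe4_carrier,
    education = demo$education, race_nhw = demo$race_nhw)
  panel <- dplyr::bind_cols(panel, tibble::as_tibble(x))
  attr(panel, "ad_seed") <- spec$seed
  attr(panel, "ad_transforms") <- character()

  truth <- list(
    block = block_of,
    informative = list(
      amyloid = strong_amyloid_markers(),
      cognition_entire = unique(c(strong_amyloid_markers(), "tau_pet",
                                  "ttau_ab40_csf")),
      cognition_apos = c("tau_pet", "ttau_ab40_csf", "nfl_csf", "nfl_plasma",
                         "cortical_signature")))
  structure(list(panel = panel, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%s), seed %d\n",
              nrow(x$panel),
              paste(x$spec$group_sizes, collapse = "/"), x$spec$seed))
  invisible(x)
}

#' Generate demographics with the published group moments
#'
#' Age and education are normal with the published per-group means and SDs;
#' sex, race and APOE e4 carriage are Bernoulli with the published
#' proportions.
#'
#' @param group_sizes Named sizes `(cn_aneg, cn_apos, ci)`.
#' @param summary Demographic summary (see [table1_summary()]).
#' @param zero_variance Draw exact means instead of sampling (continuous
#'   variables only).
#' @return A tibble with `group`, `age`, `sex`, `race_nhw`,
#'   `apoe4_carrier`, `education`.
#' @export
generate_demographics <- function(group_sizes, summary = table1_summary(),
                                  zero_variance = FALSE) {
  if (inherits(group_sizes, "cohort_spec")) group_sizes <- group_sizes$group_sizes
  out <- list()
  for (gi in seq_along(group_sizes)) {
    ng <- group_sizes[gi]
    if (ng == 0) next
    age <- if (zero_variance) rep(summary$continuous$age$mean[gi], ng)
           else rnorm(ng, summary$continuous$age$mean[gi],
                      summary$continuous$age$sd[gi])
    edu <- if (zero_variance) rep(summary$continuous$education$mean[gi], ng)
           else rnorm(ng, summary$continuous$education$mean[gi],
                      summary$continuous$education$sd[gi])
    out[[length(out) + 1]] <- tibble::tibble(
      group = names(group_sizes)[gi],
      age = age,
      sex = ifelse(runif(ng) < summary$categorical$sex_female$proportion[gi],
                   "female", "male"),
      race_nhw = runif(ng) < summary$categorical$race_nhw$proportion[gi],
      apoe4_carrier = runif(ng) <
        summary$categorical$apoe4_carrier$proportion[gi],
      education = edu)
  }
  dplyr::bind_rows(out)
}

#' Write a synthetic cohort to CSV with a truth sidecar
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Output CSV path (readable by [read_panel()]).
#' @param truth_path JSON sidecar for the planted truth.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path,
                         truth_path = sub("\\.csv$", "_truth.json", path)) {
  write_panel(cohort$panel, path, seed = cohort$spec$seed)
  jsonlite::write_json(cohort$truth, truth_path, auto_unbox = TRUE)
  invisible(path)
}
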