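# internal helpers

# derive independent per-stage seeds from one master seed (documented
# splitting rule: seed the generator, then draw 31-bit integers)
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  # headroom below .Machine$integer.max so callers can add small offsets
  sample.int(.Machine$integer.max - 100000L, n)
}

abort_stage <- function(stage, msg, class = "admarkers_error") {
  rlang::abort(paste0("[", stage, "] ", msg),
               class = c(paste0("admarkers_", stage, "_error"), class))
}

# stratified fold assignment for a binary factor
make_folds <- function(y, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}
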