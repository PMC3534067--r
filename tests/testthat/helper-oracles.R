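# Independent oracles used by the property and acceptance tests. These share
# no code with the implementations they check.

# --- secondary-structure enumeration ---------------------------------
# Exhaustively enumerates every valid structure (pairs among A-U, G-C, G-U;
# hairpin loops >= 3) of a short sequence and returns the maximum
# stacking-weighted score, computed from the pair set alone.

oracle_pairable <- function(a, b) {
  paste0(a, b) %in% c("GC", "CG", "AT", "TA", "GT", "TG")
}

oracle_stack_weight <- function(a, b) {
  if (paste0(a, b) %in% c("GC", "CG")) 3
  else if (paste0(a, b) %in% c("AT", "TA")) 2
  else 1
}

oracle_score <- function(pairs, bases) {
  if (length(pairs) == 0) return(0)
  keys <- vapply(pairs, function(p) paste(p, collapse = "-"), character(1))
  sum(vapply(pairs, function(p) {
    inner <- paste(c(p[1] + 1, p[2] - 1), collapse = "-")
    if (inner %in% keys) oracle_stack_weight(bases[p[1]], bases[p[2]]) else 1
  }, numeric(1)))
}

oracle_enumerate <- function(bases, i, j) {
  # returns a list of pair-lists covering interval [i, j]
  if (j - i < 4) return(list(list()))
  out <- list()
  for (s in oracle_enumerate(bases, i + 1, j)) {   # i unpaired
    out[[length(out) + 1]] <- s
  }
  for (k in (i + 4):j) {                           # i paired with k
    if (!oracle_pairable(bases[i], bases[k])) next
    left <- oracle_enumerate(bases, i + 1, k - 1)
    right <- if (k + 1 <= j) oracle_enumerate(bases, k + 1, j)
             else list(list())
    for (a in left) for (b in right) {
      out[[length(out) + 1]] <- c(list(c(i, k)), a, b)
    }
  }
  out
}

oracle_fold_best <- function(seq) {
  bases <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  structs <- oracle_enumerate(bases, 1, length(bases))
  max(vapply(structs, oracle_score, numeric(1), bases = bases))
}

# --- phasing permutation oracle --------------------------------------
# Monte-Carlo estimate of P[max register count >= k] for n distinct
# positions falling uniformly over the registers.
oracle_perm_phase_p <- function(n, k_obs, reps = 1e4) {
  mean(replicate(reps, max(tabulate(sample.int(21, n, replace = TRUE),
                                    nbins = 21))) >= k_obs)
}

# --- shared pipeline fixture -----------------------------------------
# The default-conditions pipeline run is expensive; build it once per test
# session and reuse it across test files.
pipeline_cache <- new.env(parent = emptyenv())

default_pipeline <- function() {
  if (is.null(pipeline_cache$pl)) {
    pipeline_cache$cfg <- sim_config(seed = 101)
    pipeline_cache$pl <- run_pipeline(pipeline_cache$cfg)
  }
  pipeline_cache$pl
}

mirna_truth <- function(sim) {
  m <- dplyr::filter(sim$features, kind == "mirna_hairpin")
  tibble::tibble(
    feature_id = m$feature_id,
    chrom = m$chrom, f_start = m$start, f_end = m$end,
    mature = vapply(m$payload, function(p) p$mature, character(1)),
    arm = vapply(m$payload, function(p) p$arm, character(1)),
    star_expressed = vapply(m$payload, function(p)
      isTRUE(p$star_expressed), logical(1)))
}
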