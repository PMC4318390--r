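# Label-permutation background model: within each structure the labels
# are shuffled across the fixed coordinates, which preserves every
# pattern's support exactly (per-structure label multisets are
# unchanged), and the cohesive radius is recomputed on each permuted
# dataset. Background radii are summarized by a normal fit and compared
# one-sided (lower tail: smaller observed radius = more cohesive than
# chance), with Bonferroni control over the patterns tested.

#' Permute labels within each structure
#'
#' Shuffles labels across point positions within every structure while
#' leaving coordinates, chains and sequence numbers untouched. In complex
#' mode, amino-acid labels shuffle only among protein points and base
#' labels only among DNA points. Deterministic given `seed`.
#'
#' @param dataset A `fresco_dataset`.
#' @param seed Integer seed.
#' @return A permuted `fresco_dataset` of the same shape.
#' @export
permute_labels <- function(dataset, seed) {
  mode <- dataset_mode(dataset)
  out <- withr::with_seed(as.integer(seed), {
    grp <- paste(dataset$structure_id, dataset$molecule_kind)
    lab <- dataset$label
    for (g in sort(unique(grp))) {
      i <- which(grp == g)
      if (length(i) > 1) lab[i] <- lab[i][sample.int(length(i))]
    }
    d <- dataset
    d$label <- lab
    d
  })
  fresco_dataset(out, mode = mode)
}

# per-round seed from a master seed: fixed counter scheme, kept inside
# 32-bit integer range (doubles hold the intermediate product exactly)
round_seed <- function(master, round) {
  as.integer((as.numeric(master) * 48271 + 7919 * as.numeric(round)) %%
               2147483646) + 1L
}

#' Background cohesive-radius distribution under label permutation
#'
#' For each permutation round, the dataset's labels are re-shuffled within
#' structures and the cohesive radius of every input pattern is recomputed
#' on the permuted data (support sets are recomputed too; they are
#' identical by the permutation invariant). Ten rounds are the default.
#'
#' @param dataset A `fresco_dataset`.
#' @param patterns List of character label vectors (or a
#'   `fresco_patterns` tibble).
#' @param n_perm Number of permutation rounds (at least 2).
#' @param seed Master seed; per-round seeds are derived by a fixed
#'   counter scheme.
#' @return A tibble with `pattern` and `background_Rs` (list-column of
#'   length-`n_perm` numeric vectors).
#' @export
background_distribution <- function(dataset, patterns, n_perm = 10, seed = 1) {
  if (n_perm < 2) abort("n_perm must be at least 2 (sd undefined otherwise)")
  if (inherits(patterns, "fresco_patterns")) patterns <- patterns$labels
  patterns <- lapply(patterns, function(p) sort(as.character(p)))
  bg <- matrix(NA_real_, nrow = length(patterns), ncol = n_perm)
  for (r in seq_len(n_perm)) {
    perm <- permute_labels(dataset, round_seed(seed, r))
    prep <- prep_structures(perm)
    stats <- pattern_stats_for(prep, patterns)
    bg[, r] <- vapply(stats$radii, function(x) {
      if (length(x) == 0) NA_real_ else mean(x)
    }, numeric(1))
  }
  tibble::tibble(
    pattern = vapply(patterns, paste, character(1), collapse = "-"),
    background_Rs = lapply(seq_along(patterns), function(i) bg[i, ])
  )
}

#' Normal-approximation p-value against a permutation background
#'
#' Fits mean and unbiased (n-1) standard deviation to the background
#' radii and returns the lower-tail normal probability of the observed
#' cohesive radius: small observed radius means more cohesive than
#' chance. A zero background sd degenerates to p = 1 when the observed
#' radius is at or above the mean and p = 0 below it.
#'
#' @param observed_R Observed cohesive radius (Angstrom).
#' @param background_Rs Numeric vector of background radii (length >= 2).
#' @return A list with `background_mean`, `background_sd`, `p_value`.
#' @export
pattern_pvalue <- function(observed_R, background_Rs) {
  if (length(background_Rs) < 2) abort("need at least 2 background values")
  if (!all(is.finite(c(observed_R, background_Rs)))) {
    abort("non-finite input to pattern_pvalue()")
  }
  mu <- mean(background_Rs)
  sigma <- sd(background_Rs)
  p <- if (sigma == 0) {
    if (observed_R >= mu) 1 else 0
  } else {
    pnorm((observed_R - mu) / sigma)
  }
  list(background_mean = mu, background_sd = sigma, p_value = p)
}

#' Bonferroni significance flags
#'
#' Flags a result significant iff its p-value is at most `alpha / m`,
#' where m is the number of patterns tested in this run.
#'
#' @param results Tibble with a `p_value` column.
#' @param alpha Family-wise error rate, in (0, 1).
#' @return `results` with a recomputed `significant` logical column.
#' @export
bonferroni_filter <- function(results, alpha = 0.01) {
  if (!(alpha > 0 && alpha < 1)) abort("alpha must be in (0, 1)")
  m <- nrow(results)
  if (m < 1) abort("no results to test")
  results$significant <- results$p_value <= alpha / m
  results
}

#' Permutation significance test for mined patterns
#'
#' Runs [background_distribution()] and [pattern_pvalue()] for every
#' mined pattern and applies the Bonferroni filter, pooled over all
#' patterns in the run.
#'
#' @param dataset The dataset the patterns were mined from.
#' @param mined A `fresco_patterns` tibble.
#' @param n_perm Number of permutation rounds (default 10).
#' @param alpha Family-wise error rate (default 0.01).
#' @param seed Master seed.
#' @return A tibble of class `fresco_significance`: `pattern`, `size`,
#'   `observed_R`, `background_mean`, `background_sd`, `p_value`,
#'   `significant`, plus `background_Rs` as a list-column.
#' @export
test_significance <- function(dataset, mined, n_perm = 10, alpha = 0.01,
                              seed = 1) {
  if (nrow(mined) == 0) {
    out <- tibble::tibble(pattern = character(), size = integer(),
                          observed_R = double(), background_mean = double(),
                          background_sd = double(), p_value = double(),
                          significant = logical(), background_Rs = list())
    class(out) <- c("fresco_significance", class(tibble::tibble()))
    return(out)
  }
  bg <- background_distribution(dataset, mined, n_perm = n_perm, seed = seed)
  fits <- purrr::map2(mined$cohesive_radius, bg$background_Rs, pattern_pvalue)
  out <- tibble::tibble(
    pattern = mined$pattern,
    size = mined$size,
    observed_R = mined$cohesive_radius,
    background_mean = vapply(fits, `[[`, numeric(1), "background_mean"),
    background_sd = vapply(fits, `[[`, numeric(1), "background_sd"),
    p_value = vapply(fits, `[[`, numeric(1), "p_value"),
    background_Rs = bg$background_Rs
  )
  out <- bonferroni_filter(out, alpha = alpha)
  out <- out[, c("pattern", "size", "observed_R", "background_mean",
                 "background_sd", "p_value", "significant", "background_Rs")]
  class(out) <- c("fresco_significance", class(tibble::tibble()))
  attr(out, "alpha") <- alpha
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

#' @export
print.fresco_significance <- function(x, ...) {
  cat(sprintf("# permutation significance: %d pattern(s), %d significant\n",
              nrow(x), sum(x$significant)))
  NextMethod()
}

#' @rdname export_patterns
#' @param sig A `fresco_significance` tibble.
#' @export
export_significance <- function(sig, path) {
  readr::write_tsv(tibble::tibble(
    pattern = sig$pattern, observed_R_A = sig$observed_R,
    bg_mean_A = sig$background_mean, bg_sd_A = sig$background_sd,
    p_value = sig$p_value, significant = sig$significant), path)
  invisible(path)
}
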