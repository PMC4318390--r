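# Downstream statistics on mined patterns: hypergeometric enrichment of
# best-match residues in conserved-domain intervals, structure-level GO
# enrichment of tight matches, a Spearman screen of per-structure radii
# against optimal growth temperature, and sequence-separation
# classification of matches.

#' Hypergeometric tail probabilities
#'
#' For X ~ Hypergeometric(N, K, n) (population N with K category members,
#' sample of n), returns the enrichment tail P(X >= k) and the depletion
#' tail P(X <= k). Vectorized over its arguments.
#'
#' @param k Observed overlap count.
#' @param n Sample size.
#' @param K Category size in the population.
#' @param N Population size.
#' @return A tibble with columns `p_enriched` and `p_depleted`.
#' @export
hypergeom_tails <- function(k, n, K, N) {
  bad <- k < 0 | k > n | n > N | K > N | K < 0 | k > K | (n - k) > (N - K)
  if (any(bad)) abort("inconsistent hypergeometric counts")
  tibble::tibble(
    p_enriched = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    p_depleted = phyper(k, K, N - K, n)
  )
}

#' Domain enrichment of best-match residues
#'
#' Tests, per pattern, whether the residues that form the best-match
#' enclosing balls fall inside conserved-domain intervals more or less
#' often than chance. The population is all protein residues of the
#' structures present in the domain table; the category is residues
#' inside any domain interval (each residue counted once even under
#' overlapping domains); the sample is the distinct best-match residues
#' of the pattern. Both hypergeometric tails are reported with Bonferroni
#' flags over the patterns tested.
#'
#' @param mined A `fresco_patterns` tibble.
#' @param domains Domain interval table (see [read_domains()]).
#' @param dataset The mined dataset.
#' @param alpha Family-wise error rate (default 0.01).
#' @return A tibble with one row per pattern: overlap counts, both tail
#'   p-values, and `enriched_significant` / `depleted_significant` flags.
#' @export
domain_enrichment <- function(mined, domains, dataset, alpha = 0.01) {
  annotated <- intersect(unique(dataset$structure_id),
                         unique(domains$structure_id))
  dropped <- setdiff(unique(dataset$structure_id), annotated)
  if (length(dropped) > 0) {
    inform(sprintf("%d structure(s) absent from the domain table excluded from the population",
                   length(dropped)))
  }
  if (length(annotated) == 0) abort("no structure is present in the domain table")
  pop <- dataset |>
    dplyr::filter(.data$structure_id %in% annotated,
                  .data$molecule_kind == "protein")
  in_domain <- function(ids, chains, pos) {
    out <- logical(length(ids))
    dom <- domains[domains$structure_id %in% unique(ids), , drop = FALSE]
    for (j in seq_len(nrow(dom))) {
      out <- out | (ids == dom$structure_id[j] & chains == dom$chain[j] &
                      pos >= dom$start[j] & pos <= dom$end[j])
    }
    out
  }
  pop_in <- in_domain(pop$structure_id, pop$chain_id, pop$seq_pos)
  N <- nrow(pop)
  K <- sum(pop_in)

  matches <- resolve_matches(mined, dataset)
  res <- purrr::map_dfr(mined$pattern, function(p) {
    m <- matches[matches$pattern == p & matches$structure_id %in% annotated, ,
                 drop = FALSE]
    m <- dplyr::distinct(m, .data$structure_id, .data$chain_id, .data$seq_pos)
    n <- nrow(m)
    k <- if (n == 0) 0L else sum(in_domain(m$structure_id, m$chain_id, m$seq_pos))
    tails <- hypergeom_tails(k, n, K, N)
    tibble::tibble(pattern = p, k_overlap = k, n_sample = n,
                   K_category = K, N_population = N,
                   p_enriched = tails$p_enriched,
                   p_depleted = tails$p_depleted)
  })
  m_tests <- nrow(res)
  res$enriched_significant <- res$p_enriched <= alpha / m_tests
  res$depleted_significant <- res$p_depleted <= alpha / m_tests
  res
}

#' GO-term enrichment of tightly matching structures
#'
#' Structure-level hypergeometric enrichment: a structure "has" a pattern
#' iff its best-match radius is strictly below `tight_radius` (3 Angstrom
#' by default), and only GO terms annotated to at least `min_structures`
#' structures are tested. The population is the structures carrying any
#' GO annotation.
#'
#' @inheritParams domain_enrichment
#' @param go GO annotation table (see [read_go()]).
#' @param tight_radius Strict upper bound on the best-match radius for a
#'   structure to count as having the pattern (Angstrom).
#' @param min_structures Minimum number of annotated structures for a GO
#'   term to be tested.
#' @return A tibble with one row per (pattern, GO term) tested.
#' @export
go_enrichment <- function(mined, go, dataset, tight_radius = 3.0,
                          min_structures = 10, alpha = 0.01) {
  population <- intersect(unique(dataset$structure_id),
                          unique(go$structure_id))
  if (length(population) == 0) abort("no structure carries a GO annotation")
  go <- go[go$structure_id %in% population, , drop = FALSE]
  term_counts <- go |>
    dplyr::distinct(.data$structure_id, .data$go_term) |>
    dplyr::count(.data$go_term)
  terms <- term_counts$go_term[term_counts$n >= min_structures]
  if (length(terms) == 0) {
    return(tibble::tibble(pattern = character(), go_term = character(),
                          k_overlap = integer(), n_sample = integer(),
                          K_category = integer(), N_population = integer(),
                          p_enriched = double(), p_depleted = double(),
                          enriched_significant = logical()))
  }
  N <- length(population)
  res <- purrr::map_dfr(seq_len(nrow(mined)), function(i) {
    m <- mined$matches[[i]]
    tight <- m$structure_id[m$radius < tight_radius]
    tight <- intersect(tight, population)
    purrr::map_dfr(terms, function(tm) {
      members <- unique(go$structure_id[go$go_term == tm])
      k <- length(intersect(tight, members))
      tails <- hypergeom_tails(k, length(tight), length(members), N)
      tibble::tibble(pattern = mined$pattern[i], go_term = tm,
                     k_overlap = k, n_sample = length(tight),
                     K_category = length(members), N_population = N,
                     p_enriched = tails$p_enriched,
                     p_depleted = tails$p_depleted)
    })
  })
  m_tests <- nrow(res)
  res$enriched_significant <- res$p_enriched <= alpha / m_tests
  res
}

#' Spearman screen of per-structure radii against growth temperature
#'
#' Correlates, per pattern, the best-match radius in each supporting
#' structure with the optimal growth temperature (OGT) of the source
#' organism. Structures with an OGT of exactly 37 degrees C are removed
#' first (pathogen bias). A positive correlation (tighter at low
#' temperature) is reported as direction `low_T`, a negative one (tighter
#' at high temperature) as `high_T`. Spearman rho uses average ranks for
#' ties; p-values come from the large-sample t approximation, with
#' Bonferroni control over the patterns tested.
#'
#' @inheritParams domain_enrichment
#' @param ogt OGT table (see [read_ogt()]).
#' @param filter_temp OGT value removed before correlating (exact
#'   equality; default 37).
#' @param min_n Minimum paired observations (below it the pattern is
#'   reported as NA).
#' @return A tibble of class `fresco_ogt` with one row per pattern:
#'   `n_structures`, `rho`, `p_value`, `significant`, `direction`.
#' @export
ogt_correlation <- function(mined, ogt, alpha = 0.01, filter_temp = 37,
                            min_n = 5) {
  ogt <- ogt[ogt$ogt_celsius != filter_temp, , drop = FALSE]
  res <- purrr::map_dfr(seq_len(nrow(mined)), function(i) {
    m <- mined$matches[[i]]
    j <- match(m$structure_id, ogt$structure_id)
    ok <- !is.na(j)
    r <- m$radius[ok]
    temp <- ogt$ogt_celsius[j[ok]]
    if (length(r) < min_n) {
      return(tibble::tibble(pattern = mined$pattern[i],
                            n_structures = length(r), rho = NA_real_,
                            p_value = NA_real_))
    }
    ct <- suppressWarnings(cor.test(r, temp, method = "spearman",
                                    exact = FALSE))
    tibble::tibble(pattern = mined$pattern[i], n_structures = length(r),
                   rho = unname(ct$estimate), p_value = ct$p.value)
  })
  m_tests <- sum(!is.na(res$p_value))
  res$significant <- !is.na(res$p_value) & res$p_value <= alpha / max(m_tests, 1)
  res$direction <- dplyr::case_when(
    res$significant & res$rho > 0 ~ "low_T",
    res$significant & res$rho < 0 ~ "high_T",
    .default = "none"
  )
  class(res) <- c("fresco_ogt", class(tibble::tibble()))
  res
}

#' Sequence separation of best-match residues
#'
#' For every (pattern, structure) best match, computes the pairwise
#' sequence-position separations of same-chain residue pairs and
#' classifies the aggregate: below 6 residues is short-range, above 10 is
#' long-range, in between is intermediate; any cross-chain pair makes the
#' match cross_chain. Singleton matches have no separation (NA).
#'
#' @inheritParams domain_enrichment
#' @param aggregate `"mean"` (default) or `"max"` over the pairwise
#'   separations.
#' @return A tibble with one row per (pattern, structure):
#'   `separation` and `class`.
#' @export
sequence_separation <- function(mined, dataset,
                                aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  matches <- resolve_matches(mined, dataset)
  agg_fun <- if (aggregate == "mean") mean else max
  matches |>
    dplyr::group_by(.data$pattern, .data$structure_id) |>
    dplyr::summarise(
      separation = {
        if (dplyr::n() < 2) NA_real_ else {
          pr <- combn(dplyr::n(), 2)
          same <- .data$chain_id[pr[1, ]] == .data$chain_id[pr[2, ]]
          if (!any(same)) NA_real_ else {
            agg_fun(abs(.data$seq_pos[pr[1, same]] - .data$seq_pos[pr[2, same]]))
          }
        }
      },
      class = {
        if (dplyr::n() < 2) NA_character_
        else if (length(unique(.data$chain_id)) > 1) "cross_chain"
        else {
          pr <- combn(dplyr::n(), 2)
          s <- agg_fun(abs(.data$seq_pos[pr[1, ]] - .data$seq_pos[pr[2, ]]))
          if (s < 6) "short_range" else if (s > 10) "long_range" else "intermediate"
        }
      },
      .groups = "drop"
    )
}
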