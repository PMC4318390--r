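# Level-wise Apriori-style mining of frequent spatially cohesive label
# sets. A pattern X (a set of distinct labels) is scored by
#   support S(X)  = |N(X)| / |D|, N(X) = structures containing every label,
#   cohesive radius R(X) = mean over N(X) of the per-structure best-match
#   radius R_g (minimum enclosing-ball radius over combinations).
# Support pruning is exact (anti-monotone); the radius threshold is a
# report filter, not a search prune, unless the lossy prune is enabled.

#' Mining configuration
#'
#' Thresholds for [mine_frescos()]. Protein-mode defaults are a minimum
#' support of 0.60 and a maximum cohesive radius of 4.5 Angstrom (the
#' C-alpha distance of typically interacting residues); complex mode uses
#' 0.70 and 7 Angstrom (patterns must bridge two macromolecules) and
#' additionally keeps only patterns with at least one base and at least
#' one amino-acid label.
#'
#' @param mode `"protein"` or `"complex"`.
#' @param min_support Minimum support, in (0, 1]. Inclusive (`>=`).
#' @param max_radius Maximum cohesive radius in Angstrom. Inclusive (`<=`).
#' @param max_pattern_size Largest pattern size explored.
#' @param report_singletons Include size-1 patterns in the report? They
#'   are always computed internally (candidate generation needs them) but
#'   have radius 0 by definition.
#' @param radius_prune Enable the lossy lattice prune: patterns whose
#'   cohesive radius exceeds `radius_prune_slack * max_radius` are not
#'   extended. Off by default because the cohesive radius (an average
#'   over a shrinking support set) is not anti-monotone.
#' @param radius_prune_slack Slack multiplier for the lossy prune.
#' @return A list of class `fresco_config`.
#' @export
mining_config <- function(mode = c("protein", "complex"),
                          min_support = NULL, max_radius = NULL,
                          max_pattern_size = 4,
                          report_singletons = FALSE,
                          radius_prune = FALSE,
                          radius_prune_slack = 2.0) {
  mode <- match.arg(mode)
  if (is.null(min_support)) min_support <- if (mode == "protein") 0.60 else 0.70
  if (is.null(max_radius)) max_radius <- if (mode == "protein") 4.5 else 7.0
  if (!(min_support > 0 && min_support <= 1)) abort("min_support must be in (0, 1]")
  if (!(max_radius > 0)) abort("max_radius must be positive")
  if (max_pattern_size < 1) abort("max_pattern_size must be >= 1")
  structure(list(mode = mode, min_support = min_support,
                 max_radius = max_radius,
                 max_pattern_size = as.integer(max_pattern_size),
                 report_singletons = report_singletons,
                 radius_prune = radius_prune,
                 radius_prune_slack = radius_prune_slack),
            class = "fresco_config")
}

#' @export
print.fresco_config <- function(x, ...) {
  cat(sprintf(paste0("<mining config> mode %s: support >= %.2f, ",
                     "cohesive radius <= %.1f A, size <= %d\n"),
              x$mode, x$min_support, x$max_radius, x$max_pattern_size))
  invisible(x)
}

# internal: structure-indexed representation reused across permutations
prep_structures <- function(dataset) {
  ids <- sort(unique(dataset$structure_id))
  alphabet <- sort(unique(dataset$label))
  split_rows <- split(seq_len(nrow(dataset)), dataset$structure_id)
  coords <- lapply(ids, function(id) {
    as_coord_matrix(dataset[split_rows[[id]], , drop = FALSE])
  })
  labels <- lapply(ids, function(id) {
    match(dataset$label[split_rows[[id]]], alphabet)
  })
  presence <- matrix(FALSE, length(ids), length(alphabet),
                     dimnames = list(ids, alphabet))
  for (i in seq_along(ids)) presence[i, unique(labels[[i]])] <- TRUE
  list(ids = ids, alphabet = alphabet, coords = coords, labels = labels,
       presence = presence, rows = split_rows)
}

pattern_key <- function(labels) paste(sort(labels), collapse = "-")

#' Support of a pattern
#'
#' A structure supports a pattern iff every label of the pattern occurs at
#' least once in it. Support is the supporting fraction of the dataset.
#'
#' @param dataset A `fresco_dataset`.
#' @param pattern Character vector of distinct labels.
#' @return A list with `support` (numeric in \[0, 1\]) and
#'   `supporting_ids` (character vector of structure IDs).
#' @export
compute_support <- function(dataset, pattern) {
  pattern <- sort(unique(as.character(pattern)))
  pres <- dataset |>
    dplyr::distinct(.data$structure_id, .data$label) |>
    dplyr::filter(.data$label %in% pattern) |>
    dplyr::count(.data$structure_id)
  ids <- sort(pres$structure_id[pres$n == length(pattern)])
  n_total <- length(unique(dataset$structure_id))
  list(support = length(ids) / n_total, supporting_ids = ids)
}

#' Cohesive radius of a pattern
#'
#' The arithmetic mean, over the supporting structures only, of the
#' per-structure best-match radius R_g.
#'
#' @inheritParams compute_support
#' @param supporting_ids The exact support set of the pattern (as from
#'   [compute_support()]).
#' @return A list with `cohesive_radius` (NA if the support set is empty)
#'   and `per_structure_radius` (named numeric vector over
#'   `supporting_ids`).
#' @export
compute_cohesive_radius <- function(dataset, pattern, supporting_ids = NULL) {
  pattern <- sort(unique(as.character(pattern)))
  if (is.null(supporting_ids)) {
    supporting_ids <- compute_support(dataset, pattern)$supporting_ids
  }
  if (length(supporting_ids) == 0) {
    return(list(cohesive_radius = NA_real_,
                per_structure_radius = setNames(double(0), character(0))))
  }
  radii <- vapply(supporting_ids, function(id) {
    bm <- best_match(dataset[dataset$structure_id == id, , drop = FALSE], pattern)
    if (is.null(bm)) NA_real_ else bm$radius
  }, numeric(1))
  list(cohesive_radius = mean(radii), per_structure_radius = radii)
}

#' Apriori candidate generation
#'
#' Classic join-and-prune: a (k+1)-set is a candidate iff all of its
#' k-subsets are frequent.
#'
#' @param frequent_k List of character vectors, all of identical size k
#'   (each a frequent pattern's label set).
#' @return List of candidate (k+1)-label sets, canonically sorted and
#'   duplicate-free.
#' @export
generate_candidates <- function(frequent_k) {
  if (length(frequent_k) < 2) return(list())
  sets <- lapply(frequent_k, function(x) sort(as.character(x)))
  k <- unique(lengths(sets))
  if (length(k) != 1) abort("all input patterns must have identical size")
  keys <- vapply(sets, paste, character(1), collapse = "-")
  sets <- sets[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  key_set <- new.env(parent = emptyenv())
  for (key in keys) assign(key, TRUE, envir = key_set)
  cands <- list()
  ord <- order(keys)
  sets <- sets[ord]
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (j <= i) next
      a <- sets[[i]]; b <- sets[[j]]
      # join: identical first k-1 labels
      if (k > 1 && !identical(a[-k], b[-k])) next
      cand <- sort(union(a, b))
      if (length(cand) != k + 1) next
      ok <- all(vapply(seq_along(cand), function(drop_i) {
        exists(paste(cand[-drop_i], collapse = "-"), envir = key_set)
      }, logical(1)))
      if (ok) cands[[length(cands) + 1]] <- cand
    }
  }
  if (length(cands) == 0) return(list())
  ckeys <- vapply(cands, paste, character(1), collapse = "-")
  cands <- cands[!duplicated(ckeys)]
  cands[order(vapply(cands, paste, character(1), collapse = "-"))]
}

# internal: per-pattern support sets and per-structure radii for a list of
# patterns, given prepped structures
pattern_stats_for <- function(prep, patterns, exhaustive_limit = 5000) {
  n_struct <- length(prep$ids)
  pat_codes <- lapply(patterns, function(p) match(p, prep$alphabet))
  supported <- lapply(seq_along(patterns), function(pi) {
    codes <- pat_codes[[pi]]
    if (anyNA(codes)) return(integer(0))
    which(rowSums(prep$presence[, codes, drop = FALSE]) == length(codes))
  })
  radii <- vector("list", length(patterns))
  match_idx <- vector("list", length(patterns))
  for (pi in seq_along(patterns)) {
    radii[[pi]] <- setNames(rep(NA_real_, length(supported[[pi]])),
                            prep$ids[supported[[pi]]])
    match_idx[[pi]] <- vector("list", length(supported[[pi]]))
  }
  # group by structure so the C++ batch call runs once per structure
  by_struct <- vector("list", n_struct)
  for (pi in seq_along(patterns)) {
    for (s in supported[[pi]]) by_struct[[s]] <- c(by_struct[[s]], pi)
  }
  for (s in seq_len(n_struct)) {
    pis <- by_struct[[s]]
    if (length(pis) == 0) next
    res <- .cpp_pattern_radii(prep$coords[[s]], prep$labels[[s]],
                              pat_codes[pis], exhaustive_limit)
    for (q in seq_along(pis)) {
      pi <- pis[q]
      pos <- match(s, supported[[pi]])
      radii[[pi]][pos] <- res$radii[q]
      match_idx[[pi]][[pos]] <- res$indices[[q]]
    }
  }
  list(supported = supported, radii = radii, match_idx = match_idx)
}

#' Mine frequent spatially cohesive patterns
#'
#' Level-wise Apriori search over label sets: exact support pruning,
#' best-match radii per supporting structure, cohesive radius averaging,
#' then report filtering by `max_radius` (and, in complex mode, the
#' at-least-one-base and at-least-one-amino-acid filter).
#'
#' @param dataset A `fresco_dataset`.
#' @param config A [mining_config()]; defaults to the mode-appropriate
#'   configuration for the dataset.
#' @return A tibble of class `fresco_patterns` with one row per reported
#'   pattern: `pattern` (labels joined by `-`), `labels` (list), `size`,
#'   `support`, `n_supporting`, `cohesive_radius`, and `matches`, a
#'   list-column of per-structure tibbles (`structure_id`, `radius`,
#'   `idx`: chosen point rows within the structure, ordered by the sorted
#'   pattern labels). Rows are sorted by size then pattern.
#' @export
mine_frescos <- function(dataset, config = NULL) {
  if (is.null(config)) config <- mining_config(mode = dataset_mode(dataset))
  prep <- prep_structures(dataset)
  n_struct <- length(prep$ids)
  if (n_struct == 0) abort("empty dataset")

  min_count <- config$min_support * n_struct
  # level 1
  sup1 <- colSums(prep$presence)
  freq <- lapply(prep$alphabet[sup1 >= min_count - 1e-9], function(l) l)
  levels_out <- list()
  current <- freq
  k <- 1
  while (length(current) > 0 && k <= config$max_pattern_size) {
    stats <- pattern_stats_for(prep, current)
    supports <- vapply(stats$supported, length, integer(1)) / n_struct
    keep <- supports >= config$min_support - 1e-12
    current <- current[keep]
    stats <- list(supported = stats$supported[keep],
                  radii = stats$radii[keep],
                  match_idx = stats$match_idx[keep])
    if (length(current) > 0) {
      lev <- tibble::tibble(
        labels = current,
        size = k,
        support = vapply(stats$supported, length, integer(1)) / n_struct,
        n_supporting = vapply(stats$supported, length, integer(1)),
        cohesive_radius = vapply(stats$radii, mean, numeric(1)),
        matches = purrr::pmap(
          list(stats$supported, stats$radii, stats$match_idx),
          function(sup, rad, mi) {
            tibble::tibble(structure_id = prep$ids[sup],
                           radius = unname(rad), idx = mi)
          })
      )
      levels_out[[k]] <- lev
      expand <- current
      if (config$radius_prune && k >= 2) {
        ok <- lev$cohesive_radius <= config$radius_prune_slack * config$max_radius
        expand <- expand[ok]
      }
      current <- generate_candidates(expand)
    }
    k <- k + 1
  }
  out <- dplyr::bind_rows(levels_out)
  if (nrow(out) == 0) {
    out <- tibble::tibble(labels = list(), size = integer(), support = double(),
                          n_supporting = integer(), cohesive_radius = double(),
                          matches = list())
  }
  out$pattern <- vapply(out$labels, paste, character(1), collapse = "-")
  out <- out[, c("pattern", "labels", "size", "support", "n_supporting",
                 "cohesive_radius", "matches")]

  # report filters
  keep <- out$cohesive_radius <= config$max_radius + 1e-12 | out$size == 1
  if (!config$report_singletons) keep <- keep & out$size >= 2
  if (config$mode == "complex") {
    has_base <- vapply(out$labels, function(l) any(l %in% DNA_BASES), logical(1))
    has_aa <- vapply(out$labels, function(l) any(l %in% AA3), logical(1))
    keep <- keep & has_base & has_aa
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$size, out$pattern), , drop = FALSE]
  class(out) <- c("fresco_patterns", class(tibble::tibble()))
  attr(out, "config") <- config
  attr(out, "structure_ids") <- prep$ids
  attr(out, "n_structures") <- n_struct
  out
}

#' Score explicit patterns without mining
#'
#' Computes support, per-structure best matches and the cohesive radius
#' for a given list of patterns, with no thresholding or filtering.
#'
#' @param dataset A `fresco_dataset`.
#' @param patterns A list of character label vectors (or a single one).
#' @return A `fresco_patterns` tibble, one row per input pattern (in
#'   canonical order). Patterns with empty support have `NaN` cohesive
#'   radius.
#' @export
pattern_stats <- function(dataset, patterns) {
  if (is.character(patterns)) patterns <- list(patterns)
  patterns <- lapply(patterns, function(p) sort(unique(as.character(p))))
  prep <- prep_structures(dataset)
  n_struct <- length(prep$ids)
  stats <- pattern_stats_for(prep, patterns)
  out <- tibble::tibble(
    pattern = vapply(patterns, paste, character(1), collapse = "-"),
    labels = patterns,
    size = lengths(patterns),
    support = vapply(stats$supported, length, integer(1)) / n_struct,
    n_supporting = vapply(stats$supported, length, integer(1)),
    cohesive_radius = vapply(stats$radii, function(x) {
      if (length(x) == 0) NaN else mean(x)
    }, numeric(1)),
    matches = purrr::pmap(
      list(stats$supported, stats$radii, stats$match_idx),
      function(sup, rad, mi) {
        tibble::tibble(structure_id = prep$ids[sup], radius = unname(rad),
                       idx = mi)
      })
  )
  class(out) <- c("fresco_patterns", class(tibble::tibble()))
  attr(out, "structure_ids") <- prep$ids
  attr(out, "n_structures") <- n_struct
  out
}

#' @export
print.fresco_patterns <- function(x, ...) {
  cat(sprintf("# FreSCO patterns: %d pattern(s) over %d structure(s)\n",
              nrow(x), attr(x, "n_structures") %||% NA_integer_))
  NextMethod()
}

#' Export mined patterns as TSV / JSON
#'
#' `export_patterns()` writes one row per pattern (labels joined by `-`,
#' size, support, supporting count, cohesive radius). `export_matches()`
#' writes one row per matched residue of each pattern's best match.
#' `export_patterns_json()` serializes the full per-structure statistics.
#'
#' @param mined A `fresco_patterns` tibble.
#' @param path Output file path.
#' @param dataset The dataset the patterns were mined from (needed to
#'   resolve match rows to chain/sequence positions).
#' @return `path`, invisibly.
#' @export
export_patterns <- function(mined, path) {
  readr::write_tsv(tibble::tibble(
    pattern = mined$pattern, size = mined$size, support = mined$support,
    n_supporting = mined$n_supporting,
    cohesive_radius_A = mined$cohesive_radius), path)
  invisible(path)
}

#' @rdname export_patterns
#' @export
export_matches <- function(mined, dataset, path) {
  readr::write_tsv(resolve_matches(mined, dataset), path)
  invisible(path)
}

#' @rdname export_patterns
#' @export
export_patterns_json <- function(mined, path) {
  payload <- purrr::pmap(
    list(mined$pattern, mined$support, mined$cohesive_radius, mined$matches),
    function(p, s, r, m) {
      list(pattern = p, support = s, cohesive_radius_A = r,
           per_structure = list(structure_id = m$structure_id,
                                radius_A = m$radius))
    })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Resolve best-match point rows to residue positions
#'
#' @inheritParams export_patterns
#' @return A tibble with one row per (pattern, structure, matched label):
#'   `pattern`, `structure_id`, `match_radius_A`, `label`, `chain_id`,
#'   `seq_pos`.
#' @export
resolve_matches <- function(mined, dataset) {
  rows_by_id <- split(seq_len(nrow(dataset)), dataset$structure_id)
  purrr::pmap_dfr(
    list(mined$pattern, mined$labels, mined$matches),
    function(p, labs, m) {
      purrr::pmap_dfr(list(m$structure_id, m$radius, m$idx),
                      function(id, r, idx) {
        pts <- dataset[rows_by_id[[id]][idx], , drop = FALSE]
        tibble::tibble(pattern = p, structure_id = id, match_radius_A = r,
                       label = sort(labs), chain_id = pts$chain_id,
                       seq_pos = pts$seq_pos)
      })
    })
}
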