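# Exact 3D geometry: smallest enclosing ball and the best-match search
# (minimum-radius combination of one occurrence per pattern label within
# one structure). The kernels live in src/geometry.cpp.

#' Exact smallest enclosing ball of a 3D point set
#'
#' Computes the unique minimum-radius ball containing all input points
#' with a Welzl-style move-to-front algorithm (exact, expected linear
#' time). The internal randomized point order uses a fixed seed, so the
#' result is deterministic for a given input.
#'
#' @param points Numeric matrix with 3 columns (x, y, z), or a point
#'   tibble with `x`, `y`, `z` columns. At least one point.
#' @return A list of class `fresco_ball` with elements `center` (length-3
#'   numeric) and `radius`.
#' @export
#' @examples
#' min_enclosing_ball(rbind(c(0, 0, 0), c(2, 0, 0)))
min_enclosing_ball <- function(points) {
  m <- as_coord_matrix(points)
  if (nrow(m) < 1) abort("minimum enclosing ball needs at least one point")
  if (!all(is.finite(m))) abort("non-finite coordinates")
  res <- .cpp_meb(m)
  structure(list(center = res$center, radius = res$radius),
            class = "fresco_ball")
}

#' @export
print.fresco_ball <- function(x, ...) {
  cat(sprintf("<ball> center (%.3f, %.3f, %.3f), radius %.4f A\n",
              x$center[1], x$center[2], x$center[3], x$radius))
  invisible(x)
}

as_coord_matrix <- function(points) {
  if (is.data.frame(points)) {
    m <- cbind(points$x, points$y, points$z)
  } else {
    m <- as.matrix(points)
  }
  if (ncol(m) != 3) abort("points must have 3 coordinate columns")
  storage.mode(m) <- "double"
  m
}

#' Best-matching residue combination for a pattern within one structure
#'
#' Finds the global minimum, over all combinations picking one occurrence
#' of each pattern label, of the smallest-enclosing-ball radius (the
#' per-structure radius R_g). Exhaustive enumeration is used whenever the
#' product of occurrence counts is at most `exhaustive_limit`; larger
#' instances use a branch-and-bound search anchored on the rarest label
#' (ties broken lexicographically) that provably returns the same optimum.
#'
#' @param structure Point tibble for one structure.
#' @param pattern Character vector of distinct labels.
#' @param exhaustive_limit Combination-count threshold below which plain
#'   enumeration is used.
#' @return `NULL` when some pattern label has no occurrence (with a
#'   warning if the label is absent); otherwise a list of class
#'   `fresco_best_match` with `radius`, `ball`, and `matched`, a tibble of
#'   the chosen points (`label`, `chain_id`, `seq_pos`, `idx` = row in
#'   `structure`).
#' @export
best_match <- function(structure, pattern, exhaustive_limit = 5000) {
  pattern <- sort(unique(as.character(pattern)))
  missing_lab <- setdiff(pattern, structure$label)
  if (length(missing_lab) > 0) {
    warn(sprintf("pattern label(s) absent from structure: %s",
                 paste(missing_lab, collapse = ", ")))
    return(NULL)
  }
  codes <- sort(unique(structure$label))
  res <- .cpp_best_match(as_coord_matrix(structure),
                         match(structure$label, codes),
                         match(pattern, codes),
                         exhaustive_limit)
  if (is.na(res$radius)) return(NULL)
  idx <- res$indices
  structure2 <- structure[idx, , drop = FALSE]
  structure(list(
    radius = res$radius,
    ball = structure(list(center = res$center, radius = res$radius),
                     class = "fresco_ball"),
    matched = tibble::tibble(label = pattern,
                             chain_id = structure2$chain_id,
                             seq_pos = structure2$seq_pos,
                             idx = idx)
  ), class = "fresco_best_match")
}

#' @export
print.fresco_best_match <- function(x, ...) {
  cat(sprintf("<best match> radius %.4f A over %d label(s)\n",
              x$radius, nrow(x$matched)))
  print(x$matched)
  invisible(x)
}

#' Per-label spatial index over one structure
#'
#' Splits the structure's coordinates by label so that radius queries
#' ("all points with label `a` within distance `r` of point `p`") can be
#' answered exactly. Queries return exactly the brute-force answer.
#'
#' @param structure Point tibble for one structure (at least one point).
#' @return An object of class `fresco_spatial_index`.
#' @export
build_spatial_index <- function(structure) {
  if (nrow(structure) < 1) abort("cannot index an empty structure")
  m <- as_coord_matrix(structure)
  idx_by_label <- split(seq_len(nrow(m)), structure$label)
  structure(list(coords = m, by_label = idx_by_label,
                 structure = structure),
            class = "fresco_spatial_index")
}

#' @rdname build_spatial_index
#' @param index A `fresco_spatial_index`.
#' @param label Label whose occurrences are queried.
#' @param point Length-3 numeric query center.
#' @param r Query radius (Angstrom; may be `Inf`).
#' @return `query_radius()` returns the matching rows of the indexed
#'   structure, with a `distance` column, ordered by distance.
#' @export
query_radius <- function(index, label, point, r) {
  stopifnot(inherits(index, "fresco_spatial_index"), length(point) == 3)
  rows <- index$by_label[[label]]
  if (is.null(rows)) {
    out <- index$structure[0, , drop = FALSE]
    out$distance <- double(0)
    return(out)
  }
  d <- sqrt(colSums((t(index$coords[rows, , drop = FALSE]) - point)^2))
  keep <- which(d <= r)
  keep <- keep[order(d[keep])]
  out <- index$structure[rows[keep], , drop = FALSE]
  out$distance <- d[keep]
  out
}
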