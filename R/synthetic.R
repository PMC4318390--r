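# Synthetic PDB-like fixtures: uniform-box point clouds with a hard-core
# minimum separation (3.8 A, the C-alpha virtual-bond scale), controlled
# label composition, plantable cohesive motifs, and plantable
# radius-temperature effects. The generator emulates exchangeable labels
# over fixed coordinates -- exactly the regime the permutation null
# assumes -- not polymer chain geometry.

#' Specification for a synthetic structure dataset
#'
#' @param n_structures Number of structures.
#' @param n_points Points (residues) per structure.
#' @param composition Named numeric vector of label frequencies (sums to
#'   1). Default: uniform over the 20 amino acids.
#' @param planted_motifs List of motifs, each a list with `labels`
#'   (character), `radius` (Angstrom), `fraction` (of structures planted)
#'   and optionally `seq_offsets` (sequence offsets of the planted
#'   residues relative to a random anchor).
#' @param box_size Cube edge in Angstrom. Default: derived from realistic
#'   protein packing density, `(n_points * 135)^(1/3)` (about 135 cubic
#'   Angstrom per residue).
#' @param min_separation Hard-core minimum distance between points
#'   (default 3.8 A).
#' @param seed Master seed; all generation is deterministic given it.
#' @param ogt_effect Optional list with `labels`, `sign` (+1: radius grows
#'   with temperature; -1: shrinks) and optionally `radius_range`
#'   (default `c(0.5, 3)`) for temperature fixtures.
#' @return A list of class `fresco_synthetic_spec`.
#' @export
synthetic_spec <- function(n_structures = 30, n_points = 80,
                           composition = NULL, planted_motifs = list(),
                           box_size = NULL, min_separation = 3.8,
                           seed = 1, ogt_effect = NULL) {
  if (is.null(composition)) {
    composition <- setNames(rep(1 / 20, 20), AA3)
  }
  if (abs(sum(composition) - 1) > 1e-9 || any(composition < 0)) {
    abort("composition frequencies must be nonnegative and sum to 1")
  }
  if (!all(names(composition) %in% c(AA3, DNA_BASES))) {
    abort("composition labels must come from the amino-acid/base alphabet")
  }
  if (is.null(box_size)) box_size <- (n_points * 135)^(1 / 3)
  if (min_separation <= 0) abort("min_separation must be positive")
  for (m in planted_motifs) {
    if (m$radius >= box_size) abort("plant radius must be below box_size")
  }
  structure(list(n_structures = as.integer(n_structures),
                 n_points = as.integer(n_points),
                 composition = composition,
                 planted_motifs = planted_motifs,
                 box_size = box_size, min_separation = min_separation,
                 seed = as.integer(seed), ogt_effect = ogt_effect),
            class = "fresco_synthetic_spec")
}

# hard-core rejection sampling in the box
sample_box_points <- function(n, box, min_sep, max_tries = 400) {
  pts <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- stats::runif(3, 0, box)
      if (i == 1 ||
          min(colSums((t(pts[seq_len(i - 1), , drop = FALSE]) - cand)^2)) >=
            min_sep^2) {
        pts[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("packing infeasible: too many points for the box")
  }
  pts
}

#' Generate one synthetic structure
#'
#' Coordinates are drawn uniformly in the box under the hard-core
#' separation; labels are drawn independently from the composition;
#' sequence positions are sequential (protein points on chain A, base
#' points on chain B). Deterministic given `(spec$seed, index)`.
#'
#' @param spec A [synthetic_spec()].
#' @param index Structure index (1-based), also used in the structure ID.
#' @return A point tibble.
#' @export
generate_structure <- function(spec, index) {
  withr::with_seed(round_seed(spec$seed, 100000 + index), {
    pts <- sample_box_points(spec$n_points, spec$box_size, spec$min_separation)
    labels <- sample(names(spec$composition), spec$n_points, replace = TRUE,
                     prob = spec$composition)
    kind <- ifelse(labels %in% DNA_BASES, "dna", "protein")
    chain <- ifelse(kind == "protein", "A", "B")
    seq_pos <- integer(spec$n_points)
    seq_pos[kind == "protein"] <- seq_len(sum(kind == "protein"))
    seq_pos[kind == "dna"] <- seq_len(sum(kind == "dna"))
    tibble::tibble(structure_id = sprintf("SYN%04d", index),
                   chain_id = chain, seq_pos = seq_pos,
                   molecule_kind = kind, label = labels,
                   x = pts[, 1], y = pts[, 2], z = pts[, 3])
  })
}

# k points with enclosing-ball radius exactly r (regular simplex scaled to
# circumradius r), randomly rotated about a center
simplex_points <- function(k, r, center) {
  if (k == 1) return(matrix(center, 1, 3))
  base <- switch(as.character(min(k, 4)),
    "2" = rbind(c(-1, 0, 0), c(1, 0, 0)),
    "3" = rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0)),
    "4" = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3))
  if (k > 4) {
    extra <- matrix(stats::rnorm(3 * (k - 4)), ncol = 3)
    extra <- extra / sqrt(rowSums(extra^2)) * 0.9
    base <- rbind(base, extra)
  }
  # random rotation via QR of a Gaussian matrix
  qr_m <- qr(matrix(stats::rnorm(9), 3, 3))
  rot <- qr.Q(qr_m)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  sweep(base %*% t(rot) * r, 2, center, `+`)
}

#' Plant a cohesive motif into a structure
#'
#' Relabels one point per motif label and moves the chosen points inside
#' a ball of radius `plant_radius`, so that afterwards
#' `best_match(structure, labels)$radius <= plant_radius`. The full
#' `min_separation` is kept between motif points and the rest of the
#' structure; among the motif points themselves the separation floor is
#' `min(min_separation, plant_radius)` (a ball of radius r cannot hold
#' three points pairwise further apart than r*sqrt(3)).
#'
#' @param structure Point tibble for one structure.
#' @param labels Character vector of motif labels (the pattern).
#' @param plant_radius Target enclosing-ball radius (Angstrom).
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param seq_offsets Optional integer offsets: the planted points are
#'   those at sequence positions `anchor + seq_offsets` on chain A, so
#'   the sequence separations of the motif are controlled exactly.
#' @param min_separation Hard-core distance to non-motif points.
#' @param exact_radius Place the motif as a regular simplex with
#'   enclosing-ball radius exactly `plant_radius` (used by the
#'   temperature fixtures); otherwise points are sampled inside the ball.
#' @return The modified point tibble.
#' @export
plant_motif <- function(structure, labels, plant_radius, seed = NULL,
                        seq_offsets = NULL, min_separation = 3.8,
                        exact_radius = FALSE) {
  labels <- sort(as.character(labels))
  k <- length(labels)
  if (k > nrow(structure)) abort("motif larger than the structure")
  run <- function() {
    coords <- as_coord_matrix(structure)
    lo <- apply(coords, 2, min)
    hi <- apply(coords, 2, max)
    # rows to relabel
    if (!is.null(seq_offsets)) {
      if (length(seq_offsets) != k) abort("need one seq offset per motif label")
      prot <- which(structure$molecule_kind == "protein" &
                      structure$chain_id == structure$chain_id[1])
      anchors <- structure$seq_pos[prot]
      ok_anchor <- anchors[vapply(anchors, function(a) {
        all((a + seq_offsets) %in% anchors)
      }, logical(1))]
      if (length(ok_anchor) == 0) abort("no anchor admits the requested offsets")
      anchor <- sample(ok_anchor, 1)
      rows <- prot[match(anchor + seq_offsets, anchors)]
    } else {
      rows <- sample(nrow(structure), k)
    }
    floor_sep <- if (k > 1) min(min_separation, plant_radius) else 0
    margin <- max(plant_radius, 1)
    center <- stats::runif(3, pmin(lo + margin, hi), pmax(hi - margin, lo))

    # points inside the motif ball (and to one full hard-core shell around
    # it) are cleared out and relocated: every kept point is then farther
    # than min_separation from any motif point by construction
    d2c <- sqrt(colSums((t(coords) - center)^2))
    displaced <- setdiff(which(d2c <= plant_radius + min_separation), rows)

    place <- NULL
    if (k == 1) place <- matrix(center, 1, 3)
    if (is.null(place) && !exact_radius) {
      for (try in seq_len(300)) {
        u <- matrix(stats::rnorm(3 * k), k, 3)
        u <- u / sqrt(rowSums(u^2)) * plant_radius * stats::runif(k)^(1 / 3)
        cand <- sweep(u, 2, center, `+`)
        if (min(stats::dist(cand)) >= floor_sep * 0.999) {
          place <- cand
          break
        }
      }
    }
    # the regular simplex attains the exact radius and a pairwise
    # separation of at least the radius itself
    if (is.null(place)) place <- simplex_points(k, plant_radius, center)

    coords[rows, ] <- place
    # relocate the displaced points anywhere in the bounding box under the
    # full hard-core constraint
    for (i in displaced) {
      ok <- FALSE
      for (try in seq_len(400)) {
        cand <- stats::runif(3, lo, hi)
        if (min(colSums((t(coords[-i, , drop = FALSE]) - cand)^2)) >=
              min_separation^2) {
          coords[i, ] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) abort("cannot relocate displaced points: box too crowded")
    }
    structure$label[rows] <- labels
    structure$molecule_kind[rows] <- ifelse(labels %in% DNA_BASES, "dna", "protein")
    structure$x <- coords[, 1]
    structure$y <- coords[, 2]
    structure$z <- coords[, 3]
    structure
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Generate a full synthetic dataset
#'
#' Generates `n_structures` structures and plants each motif of the spec
#' into a random subset of them (`fraction` of the structures).
#' Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A `fresco_dataset` (complex mode iff the composition or a
#'   motif contains base labels).
#' @export
generate_dataset <- function(spec) {
  structures <- lapply(seq_len(spec$n_structures), generate_structure,
                       spec = spec)
  withr::with_seed(round_seed(spec$seed, 999), {
    for (m in spec$planted_motifs) {
      n_plant <- round(m$fraction * spec$n_structures)
      chosen <- sample(spec$n_structures, n_plant)
      for (s in chosen) {
        structures[[s]] <- plant_motif(structures[[s]], m$labels, m$radius,
                                       seq_offsets = m$seq_offsets,
                                       min_separation = spec$min_separation)
      }
    }
    pts <- dplyr::bind_rows(structures)
    has_dna <- any(pts$molecule_kind == "dna")
    fresco_dataset(pts, mode = if (has_dna) "complex" else "protein")
  })
}

#' Generate a temperature fixture with a planted radius-OGT effect
#'
#' Draws an optimal growth temperature per structure uniformly in
#' \[15, 95\] degrees C, excluding 37 +/- 0.5 by construction, and plants
#' the effect pattern in every structure with an enclosing-ball radius
#' that maps linearly (and exactly, via simplex placement) onto the
#' temperature with the requested sign. A Spearman screen of the planted
#' pattern must therefore recover that sign.
#'
#' @param spec A [synthetic_spec()] with `ogt_effect` set.
#' @return A list with `dataset` (a `fresco_dataset`) and `ogt` (a tibble
#'   `structure_id` / `ogt_celsius`).
#' @export
generate_ogt_fixture <- function(spec) {
  eff <- spec$ogt_effect
  if (is.null(eff)) abort("spec$ogt_effect must be set")
  rng_range <- eff$radius_range %||% c(0.5, 3)
  structures <- lapply(seq_len(spec$n_structures), generate_structure,
                       spec = spec)
  withr::with_seed(round_seed(spec$seed, 424242), {
    ogt <- numeric(spec$n_structures)
    for (i in seq_len(spec$n_structures)) {
      repeat {
        t_i <- stats::runif(1, 15, 95)
        if (abs(t_i - 37) > 0.5) break
      }
      ogt[i] <- t_i
      frac <- (t_i - 15) / 80
      if (eff$sign < 0) frac <- 1 - frac
      r_i <- rng_range[1] + frac * (rng_range[2] - rng_range[1])
      structures[[i]] <- plant_motif(structures[[i]], eff$labels, r_i,
                                     min_separation = spec$min_separation,
                                     exact_radius = TRUE)
    }
    pts <- dplyr::bind_rows(structures)
    has_dna <- any(pts$molecule_kind == "dna")
    list(dataset = fresco_dataset(pts, mode = if (has_dna) "complex" else "protein"),
         ogt = tibble::tibble(structure_id = sprintf("SYN%04d",
                                                     seq_len(spec$n_structures)),
                              ogt_celsius = ogt))
  })
}
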