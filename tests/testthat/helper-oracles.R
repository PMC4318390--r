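# Independent oracles used across the suite.

# --- closed-form balls through 1..4 boundary points --------------------

oracle_ball_from <- function(P) {
  n <- nrow(P)
  if (n == 1) return(list(c = P[1, ], r = 0))
  if (n == 2) {
    return(list(c = colMeans(P), r = sqrt(sum((P[1, ] - P[2, ])^2)) / 2))
  }
  if (n == 3) {
    a <- P[1, ]; B <- P[2, ] - a; C <- P[3, ] - a
    bxc <- c(B[2] * C[3] - B[3] * C[2],
             B[3] * C[1] - B[1] * C[3],
             B[1] * C[2] - B[2] * C[1])
    den <- 2 * sum(bxc^2)
    if (den < 1e-12) return(NULL)  # collinear
    t <- sum(B^2) * C - sum(C^2) * B
    off <- c(t[2] * bxc[3] - t[3] * bxc[2],
             t[3] * bxc[1] - t[1] * bxc[3],
             t[1] * bxc[2] - t[2] * bxc[1]) / den
    return(list(c = a + off, r = sqrt(sum(off^2))))
  }
  a <- P[1, ]
  M <- sweep(P[2:4, , drop = FALSE], 2, a)
  # solve (p_i - a) . x = (|p_i|^2 - |a|^2) / 2 for the circumcenter,
  # by Cramer's rule
  rhs <- 0.5 * (rowSums(P[2:4, , drop = FALSE]^2) - sum(a^2))
  d0 <- M[1, 1] * (M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2]) -
        M[1, 2] * (M[2, 1] * M[3, 3] - M[2, 3] * M[3, 1]) +
        M[1, 3] * (M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1])
  if (abs(d0) < 1e-10) return(NULL)  # coplanar
  ctr <- vapply(1:3, function(j) {
    Mj <- M
    Mj[, j] <- rhs
    (Mj[1, 1] * (Mj[2, 2] * Mj[3, 3] - Mj[2, 3] * Mj[3, 2]) -
       Mj[1, 2] * (Mj[2, 1] * Mj[3, 3] - Mj[2, 3] * Mj[3, 1]) +
       Mj[1, 3] * (Mj[2, 1] * Mj[3, 2] - Mj[2, 2] * Mj[3, 1])) / d0
  }, numeric(1))
  list(c = ctr, r = sqrt(sum((ctr - a)^2)))
}

# brute-force minimum enclosing ball: smallest ball determined by a
# support subset of 1..4 points that contains everything
oracle_meb_radius <- function(P) {
  n <- nrow(P)
  tP <- t(P)
  best <- Inf
  for (k in seq_len(min(4, n))) {
    subsets <- combn(n, k)
    for (ci in seq_len(ncol(subsets))) {
      b <- oracle_ball_from(P[subsets[, ci], , drop = FALSE])
      if (is.null(b)) next
      if (b$r < best && all(colSums((tP - b$c)^2) <= (b$r + 1e-9)^2)) {
        best <- b$r
      }
    }
  }
  best
}

# --- exhaustive best-match enumeration ---------------------------------

# minimum enclosing-ball radius over all combinations of one occurrence
# per label; ball radii via the package MEB (itself validated against
# oracle_meb_radius)
oracle_best_radius <- function(coords, occ) {
  k <- length(occ)
  if (k == 1) return(0)
  if (k == 2) {
    d2 <- outer(seq_along(occ[[1]]), seq_along(occ[[2]]), function(i, j) {
      rowSums((coords[occ[[1]][i], , drop = FALSE] -
                 coords[occ[[2]][j], , drop = FALSE])^2)
    })
    return(sqrt(min(d2)) / 2)
  }
  combos <- as.matrix(expand.grid(occ))
  min(apply(combos, 1, function(ix) {
    min_enclosing_ball(coords[ix, , drop = FALSE])$radius
  }))
}

occ_of <- function(structure, pattern) {
  lapply(sort(pattern), function(l) which(structure$label == l))
}

# --- brute-force miner --------------------------------------------------

# enumerate every label subset up to max_size and score it by definition
oracle_mine <- function(dataset, min_support, max_radius, max_size) {
  ids <- sort(unique(dataset$structure_id))
  alphabet <- sort(unique(dataset$label))
  structs <- lapply(ids, function(id) dataset[dataset$structure_id == id, ])
  coords <- lapply(structs, function(s) cbind(s$x, s$y, s$z))
  out <- list()
  for (k in seq_len(max_size)) {
    for (S in asplit(combn(alphabet, k), 2)) {
      S <- as.character(S)
      sup <- which(vapply(structs, function(st) all(S %in% st$label), logical(1)))
      support <- length(sup) / length(ids)
      if (support < min_support) next
      if (length(sup) == 0) next
      radii <- vapply(sup, function(i) {
        oracle_best_radius(coords[[i]], occ_of(structs[[i]], S))
      }, numeric(1))
      R <- mean(radii)
      if (k >= 2 && R <= max_radius) {
        out[[length(out) + 1]] <- tibble::tibble(
          pattern = paste(sort(S), collapse = "-"), size = k,
          support = support, cohesive_radius = R)
      }
    }
  }
  dplyr::bind_rows(out) |> dplyr::arrange(size, pattern)
}

# --- statistics ---------------------------------------------------------

# hypergeometric tails by explicit pmf summation with choose()
oracle_hyper_tails <- function(k, n, K, N) {
  j <- 0:min(n, K)
  pmf <- choose(K, j) * choose(N - K, n - j) / choose(N, n)
  list(p_enriched = sum(pmf[j >= k]), p_depleted = sum(pmf[j <= k]))
}

# Spearman rho by explicit average ranking then the Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# --- fixtures -----------------------------------------------------------

# small random labeled structure as a point tibble
random_structure <- function(n, labels, box = 20, id = "s1", seed = NULL) {
  gen <- function() {
    tibble::tibble(
      structure_id = id, chain_id = "A", seq_pos = seq_len(n),
      molecule_kind = "protein",
      label = sample(labels, n, replace = TRUE),
      x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

random_dataset <- function(n_struct, n_points, labels, box = 20, seed = 1) {
  withr::with_seed(seed, {
    pts <- dplyr::bind_rows(lapply(seq_len(n_struct), function(i) {
      random_structure(n_points, labels, box, id = sprintf("d%02d", i))
    }))
    fresco_dataset(pts, mode = "protein")
  })
}
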