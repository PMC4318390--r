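# builds a one-row fresco_patterns-like tibble from explicit per-structure
# matches, for driving the association statistics directly
manual_pattern <- function(pattern, matches) {
  out <- tibble::tibble(
    pattern = pattern,
    labels = list(strsplit(pattern, "-", fixed = TRUE)[[1]]),
    size = lengths(labels), support = NA_real_,
    n_supporting = nrow(matches), cohesive_radius = mean(matches$radius),
    matches = list(matches))
  class(out) <- c("fresco_patterns", class(tibble::tibble()))
  out
}

test_that("hypergeometric tails match the closed-form and pmf-summation oracles", {
  # all-overlap draw: P(X >= 5) = 1 / C(10, 5)
  t1 <- hypergeom_tails(5, 5, 5, 10)
  expect_equal(t1$p_enriched, 1 / choose(10, 5), tolerance = 1e-12)
  # empty sample
  t0 <- hypergeom_tails(0, 0, 5, 10)
  expect_equal(t0$p_enriched, 1)
  expect_equal(t0$p_depleted, 1)
  withr::with_seed(40, {
    for (i in 1:60) {
      N <- sample(1:30, 1)
      K <- sample(0:N, 1)
      n <- sample(0:N, 1)
      ks <- max(0, n - (N - K)):min(n, K)
      k <- ks[sample.int(length(ks), 1)]
      got <- hypergeom_tails(k, n, K, N)
      want <- oracle_hyper_tails(k, n, K, N)
      expect_lte(abs(got$p_enriched - want$p_enriched), 1e-12)
      expect_lte(abs(got$p_depleted - want$p_depleted), 1e-12)
      # the two tails share exactly the pmf at k
      pmf_k <- choose(K, k) * choose(N - K, n - k) / choose(N, n)
      expect_lte(abs(got$p_enriched + got$p_depleted - 1 - pmf_k), 1e-12)
    }
  })
  expect_error(hypergeom_tails(5, 4, 5, 10), "inconsistent")
})

test_that("domain enrichment reproduces the direct combinatorial count", {
  # 100 residues, domain covers 1-50, matches at 10/20/30:
  # p_enriched = C(50,3)/C(100,3)
  st <- tibble::tibble(structure_id = "s1", chain_id = "A", seq_pos = 1:100,
                       molecule_kind = "protein",
                       label = rep(c("ALA", "GLY", "LEU", "SER"), 25),
                       x = 4 * (1:100), y = 0, z = 0)
  ds <- fresco_dataset(st)
  dom <- tibble::tibble(structure_id = "s1", chain = "A", start = 1L,
                        end = 50L, domain = "PF1")
  mp <- manual_pattern("ALA-GLY-LEU", tibble::tibble(
    structure_id = "s1", radius = 1,
    idx = list(c(10L, 20L, 30L))))
  res <- domain_enrichment(mp, dom, ds)
  expect_equal(res$k_overlap, 3L)
  expect_equal(res$n_sample, 3L)
  expect_equal(res$K_category, 50L)
  expect_equal(res$N_population, 100L)
  expect_equal(res$p_enriched, choose(50, 3) / choose(100, 3), tolerance = 1e-12)
  # saturated category: everything in domains, no surprise
  dom_all <- tibble::tibble(structure_id = "s1", chain = "A", start = 1L,
                            end = 100L, domain = "PF1")
  expect_equal(domain_enrichment(mp, dom_all, ds)$p_enriched, 1)
})

test_that("matches planted outside domains come out depleted", {
  # 20 structures; domains cover 1-80 of 100; matches always in 81-100
  pts <- dplyr::bind_rows(lapply(1:20, function(i) {
    tibble::tibble(structure_id = sprintf("s%02d", i), chain_id = "A",
                   seq_pos = 1:100, molecule_kind = "protein",
                   label = rep(c("ALA", "GLY", "LEU", "SER"), 25),
                   x = 4 * (1:100), y = i, z = 0)
  }))
  ds <- fresco_dataset(pts)
  dom <- tibble::tibble(structure_id = sprintf("s%02d", 1:20), chain = "A",
                        start = 1L, end = 80L, domain = "PF1")
  mp <- manual_pattern("ALA-GLY-LEU", tibble::tibble(
    structure_id = sprintf("s%02d", 1:20), radius = 1,
    idx = lapply(1:20, function(i) c(85L, 90L, 95L))))
  res <- domain_enrichment(mp, dom, ds)
  expect_equal(res$k_overlap, 0L)
  expect_lt(res$p_depleted, 0.01)
  expect_true(res$depleted_significant)
  expect_gt(res$p_enriched, 0.99)
})

test_that("GO enrichment counts tight structures with a strict radius cut", {
  ids <- sprintf("g%03d", 1:100)
  pts <- dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    tibble::tibble(structure_id = ids[i], chain_id = "A", seq_pos = 1:4,
                   molecule_kind = "protein",
                   label = c("ALA", "GLY", "LEU", "SER"),
                   x = 5 * (1:4), y = i, z = 0)
  }))
  ds <- fresco_dataset(pts)
  go <- tibble::tibble(structure_id = ids, go_term = "GO:any")
  go <- dplyr::bind_rows(go, tibble::tibble(structure_id = ids[1:20],
                                            go_term = "GO:coh"))
  # tight (< 3) exactly in the 20 GO:coh structures; radius exactly 3.0
  # elsewhere must NOT count
  mp <- manual_pattern("ALA-GLY", tibble::tibble(
    structure_id = ids, radius = c(rep(1, 20), rep(3.0, 80)),
    idx = lapply(1:100, function(i) c(1L, 2L))))
  res <- go_enrichment(mp, go, ds, tight_radius = 3.0, min_structures = 10)
  coh <- res[res$go_term == "GO:coh", ]
  expect_equal(coh$n_sample, 20L)
  expect_equal(coh$k_overlap, 20L)
  want <- oracle_hyper_tails(20, 20, 20, 100)
  expect_lte(abs(coh$p_enriched - want$p_enriched), 1e-12)
  # terms under the annotation floor are skipped
  go9 <- dplyr::bind_rows(go, tibble::tibble(structure_id = ids[1:9],
                                             go_term = "GO:rare"))
  res9 <- go_enrichment(mp, go9, ds, min_structures = 10)
  expect_false("GO:rare" %in% res9$go_term)
})

test_that("GO-shuffle p-values are exactly uniform after discrete randomization", {
  # u = P(X > k) + U * pmf(k) is U(0,1) under the hypergeometric null
  ids <- sprintf("h%03d", 1:100)
  tight <- ids[1:30]
  withr::with_seed(50, {
    u <- replicate(1000, {
      members <- sample(ids, 50)
      k <- length(intersect(tight, members))
      p_gt <- phyper(k, 50, 50, 30, lower.tail = FALSE)
      p_gt + runif(1) * dhyper(k, 50, 50, 30)
    })
    expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
  })
})

test_that("OGT correlation recovers monotone relations and is rank-invariant", {
  radii <- c(1.2, 1.5, 1.9, 2.2, 2.6, 2.9, 3.1, 3.4, 3.8, 4.0)
  ids <- sprintf("o%02d", 1:10)
  ogt_up <- tibble::tibble(structure_id = ids, ogt_celsius = 10 * (1:10))
  mp <- manual_pattern("ALA-GLY", tibble::tibble(
    structure_id = ids, radius = radii, idx = lapply(1:10, function(i) 1:2)))
  res <- ogt_correlation(mp, ogt_up)
  expect_equal(res$rho, 1)
  expect_equal(res$direction, "low_T")
  res_dn <- ogt_correlation(mp, tibble::tibble(structure_id = ids,
                                               ogt_celsius = 100 - 10 * (1:10)))
  expect_equal(res_dn$rho, -1)
  expect_equal(res_dn$direction, "high_T")
  # invariance under a strictly monotone transform of the temperatures
  res_tr <- ogt_correlation(mp, tibble::tibble(structure_id = ids,
                                               ogt_celsius = exp(0.1 * 10 * (1:10))))
  expect_equal(res_tr$rho, res$rho)
  expect_equal(res_tr$p_value, res$p_value)
})

test_that("exact 37-degree rows are removed and small n yields NA", {
  ids <- sprintf("p%02d", 1:8)
  mp <- manual_pattern("ALA-GLY", tibble::tibble(
    structure_id = ids, radius = 1:8, idx = lapply(1:8, function(i) 1:2)))
  ogt <- tibble::tibble(structure_id = ids,
                        ogt_celsius = c(37, 37, 37, 37, 20, 30, 40, 50))
  res <- ogt_correlation(mp, ogt)
  expect_equal(res$n_structures, 4L)
  expect_true(is.na(res$rho))
  expect_equal(res$direction, "none")
  # 37.0001 survives the exact filter
  ogt2 <- ogt
  ogt2$ogt_celsius[1] <- 37.0001
  expect_equal(ogt_correlation(mp, ogt2)$n_structures, 5L)
})

test_that("Spearman rho with ties matches the rank-then-Pearson oracle", {
  withr::with_seed(60, {
    for (i in 1:30) {
      n <- 12
      r <- sample(1:5, n, replace = TRUE) + runif(n, 0, 0.2)
      temp <- sample(seq(20, 90, by = 10), n, replace = TRUE)
      ids <- sprintf("q%02d", 1:n)
      mp <- manual_pattern("ALA-GLY", tibble::tibble(
        structure_id = ids, radius = r, idx = lapply(1:n, function(i) 1:2)))
      res <- ogt_correlation(mp, tibble::tibble(structure_id = ids,
                                                ogt_celsius = temp))
      expect_lte(abs(res$rho - oracle_spearman(r, temp)), 1e-12)
    }
  })
})

test_that("sequence separation classifies by the 6/10 residue cut-offs", {
  st <- tibble::tibble(structure_id = "s1",
                       chain_id = c("A", "A", "A", "A", "A", "B"),
                       seq_pos = c(10L, 12L, 14L, 5L, 200L, 3L),
                       molecule_kind = "protein",
                       label = c("ALA", "GLY", "LEU", "TRP", "TYR", "HIS"),
                       x = 5 * (1:6), y = 0, z = 0)
  ds <- fresco_dataset(st)
  # positions 10, 12, 14: mean pairwise separation (2+4+2)/3 = 8/3
  mp1 <- manual_pattern("ALA-GLY-LEU", tibble::tibble(
    structure_id = "s1", radius = 1, idx = list(1:3)))
  r1 <- sequence_separation(mp1, ds)
  expect_equal(r1$separation, 8 / 3)
  expect_equal(r1$class, "short_range")
  # positions 5 and 200
  mp2 <- manual_pattern("TRP-TYR", tibble::tibble(
    structure_id = "s1", radius = 1, idx = list(4:5)))
  r2 <- sequence_separation(mp2, ds)
  expect_equal(r2$separation, 195)
  expect_equal(r2$class, "long_range")
  # chains A and B
  mp3 <- manual_pattern("ALA-HIS", tibble::tibble(
    structure_id = "s1", radius = 1, idx = list(c(1L, 6L))))
  expect_equal(sequence_separation(mp3, ds)$class, "cross_chain")
  # singleton: undefined
  mp4 <- manual_pattern("ALA", tibble::tibble(
    structure_id = "s1", radius = 0, idx = list(1L)))
  expect_true(is.na(sequence_separation(mp4, ds)$separation))
})

test_that("planted sequence offsets reproduce the short/long mixture", {
  short_frac <- 0.6
  props <- vapply(1:20, function(seed) {
    withr::with_seed(7000 + seed, {
      n <- 40
      comp <- setNames(rep(1 / 17, 17),
                       setdiff(amino_acid_labels(), c("TRP", "TYR", "HIS")))
      spec <- synthetic_spec(n, 60, composition = comp, seed = 7000 + seed)
      n_short <- round(short_frac * n)
      structures <- lapply(seq_len(n), function(i) {
        st <- generate_structure(spec, i)
        offs <- if (i <= n_short) c(0L, 2L, 4L) else c(0L, 15L, 30L)
        plant_motif(st, c("TRP", "TYR", "HIS"), 2.5, seq_offsets = offs)
      })
      ds <- fresco_dataset(dplyr::bind_rows(structures))
      mp <- pattern_stats(ds, list(c("TRP", "TYR", "HIS")))
      sep <- sequence_separation(mp, ds)
      mean(sep$class == "short_range")
    })
  }, numeric(1))
  expect_lte(abs(mean(props) - short_frac), 0.05)
})
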