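make_presence_dataset <- function(label_sets, box = 30) {
  # one structure per element; labels placed on a coarse grid
  pts <- dplyr::bind_rows(lapply(seq_along(label_sets), function(i) {
    labs <- label_sets[[i]]
    tibble::tibble(structure_id = sprintf("p%02d", i), chain_id = "A",
                   seq_pos = seq_along(labs), molecule_kind = "protein",
                   label = labs,
                   x = 5 * seq_along(labs), y = i, z = 0)
  }))
  fresco_dataset(pts)
}

test_that("support counts structures containing every pattern label", {
  ds <- make_presence_dataset(list(
    c("ASP", "GLU", "ARG"), c("ASP", "GLU", "ARG", "ALA"),
    c("ASP", "GLU", "ARG"), c("ASP", "GLU")))
  res <- compute_support(ds, c("ASP", "GLU", "ARG"))
  expect_equal(res$support, 0.75)
  expect_equal(length(res$supporting_ids), 3)
  # absent label: zero support, empty id set
  res0 <- compute_support(ds, c("ASP", "TRP"))
  expect_equal(res0$support, 0)
  expect_equal(res0$supporting_ids, character(0))
})

test_that("cohesive radius averages per-structure best radii over the support set", {
  # two structures engineered to R_g = 2 and 4
  pts <- dplyr::bind_rows(
    tibble::tibble(structure_id = "a", chain_id = "A", seq_pos = 1:2,
                   molecule_kind = "protein", label = c("ALA", "GLY"),
                   x = c(0, 4), y = 0, z = 0),
    tibble::tibble(structure_id = "b", chain_id = "A", seq_pos = 1:2,
                   molecule_kind = "protein", label = c("ALA", "GLY"),
                   x = c(0, 8), y = 0, z = 0))
  ds <- fresco_dataset(pts)
  res <- compute_cohesive_radius(ds, c("ALA", "GLY"))
  expect_equal(unname(res$per_structure_radius), c(2, 4))
  expect_equal(res$cohesive_radius, 3)
  # empty support: undefined sentinel
  res0 <- compute_cohesive_radius(ds, c("TRP", "TYR"), character(0))
  expect_true(is.na(res0$cohesive_radius))
})

test_that("candidate generation is the classic Apriori join and prune", {
  got <- generate_candidates(list(c("A", "B"), c("A", "C"), c("B", "C")))
  expect_equal(got, list(c("A", "B", "C")))
  expect_equal(generate_candidates(list(c("A", "B"), c("A", "C"))), list())
  # brute-force check: candidates = all (k+1)-subsets whose k-subsets are frequent
  withr::with_seed(21, {
    alphabet <- LETTERS[1:7]
    for (rep in 1:10) {
      freq <- asplit(combn(alphabet, 3), 2)
      freq <- lapply(freq[sample(length(freq), 18)], as.character)
      keys <- vapply(freq, paste, character(1), collapse = "-")
      want <- Filter(function(S) {
        all(vapply(seq_along(S), function(i) {
          paste(S[-i], collapse = "-") %in% keys
        }, logical(1)))
      }, lapply(asplit(combn(alphabet, 4), 2), as.character))
      got <- generate_candidates(freq)
      expect_equal(vapply(got, paste, character(1), collapse = "-"),
                   vapply(want, paste, character(1), collapse = "-"))
    }
  })
})

test_that("mining with no thresholds returns all pairs present everywhere", {
  ds <- random_dataset(4, 25, c("ALA", "GLY", "LEU"), seed = 31)
  mined <- mine_frescos(ds, mining_config(min_support = 1.0, max_radius = 1e6,
                                          max_pattern_size = 2))
  expect_setequal(mined$pattern, c("ALA-GLY", "ALA-LEU", "GLY-LEU"))
  expect_true(all(mined$support == 1))
})

test_that("mine_frescos equals brute-force subset enumeration on random datasets", {
  labs <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN")
  for (seed in 1:6) {
    ds <- random_dataset(6, 22, labs, box = 18, seed = 400 + seed)
    cfg <- mining_config(min_support = 0.5, max_radius = 6,
                         max_pattern_size = 3)
    mined <- mine_frescos(ds, cfg)
    want <- oracle_mine(ds, 0.5, 6, 3)
    expect_equal(mined$pattern, want$pattern)
    expect_equal(mined$support, want$support)
    expect_lte(max(abs(mined$cohesive_radius - want$cohesive_radius)), 1e-9)
  }
})

test_that("support is anti-monotone and support sets are nested", {
  ds <- random_dataset(8, 20, c("ALA", "GLY", "LEU", "SER"), seed = 77)
  withr::with_seed(78, {
    for (i in 1:15) {
      x <- sample(c("ALA", "GLY", "LEU", "SER"), 2)
      y <- c(x, sample(setdiff(c("ALA", "GLY", "LEU", "SER"), x), 1))
      sx <- compute_support(ds, x)
      sy <- compute_support(ds, y)
      expect_gte(sx$support, sy$support)
      expect_true(all(sy$supporting_ids %in% sx$supporting_ids))
    }
  })
})

test_that("mining output is independent of structure input order", {
  ds <- random_dataset(5, 20, c("ALA", "GLY", "LEU"), seed = 55)
  shuffled <- withr::with_seed(56, ds[sample(nrow(ds)), ])
  shuffled <- fresco_dataset(shuffled)
  cfg <- mining_config(min_support = 0.4, max_radius = 8, max_pattern_size = 3)
  a <- mine_frescos(ds, cfg)
  b <- mine_frescos(shuffled, cfg)
  expect_equal(a$pattern, b$pattern)
  expect_equal(a$cohesive_radius, b$cohesive_radius)
})

test_that("complex mode keeps only patterns bridging bases and amino acids", {
  # T, GLY, ARG tight in every structure; GLY-ARG equally tight
  pts <- dplyr::bind_rows(lapply(1:4, function(i) {
    tibble::tibble(
      structure_id = sprintf("c%d", i), chain_id = c("B", "A", "A", "A"),
      seq_pos = c(1L, 1L, 2L, 3L), molecule_kind = c("dna", rep("protein", 3)),
      label = c("T", "GLY", "ARG", "TRP"),
      x = c(0, 1, 2, 40), y = i, z = 0)
  }))
  ds <- fresco_dataset(pts, mode = "complex")
  mined <- mine_frescos(ds, mining_config("complex", min_support = 0.7,
                                          max_radius = 7, max_pattern_size = 3))
  expect_true("GLY-T" %in% mined$pattern || "ARG-GLY-T" %in% mined$pattern)
  expect_true(all(vapply(mined$labels, function(l) {
    any(l %in% dna_base_labels()) && any(l %in% amino_acid_labels())
  }, logical(1))))
  expect_false("ARG-GLY" %in% mined$pattern)
})

test_that("the lossy radius prune reproduces default results on a benign fixture", {
  ds <- random_dataset(6, 30, c("ALA", "GLY", "LEU", "SER", "VAL"), seed = 91)
  cfg0 <- mining_config(min_support = 0.5, max_radius = 5, max_pattern_size = 3)
  cfg1 <- mining_config(min_support = 0.5, max_radius = 5, max_pattern_size = 3,
                        radius_prune = TRUE)
  a <- mine_frescos(ds, cfg0)
  b <- mine_frescos(ds, cfg1)
  expect_equal(a$pattern, b$pattern)
  expect_equal(a$cohesive_radius, b$cohesive_radius)
})

test_that("removing a structure leaves other per-structure radii unchanged and rescales support", {
  ds <- random_dataset(6, 25, c("ALA", "GLY", "LEU"), seed = 61)
  ids <- unique(ds$structure_id)
  sub <- fresco_dataset(ds[ds$structure_id != ids[1], ])
  full <- pattern_stats(ds, list(c("ALA", "GLY"), c("ALA", "GLY", "LEU")))
  part <- pattern_stats(sub, list(c("ALA", "GLY"), c("ALA", "GLY", "LEU")))
  for (i in 1:2) {
    fm <- full$matches[[i]]
    pm <- part$matches[[i]]
    common <- intersect(fm$structure_id, pm$structure_id)
    expect_equal(fm$radius[match(common, fm$structure_id)],
                 pm$radius[match(common, pm$structure_id)])
    expect_equal(part$support[i],
                 sum(fm$structure_id != ids[1]) / (length(ids) - 1))
  }
})

test_that("mining configs validate their inputs", {
  expect_error(mining_config(min_support = 0), "min_support")
  expect_error(mining_config(min_support = 1.2), "min_support")
  expect_error(mining_config(max_radius = -1), "max_radius")
  expect_error(mining_config(max_pattern_size = 0), "max_pattern_size")
})
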