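test_that("standardization merges protonation states and strips counterions", {
  s <- standardize_smiles(c(a = "C(C(=O)O)N", b = "C(C(=O)[O-])[NH3+]"))
  expect_equal(s$smiles_canonical[1], s$smiles_canonical[2])
  s2 <- standardize_smiles(c(salt = "CCO.Cl", plain = "CCO"))
  expect_equal(s2$smiles_canonical[1], s2$smiles_canonical[2])
  expect_equal(s2$molecular_formula[1], "C2H6O")
  expect_error(standardize_smiles(c(bad = "C1CC")), "parse error in record bad")
})

test_that("canonicalization is idempotent and the toy library collapses as planted", {
  lib <- toy_library()
  std <- standardize_smiles(lib$smiles, lib$compound_id)
  expect_equal(nrow(std), 60L)
  expect_equal(length(unique(std$smiles_canonical)), 48L)
  # idempotence
  again <- standardize_smiles(std$smiles_canonical, std$compound_id)
  expect_equal(again$smiles_canonical, std$smiles_canonical)
  # every planted redundant entry maps onto its target structure
  dup <- lib[!is.na(lib$duplicate_of), ]
  for (i in seq_len(nrow(dup))) {
    expect_equal(
      std$smiles_canonical[std$compound_id == dup$compound_id[i]],
      std$smiles_canonical[std$compound_id == dup$duplicate_of[i]],
      label = dup$compound_id[i]
    )
  }
})

test_that("consolidation aggregates wells and keeps hit status", {
  rec <- data.frame(
    compound_id = c("w1", "w2", "w3"),
    smiles_canonical = c("CCO", "CCO", "CCN"),
    molecular_formula = c("C2H6O", "C2H6O", "C2H7N"),
    plate_id = "p1", scaled = c(0.9, 0.1, 0.5),
    is_hit = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE
  )
  out <- consolidate(rec)
  expect_equal(nrow(out), 2L)
  ccc <- out[out$smiles_canonical == "CCO", ]
  expect_equal(ccc$n_wells, 2L)
  expect_true(ccc$is_hit)          # any constituent hit well keeps hit status
  expect_equal(ccc$best_scaled, 0.9)
  expect_equal(nrow(consolidate(rec[0, ])), 0L)

  # the toy library's multiplicity histogram matches the planted map:
  # 12 structures from two entries, 36 singletons
  lib <- toy_library()
  std <- standardize_smiles(lib$smiles, lib$compound_id)
  std$scaled <- 0; std$is_hit <- TRUE
  cons <- consolidate(std)
  expect_equal(sum(cons$n_wells == 2L), 12L)
  expect_equal(sum(cons$n_wells == 1L), 36L)
})

test_that("sphere-exclusion clustering matches its definition at the extremes", {
  lib <- toy_library()
  std <- standardize_smiles(lib$smiles, lib$compound_id)
  uni <- std[!duplicated(std$smiles_canonical), ][1:12, ]
  uni$best_scaled <- seq(1.2, by = -0.05, length.out = nrow(uni))
  cl0 <- cluster_hits(uni, mode = "threshold", param = 0)
  expect_equal(length(unique(cl0$cluster_id)), nrow(uni))
  cl1 <- cluster_hits(uni, mode = "threshold", param = 1)
  expect_equal(length(unique(cl1$cluster_id)), 1L)
  # radius bound: every member within threshold of its leader
  cl <- cluster_hits(uni, mode = "threshold", param = 0.5)
  expect_true(all(cl$dist_to_leader <= 0.5 + 1e-12))
  # partition: disjoint and covering
  expect_setequal(cl$compound_id, uni$compound_id)
  expect_false(any(duplicated(cl$compound_id)))
})

test_that("clustering equals the brute-force reference and ignores row order", {
  lib <- toy_library()
  std <- standardize_smiles(lib$smiles, lib$compound_id)
  uni <- std[!duplicated(std$smiles_canonical), ][1:20, ]
  set.seed(1)
  uni$best_scaled <- round(stats::runif(nrow(uni), 0.8, 1.5), 3)
  smi <- structure(uni$smiles_canonical, names = uni$compound_id)
  fps <- ecfp_fingerprints(smi)
  for (thr in c(0.3, 0.4, 0.5)) {
    got <- cluster_hits(uni, mode = "threshold", param = thr, fps = fps)
    want <- oracle_sphere_exclusion(fps, uni$best_scaled, uni$compound_id, thr)
    expect_equal(partition_signature(got$compound_id, got$cluster_id),
                 partition_signature(names(want), unname(want)),
                 label = paste("threshold", thr))
  }
  # permutation invariance of the partition
  perm <- sample(nrow(uni))
  got2 <- cluster_hits(uni[perm, ], mode = "threshold", param = 0.4, fps = fps)
  got1 <- cluster_hits(uni, mode = "threshold", param = 0.4, fps = fps)
  expect_equal(partition_signature(got1$compound_id, got1$cluster_id),
               partition_signature(got2$compound_id, got2$cluster_id))
})

test_that("target_k mode is monotone in threshold and lands on k", {
  lib <- toy_library()
  std <- standardize_smiles(lib$smiles, lib$compound_id)
  uni <- std[!duplicated(std$smiles_canonical), ][1:15, ]
  uni$best_scaled <- seq_len(nrow(uni)) / 10
  smi <- structure(uni$smiles_canonical, names = uni$compound_id)
  fps <- ecfp_fingerprints(smi)
  ks <- vapply(seq(0, 1, by = 0.1), function(thr) {
    length(unique(cluster_hits(uni, "threshold", thr, fps = fps)$cluster_id))
  }, 0L)
  expect_true(all(diff(ks) <= 0))
  for (k in c(3L, 8L, 15L)) {
    got <- cluster_hits(uni, mode = "target_k", param = k, fps = fps)
    expect_equal(length(unique(got$cluster_id)), k)
  }
  expect_error(cluster_hits(uni, mode = "target_k", param = 99, fps = fps),
               "infeasible")
})

test_that("representative selection favors central members over peripheral top scorers", {
  # singleton
  single <- data.frame(compound_id = "x", mean_dist = 0, best_scaled = 1)
  expect_equal(select_representative(single), "x")
  # two members: both maximally central; higher score wins
  two <- data.frame(compound_id = c("a", "b"), mean_dist = c(0.2, 0.2),
                    best_scaled = c(0.9, 1.2))
  expect_equal(select_representative(two), "b")
  # seven members: the top scorer is peripheral, so the best *central*
  # member is returned
  seven <- data.frame(
    compound_id = sprintf("m%d", 1:7),
    mean_dist = c(0.10, 0.12, 0.15, 0.18, 0.40, 0.45, 0.50),
    best_scaled = c(0.9, 1.0, 0.95, 0.97, 1.1, 1.0, 1.5)
  )
  # central half = mean_dist <= median(0.18); best scaled among those = m2
  expect_equal(select_representative(seven), "m2")
  # permutation invariance
  expect_equal(select_representative(seven[sample(7), ]), "m2")
})

test_that("liability filters catch planted PAINS and frequent hitters", {
  lib <- toy_library()
  std <- standardize_smiles(lib$smiles, lib$compound_id)
  uni <- std[!duplicated(std$smiles_canonical), ]
  fl <- filter_liabilities(uni)
  removed <- fl$compound_id[!fl$kept]
  expect_setequal(removed, c("D03", "P01", "P02", "P03"))
  expect_match(fl$reason[fl$compound_id == "P01"], "PAINS:quinone")
  expect_match(fl$reason[fl$compound_id == "D03"], "PAINS:catechol")

  # frequent-hitter arithmetic: 9/40 = 22.5% > 20% -> removed;
  # 11 total hits > 10 -> removed even at a low rate; 5/40 kept
  hist <- data.frame(compound_id = c("A01", "A03", "A06"),
                     n_screens = c(40, 100, 40), n_hits = c(9, 11, 5))
  fl2 <- filter_liabilities(uni, history = hist)
  expect_equal(fl2$reason[fl2$compound_id == "A01"], "frequent_hitter")
  expect_equal(fl2$reason[fl2$compound_id == "A03"], "frequent_hitter")
  expect_true(fl2$kept[fl2$compound_id == "A06"])
  # without a history table there are no frequent-hitter removals
  expect_false(any(fl$reason == "frequent_hitter"))
})

test_that("the PAINS catalog loader validates its input", {
  pains <- load_pains()
  expect_true(nrow(pains) >= 10)
  bad <- tempfile(fileext = ".smarts")
  writeLines(c("O=C1[#6]=[#6]C(=O)[#6]=[#6]1\tok", "no_tab_line"), bad)
  expect_error(load_pains(bad), "catalog error")
  bad2 <- tempfile(fileext = ".smarts")
  writeLines("[#6]1[#6\tunbalanced", bad2)
  expect_error(load_pains(bad2), "catalog error")
})

test_that("reference-similarity filter removes the positive-control lookalike", {
  lib <- toy_library()
  std <- standardize_smiles(lib$smiles, lib$compound_id)
  uni <- std[!duplicated(std$smiles_canonical), ]
  rs <- filter_reference_similarity(uni, tau = 0.6)
  expect_equal(rs$compound_id[!rs$kept], "E02")
  expect_equal(rs$ref_similarity[rs$compound_id == "E02"], 1)
})

test_that("formula deduplication keeps the strongest isomer", {
  d <- data.frame(compound_id = c("i1", "i2", "u1", "i3", "i4", "i5", "i6"),
                  molecular_formula = c("C10H14N2", "C10H14N2", "CH4O",
                                        "C7H8O", "C7H8O", "C9H9N", "C9H9N"),
                  best_scaled = c(0.9, 1.1, 0.5, 1.0, 0.2, 0.7, 0.6))
  out <- dedup_by_formula(d)
  expect_equal(sum(!out$kept), 3L)   # one removal per planted isomer pair
  expect_false(out$kept[out$compound_id == "i1"])
  expect_true(out$kept[out$compound_id == "i2"])
  expect_true(all(out$reason[!out$kept] == "formula_duplicate"))
  # all-unique input is untouched
  u <- dedup_by_formula(d[c(3), ])
  expect_true(all(u$kept))
})
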