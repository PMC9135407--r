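test_that("percent_positive evaluates the count ratio and flags empty wells", {
  expect_equal(percent_positive(0, 500), 0)
  expect_equal(percent_positive(500, 500), 100)
  expect_equal(percent_positive(123, 400), 30.75)
  expect_warning(p <- percent_positive(c(10, 0), c(100, 0)), "zero cell count")
  expect_equal(p, c(10, NA))
  expect_error(percent_positive(10, 5), "exceeds")
})

test_that("raw_score decomposes into distance minus penalties", {
  # duplicates at the baseline with control-level counts: everything cancels
  s <- raw_score(c(30, 30), c(1000, 1000), p75 = 30, nor_cells_mean = 1000)
  expect_equal(s$score, 0)
  # distance only
  s <- raw_score(c(40, 40), c(1000, 1000), p75 = 30, nor_cells_mean = 1000)
  expect_equal(s$score, 10)
  # hand arithmetic: mean 35, P75 30 -> +5; cells at 50% of control -> -50;
  # |40-30|/2 -> -5
  s <- raw_score(c(40, 30), c(500, 500), p75 = 30, nor_cells_mean = 1000)
  expect_equal(s$baseline_distance, 5)
  expect_equal(s$toxicity_penalty, 50)
  expect_equal(s$reproducibility_penalty, 5)
  expect_equal(s$score, -50)
  # supra-control counts earn no bonus
  s <- raw_score(c(40, 40), c(2000, 2000), p75 = 30, nor_cells_mean = 1000)
  expect_equal(s$toxicity_penalty, 0)
  expect_error(raw_score(c(40), c(500), 30, 1000), "incomplete duplicate")
})

test_that("scaled_value pins the control medians at 0 and -1", {
  expect_equal(scaled_value(20, median_nor = 20, median_dmso = 0), 0)
  expect_equal(scaled_value(0, median_nor = 20, median_dmso = 0), -1)
  expect_equal(scaled_value(37, median_nor = 20, median_dmso = 0), 0.85)
  expect_error(scaled_value(5, 10, 10), "degenerate")
  # strictly increasing in score
  expect_true(scaled_value(11, 20, 0) > scaled_value(10, 20, 0))
})

test_that("score_screen is affine-invariant in percent-positive", {
  pairs <- list(c(10, 12), c(20, 18), c(30, 31), c(5, 6), c(15, 15))
  w1 <- make_plate(pairs, dmso_pct = rep(c(9, 11), 3), nor_pct = rep(c(19, 21), 3))
  pairs2 <- lapply(pairs, function(p) p + 10)
  w2 <- make_plate(pairs2, dmso_pct = rep(c(9, 11), 3) + 10,
                   nor_pct = rep(c(19, 21), 3) + 10)
  s1 <- score_screen(w1)
  s2 <- score_screen(w2)
  expect_equal(s2$scaled, s1$scaled, tolerance = 1e-12)
  # and the nortriptyline median itself sits at Scaled 0 by construction
  ctrl <- attr(s1, "plate_controls")
  expect_equal(scaled_value(ctrl$median_nor, ctrl$median_nor, ctrl$median_dmso), 0)
  expect_equal(scaled_value(ctrl$median_dmso, ctrl$median_nor, ctrl$median_dmso), -1)
})

test_that("higher mean percent-positive never lowers the scaled value", {
  base <- seq(8, 30, by = 2)
  scores <- vapply(base, function(m) {
    raw_score(c(m, m), c(1000, 1000), p75 = 15, nor_cells_mean = 1000)$score
  }, 0)
  expect_true(all(diff(scores) > 0))
  expect_true(all(diff(scaled_value(scores, 10, -2)) > 0))
})

test_that("call_hits applies the cutoff and the top-k rescue with reasons", {
  sc <- data.frame(compound_id = paste0("c", 1:4), plate_id = "p1",
                   scaled = c(0.9, 0.2, 0.1, 0.05))
  h <- call_hits(sc, cutoff = 0.85, rescue_top_k = 3)
  h <- h[order(h$compound_id), ]
  expect_equal(h$is_hit, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(h$reason, c("scaled_cutoff", "plate_top3", "plate_top3", "none"))

  # rescue guarantees plate representation even when nothing passes
  sc2 <- data.frame(compound_id = paste0("c", 1:5), plate_id = "p1", scaled = -1)
  h2 <- call_hits(sc2)
  expect_equal(sum(h2$is_hit), 3L)
  expect_true(all(h2$reason[h2$is_hit] == "plate_top3"))

  # plates with fewer entries than k: all eligible, no error
  sc3 <- data.frame(compound_id = paste0("c", 1:2), plate_id = "p1",
                    scaled = c(-0.5, -0.6))
  expect_equal(sum(call_hits(sc3)$is_hit), 2L)
})

test_that("per-plate nortriptyline-percentile cutoff mode works", {
  sc <- data.frame(compound_id = paste0("c", 1:3), plate_id = "p1",
                   scaled = c(0.5, 0.01, -0.2))
  ns <- data.frame(plate_id = "p1", scaled = rep(0, 8))
  h <- call_hits(sc, cutoff_mode = "nor_percentile", nor_scaled = ns)
  # cutoff = 0: compounds above 0 pass by cutoff
  expect_equal(h$reason[h$compound_id %in% c("c1", "c2")],
               rep("scaled_cutoff", 2))
  expect_error(call_hits(sc, cutoff_mode = "nor_percentile"), "nor_scaled")
})

test_that("hit calling matches the brute-force two-rule oracle on random plates", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(5:20, 1)
    scaled <- round(stats::rnorm(n, 0, 0.6), 3)
    ids <- sprintf("c%02d", seq_len(n))
    sc <- data.frame(compound_id = ids, plate_id = "p1", scaled = scaled)
    got <- call_hits(sc)
    want <- oracle_hits(scaled, ids)
    got <- got[match(want$compound_id, got$compound_id), ]
    expect_equal(got$is_hit, want$is_hit)
    expect_equal(got$reason, want$reason)
  }
})

test_that("degenerate plates and missing controls are rejected", {
  w <- make_plate(list(c(10, 12), c(20, 18), c(30, 31), c(5, 6)),
                  dmso_pct = rep(10, 4), nor_pct = rep(10, 4))
  expect_warning(s <- score_screen(w), "degenerate")
  expect_equal(nrow(s), 0L)
  w2 <- w[w$role != "dmso", ]
  expect_error(score_screen(w2), "control wells")
})
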