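make_qpcr <- function(effect_map, noise_sd = 0, seed = 1, n_plates = 2,
                      plate_effect_sd = 0.4) {
  simulate_qpcr(qpcr_sim_config(effect_map, n_plates = n_plates,
                                noise_sd = noise_sd,
                                plate_effect_sd = plate_effect_sd,
                                seed = seed))
}

test_that("the delta-Ct model inverts the generator exactly at zero noise", {
  em <- rbind(DMSO = c(COL1A1 = 0), chemX = c(COL1A1 = 1),
              chemY = c(COL1A1 = 0))
  q <- make_qpcr(em)
  eff <- suppressWarnings(fit_delta_ct_model(q, "COL1A1"))
  expect_equal(eff$delta_ct_estimate[eff$chemical == "chemX"], 1,
               tolerance = 1e-9)
  expect_equal(eff$fold_change[eff$chemical == "chemX"], 0.5,
               tolerance = 1e-9)
  expect_equal(eff$delta_ct_estimate[eff$chemical == "chemY"], 0,
               tolerance = 1e-9)
  expect_equal(eff$fold_change[eff$chemical == "chemY"], 1, tolerance = 1e-9)
  # log-symmetry of the fold-change transform
  em2 <- rbind(DMSO = c(COL1A1 = 0), up = c(COL1A1 = -2), dn = c(COL1A1 = 2))
  e2 <- suppressWarnings(fit_delta_ct_model(make_qpcr(em2), "COL1A1"))
  expect_equal(e2$fold_change[e2$chemical == "up"] *
                 e2$fold_change[e2$chemical == "dn"], 1, tolerance = 1e-9)
})

test_that("chemical coefficients are invariant to a global Ct shift", {
  em <- rbind(DMSO = c(COL1A1 = 0), chemX = c(COL1A1 = 1.5))
  q <- make_qpcr(em, noise_sd = 0.2, seed = 4)
  q2 <- q
  q2$ct_target <- q2$ct_target + 7
  e1 <- fit_delta_ct_model(q, "COL1A1")
  e2 <- fit_delta_ct_model(q2, "COL1A1")
  expect_equal(e1$delta_ct_estimate, e2$delta_ct_estimate, tolerance = 1e-10)
  expect_equal(e1$p_value, e2$p_value, tolerance = 1e-8)
})

test_that("single-plate data drop the plate term and confounding is caught", {
  em <- rbind(DMSO = c(COL1A1 = 0), chemX = c(COL1A1 = 1))
  q1 <- make_qpcr(em, noise_sd = 0.1, n_plates = 1, plate_effect_sd = 0)
  expect_silent(e <- fit_delta_ct_model(q1, "COL1A1"))
  expect_equal(e$delta_ct_estimate, 1, tolerance = 0.2)

  # chemical perfectly confounded with plate
  q <- make_qpcr(em, noise_sd = 0.1)
  q$plate_id <- ifelse(q$chemical == "chemX", "plateA", "plateB")
  expect_error(fit_delta_ct_model(q, "COL1A1"), "confounded.*chemX")
})

test_that("single-replicate chemicals are flagged without a p-value", {
  em <- rbind(DMSO = c(COL1A1 = 0), chemX = c(COL1A1 = 1),
              chemZ = c(COL1A1 = 2))
  q <- make_qpcr(em, noise_sd = 0.1, seed = 9)
  q <- rbind(q[q$chemical != "chemZ", ], q[q$chemical == "chemZ", ][1, ])
  expect_warning(e <- fit_delta_ct_model(q, "COL1A1"), "single replicate")
  expect_true(is.na(e$p_value[e$chemical == "chemZ"]))
  expect_false(is.na(e$delta_ct_estimate[e$chemical == "chemZ"]))
})

test_that("BH adjustment reproduces hand computations and its invariants", {
  eff <- data.frame(chemical = paste0("c", 1:4), gene = "COL1A1",
                    p_value = c(0.01, 0.02, 0.03, 0.04))
  out <- apply_fdr(eff)
  expect_equal(out$fdr, rep(0.04, 4))
  one <- apply_fdr(data.frame(chemical = "c", gene = "g", p_value = 0.01))
  expect_equal(one$fdr, 0.01)
  allone <- apply_fdr(data.frame(chemical = paste0("c", 1:5), gene = "g",
                                 p_value = rep(1, 5)))
  expect_equal(allone$fdr, rep(1, 5))
  # fdr >= p, bounded by 1, monotone in sorted p
  set.seed(8)
  r <- apply_fdr(data.frame(chemical = paste0("c", 1:50), gene = "g",
                            p_value = stats::runif(50)))
  expect_true(all(r$fdr >= r$p_value & r$fdr <= 1))
  o <- order(r$p_value)
  expect_true(all(diff(r$fdr[o]) >= -1e-12))
})

test_that("advancement requires all three criteria", {
  mk <- function(fc, fdr) data.frame(chemical = "X", gene = "g",
                                     fold_change = fc, fdr = fdr)
  ok <- advancement(mk(0.3, 0.01), mk(0.3, 0.01), c(X = 1.0))
  expect_true(ok$advanced)
  # ACTA2 fold change too high
  no2 <- advancement(mk(0.3, 0.01), mk(0.6, 0.01), c(X = 1.0))
  expect_false(no2$advanced)
  expect_true(no2$pass_col1a1); expect_false(no2$pass_acta2)
  # reference gene outside the window
  no3 <- advancement(mk(0.3, 0.01), mk(0.3, 0.01), c(X = 0.1))
  expect_false(no3$advanced); expect_false(no3$pass_psmb2_window)
  # boundary: FDR must be strictly below the cutoff
  no4 <- advancement(mk(0.3, 0.05), mk(0.3, 0.01), c(X = 1.0))
  expect_false(no4$advanced)
  expect_error(advancement(mk(0.3, 0.01), mk(0.3, 0.01), c(Y = 1)),
               "incomplete input")
})

test_that("reference-gene ranking recovers a planted stable gene", {
  set.seed(21)
  n_gene <- 18
  conds <- 8
  expr <- matrix(stats::rnorm(n_gene * conds, mean = 8, sd = 0.5),
                 nrow = n_gene,
                 dimnames = list(sprintf("G%02d", 1:n_gene), NULL))
  # planted stable gene: tiny SD, no group shift
  expr["G07", ] <- 8 + stats::rnorm(conds, 0, 0.02)
  # a gene that is flat but shifts between groups (fails stage 2)
  expr["G03", ] <- c(rep(8, 4), rep(8.4, 4)) + stats::rnorm(conds, 0, 0.02)
  ranked <- rank_reference_genes(expr, activated_cols = 1:4,
                                 inactivated_cols = 5:8)
  expect_equal(ranked$gene[1], "G07")
  expect_false("G03" %in% ranked$gene)
  # constant gene dominates by construction
  expr["G01", ] <- 8
  ranked2 <- rank_reference_genes(expr, 1:4, 5:8)
  expect_equal(ranked2$gene[1], "G01")
  expect_equal(ranked2$sd[1], 0)
  # SD above the stage-1 cutoff is excluded even with fold change 1
  expr3 <- rbind(S = c(8, 8.2, 7.8, 8, 8.2, 7.8, 8, 8.05))
  expect_warning(r3 <- rank_reference_genes(expr3, 1:4, 5:8), "no reference")
  expect_equal(nrow(r3), 0L)
})

test_that("Ct-level ranking orders genes by standard deviation", {
  ct <- data.frame(gene = rep(c("PSMB2", "GAPDH", "GUSB"), each = 6),
                   ct = c(20 + stats::rnorm(6, 0, 0.05),
                          18 + stats::rnorm(6, 0, 0.8),
                          22 + stats::rnorm(6, 0, 0.3)))
  r <- rank_by_ct_sd(ct)
  expect_equal(r$gene[1], "PSMB2")
  expect_true(all(diff(r$ct_sd) >= 0))
})

test_that("reference relative expression tracks a planted reference-gene shift", {
  # build a Ct table directly: chemical Z halves PSMB2 expression (+1 Ct)
  d <- expand.grid(plate_id = c("p1", "p2"), rep = 1:4,
                   chemical = c("DMSO", "Z"), stringsAsFactors = FALSE)
  d$ct_ref <- 20 + ifelse(d$plate_id == "p2", 0.3, 0) + ifelse(d$chemical == "Z", 1, 0)
  rel <- reference_relative_expression(d)
  expect_equal(unname(rel["Z"]), 0.5, tolerance = 1e-9)
})
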