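# Secondary qPCR screen: per-gene delta-Ct linear models with the
# reference-gene Ct as a continuous covariate and plate/chemical as
# categorical effects, fold changes versus the DMSO reference level,
# BH-FDR, the three advancement criteria, and reference-gene ranking.

#' Fit the delta-Ct linear model for one target gene
#'
#' Ordinary least squares of
#' `ct_target ~ ct_ref + plate + chemical`, with DMSO as the reference
#' level of `chemical`, so each chemical's coefficient is its delta-Ct
#' versus DMSO on the same plate at matched reference-gene signal. With a
#' single plate the plate term is dropped. Fold change is
#' `efficiency^(-delta_ct)`.
#'
#' @param measurements data.frame with `plate_id`, `chemical`, `gene`,
#'   `ct_target`, `ct_ref`.
#' @param gene Target gene symbol to fit.
#' @param efficiency Amplification efficiency (default 2).
#' @return data.frame, one row per non-DMSO chemical: `chemical`, `gene`,
#'   `delta_ct_estimate`, `fold_change`, `p_value`, `n_replicates`.
#'   Chemicals with a single replicate are flagged: coefficient reported,
#'   `p_value` set `NA`.
#' @export
fit_delta_ct_model <- function(measurements, gene, efficiency = 2) {
  d <- measurements[measurements$gene == gene, , drop = FALSE]
  if (nrow(d) == 0L) stop("no measurements for gene ", gene)
  if (!"DMSO" %in% d$chemical) stop("DMSO reference level missing for gene ", gene)
  d$chemical <- stats::relevel(factor(d$chemical), ref = "DMSO")
  multi_plate <- length(unique(d$plate_id)) > 1L
  form <- if (multi_plate) ct_target ~ ct_ref + factor(plate_id) + chemical
          else ct_target ~ ct_ref + chemical
  fit <- stats::lm(form, data = d)
  if (any(is.na(stats::coef(fit)))) {
    al <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    al <- sub("^chemical", "", al[grepl("^chemical", al)])
    stop("confounded design: chemical(s) aliased with plate: ",
         paste(al, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  rows <- grep("^chemical", rownames(sm))
  chem <- sub("^chemical", "", rownames(sm)[rows])
  n_rep <- as.integer(table(d$chemical)[chem])
  out <- data.frame(
    chemical = chem, gene = gene,
    delta_ct_estimate = sm[rows, "Estimate"],
    fold_change = efficiency^(-sm[rows, "Estimate"]),
    p_value = ifelse(n_rep >= 2L, sm[rows, "Pr(>|t|)"], NA_real_),
    n_replicates = n_rep,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (any(n_rep < 2L)) {
    warning("chemical(s) with a single replicate flagged (no p-value): ",
            paste(chem[n_rep < 2L], collapse = ", "))
  }
  out
}

#' Benjamini-Hochberg FDR within gene
#'
#' @param effects data.frame from [fit_delta_ct_model()] (may contain
#'   several genes stacked).
#' @return `effects` with an `fdr` column, adjusted across chemicals
#'   within each gene.
#' @export
apply_fdr <- function(effects) {
  effects$fdr <- NA_real_
  for (g in unique(effects$gene)) {
    idx <- which(effects$gene == g)
    effects$fdr[idx] <- stats::p.adjust(effects$p_value[idx], method = "BH")
  }
  effects
}

#' Plate-adjusted relative expression of the reference gene
#'
#' Fits `ct_ref ~ plate + chemical` (DMSO reference level) and converts
#' each chemical's coefficient to relative expression
#' `efficiency^(-delta_ct)`; used for the reference-gene stability window
#' of the advancement criteria.
#'
#' @param measurements data.frame with `plate_id`, `chemical`, `ct_ref`
#'   (rows may repeat across genes; duplicates by plate/well are fine).
#' @param efficiency Amplification efficiency (default 2).
#' @return Named numeric vector of relative expression per chemical.
#' @export
reference_relative_expression <- function(measurements, efficiency = 2) {
  d <- measurements
  if (!"DMSO" %in% d$chemical) stop("DMSO reference level missing")
  d$chemical <- stats::relevel(factor(d$chemical), ref = "DMSO")
  form <- if (length(unique(d$plate_id)) > 1L) ct_ref ~ factor(plate_id) + chemical
          else ct_ref ~ chemical
  fit <- stats::lm(form, data = d)
  cf <- stats::coef(fit)
  rows <- grep("^chemical", names(cf))
  stats::setNames(efficiency^(-cf[rows]), sub("^chemical", "", names(cf)[rows]))
}

#' Advancement decision for the secondary screen
#'
#' A chemical advances when all three criteria hold: COL1A1 fold change
#' below `fc_cutoff` with FDR below `fdr_cutoff`; ACTA2 fold change below
#' `fc_cutoff` with FDR below `fdr_cutoff`; and reference-gene (PSMB2)
#' relative expression within `ref_window` of DMSO.
#'
#' @param col1a1,acta2 Per-chemical effect tables (with `fdr`) for the two
#'   target genes, from [fit_delta_ct_model()] + [apply_fdr()].
#' @param psmb2_relative Named vector from
#'   [reference_relative_expression()].
#' @param fc_cutoff Fold-change cutoff (default 0.5).
#' @param fdr_cutoff FDR cutoff (default 0.05).
#' @param ref_window Allowed reference-gene window (default `c(0.2, 2)`).
#' @return data.frame per chemical: `chemical`, `pass_col1a1`,
#'   `pass_acta2`, `pass_psmb2_window`, `advanced`.
#' @export
advancement <- function(col1a1, acta2, psmb2_relative,
                        fc_cutoff = 0.5, fdr_cutoff = 0.05,
                        ref_window = c(0.2, 2.0)) {
  chems <- union(col1a1$chemical, acta2$chemical)
  missing_ref <- setdiff(chems, names(psmb2_relative))
  if (length(missing_ref)) {
    stop("incomplete input: no reference-gene expression for ",
         paste(missing_ref, collapse = ", "))
  }
  pass_gene <- function(tab, chem) {
    i <- match(chem, tab$chemical)
    !is.na(i) & tab$fold_change[i] < fc_cutoff &
      !is.na(tab$fdr[i]) & tab$fdr[i] < fdr_cutoff
  }
  p1 <- pass_gene(col1a1, chems)
  p2 <- pass_gene(acta2, chems)
  pr <- psmb2_relative[chems] >= ref_window[1] & psmb2_relative[chems] <= ref_window[2]
  data.frame(
    chemical = chems, pass_col1a1 = p1, pass_acta2 = p2,
    pass_psmb2_window = unname(pr), advanced = p1 & p2 & unname(pr),
    stringsAsFactors = FALSE
  )
}

#' Rank reference-gene candidates from an expression matrix
#'
#' Two-stage screen for a stable housekeeping gene: stage 1 keeps genes
#' whose across-condition standard deviation of log2 expression is at
#' most `sd_cutoff`; stage 2 keeps genes whose fold change between the
#' inactivated and activated condition groups differs from 1 by at most
#' `fc_cutoff`. Survivors are ranked by SD ascending.
#'
#' @param expression Numeric matrix, genes x conditions, log2 scale.
#' @param activated_cols,inactivated_cols Column indices or names of the
#'   two condition groups.
#' @param sd_cutoff Stage-1 SD cutoff (default 0.15).
#' @param fc_cutoff Stage-2 fold-change tolerance (default 0.10).
#' @return data.frame of survivors ranked by SD: `gene`, `sd`,
#'   `fold_change`. Empty (with a warning) when no gene survives.
#' @export
rank_reference_genes <- function(expression, activated_cols, inactivated_cols,
                                 sd_cutoff = 0.15, fc_cutoff = 0.10) {
  if (ncol(expression) < 2L) stop("need at least two conditions")
  sds <- apply(expression, 1, stats::sd)
  fc <- 2^(rowMeans(expression[, inactivated_cols, drop = FALSE]) -
             rowMeans(expression[, activated_cols, drop = FALSE]))
  keep <- sds <= sd_cutoff & abs(fc - 1) <= fc_cutoff
  out <- data.frame(gene = rownames(expression), sd = sds, fold_change = fc,
                    stringsAsFactors = FALSE, row.names = NULL)[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no reference-gene candidate survives the cutoffs")
    return(out)
  }
  out[order(out$sd), , drop = FALSE]
}

#' Rank reference-gene candidates by Ct standard deviation
#'
#' Final-stage ranking on measured Ct values: lower SD across samples
#' means a more stable reference gene.
#'
#' @param ct_table data.frame with `gene` and `ct` columns.
#' @return data.frame `gene`, `ct_sd`, ranked ascending.
#' @export
rank_by_ct_sd <- function(ct_table) {
  sds <- tapply(ct_table$ct, ct_table$gene, stats::sd)
  out <- data.frame(gene = names(sds), ct_sd = as.numeric(sds),
                    stringsAsFactors = FALSE)
  out[order(out$ct_sd), , drop = FALSE]
}
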