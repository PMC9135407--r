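# Orchestrates the triage cascade: score -> call hits -> consolidate ->
# cluster -> representative selection -> liability filters -> (optional)
# secondary qPCR decisions -> (optional) dose-response scoring, with a
# manifest of counts and exclusion reasons at every stage.

#' Run the compound-triage cascade
#'
#' Chains the pipeline stages over one plate table and compound library.
#' Later stages run only when their inputs are supplied. Every stage's
#' output and every exclusion reason is kept, and the manifest records
#' the count at each step.
#'
#' @param plates Per-well table (see [score_screen()]).
#' @param library_df data.frame mapping `compound_id` to `smiles` (one
#'   row per screened compound).
#' @param ct_table Optional qPCR table (see [fit_delta_ct_model()]) with
#'   target genes `COL1A1` and `ACTA2`; chemicals must be compound ids.
#' @param drc_tables Optional named list of dose-response series (%CTL
#'   `response`, `concentration`, `cell_count`, attribute
#'   `dmso_cell_count`), one per compound.
#' @param config List of stage parameters; recognized entries (with
#'   defaults): `cutoff` (0.85), `rescue_top_k` (3), `w_tox`, `w_rep`
#'   (1), `cluster_mode` ("threshold"), `cluster_param` (0.6),
#'   `central_fraction` (0.5), `pains` (packaged catalog), `history`
#'   (NULL), `exclude_reference_like` (FALSE), `reference_smiles`
#'   (nortriptyline), `reference_tau` (0.6), `include_ids`,
#'   `exclude_ids` (explicit manual curation lists, NULL), `seed` (1).
#' @return List of class `triage_manifest`: `manifest` (stage/count
#'   data.frame), `stages` (per-stage tables), `config`, `seed`,
#'   `versions`.
#' @export
run_cascade <- function(plates, library_df, ct_table = NULL,
                        drc_tables = NULL, config = list()) {
  cfg <- utils::modifyList(list(
    cutoff = 0.85, rescue_top_k = 3, w_tox = 1, w_rep = 1,
    cluster_mode = "threshold", cluster_param = 0.6,
    central_fraction = 0.5, pains = NULL, history = NULL,
    exclude_reference_like = FALSE,
    reference_smiles = nortriptyline_smiles(), reference_tau = 0.6,
    include_ids = NULL, exclude_ids = NULL, seed = 1L
  ), config)
  stages <- list()
  counts <- list()

  # stage 1: score + hit calling
  scores <- score_screen(plates, w_tox = cfg$w_tox, w_rep = cfg$w_rep)
  counts$wells_screened <- sum(plates$role == "experimental")
  if (nrow(scores) == 0L) {
    counts$hit_wells <- 0L
    counts$unique_hit_compounds <- 0L
    manifest <- data.frame(stage = names(counts),
                           count = unlist(counts, use.names = FALSE),
                           stringsAsFactors = FALSE)
    return(structure(list(manifest = manifest, stages = stages,
                          config = cfg, seed = cfg$seed,
                          versions = cascade_versions()),
                     class = "triage_manifest"))
  }
  hits <- call_hits(scores, cutoff = cfg$cutoff, rescue_top_k = cfg$rescue_top_k)
  stages$scores <- hits
  counts$hit_wells <- 2L * sum(hits$is_hit)

  # stage 2: consolidation on standardized structures
  m <- match(hits$compound_id, library_df$compound_id)
  if (anyNA(m)) {
    stop("schema mismatch at consolidation: compounds without library ",
         "structures: ", paste(utils::head(hits$compound_id[is.na(m)], 5),
                               collapse = ", "))
  }
  std <- standardize_smiles(library_df$smiles, library_df$compound_id)
  rec <- data.frame(
    compound_id = hits$compound_id,
    smiles_canonical = std$smiles_canonical[m],
    molecular_formula = std$molecular_formula[m],
    plate_id = hits$plate_id, scaled = hits$scaled, is_hit = hits$is_hit,
    stringsAsFactors = FALSE
  )
  compounds <- consolidate(rec)
  stages$compounds <- compounds
  hit_compounds <- compounds[compounds$is_hit, , drop = FALSE]
  counts$unique_hit_compounds <- nrow(hit_compounds)

  if (nrow(hit_compounds) == 0L) {
    manifest <- data.frame(stage = names(counts),
                           count = unlist(counts, use.names = FALSE))
    return(structure(list(manifest = manifest, stages = stages,
                          config = cfg, seed = cfg$seed,
                          versions = cascade_versions()),
                     class = "triage_manifest"))
  }

  # stage 3: clustering + representatives
  clusters <- cluster_hits(hit_compounds, mode = cfg$cluster_mode,
                           param = cfg$cluster_param)
  stages$clusters <- clusters
  counts$clusters <- length(unique(clusters$cluster_id))
  reps <- vapply(split(clusters, clusters$cluster_id), select_representative,
                 "", central_fraction = cfg$central_fraction)
  rep_tab <- hit_compounds[match(reps, hit_compounds$compound_id), , drop = FALSE]
  counts$representatives <- nrow(rep_tab)

  # stage 4: liability filters on representatives
  pains <- cfg$pains %||% load_pains()
  filt <- filter_liabilities(rep_tab, pains = pains, history = cfg$history)
  if (isTRUE(cfg$exclude_reference_like)) {
    rs <- filter_reference_similarity(filt[filt$kept, , drop = FALSE],
                                      ref_smiles = cfg$reference_smiles,
                                      tau = cfg$reference_tau)
    drop_ids <- rs$compound_id[!rs$kept]
    filt$kept[filt$compound_id %in% drop_ids] <- FALSE
    filt$reason[filt$compound_id %in% drop_ids] <- "reference_similarity"
  }
  dd <- dedup_by_formula(filt[filt$kept, , drop = FALSE])
  filt$kept[filt$compound_id %in% dd$compound_id[!dd$kept]] <- FALSE
  filt$reason[filt$compound_id %in% dd$compound_id[!dd$kept]] <- "formula_duplicate"
  if (!is.null(cfg$exclude_ids)) {
    sel <- filt$kept & filt$compound_id %in% cfg$exclude_ids
    filt$kept[sel] <- FALSE
    filt$reason[sel] <- "manual_exclusion"
  }
  stages$filtered <- filt
  selected <- filt$compound_id[filt$kept]
  if (!is.null(cfg$include_ids)) {
    extra <- setdiff(cfg$include_ids, selected)
    selected <- c(selected, extra)
    stages$manual_additions <- extra
  }
  counts$selected_after_filters <- length(selected)

  # stage 5: secondary qPCR advancement
  if (!is.null(ct_table)) {
    col1 <- apply_fdr(fit_delta_ct_model(ct_table, "COL1A1"))
    acta <- apply_fdr(fit_delta_ct_model(ct_table, "ACTA2"))
    psmb <- reference_relative_expression(ct_table[ct_table$gene == "COL1A1", ])
    adv <- advancement(col1, acta, psmb)
    stages$advancement <- adv
    counts$advanced_after_qpcr <- sum(adv$advanced)
  }

  # stage 6: dose-response scoring
  if (!is.null(drc_tables)) {
    drc_scores <- vapply(drc_tables, function(s) {
      kept <- exclude_toxic(s)
      fit <- fit_4pl(kept)
      score_drc(s, fit, nearest = TRUE)$priority
    }, 0L)
    stages$drc_priorities <- drc_scores
    counts$passing_drc <- sum(drc_scores <= 2L)
  }

  manifest <- data.frame(stage = names(counts),
                         count = unlist(counts, use.names = FALSE),
                         stringsAsFactors = FALSE)
  structure(list(manifest = manifest, stages = stages, config = cfg,
                 seed = cfg$seed, versions = cascade_versions()),
            class = "triage_manifest")
}

cascade_versions <- function() {
  c(hscTriage = as.character(utils::packageVersion("hscTriage")),
    ChemmineOB = as.character(utils::packageVersion("ChemmineOB")),
    R = paste(R.version$major, R.version$minor, sep = "."))
}

#' @export
print.triage_manifest <- function(x, ...) {
  cat("Triage cascade manifest (seed ", x$seed, "):\n", sep = "")
  for (i in seq_len(nrow(x$manifest))) {
    cat(sprintf("  %-24s %d\n", x$manifest$stage[i], x$manifest$count[i]))
  }
  invisible(x)
}
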