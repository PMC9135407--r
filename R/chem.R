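# Structure standardization, fingerprints, clustering and liability
# filters. All structure handling goes through Open Babel (ChemmineOB);
# the canonical SMILES dialect is therefore Open Babel's, fixed within a
# run. Cross-toolkit string equality is not promised, only within-run
# consistency and equivalence-class correctness.

ob_convert <- function(smiles,
                       options = data.frame(names = character(),
                                            args = character())) {
  input <- paste0(smiles, "\tm\n")
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", input,
                                               options = options)),
    error = function(e) ""
  )
  if (!nzchar(out)) return(NA_character_)
  strsplit(sub("\n$", "", out), "\t")[[1]][1]
}

mol_props <- function(smiles) {
  refs <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", paste0(smiles, "\tm\n"),
                                            identity)),
    error = function(e) NULL
  )
  if (is.null(refs) || length(refs) == 0L) return(NULL)
  ChemmineOB::prop_OB(refs[[1]])
}

ob_mol <- function(smiles) {
  refs <- ChemmineOB::forEachMol("SMILES", paste0(smiles, "\tm\n"), identity)
  refs[[1]]
}

# Heavy (non-hydrogen) atom count from a Hill-order formula string.
heavy_atom_count <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)(\\d*)", formula))[[1]]
  n <- 0L
  for (t in toks) {
    el <- sub("\\d+$", "", t)
    cnt <- sub("^[A-Za-z]+", "", t)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (el != "H") n <- n + cnt
  }
  n
}

#' Standardize and canonicalize SMILES
#'
#' Removes counterions (keeps the fragment with the most heavy atoms,
#' ties broken by lexicographically smallest canonical SMILES), applies
#' Open Babel's charge neutralization as the fixed protonation
#' normalization, and emits the canonical SMILES and Hill-order molecular
#' formula of the standardized structure. Records differing only by
#' counterions or protonation state map to identical canonical strings.
#'
#' @param smiles Character vector of raw SMILES.
#' @param compound_id Identifiers (default `names(smiles)` or an index).
#' @return data.frame with `compound_id`, `smiles_raw`, `smiles_canonical`,
#'   `molecular_formula`.
#' @export
standardize_smiles <- function(smiles, compound_id = NULL) {
  if (is.null(compound_id)) {
    compound_id <- if (!is.null(names(smiles))) names(smiles)
                   else as.character(seq_along(smiles))
  }
  stopifnot(length(compound_id) == length(smiles))
  can <- character(length(smiles))
  form <- character(length(smiles))
  for (i in seq_along(smiles)) {
    s <- trimws(smiles[i])
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    if (length(frags) > 1L) {
      fr_can <- vapply(frags, ob_convert, "")
      if (anyNA(fr_can)) {
        stop("parse error in record ", compound_id[i], ": ", smiles[i])
      }
      fr_heavy <- vapply(fr_can, function(x) {
        p <- mol_props(x)
        if (is.null(p)) return(NA_integer_)
        heavy_atom_count(p$formula)
      }, 0L)
      keep <- which(fr_heavy == max(fr_heavy))
      if (length(keep) > 1L) keep <- keep[order(fr_can[keep])][1]
      s <- frags[keep]
    }
    neutral <- ob_convert(s, options = data.frame(names = "neutralize", args = "",
                                                  stringsAsFactors = FALSE))
    if (is.na(neutral)) {
      stop("parse error in record ", compound_id[i], ": ", smiles[i])
    }
    p <- mol_props(neutral)
    if (is.null(p)) stop("parse error in record ", compound_id[i], ": ", smiles[i])
    can[i] <- p$cansmi
    form[i] <- p$formula
  }
  data.frame(compound_id = compound_id, smiles_raw = smiles,
             smiles_canonical = can, molecular_formula = form,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Consolidate well-level records into unique compounds
#'
#' Groups records by standardized canonical SMILES: one output row per
#' unique structure, aggregating wells, keeping hit status if any
#' constituent well is a hit, and the maximum Scaled value.
#'
#' @param records data.frame with `compound_id`, `smiles_canonical`,
#'   `molecular_formula`, and optionally `plate_id`, `well_id`, `scaled`,
#'   `is_hit`.
#' @return data.frame with one row per unique canonical structure:
#'   `compound_id` (first member id in sort order), `smiles_canonical`,
#'   `molecular_formula`, `member_ids` (semicolon-joined), `n_wells`,
#'   `best_scaled`, `is_hit`.
#' @export
consolidate <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(compound_id = character(), smiles_canonical = character(),
                      molecular_formula = character(), member_ids = character(),
                      n_wells = integer(), best_scaled = numeric(),
                      is_hit = logical(), stringsAsFactors = FALSE))
  }
  sp <- split(records, records$smiles_canonical)
  out <- lapply(sp, function(d) {
    ids <- sort(unique(d$compound_id))
    data.frame(
      compound_id = ids[1],
      smiles_canonical = d$smiles_canonical[1],
      molecular_formula = d$molecular_formula[1],
      member_ids = paste(ids, collapse = ";"),
      n_wells = nrow(d),
      best_scaled = if ("scaled" %in% names(d)) max(d$scaled) else NA_real_,
      is_hit = if ("is_hit" %in% names(d)) any(d$is_hit) else NA,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  res <- res[order(res$compound_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Circular (ECFP4) fingerprints
#'
#' Open Babel extended-connectivity fingerprints of radius 2 over 4096
#' bits, as a binary matrix.
#'
#' @param smiles Character vector of (canonical) SMILES.
#' @return Integer matrix, one row per molecule, 4096 columns; rownames
#'   are `names(smiles)` when present.
#' @export
ecfp_fingerprints <- function(smiles) {
  fps <- t(vapply(smiles, function(s) {
    as.integer(ChemmineOB::fingerprint_OB(list(ob_mol(s)), "ECFP4") > 0)
  }, integer(4096)))
  rownames(fps) <- names(smiles)
  fps
}

#' Tanimoto distance matrix from binary fingerprints
#'
#' Distance = 1 - (intersection / union) of on-bits; two all-zero
#' fingerprints have distance 0.
#'
#' @param fps Binary fingerprint matrix (rows = molecules).
#' @return Symmetric distance matrix.
#' @export
tanimoto_distance <- function(fps) {
  inter <- tcrossprod(fps)
  on <- rowSums(fps)
  un <- outer(on, on, "+") - inter
  sim <- ifelse(un == 0, 1, inter / un)
  d <- 1 - sim
  dimnames(d) <- list(rownames(fps), rownames(fps))
  d
}

# Leader-style sphere exclusion on a precomputed distance matrix, in the
# given row order: the first unassigned molecule becomes a leader and
# captures every unassigned molecule within `threshold` of it.
sphere_exclusion <- function(dmat, threshold) {
  n <- nrow(dmat)
  assigned <- integer(n)
  leaders <- integer(0)
  k <- 0L
  for (i in seq_len(n)) {
    if (assigned[i] > 0L) next
    k <- k + 1L
    leaders[k] <- i
    free <- which(assigned == 0L)
    assigned[free[dmat[i, free] <= threshold]] <- k
  }
  list(assignment = assigned, leaders = leaders)
}

#' Cluster hit compounds by Tanimoto distance
#'
#' Deterministic sphere-exclusion (leader) clustering: compounds are
#' processed in descending `best_scaled` order (ties by id); each leader
#' captures all unassigned compounds within the threshold. In
#' `mode = "target_k"` the threshold is found by bisection so the cluster
#' count equals (or is nearest to) `param`.
#'
#' @param compounds data.frame with `compound_id`, `best_scaled`, and
#'   `smiles_canonical` (used when `fps` is not supplied).
#' @param mode `"threshold"` (param = Tanimoto distance radius) or
#'   `"target_k"` (param = desired number of clusters).
#' @param param Threshold in `[0, 1]`, or target cluster count.
#' @param fps Optional precomputed fingerprint matrix (rows in any order,
#'   rownames = compound ids).
#' @return data.frame with one row per compound: `compound_id`,
#'   `cluster_id`, `leader_id` (sphere center, radius bound holds),
#'   `center_id` (member minimizing mean Tanimoto distance to the
#'   cluster), `dist_to_leader`, `mean_dist`, `best_scaled`. The realized
#'   threshold is attached as attribute `"threshold"`.
#' @export
cluster_hits <- function(compounds, mode = c("threshold", "target_k"),
                         param, fps = NULL) {
  mode <- match.arg(mode)
  ord <- order(-compounds$best_scaled, compounds$compound_id)
  compounds <- compounds[ord, , drop = FALSE]
  if (is.null(fps)) {
    smi <- compounds$smiles_canonical
    names(smi) <- compounds$compound_id
    fps <- ecfp_fingerprints(smi)
  } else {
    fps <- fps[compounds$compound_id, , drop = FALSE]
  }
  dmat <- tanimoto_distance(fps)
  n <- nrow(compounds)

  if (mode == "target_k") {
    k_target <- as.integer(param)
    if (k_target > n) stop("infeasible: target_k exceeds number of compounds")
    n_clusters <- function(thr) length(sphere_exclusion(dmat, thr)$leaders)
    lo <- 0; hi <- 1
    best_thr <- NA_real_; best_gap <- Inf
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      k <- n_clusters(mid)
      gap <- abs(k - k_target)
      if (gap < best_gap || (gap == best_gap && is.na(best_thr))) {
        best_gap <- gap; best_thr <- mid
      }
      if (k > k_target) lo <- mid else if (k < k_target) hi <- mid else break
    }
    threshold <- best_thr
  } else {
    threshold <- param
  }

  cl <- sphere_exclusion(dmat, threshold)
  res <- data.frame(
    compound_id = compounds$compound_id,
    cluster_id = cl$assignment,
    leader_id = compounds$compound_id[cl$leaders][cl$assignment],
    dist_to_leader = dmat[cbind(cl$leaders[cl$assignment], seq_len(n))],
    best_scaled = compounds$best_scaled,
    stringsAsFactors = FALSE
  )
  # centroid = member minimizing mean distance to the other members
  res$mean_dist <- NA_real_
  res$center_id <- NA_character_
  for (k in unique(res$cluster_id)) {
    idx <- which(res$cluster_id == k)
    md <- if (length(idx) == 1L) 0 else rowMeans(dmat[idx, idx, drop = FALSE])
    res$mean_dist[idx] <- md
    best <- idx[order(md, res$compound_id[idx])][1]
    res$center_id[idx] <- res$compound_id[best]
  }
  attr(res, "threshold") <- threshold
  res
}

#' Select a cluster's representative compound
#'
#' Operationalizes "strongest hit with the most common structure": among
#' the most-central members (mean Tanimoto distance within the central
#' `central_fraction` of the cluster), the one with the highest Scaled
#' value; ties broken by smaller mean distance, then id.
#'
#' @param cluster_members data.frame for one cluster with `compound_id`,
#'   `mean_dist`, `best_scaled` (as emitted by [cluster_hits()]).
#' @param central_fraction Fraction of members considered central
#'   (default 0.5).
#' @return The representative `compound_id`.
#' @export
select_representative <- function(cluster_members, central_fraction = 0.5) {
  stopifnot(nrow(cluster_members) >= 1L)
  if (nrow(cluster_members) == 1L) return(cluster_members$compound_id)
  cutoff <- stats::quantile(cluster_members$mean_dist, central_fraction,
                            names = FALSE)
  central <- cluster_members[cluster_members$mean_dist <= cutoff, , drop = FALSE]
  central <- central[order(-central$best_scaled, central$mean_dist,
                           central$compound_id), , drop = FALSE]
  central$compound_id[1]
}

#' Load a PAINS SMARTS catalog
#'
#' Reads a plain-text catalog (`SMARTS<TAB>name` per line, `#` comments).
#' The packaged default is a curated subset of the published pan-assay
#' interference families (quinones, catechols, rhodanines, azo dyes,
#' phenolic Mannich bases, ...); a full catalog in the same format can be
#' substituted.
#'
#' @param path Catalog file (default: packaged subset).
#' @return data.frame with `smarts`, `name`.
#' @export
load_pains <- function(path = system.file("extdata", "pains_subset.smarts",
                                          package = "hscTriage")) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  bad <- vapply(parts, length, 0L) < 2L
  if (any(bad)) stop("catalog error: malformed line(s): ",
                     paste(lines[bad], collapse = "; "))
  smarts <- vapply(parts, `[[`, "", 1L)
  balanced <- function(s, open, close) {
    v <- strsplit(s, "")[[1]]
    sum(v == open) == sum(v == close)
  }
  ok <- vapply(smarts, function(s) balanced(s, "[", "]") && balanced(s, "(", ")"),
               TRUE)
  if (any(!ok)) stop("catalog error: unbalanced SMARTS: ",
                     paste(smarts[!ok], collapse = "; "))
  data.frame(smarts = smarts, name = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Filter assay-interference and frequent-hitter liabilities
#'
#' Removes compounds that match any PAINS pattern, or whose screening
#' history shows a positive hit rate above `hit_rate_cutoff` (default
#' 20%) or more than `total_hits_cutoff` (default 10) total positive
#' hits. Without a history table no frequent-hitter removals occur.
#'
#' @param compounds data.frame with `compound_id` and `smiles_canonical`.
#' @param pains PAINS catalog from [load_pains()].
#' @param history Optional data.frame with `compound_id`, `n_screens`,
#'   `n_hits`.
#' @param hit_rate_cutoff,total_hits_cutoff Frequent-hitter thresholds.
#' @return `compounds` with added logical `kept` and character `reason`
#'   (`""`, `"PAINS:<pattern>"` or `"frequent_hitter"`).
#' @export
filter_liabilities <- function(compounds, pains = load_pains(), history = NULL,
                               hit_rate_cutoff = 0.20, total_hits_cutoff = 10) {
  reason <- rep("", nrow(compounds))
  for (i in seq_len(nrow(compounds))) {
    mol <- list(ob_mol(compounds$smiles_canonical[i]))
    for (j in seq_len(nrow(pains))) {
      if (ChemmineOB::smartsSearch_OB(mol, pains$smarts[j]) > 0) {
        reason[i] <- paste0("PAINS:", pains$name[j])
        break
      }
    }
  }
  if (!is.null(history)) {
    m <- match(compounds$compound_id, history$compound_id)
    rate <- history$n_hits[m] / history$n_screens[m]
    freq <- !is.na(m) & (rate > hit_rate_cutoff | history$n_hits[m] > total_hits_cutoff)
    reason[reason == "" & freq] <- "frequent_hitter"
  }
  compounds$kept <- reason == ""
  compounds$reason <- reason
  compounds
}

#' Remove compounds similar to a reference structure
#'
#' Optional exclusion filter: compounds with Tanimoto similarity to a
#' named reference structure at or above `tau` are removed (used in the
#' screen to drop a compound of the same class as the positive control).
#'
#' @param compounds data.frame with `compound_id`, `smiles_canonical`.
#' @param ref_smiles Reference structure (default nortriptyline).
#' @param tau Tanimoto similarity cutoff (default 0.6).
#' @return `compounds` with added `ref_similarity`, `kept`, `reason`.
#' @export
filter_reference_similarity <- function(compounds,
                                        ref_smiles = nortriptyline_smiles(),
                                        tau = 0.6) {
  smi <- c(ref = ref_smiles, structure(compounds$smiles_canonical,
                                       names = compounds$compound_id))
  fps <- ecfp_fingerprints(smi)
  d <- tanimoto_distance(fps)
  sim <- 1 - d[1, -1]
  compounds$ref_similarity <- unname(sim)
  compounds$kept <- sim < tau
  compounds$reason <- ifelse(compounds$kept, "", "reference_similarity")
  compounds
}

#' Deduplicate selected compounds by molecular formula
#'
#' Within each molecular-formula group keeps the compound with the
#' highest Scaled value (ties by id) and drops the rest.
#'
#' @param compounds data.frame with `compound_id`, `molecular_formula`,
#'   `best_scaled`.
#' @return `compounds` with added `kept` and `reason`
#'   (`"formula_duplicate"` for dropped rows).
#' @export
dedup_by_formula <- function(compounds) {
  kept <- rep(TRUE, nrow(compounds))
  for (f in unique(compounds$molecular_formula)) {
    idx <- which(compounds$molecular_formula == f)
    if (length(idx) > 1L) {
      best <- idx[order(-compounds$best_scaled[idx], compounds$compound_id[idx])][1]
      kept[setdiff(idx, best)] <- FALSE
    }
  }
  compounds$kept <- kept
  compounds$reason <- ifelse(kept, "", "formula_duplicate")
  compounds
}
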