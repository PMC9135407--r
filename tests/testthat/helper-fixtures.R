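# Fixture builders and independent oracle implementations used across
# the test files.

# Build a one-plate well table from percent-positive values (cells fixed
# at 1000 so counts carry the percentages exactly).
make_plate <- function(exp_pct_pairs, dmso_pct, nor_pct,
                       plate_id = "p1", cells = 1000,
                       exp_cells = NULL) {
  n <- length(exp_pct_pairs)
  if (is.null(exp_cells)) exp_cells <- rep(cells, n)
  rows <- list()
  for (i in seq_len(n)) {
    pcts <- exp_pct_pairs[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      plate_id = plate_id, well_id = sprintf("E%02d_%d", i, 1:2),
      role = "experimental", compound_id = sprintf("c%02d", i),
      replicate = 1:2, cell_count = exp_cells[i],
      positive_count = round(exp_cells[i] * pcts / 100),
      stringsAsFactors = FALSE
    )
  }
  rows[[length(rows) + 1L]] <- data.frame(
    plate_id = plate_id, well_id = sprintf("D%02d", seq_along(dmso_pct)),
    role = "dmso", compound_id = NA_character_, replicate = NA_integer_,
    cell_count = cells, positive_count = round(cells * dmso_pct / 100),
    stringsAsFactors = FALSE
  )
  rows[[length(rows) + 1L]] <- data.frame(
    plate_id = plate_id, well_id = sprintf("N%02d", seq_along(nor_pct)),
    role = "nortriptyline", compound_id = NA_character_, replicate = NA_integer_,
    cell_count = cells, positive_count = round(cells * nor_pct / 100),
    stringsAsFactors = FALSE
  )
  do.call(rbind, rows)
}

# Independent two-rule hit oracle: sorts and applies the cutoff rule and
# the top-k rescue rule separately, by explicit enumeration.
oracle_hits <- function(scaled, ids, cutoff = 0.85, k = 3) {
  hit_cut <- ids[scaled > cutoff]
  ord <- order(-scaled, ids)
  top_k <- ids[ord][seq_len(min(k, length(ids)))]
  is_hit <- ids %in% union(hit_cut, top_k)
  reason <- ifelse(ids %in% hit_cut, "scaled_cutoff",
                   ifelse(ids %in% top_k, "plate_top3", "none"))
  data.frame(compound_id = ids, is_hit = is_hit, reason = reason,
             stringsAsFactors = FALSE)
}

# Brute-force sphere-exclusion reference: pairwise Tanimoto computed
# bit-by-bit, leaders picked by explicit scan in score order.
oracle_sphere_exclusion <- function(fps, scaled, ids, threshold) {
  ord <- order(-scaled, ids)
  fps <- fps[ord, , drop = FALSE]
  ids <- ids[ord]
  n <- nrow(fps)
  tani_dist <- function(a, b) {
    inter <- sum(a == 1 & b == 1)
    uni <- sum(a == 1 | b == 1)
    if (uni == 0) 0 else 1 - inter / uni
  }
  cluster <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(cluster[i])) next
    k <- k + 1L
    cluster[i] <- k
    for (j in seq_len(n)) {
      if (is.na(cluster[j]) && tani_dist(fps[i, ], fps[j, ]) <= threshold) {
        cluster[j] <- k
      }
    }
  }
  stats::setNames(cluster, ids)
}

# Canonical representation of a partition for order-independent
# comparison: sorted list of sorted member-id groups.
partition_signature <- function(ids, cluster) {
  groups <- split(ids, cluster)
  groups <- lapply(groups, sort)
  paste(sort(vapply(groups, paste, "", collapse = ",")), collapse = "|")
}
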