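#' Percent Bodipy-positive cells in a well
#'
#' The primary screen's per-well readout: the number of cells whose
#' lipid-droplet stain exceeds the imaging threshold, divided by the total
#' cell count, as a percentage.
#'
#' @param positive_count Number of Bodipy-positive cells (non-negative).
#' @param cell_count Total cell count in the well (positive).
#' @return Numeric vector of percentages in `[0, 100]`. Wells with
#'   `cell_count == 0` return `NA` with a warning; they carry no usable
#'   ratio and are excluded from plate baselines downstream.
#' @examples
#' percent_positive(123, 400) # 30.75
#' @export
percent_positive <- function(positive_count, cell_count) {
  stopifnot(length(positive_count) == length(cell_count))
  if (any(positive_count < 0) || any(cell_count < 0)) {
    stop("counts must be non-negative")
  }
  if (any(positive_count > cell_count, na.rm = TRUE)) {
    stop("positive_count exceeds cell_count")
  }
  zero <- !is.na(cell_count) & cell_count == 0
  if (any(zero)) {
    warning(sum(zero), " well(s) with zero cell count flagged as NA")
  }
  out <- 100 * positive_count / cell_count
  out[zero] <- NA_real_
  out
}

#' Plate-normalized 'Scaled' value
#'
#' Maps a raw well score onto a control-anchored scale:
#' `Scaled = -(median_nor - score) / |median_nor - median_dmso|`,
#' so the nortriptyline (positive-control) score median sits at 0 and the
#' DMSO (negative-control) median at -1 when nortriptyline scores higher.
#'
#' @param score Raw score(s) in percent-positive units.
#' @param median_nor Plate median of nortriptyline well scores.
#' @param median_dmso Plate median of DMSO well scores.
#' @return Unitless scaled value(s), strictly increasing in `score`.
#' @export
scaled_value <- function(score, median_nor, median_dmso) {
  if (isTRUE(all.equal(median_nor, median_dmso))) {
    stop("degenerate plate: nortriptyline and DMSO score medians are equal")
  }
  -1 * (median_nor - score) / abs(median_nor - median_dmso)
}

# Score for a single (control) well: distance from the experimental baseline
# minus the toxicity penalty. No reproducibility term (controls are not
# duplicated per compound).
control_well_score <- function(pct, cells, p75, nor_cells_mean, w_tox = 1) {
  tox <- 100 * pmax(0, (nor_cells_mean - cells) / nor_cells_mean)
  (pct - p75) - w_tox * tox
}

#' Score the duplicate wells of one compound
#'
#' Combines the three components of the primary-screen score:
#' distance of the duplicate-mean percent-positive from the plate baseline
#' (75th percentile of experimental well means), a toxicity penalty
#' (one-sided relative cell-count deficit versus the nortriptyline mean,
#' in percent), and a reproducibility penalty (half the absolute
#' difference of the duplicates, i.e. their mean absolute deviation).
#'
#' @param pct Length-2 numeric, percent-positive of the two replicate wells.
#' @param cells Length-2 numeric, cell counts of the two replicate wells.
#' @param p75 Plate baseline: 75th percentile of experimental duplicate-mean
#'   percent-positive (linear interpolation).
#' @param nor_cells_mean Mean cell count of nortriptyline wells on the plate.
#' @param w_tox,w_rep Penalty weights (default 1).
#' @return A list with `mean_pct`, `baseline_distance`, `toxicity_penalty`,
#'   `reproducibility_penalty` and `score`.
#' @export
raw_score <- function(pct, cells, p75, nor_cells_mean, w_tox = 1, w_rep = 1) {
  if (length(pct) != 2L || any(is.na(pct))) {
    stop("incomplete duplicate: exactly two replicate percent-positive values required")
  }
  mean_pct <- mean(pct)
  baseline_distance <- mean_pct - p75
  toxicity_penalty <- 100 * max(0, (nor_cells_mean - mean(cells)) / nor_cells_mean)
  reproducibility_penalty <- abs(pct[1] - pct[2]) / 2
  list(
    mean_pct = mean_pct,
    baseline_distance = baseline_distance,
    toxicity_penalty = toxicity_penalty,
    reproducibility_penalty = reproducibility_penalty,
    score = baseline_distance - w_tox * toxicity_penalty - w_rep * reproducibility_penalty
  )
}

#' Score all plates of a primary screen
#'
#' Computes per-compound scores and plate-normalized Scaled values for a
#' per-well plate table. Each experimental compound must appear in exactly
#' two wells (duplicates) on one plate; DMSO and nortriptyline wells anchor
#' the normalization.
#'
#' @param wells data.frame with columns `plate_id`, `well_id`, `role`
#'   (`"experimental"`, `"dmso"` or `"nortriptyline"`), `compound_id`
#'   (`NA` for control wells), `cell_count`, `positive_count`.
#' @param w_tox,w_rep Penalty weights passed to [raw_score()].
#' @param baseline Which wells define the 75th-percentile baseline:
#'   `"experimental"` (default) or `"all"`.
#' @return data.frame with one row per compound: `compound_id`, `plate_id`,
#'   `mean_pct_positive`, `baseline_p75`, `baseline_distance`,
#'   `toxicity_penalty`, `reproducibility_penalty`, `score`, `scaled`.
#'   Plate control-score medians are attached as attribute
#'   `"plate_controls"`.
#' @export
score_screen <- function(wells, w_tox = 1, w_rep = 1,
                         baseline = c("experimental", "all")) {
  baseline <- match.arg(baseline)
  req <- c("plate_id", "well_id", "role", "compound_id", "cell_count", "positive_count")
  miss <- setdiff(req, names(wells))
  if (length(miss)) stop("wells table missing columns: ", paste(miss, collapse = ", "))

  wells$pct <- percent_positive(wells$positive_count, wells$cell_count)
  out <- list()
  ctrl <- list()
  for (pid in unique(wells$plate_id)) {
    pw <- wells[wells$plate_id == pid & !is.na(wells$pct), , drop = FALSE]
    exp_w <- pw[pw$role == "experimental", , drop = FALSE]
    nor_w <- pw[pw$role == "nortriptyline", , drop = FALSE]
    dmso_w <- pw[pw$role == "dmso", , drop = FALSE]
    if (nrow(nor_w) == 0L || nrow(dmso_w) == 0L) {
      stop("plate ", pid, ": both DMSO and nortriptyline control wells are required")
    }
    nor_cells_mean <- mean(nor_w$cell_count)

    # duplicate means per compound
    sp <- split(exp_w, exp_w$compound_id)
    if (length(sp) == 0L) next
    bad <- names(sp)[vapply(sp, nrow, 0L) != 2L]
    if (length(bad)) {
      stop("plate ", pid, ": compounds without exactly two replicate wells: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    mean_pcts <- vapply(sp, function(d) mean(d$pct), 0)
    p75 <- if (baseline == "experimental") {
      stats::quantile(mean_pcts, 0.75, names = FALSE)
    } else {
      stats::quantile(pw$pct, 0.75, names = FALSE)
    }

    comp <- do.call(rbind, lapply(names(sp), function(cid) {
      d <- sp[[cid]]
      s <- raw_score(d$pct, d$cell_count, p75, nor_cells_mean, w_tox, w_rep)
      data.frame(
        compound_id = cid, plate_id = pid,
        mean_pct_positive = s$mean_pct, baseline_p75 = p75,
        baseline_distance = s$baseline_distance,
        toxicity_penalty = s$toxicity_penalty,
        reproducibility_penalty = s$reproducibility_penalty,
        score = s$score, stringsAsFactors = FALSE
      )
    }))

    med_nor <- stats::median(control_well_score(nor_w$pct, nor_w$cell_count,
                                                p75, nor_cells_mean, w_tox))
    med_dmso <- stats::median(control_well_score(dmso_w$pct, dmso_w$cell_count,
                                                 p75, nor_cells_mean, w_tox))
    if (isTRUE(all.equal(med_nor, med_dmso))) {
      warning("plate ", pid, " flagged degenerate (equal control medians); wells excluded")
      next
    }
    comp$scaled <- scaled_value(comp$score, med_nor, med_dmso)
    ctrl[[as.character(pid)]] <- data.frame(
      plate_id = pid, median_nor = med_nor, median_dmso = med_dmso,
      baseline_p75 = p75, nor_cells_mean = nor_cells_mean,
      stringsAsFactors = FALSE
    )
    out[[as.character(pid)]] <- comp
  }
  if (length(out) == 0L) {
    res <- data.frame(compound_id = character(), plate_id = character(),
                      mean_pct_positive = numeric(), baseline_p75 = numeric(),
                      baseline_distance = numeric(), toxicity_penalty = numeric(),
                      reproducibility_penalty = numeric(), score = numeric(),
                      scaled = numeric(), stringsAsFactors = FALSE)
    attr(res, "plate_controls") <- NULL
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "plate_controls") <- do.call(rbind, ctrl)
  res
}

#' Call primary-screen hits
#'
#' Applies the two hit rules per plate: (1) Scaled value above a cutoff
#' (default 0.85, the value the screen derived as the top 10th percentile
#' of nortriptyline wells), and (2) a rescue rule keeping the top-k
#' experimental entries per plate by Scaled value regardless of the
#' cutoff, so every plate stays represented despite plate effects.
#'
#' @param scores data.frame from [score_screen()] (needs `compound_id`,
#'   `plate_id`, `scaled`).
#' @param cutoff Fixed Scaled cutoff (default 0.85). Ignored when
#'   `cutoff_mode = "nor_percentile"`.
#' @param rescue_top_k Number of per-plate top entries kept as hits
#'   (default 3).
#' @param cutoff_mode `"fixed"` (default) or `"nor_percentile"`, which
#'   derives each plate's cutoff as the 90th percentile of that plate's
#'   nortriptyline-well Scaled values; requires `nor_scaled`, a data.frame
#'   with columns `plate_id` and `scaled` for nortriptyline wells.
#' @param nor_scaled Optional per-plate nortriptyline Scaled values (see
#'   `cutoff_mode`).
#' @return `scores` with added columns `is_hit` (logical) and `reason`
#'   (`"scaled_cutoff"`, `"plate_top3"` or `"none"`).
#' @export
call_hits <- function(scores, cutoff = 0.85, rescue_top_k = 3,
                      cutoff_mode = c("fixed", "nor_percentile"),
                      nor_scaled = NULL) {
  cutoff_mode <- match.arg(cutoff_mode)
  res <- lapply(split(scores, scores$plate_id), function(d) {
    co <- cutoff
    if (cutoff_mode == "nor_percentile") {
      if (is.null(nor_scaled)) stop("nor_scaled required for nor_percentile mode")
      ns <- nor_scaled$scaled[nor_scaled$plate_id == d$plate_id[1]]
      if (!length(ns)) stop("no nortriptyline scaled values for plate ", d$plate_id[1])
      co <- stats::quantile(ns, 0.90, names = FALSE)
    }
    # deterministic rank: scaled descending, ties by compound id
    ord <- order(-d$scaled, d$compound_id)
    rank_in_plate <- integer(nrow(d))
    rank_in_plate[ord] <- seq_len(nrow(d))
    pass_cut <- d$scaled > co
    in_top <- rank_in_plate <= rescue_top_k
    d$is_hit <- pass_cut | in_top
    d$reason <- ifelse(pass_cut, "scaled_cutoff",
                       ifelse(in_top, "plate_top3", "none"))
    d
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
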