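# Synthetic-data generators for every input the triage pipeline consumes:
# per-well screen plates, multiplexed qPCR Ct tables, dose-response series,
# and PK / microsomal-depletion profiles. All draws are governed by a single
# seed per call so identical config + seed reproduces identical tables.

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

well_ids_384 <- function(n_rows = 16, n_cols = 24) {
  as.vector(t(outer(LETTERS[seq_len(n_rows)],
                    sprintf("%02d", seq_len(n_cols)), paste0)))
}

#' Configuration for the primary-screen simulator
#'
#' Defines the study conditions a simulated screen emulates: 384-well
#' plates carrying DMSO negative and nortriptyline positive control wells,
#' experimental compounds in duplicate, a minority of true actives with
#' graded percent-positive effects, compound-specific toxicity and
#' plate-to-plate shifts.
#'
#' @param n_plates Number of plates.
#' @param wells_per_plate Plate capacity (default 384).
#' @param n_dmso_per_plate,n_nor_per_plate Control wells per plate
#'   (default 16 each).
#' @param n_compounds_per_plate Experimental compounds per plate, each in
#'   duplicate (default 160, i.e. 320 experimental wells).
#' @param active_fraction Proportion of compounds that are true actives.
#' @param effect_size_range Range (length-2) of the percent-positive shift
#'   drawn uniformly for each active.
#' @param toxicity_fraction Proportion of compounds that are toxic.
#' @param toxicity_severity Proportional reduction of the expected cell
#'   count in toxic wells.
#' @param plate_shift_sd SD (percent-positive units) of the additive
#'   plate-level shift applied to every well on a plate.
#' @param count_mean Expected cells per well.
#' @param count_size Negative-binomial size (dispersion) of cell counts.
#' @param replicate_noise_sd Target SD of percent-positive across replicate
#'   wells, in percentage points.
#' @param dmso_mean_pct,dmso_sd Mean/SD of DMSO-well percent-positive.
#' @param nor_mean_pct,nor_sd Mean/SD of nortriptyline-well
#'   percent-positive; the default places nortriptyline near the top
#'   decile of experimental wells, mirroring how the screen anchored its
#'   cutoff.
#' @param positive_model `"betabinom"` (default): positive counts drawn
#'   beta-binomially given the cell count, with overdispersion calibrated
#'   so the percent-positive SD matches `replicate_noise_sd`;
#'   `"gaussian"`: percent-positive drawn normally (closed-form checks).
#' @param seed Integer seed fixing all draws.
#' @return An object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_plates = 10, wells_per_plate = 384,
                              n_dmso_per_plate = 16, n_nor_per_plate = 16,
                              n_compounds_per_plate = 160,
                              active_fraction = 0.05,
                              effect_size_range = c(10, 30),
                              toxicity_fraction = 0.05,
                              toxicity_severity = 0.5,
                              plate_shift_sd = 2,
                              count_mean = 1000, count_size = 1000,
                              replicate_noise_sd = 3,
                              dmso_mean_pct = 10, dmso_sd = 3,
                              nor_mean_pct = 18, nor_sd = 4,
                              positive_model = c("betabinom", "gaussian"),
                              seed = 1L) {
  positive_model <- match.arg(positive_model)
  props <- c(active_fraction, toxicity_fraction, toxicity_severity)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (length(effect_size_range) != 2L || diff(effect_size_range) < 0) {
    stop("effect_size_range must be an increasing pair")
  }
  n_used <- n_dmso_per_plate + n_nor_per_plate + 2L * n_compounds_per_plate
  if (n_used > wells_per_plate) {
    stop("layout error: ", n_used, " wells requested on a ",
         wells_per_plate, "-well plate")
  }
  structure(as.list(environment()), class = "screen_sim_config")
}

# Draw positive counts for wells with expected percent-positive mu_pct and
# target replicate SD sd_pct, given realized cell counts.
draw_positive <- function(cells, mu_pct, sd_pct, model) {
  if (model == "gaussian") {
    pct <- stats::rnorm(length(cells), mu_pct, sd_pct)
    pct <- pmin(pmax(pct, 0), 100)
    return(pmin(round(cells * pct / 100), cells))
  }
  p <- pmin(pmax(mu_pct / 100, 1e-4), 1 - 1e-4)
  s2 <- (sd_pct / 100)^2
  out <- integer(length(cells))
  for (i in seq_along(cells)) {
    n <- cells[i]
    if (n == 0L) { out[i] <- 0L; next }
    v_bin <- p[i] * (1 - p[i]) / n
    if (s2[i] <= v_bin || n == 1L) {
      out[i] <- stats::rbinom(1L, n, p[i])
    } else {
      rho <- (s2[i] * n / (p[i] * (1 - p[i])) - 1) / (n - 1)
      rho <- min(rho, 1 - 1e-8)
      a <- p[i] * (1 - rho) / rho
      b <- (1 - p[i]) * (1 - rho) / rho
      out[i] <- stats::rbinom(1L, n, stats::rbeta(1L, a, b))
    }
  }
  out
}

#' Simulate a primary lipid-accumulation screen
#'
#' @param config A [screen_sim_config()].
#' @return A list with `wells` (per-well table: `plate_id`, `well_id`,
#'   `role`, `compound_id`, `replicate`, `cell_count`, `positive_count`)
#'   and `truth` (per-compound: `compound_id`, `plate_id`, `active`,
#'   `effect`, `toxic`).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(config$seed, {
    wells_all <- list()
    truth_all <- list()
    ids <- well_ids_384()
    if (config$wells_per_plate > length(ids)) {
      ids <- sprintf("W%04d", seq_len(config$wells_per_plate))
    }
    for (p in seq_len(config$n_plates)) {
      pid <- sprintf("plate%02d", p)
      shift <- stats::rnorm(1, 0, config$plate_shift_sd)
      nc <- config$n_compounds_per_plate
      cid <- sprintf("%s-C%03d", pid, seq_len(nc))
      active <- stats::runif(nc) < config$active_fraction
      effect <- ifelse(active,
                       stats::runif(nc, config$effect_size_range[1],
                                    config$effect_size_range[2]), 0)
      toxic <- stats::runif(nc) < config$toxicity_fraction

      n_wells <- config$n_dmso_per_plate + config$n_nor_per_plate + 2L * nc
      pos <- sample(ids[seq_len(config$wells_per_plate)], n_wells)
      role <- c(rep("dmso", config$n_dmso_per_plate),
                rep("nortriptyline", config$n_nor_per_plate),
                rep("experimental", 2L * nc))
      compound <- c(rep(NA_character_, config$n_dmso_per_plate + config$n_nor_per_plate),
                    rep(cid, each = 2L))
      replicate <- c(rep(NA_integer_, config$n_dmso_per_plate + config$n_nor_per_plate),
                     rep(c(1L, 2L), nc))

      count_mu <- rep(config$count_mean, n_wells)
      is_exp <- role == "experimental"
      tox_by_well <- rep(FALSE, n_wells)
      tox_by_well[is_exp] <- rep(toxic, each = 2L)
      count_mu[tox_by_well] <- count_mu[tox_by_well] * (1 - config$toxicity_severity)
      cells <- stats::rnbinom(n_wells, size = config$count_size, mu = count_mu)

      mu_pct <- rep(config$dmso_mean_pct, n_wells)
      mu_pct[role == "nortriptyline"] <- config$nor_mean_pct
      mu_pct[is_exp] <- config$dmso_mean_pct + rep(effect, each = 2L)
      mu_pct <- mu_pct + shift
      sd_pct <- rep(config$replicate_noise_sd, n_wells)
      sd_pct[role == "dmso"] <- config$dmso_sd
      sd_pct[role == "nortriptyline"] <- config$nor_sd

      positive <- draw_positive(cells, mu_pct, sd_pct, config$positive_model)

      wells_all[[p]] <- data.frame(
        plate_id = pid, well_id = pos, role = role, compound_id = compound,
        replicate = replicate, cell_count = cells, positive_count = positive,
        stringsAsFactors = FALSE
      )
      truth_all[[p]] <- data.frame(
        compound_id = cid, plate_id = pid, active = active,
        effect = effect, toxic = toxic, stringsAsFactors = FALSE
      )
    }
    list(wells = do.call(rbind, wells_all), truth = do.call(rbind, truth_all))
  })
}

#' Configuration for the qPCR simulator
#'
#' Generative counterpart of the secondary screen's linear model:
#' `Ct_target = a + b * Ct_ref + plate effect + chemical shift + noise`.
#' A chemical shift (delta Ct) of +1 corresponds to a fold change of 0.5
#' at amplification efficiency 2.
#'
#' @param effect_map Numeric matrix of delta-Ct shifts, rownames =
#'   chemicals (must include `"DMSO"` with all-zero row), colnames =
#'   target genes.
#' @param n_plates Number of plates; replicates are spread across them.
#' @param replicates_per_chemical Replicates per chemical per gene
#'   (default 4, minimum 2).
#' @param intercept_a,slope_b Intercept and reference-Ct slope of the
#'   generative model.
#' @param plate_effect_sd SD (Ct) of the additive plate effect.
#' @param ref_ct_mean,ref_ct_sd Distribution of reference-gene Ct values.
#' @param noise_sd Residual SD (Ct), `>= 0`.
#' @param seed Integer seed.
#' @return An object of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(effect_map, n_plates = 2,
                            replicates_per_chemical = 4,
                            intercept_a = 5, slope_b = 1,
                            plate_effect_sd = 0.5,
                            ref_ct_mean = 20, ref_ct_sd = 0.5,
                            noise_sd = 0.2, seed = 1L) {
  if (!is.matrix(effect_map) || is.null(rownames(effect_map)) ||
      is.null(colnames(effect_map))) {
    stop("configuration error: effect_map must be a chemical x gene matrix ",
         "with dimnames")
  }
  if (!"DMSO" %in% rownames(effect_map)) {
    stop("configuration error: effect_map must include a DMSO row")
  }
  if (any(effect_map["DMSO", ] != 0)) {
    stop("configuration error: DMSO row of effect_map must be all zero")
  }
  if (replicates_per_chemical < 2) stop("replicates_per_chemical must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(as.list(environment()), class = "qpcr_sim_config")
}

#' Simulate a multiplexed qPCR Ct table
#'
#' @param config A [qpcr_sim_config()].
#' @param genes Genes to emit (default: all columns of the effect map). A
#'   gene absent from the effect map is a configuration error.
#' @return data.frame with columns `plate_id`, `well_id`, `chemical`,
#'   `gene`, `ct_target`, `ct_ref`.
#' @export
simulate_qpcr <- function(config, genes = colnames(config$effect_map)) {
  stopifnot(inherits(config, "qpcr_sim_config"))
  missing_genes <- setdiff(genes, colnames(config$effect_map))
  if (length(missing_genes)) {
    stop("configuration error: effect_map missing gene(s): ",
         paste(missing_genes, collapse = ", "))
  }
  with_seed(config$seed, {
    chems <- rownames(config$effect_map)
    plate_eff <- stats::rnorm(config$n_plates, 0, config$plate_effect_sd)
    grid <- expand.grid(chemical = chems, gene = genes,
                        replicate = seq_len(config$replicates_per_chemical),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    plate_idx <- ((grid$replicate - 1L) %% config$n_plates) + 1L
    ct_ref <- stats::rnorm(nrow(grid), config$ref_ct_mean, config$ref_ct_sd)
    delta <- config$effect_map[cbind(grid$chemical, grid$gene)]
    ct_target <- config$intercept_a + config$slope_b * ct_ref +
      plate_eff[plate_idx] + delta +
      stats::rnorm(nrow(grid), 0, config$noise_sd)
    data.frame(
      plate_id = sprintf("plate%02d", plate_idx),
      well_id = sprintf("w%04d", seq_len(nrow(grid))),
      chemical = grid$chemical, gene = grid$gene,
      ct_target = ct_target, ct_ref = ct_ref,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a dose-response series
#'
#' Mean response follows a four-parameter logistic at each concentration;
#' concentrations above `toxic_above` get cell counts reduced to 30% of
#' the DMSO reference, below the default toxicity-exclusion threshold.
#'
#' @param true_params List with `bottom`, `top`, `ec50`, `hill`.
#' @param concentrations Positive, strictly increasing (molar).
#' @param noise_sd Response noise SD (%CTL units).
#' @param toxic_above Concentration above which wells are toxic, or `NULL`.
#' @param seed Integer seed.
#' @param replicates Wells per concentration (default 2).
#' @param cell_count_mean Expected cells per well; also the attached DMSO
#'   cell-count reference.
#' @param compound_id Identifier used in the output.
#' @return data.frame `compound_id`, `concentration`, `replicate`,
#'   `response`, `cell_count`, with attribute `dmso_cell_count`.
#' @export
simulate_drc <- function(true_params, concentrations, noise_sd = 3,
                         toxic_above = NULL, seed = 1L, replicates = 2,
                         cell_count_mean = 500, compound_id = "cmpd") {
  if (any(concentrations <= 0)) stop("domain error: concentrations must be positive")
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be strictly increasing")
  }
  with_seed(seed, {
    conc <- rep(concentrations, each = replicates)
    mu <- four_pl(conc, true_params$bottom, true_params$top,
                  true_params$ec50, true_params$hill)
    resp <- mu + stats::rnorm(length(conc), 0, noise_sd)
    count_mu <- rep(cell_count_mean, length(conc))
    if (!is.null(toxic_above)) count_mu[conc > toxic_above] <- 0.3 * cell_count_mean
    cells <- if (noise_sd == 0) round(count_mu) else
      stats::rpois(length(conc), count_mu)
    out <- data.frame(
      compound_id = compound_id, concentration = conc,
      replicate = rep(seq_len(replicates), times = length(concentrations)),
      response = resp, cell_count = cells, stringsAsFactors = FALSE
    )
    attr(out, "dmso_cell_count") <- cell_count_mean
    out
  })
}

#' Simulate a concentration-time PK profile
#'
#' @param params For `model = "mono"`: list(`c0`, `lambda`); for
#'   `model = "bi"`: list(`a`, `alpha`, `b`, `beta`). Rates per hour,
#'   concentrations nmol/L.
#' @param times Non-negative, sorted times (hours).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   noise (`>= 0`; 0 gives the exact expectation).
#' @param seed Integer seed.
#' @param model `"mono"` or `"bi"`.
#' @return data.frame `time`, `concentration`.
#' @export
simulate_pk <- function(params, times, noise_cv = 0, seed = 1L,
                        model = c("mono", "bi")) {
  model <- match.arg(model)
  if (noise_cv < 0) stop("domain error: noise_cv must be >= 0")
  if (any(times < 0) || is.unsorted(times)) stop("times must be non-negative and sorted")
  mu <- if (model == "mono") {
    params$c0 * exp(-params$lambda * times)
  } else {
    params$a * exp(-params$alpha * times) + params$b * exp(-params$beta * times)
  }
  with_seed(seed, {
    conc <- if (noise_cv == 0) mu else {
      sdlog <- sqrt(log(1 + noise_cv^2))
      mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog)
    }
    data.frame(time = times, concentration = conc)
  })
}

#' Simulate a microsomal substrate-depletion assay
#'
#' First-order depletion with true half-life `t_half_true` (minutes).
#'
#' @param t_half_true True in-vitro half-life, minutes.
#' @param times Non-negative, sorted times (minutes).
#' @param noise_cv Multiplicative lognormal CV (`>= 0`).
#' @param seed Integer seed.
#' @param c0 Initial amount (fraction or concentration), default 1.
#' @param protein_mg_per_ml Microsomal protein content (default 0.5).
#' @return data.frame `time`, `remaining` with attribute `protein_mg_per_ml`.
#' @export
simulate_microsome <- function(t_half_true, times, noise_cv = 0, seed = 1L,
                               c0 = 1, protein_mg_per_ml = 0.5) {
  if (noise_cv < 0) stop("domain error: noise_cv must be >= 0")
  if (any(times < 0) || is.unsorted(times)) stop("times must be non-negative and sorted")
  mu <- c0 * exp(-log(2) / t_half_true * times)
  with_seed(seed, {
    rem <- if (noise_cv == 0) mu else {
      sdlog <- sqrt(log(1 + noise_cv^2))
      mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog)
    }
    out <- data.frame(time = times, remaining = rem)
    attr(out, "protein_mg_per_ml") <- protein_mg_per_ml
    out
  })
}
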