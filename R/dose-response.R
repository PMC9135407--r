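# Dose-response analysis: percent-of-control normalization, toxicity-based
# point exclusion, four-parameter logistic fitting (minpack.lm), EC50
# estimation and the Priority 1-5 curve rubric.

#' Four-parameter logistic function
#'
#' `f(c) = bottom + (top - bottom) / (1 + (ec50 / c)^hill)`.
#'
#' @param conc Concentration(s), positive.
#' @param bottom,top Lower/upper asymptote (%CTL).
#' @param ec50 Concentration of half-maximal response.
#' @param hill Hill slope.
#' @return Response value(s).
#' @export
four_pl <- function(conc, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / conc)^hill)
}

#' Percent-of-control normalization
#'
#' `%CTL = 100 * (raw - dmso_mean) / (nor_mean - dmso_mean)`: the DMSO
#' mean maps to 0 and the nortriptyline mean to 100.
#'
#' @param raw Raw readout (e.g. Bodipy area per nucleus).
#' @param dmso_mean,nor_mean Control means (must differ).
#' @return %CTL value(s).
#' @export
percent_ctl <- function(raw, dmso_mean, nor_mean) {
  if (isTRUE(all.equal(nor_mean, dmso_mean))) {
    stop("degenerate controls: DMSO and nortriptyline means are equal")
  }
  100 * (raw - dmso_mean) / (nor_mean - dmso_mean)
}

#' Exclude toxic concentrations from a dose-response series
#'
#' Concentrations whose mean cell count falls below
#' `fraction_of_dmso` times the DMSO cell-count reference are excluded
#' from fitting and recorded, mirroring the practice of dropping
#' high-concentration points whose apparent response is confounded by
#' cell loss.
#'
#' @param series data.frame with `concentration`, `response`,
#'   `cell_count`.
#' @param dmso_cell_count DMSO mean cell count (default: the
#'   `"dmso_cell_count"` attribute of `series`).
#' @param fraction_of_dmso Exclusion threshold (default 0.5).
#' @return `series` rows at retained concentrations, with attribute
#'   `"excluded_concentrations"`.
#' @export
exclude_toxic <- function(series, dmso_cell_count = attr(series, "dmso_cell_count"),
                          fraction_of_dmso = 0.5) {
  if (is.null(dmso_cell_count)) stop("DMSO cell-count reference required")
  u <- unique(series$concentration)
  mean_counts <- vapply(u, function(cc) {
    mean(series$cell_count[series$concentration == cc])
  }, 0)
  bad <- u[mean_counts < fraction_of_dmso * dmso_cell_count]
  out <- series[!series$concentration %in% bad, , drop = FALSE]
  if (nrow(out) == 0L) stop("untestable series: all concentrations excluded as toxic")
  attr(out, "excluded_concentrations") <- bad
  attr(out, "dmso_cell_count") <- dmso_cell_count
  out
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Levenberg-Marquardt least squares of the 4PL on the (already
#' %CTL-normalized or raw) response versus concentration, fitting EC50 on
#' the log10 scale. Initialization: bottom/top from the min/max of
#' per-concentration means, EC50 from the concentration whose mean is
#' nearest half-span, hill = 1. Bounds: hill in `[0.2, 10]`, EC50 within
#' 100x the tested concentration range. Flat series (response SD below
#' `flat_tol`) are returned as converged no-response fits rather than
#' being sent to the optimizer.
#'
#' @param series data.frame with `concentration` and `response`
#'   (replicate-resolved rows).
#' @param flat_tol Response SD below which the series is treated as flat
#'   (default 1e-8, same units as the response).
#' @return Object of class `four_pl_fit`: `bottom`, `top`, `ec50`,
#'   `hill`, `rss`, `r_squared`, `converged`, `no_response`,
#'   `extrapolated`, `n_points_used`, `excluded_concentrations`.
#' @export
fit_4pl <- function(series, flat_tol = 1e-8) {
  conc <- series$concentration
  resp <- series$response
  u <- sort(unique(conc))
  if (length(u) < 4L) stop("insufficient data: need >= 4 usable concentrations")
  excl <- attr(series, "excluded_concentrations")
  if (is.null(excl)) excl <- numeric(0)

  means <- tapply(resp, conc, mean)
  if (stats::sd(resp) < flat_tol) {
    out <- list(bottom = mean(resp), top = mean(resp),
                ec50 = stats::median(u), hill = 1,
                rss = sum((resp - mean(resp))^2), r_squared = NA_real_,
                converged = TRUE, no_response = TRUE, extrapolated = FALSE,
                n_points_used = length(resp), excluded_concentrations = excl)
    class(out) <- "four_pl_fit"
    return(out)
  }
  bot0 <- min(means); top0 <- max(means)
  half <- (bot0 + top0) / 2
  ec0 <- u[which.min(abs(means[as.character(u)] - half))]
  lec_lo <- log10(min(u) / 100); lec_hi <- log10(max(u) * 100)
  start <- c(bottom = bot0, top = top0, lec50 = log10(ec0), hill = 1)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ bottom + (top - bottom) / (1 + 10^((lec50 - log10(conc)) * hill)),
      start = as.list(start),
      lower = c(bottom = -Inf, top = -Inf, lec50 = lec_lo, hill = 0.2),
      upper = c(bottom = Inf, top = Inf, lec50 = lec_hi, hill = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- list(bottom = unname(start["bottom"]), top = unname(start["top"]),
                ec50 = 10^unname(start["lec50"]), hill = 1,
                rss = NA_real_, r_squared = NA_real_, converged = FALSE,
                no_response = FALSE, extrapolated = FALSE,
                n_points_used = length(resp), excluded_concentrations = excl)
    class(out) <- "four_pl_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  ec50 <- 10^unname(cf["lec50"])
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((resp - mean(resp))^2)
  out <- list(
    bottom = unname(cf["bottom"]), top = unname(cf["top"]),
    ec50 = ec50, hill = unname(cf["hill"]),
    rss = rss, r_squared = 1 - rss / tss,
    converged = fit$convInfo$isConv %||% TRUE,
    no_response = FALSE,
    extrapolated = ec50 < min(u) || ec50 > max(u),
    n_points_used = length(resp),
    excluded_concentrations = excl
  )
  class(out) <- "four_pl_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.four_pl_fit <- function(x, ...) {
  cat("4PL fit: bottom =", signif(x$bottom, 4), " top =", signif(x$top, 4),
      " EC50 =", signif(x$ec50, 4), " hill =", signif(x$hill, 3), "\n")
  cat("  R^2 =", signif(x$r_squared, 4), " converged:", x$converged,
      if (x$no_response) " [no response]" else "",
      if (x$extrapolated) " [EC50 extrapolated]" else "", "\n")
  invisible(x)
}

#' Score a dose-response curve on the Priority 1-5 rubric
#'
#' Quantitative rendering of the screen's curve-review rubric, applied
#' top-down (exactly one branch taken):
#' Priority 1: %CTL increased at 1 uM, the fit is sigmoidal, and at least
#' two pre-toxic concentrations are increased. Priority 2: increased at
#' both of the two highest concentrations and %CTL at 10 uM is at least
#' 70. Priority 3: increased at both top concentrations but %CTL at
#' 10 uM below 70. Priority 4: increased only at the highest
#' concentration. Priority 5: otherwise (flat / no response).
#' "Increased" means %CTL at or above `increase_threshold`; "sigmoidal"
#' means a converged fit with span above `span_min` and R^2 at least
#' `r2_min`.
#'
#' @param series data.frame with `concentration` and `response` (%CTL),
#'   including any toxic concentrations (pre-exclusion).
#' @param fit A `four_pl_fit` for the series (post-exclusion).
#' @param increase_threshold %CTL threshold for "increased" (default 20).
#' @param span_min Minimum top-bottom span for a sigmoidal call
#'   (default 20).
#' @param r2_min Minimum R^2 for a sigmoidal call (default 0.8).
#' @param rubric_concentrations The 1/3.03/10 uM rubric grid, in the
#'   units of `concentration` (default `c(1, 3.03, 10) * 1e-6` molar).
#' @param nearest Use the nearest tested concentration for each rubric
#'   point instead of requiring exact membership (default FALSE).
#' @return List of class `drc_score`: `priority` (1-5) and the rationale
#'   flags.
#' @export
score_drc <- function(series, fit, increase_threshold = 20, span_min = 20,
                      r2_min = 0.8,
                      rubric_concentrations = c(1, 3.03, 10) * 1e-6,
                      nearest = FALSE) {
  u <- sort(unique(series$concentration))
  find_conc <- function(target) {
    hit <- which(abs(u - target) <= 1e-9 + 1e-6 * target)
    if (length(hit)) return(u[hit[1]])
    if (nearest) return(u[which.min(abs(log10(u) - log10(target)))])
    stop("rubric inapplicable: concentration ", target,
         " not tested; re-run with nearest = TRUE to use the nearest ",
         "tested concentration")
  }
  c1 <- find_conc(rubric_concentrations[1])
  c3 <- find_conc(rubric_concentrations[2])
  c10 <- find_conc(rubric_concentrations[3])
  mean_at <- function(cc) mean(series$response[series$concentration == cc])
  excl <- fit$excluded_concentrations
  pre_toxic <- if (length(excl)) u[u < min(excl)] else u

  increased_at_1uM <- mean_at(c1) >= increase_threshold
  increased_top2 <- mean_at(c3) >= increase_threshold && mean_at(c10) >= increase_threshold
  increased_10_only <- mean_at(c10) >= increase_threshold
  ctl70_at_10uM <- mean_at(c10) >= 70
  n_pre_toxic_increased <- sum(vapply(pre_toxic, mean_at, 0) >= increase_threshold)
  sigmoidal <- isTRUE(fit$converged) && !isTRUE(fit$no_response) &&
    (fit$top - fit$bottom) > span_min &&
    !is.na(fit$r_squared) && fit$r_squared >= r2_min

  priority <- if (increased_at_1uM && sigmoidal && n_pre_toxic_increased >= 2) 1L
    else if (increased_top2 && ctl70_at_10uM) 2L
    else if (increased_top2) 3L
    else if (increased_10_only) 4L
    else 5L

  structure(list(priority = priority, sigmoidal = sigmoidal,
                 increased_at_1uM = increased_at_1uM,
                 increased_at_top2 = increased_top2,
                 ctl70_at_10uM = ctl70_at_10uM,
                 n_pre_toxic_increased = n_pre_toxic_increased,
                 toxic_concentrations = excl),
            class = "drc_score")
}

#' Pass/fail dose-response compounds against a reference score
#'
#' Compares each compound's mean priority score (e.g. averaged over
#' raters or replicates) to the positive-control reference; by default a
#' numerically lower priority is better and a compound passes when its
#' mean is at or below the reference ("same as or higher" in rank terms).
#'
#' @param mean_scores Named numeric vector of per-compound mean scores.
#' @param reference_mean Reference (positive-control) mean score.
#' @param direction `"lower"` (default: lower = better) or `"higher"`.
#' @return data.frame `compound_id`, `mean_score`, `pass`.
#' @export
select_by_reference <- function(mean_scores, reference_mean,
                                direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  pass <- if (direction == "lower") mean_scores <= reference_mean
          else mean_scores >= reference_mean
  data.frame(compound_id = names(mean_scores), mean_score = unname(mean_scores),
             pass = unname(pass), stringsAsFactors = FALSE)
}
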