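# Non-compartmental PK and microsomal stability calculations: Cmax/Tmax,
# trapezoidal AUC, terminal log-linear regression for lambda_z and t1/2,
# MRT-based Vss/F, substrate-depletion half-life and the intrinsic
# clearance formula, plus the group summary arithmetic (mean, SD, CV%).

auc_trapezoid <- function(times, conc, method = c("linear", "log")) {
  method <- match.arg(method)
  dt <- diff(times)
  c1 <- utils::head(conc, -1)
  c2 <- utils::tail(conc, -1)
  lin <- dt * (c1 + c2) / 2
  if (method == "linear") return(sum(lin))
  # log-trapezoid where the segment is a positive decline (exact for
  # exponential decay); linear elsewhere
  use_log <- c1 > 0 & c2 > 0 & c2 < c1
  seg <- lin
  seg[use_log] <- dt[use_log] * (c1[use_log] - c2[use_log]) /
    log(c1[use_log] / c2[use_log])
  sum(seg)
}

#' Non-compartmental analysis of a concentration-time profile
#'
#' Cmax/Tmax from the observed maximum; AUC0-t by the linear trapezoid;
#' lambda_z by least squares on ln(concentration) over the terminal
#' points (default: all quantifiable points after Tmax, minimum 3);
#' t1/2 = ln(2)/lambda_z; AUC0-inf = AUC0-t + Clast/lambda_z;
#' MRT = AUMC0-inf/AUC0-inf; Vss/F = (Dose/AUC0-inf) * MRT.
#'
#' @param times Sampling times, hours, strictly increasing.
#' @param conc Concentrations, nmol/L; `NA` marks below-limit values
#'   (treated as missing, not zero).
#' @param dose_mg_per_kg Optional dose for Vss/F.
#' @param molecular_weight Optional g/mol, converts the dose to nmol/kg.
#' @param terminal_points Optional integer indices (into `times`)
#'   overriding the terminal-phase selection.
#' @param auc_method `"linear"` trapezoid (default) or `"log"`, which
#'   uses the log-trapezoid on declining positive segments (exact for
#'   exponential decay).
#' @return List of class `nca_result`: `cmax`, `tmax`, `auc_0_t`,
#'   `lambda_z`, `t_half`, `auc_0_inf`, `aumc_0_inf`, `mrt`, `vss_f`
#'   (L/kg, `NA` without dose and molecular weight), `n_terminal`.
#' @export
nca <- function(times, conc, dose_mg_per_kg = NULL, molecular_weight = NULL,
                terminal_points = NULL, auc_method = c("linear", "log")) {
  auc_method <- match.arg(auc_method)
  stopifnot(length(times) == length(conc))
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  ok <- !is.na(conc)
  t_obs <- times[ok]; c_obs <- conc[ok]
  if (length(c_obs) < 3L) stop("need >= 3 quantifiable points")

  imax <- which.max(c_obs)
  cmax <- c_obs[imax]; tmax <- t_obs[imax]
  auc_t <- auc_trapezoid(t_obs, c_obs, auc_method)

  if (is.null(terminal_points)) {
    term <- which(t_obs > tmax & c_obs > 0)
  } else {
    term <- match(times[terminal_points], t_obs)
    term <- term[!is.na(term)]
    if (any(c_obs[term] <= 0)) {
      warning("non-positive concentrations in terminal window excluded")
      term <- term[c_obs[term] > 0]
    }
  }
  lambda_z <- t_half <- auc_inf <- aumc_inf <- mrt <- vss_f <- NA_real_
  if (length(term) < 3L) {
    warning("fewer than 3 terminal points: lambda_z and derived ",
            "quantities reported as NA")
  } else {
    fit <- stats::lm(log(c_obs[term]) ~ t_obs[term])
    lambda_z <- -unname(stats::coef(fit)[2])
    if (lambda_z <= 0) stop("no elimination phase: lambda_z <= 0")
    t_half <- log(2) / lambda_z

    c_last <- c_obs[length(c_obs)]; t_last <- t_obs[length(t_obs)]
    auc_inf <- auc_t + c_last / lambda_z
    aumc_t <- auc_trapezoid(t_obs, t_obs * c_obs)
    aumc_inf <- aumc_t + c_last * t_last / lambda_z + c_last / lambda_z^2
    mrt <- aumc_inf / auc_inf
    if (!is.null(dose_mg_per_kg) && !is.null(molecular_weight)) {
      dose_nmol_per_kg <- dose_mg_per_kg * 1e6 / molecular_weight
      vss_f <- dose_nmol_per_kg / auc_inf * mrt   # L/kg
    }
  }
  structure(list(cmax = cmax, tmax = tmax, auc_0_t = auc_t,
                 lambda_z = lambda_z, t_half = t_half,
                 auc_0_inf = auc_inf, aumc_0_inf = aumc_inf, mrt = mrt,
                 vss_f = vss_f, n_terminal = length(term)),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("NCA: Cmax =", signif(x$cmax, 4), "at Tmax =", x$tmax, "h;",
      "t1/2 =", signif(x$t_half, 3), "h; AUC0-inf =", signif(x$auc_0_inf, 4),
      "; MRT =", signif(x$mrt, 3), "h; Vss/F =", signif(x$vss_f, 3), "L/kg\n")
  invisible(x)
}

#' Microsomal depletion half-life and intrinsic clearance
#'
#' OLS of ln(remaining) versus time gives the semilogarithmic slope;
#' t1/2 = ln(2)/(-slope). A non-negative slope is flagged as no
#' depletion (infinite half-life, zero clearance). The NADPH-independent
#' series, when supplied, is reported as a parallel QC estimate.
#'
#' @param assay data.frame with `time` (minutes) and `remaining`
#'   (positive), e.g. from [simulate_microsome()].
#' @param protein_mg_per_ml Protein content of the incubation (default:
#'   the assay attribute, else 0.5 mg/ml).
#' @param no_nadph Optional data.frame of the NADPH-free control series.
#' @return List of class `clint_result`: `t_half_min`, `slope`,
#'   `r_squared`, `cl_intrinsic` (ul/min/mg protein), `no_depletion`,
#'   and optionally `t_half_no_nadph`.
#' @export
microsome_t_half <- function(assay,
                             protein_mg_per_ml = attr(assay, "protein_mg_per_ml") %||% 0.5,
                             no_nadph = NULL) {
  if (nrow(assay) < 3L) stop("need >= 3 time points")
  if (any(assay$remaining <= 0)) stop("remaining amounts must be positive")
  fit <- stats::lm(log(remaining) ~ time, data = assay)
  slope <- unname(stats::coef(fit)[2])
  y <- log(assay$remaining)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  if (slope >= 0) {
    res <- list(t_half_min = Inf, slope = slope, r_squared = r2,
                cl_intrinsic = 0, no_depletion = TRUE,
                protein_mg_per_ml = protein_mg_per_ml)
  } else {
    t_half <- log(2) / (-slope)
    res <- list(t_half_min = t_half, slope = slope, r_squared = r2,
                cl_intrinsic = cl_intrinsic(t_half, protein_mg_per_ml),
                no_depletion = FALSE, protein_mg_per_ml = protein_mg_per_ml)
  }
  if (!is.null(no_nadph)) {
    f2 <- stats::lm(log(remaining) ~ time, data = no_nadph)
    s2 <- unname(stats::coef(f2)[2])
    res$t_half_no_nadph <- if (s2 >= 0) Inf else log(2) / (-s2)
  }
  class(res) <- "clint_result"
  res
}

#' @export
print.clint_result <- function(x, ...) {
  if (x$no_depletion) {
    cat("No depletion (slope >= 0): t1/2 = Inf, CL_int = 0\n")
  } else {
    cat("Microsomal t1/2 =", signif(x$t_half_min, 3), "min;",
        "CL_int =", signif(x$cl_intrinsic, 3), "ul/min/mg protein",
        "(R^2 =", paste0(signif(x$r_squared, 3), ")"), "\n")
  }
  invisible(x)
}

#' Microsomal intrinsic clearance
#'
#' `CL_int [ul/min/mg protein] =
#'  (ln 2 / (t_half [min] * protein [mg/ml])) * 1000`.
#'
#' @param t_half_min In-vitro half-life, minutes (> 0).
#' @param protein_mg_per_ml Microsomal protein content, mg/ml (> 0).
#' @return Intrinsic clearance in ul/min/mg protein.
#' @examples
#' cl_intrinsic(37.8, 0.5) # ~36.7
#' @export
cl_intrinsic <- function(t_half_min, protein_mg_per_ml) {
  if (any(t_half_min <= 0) || any(protein_mg_per_ml <= 0)) {
    stop("domain error: t_half and protein content must be positive")
  }
  (log(2) / (t_half_min * protein_mg_per_ml)) * 1000
}

#' Group summary: mean, SD, CV%
#'
#' Sample SD (n-1 denominator); CV = 100 * SD / mean, flagged `NA` when
#' the mean is zero.
#'
#' @param values Numeric vector (n >= 2).
#' @return List `n`, `mean`, `sd`, `cv_percent`.
#' @export
summarize_group <- function(values) {
  if (length(values) < 2L) stop("need n >= 2")
  m <- mean(values); s <- stats::sd(values)
  cv <- if (isTRUE(all.equal(m, 0))) NA_real_ else 100 * s / m
  list(n = length(values), mean = m, sd = s, cv_percent = cv)
}
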