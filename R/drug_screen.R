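# Differential small-molecule sensitivity: viability normalization,
# log-logistic dose-response fitting, normalized AUC, median-centered
# delta-AUC ranking.

logistic_viability <- function(dose, top, bottom, log10_ec50, hill = 1) {
  bottom + (top - bottom) / (1 + 10^((log10(dose) - log10_ec50) * hill))
}

#' Normalize raw luminescence to a viability fraction
#'
#' @param luminescence numeric vector of test-well readings.
#' @param reference_luminescence readings from the reference condition
#'   (e.g. cells treated with the anchor drug only); must be positive.
#' @return `luminescence / mean(reference_luminescence)`.
#' @export
normalize_viability <- function(luminescence, reference_luminescence) {
  if (any(reference_luminescence <= 0)) {
    stop("reference luminescence must be positive")
  }
  luminescence / mean(reference_luminescence)
}

#' Fit a logistic inhibitor dose-response curve
#'
#' Model: `v(d) = bottom + (top - bottom) / (1 + 10^((log10(d) -
#' log10_ec50) * hill))`. The default three-parameter mode fixes
#' `hill = 1`; `model = "four"` also fits the slope. Bounded
#' Levenberg-Marquardt least squares with `top` in [0, 1.5], `bottom` in
#' [0, top], and `log10_ec50` within two decades of the tested range.
#' Replicates are averaged per dose before fitting.
#'
#' @param doses positive dose vector.
#' @param viability viability fractions, same length.
#' @param model `"three"` (hill fixed at 1) or `"four"`.
#' @return list of class `dose_response_fit`: `top`, `bottom`,
#'   `log10_ec50`, `hill`, `converged`, `residual_norm`, `doses`,
#'   `viability` (per-dose means). On non-convergence the parameters are
#'   `NA` and downstream AUC falls back to the trapezoid rule.
#' @export
fit_dose_response <- function(doses, viability, model = c("three", "four")) {
  model <- match.arg(model)
  stopifnot(length(doses) == length(viability), all(doses > 0))
  v <- tapply(viability, doses, mean)
  d <- as.numeric(names(v))
  o <- order(d); d <- d[o]; v <- as.numeric(v[o])
  if (length(d) < 4L) stop("need >=4 distinct dose points")
  ld <- log10(d)
  if (diff(range(v)) < 1e-9) {
    # flat plate: top = bottom = the constant, EC50 undefined (flagged by
    # NA; AUC falls back to the trapezoid rule, which returns the constant)
    out <- list(top = v[1L], bottom = v[1L], log10_ec50 = NA_real_,
                hill = if (model == "three") 1 else NA_real_,
                converged = TRUE, degenerate = TRUE, residual_norm = 0,
                doses = d, viability = v)
    return(structure(out, class = "dose_response_fit"))
  }
  start <- list(top = min(max(v), 1.5), bottom = max(min(v), 0),
                log10_ec50 = stats::weighted.mean(ld, w = abs(diff(c(v, v[length(v)])))
                                                  + 1e-6))
  if (start$bottom >= start$top) start$bottom <- max(0, start$top - 0.1)
  lower <- c(top = 0, bottom = 0, log10_ec50 = min(ld) - 2)
  upper <- c(top = 1.5, bottom = 1.5, log10_ec50 = max(ld) + 2)
  if (model == "four") {
    start$hill <- 1; lower <- c(lower, hill = 0.1); upper <- c(upper, hill = 10)
    form <- v ~ bottom + (top - bottom) / (1 + 10^((ld - log10_ec50) * hill))
  } else {
    form <- v ~ bottom + (top - bottom) / (1 + 10^(ld - log10_ec50))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(ld = ld, v = v),
                      start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- list(top = NA_real_, bottom = NA_real_, log10_ec50 = NA_real_,
                hill = if (model == "three") 1 else NA_real_,
                converged = FALSE, residual_norm = NA_real_,
                doses = d, viability = v)
    return(structure(out, class = "dose_response_fit"))
  }
  cf <- as.list(stats::coef(fit))
  if (model == "three") cf$hill <- 1
  # bottom <= top by re-ordering if the optimizer crossed them
  if (cf$bottom > cf$top) cf[c("top", "bottom")] <- cf[c("bottom", "top")]
  pred <- logistic_viability(d, cf$top, cf$bottom, cf$log10_ec50, cf$hill)
  structure(list(top = cf$top, bottom = cf$bottom,
                 log10_ec50 = cf$log10_ec50, hill = cf$hill,
                 converged = TRUE,
                 residual_norm = sqrt(sum((v - pred)^2)),
                 doses = d, viability = v),
            class = "dose_response_fit")
}

#' Area under a dose-response curve, normalized to the dose range
#'
#' Integrates viability over log10 dose across the tested range and
#' divides by the range width, so a constant viability v gives AUC = v
#' and typical values are comparable on a [0, 1] scale. Uses the fitted
#' curve when available, otherwise the trapezoid rule on the per-dose
#' means.
#'
#' @param fit a `dose_response_fit` (or a list with `doses` and
#'   `viability` for the trapezoid fallback).
#' @param dose_range optional `c(min, max)` in dose units; defaults to
#'   the tested range.
#' @return AUC, a single number.
#' @export
auc <- function(fit, dose_range = NULL) {
  d <- fit$doses
  if (length(d) < 2L) stop("AUC needs at least two doses")
  if (is.null(dose_range)) dose_range <- range(d)
  lo <- log10(dose_range[1L]); hi <- log10(dose_range[2L])
  if (isTRUE(fit$converged) && is.finite(fit$log10_ec50)) {
    val <- integrate(function(x) {
      logistic_viability(10^x, fit$top, fit$bottom, fit$log10_ec50, fit$hill)
    }, lo, hi, rel.tol = 1e-9)$value
    return(val / (hi - lo))
  }
  ld <- log10(d)
  v <- fit$viability
  sum(diff(ld) * (head(v, -1) + v[-1]) / 2) / (max(ld) - min(ld))
}

#' Median-centered differential AUC between two cell lines
#'
#' For each compound, `delta_auc = auc_b - auc_a`; the compound-wise
#' median is then subtracted so the bulk of compounds sits at 0 and
#' line-selective compounds stand out in the tails. Compounds present in
#' only one line are dropped with a warning.
#'
#' @param auc_a,auc_b data.frames with `compound` and `auc` columns
#'   (line A and line B).
#' @return `data.frame(compound, auc_a, auc_b, delta_auc,
#'   centered_delta_auc)` sorted ascending by `centered_delta_auc`.
#' @export
delta_auc <- function(auc_a, auc_b) {
  common <- intersect(auc_a$compound, auc_b$compound)
  missing_n <- length(union(auc_a$compound, auc_b$compound)) - length(common)
  if (missing_n > 0L) {
    warning("dropped ", missing_n, " compound(s) missing in one line")
  }
  a <- auc_a$auc[match(common, auc_a$compound)]
  b <- auc_b$auc[match(common, auc_b$compound)]
  dauc <- b - a
  out <- data.frame(compound = common, auc_a = a, auc_b = b,
                    delta_auc = dauc,
                    centered_delta_auc = dauc - median(dauc),
                    stringsAsFactors = FALSE)
  out[order(out$centered_delta_auc), , drop = FALSE]
}

#' Fit and score every compound on a long-format plate table
#'
#' @param plate `data.frame(compound, dose, replicate, viability)` as
#'   produced by [simulate_dose_response()] or read from a plate CSV
#'   after [normalize_viability()].
#' @param model passed to [fit_dose_response()].
#' @return `data.frame(compound, top, bottom, log10_ec50, hill,
#'   converged, auc)`.
#' @export
screen_plate_auc <- function(plate, model = "three") {
  stopifnot(all(c("compound", "dose", "viability") %in% names(plate)))
  res <- lapply(split(plate, plate$compound), function(x) {
    f <- fit_dose_response(x$dose, x$viability, model = model)
    data.frame(compound = x$compound[1L], top = f$top, bottom = f$bottom,
               log10_ec50 = f$log10_ec50, hill = f$hill,
               converged = f$converged, auc = auc(f),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
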