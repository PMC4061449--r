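# qPCR standard-curve quantitation, limit-of-detection censoring, and
# decontamination fold-reduction bounds. All masses are handled in picograms
# internally; parse_mass() converts suffixed I/O values.

#' Fit a qPCR standard curve
#'
#' Least-squares regression of Cq on log10(quantity). The amplification
#' efficiency is derived from the slope as `E = 10^(-1/slope) - 1`; a perfect
#' assay doubles template each cycle (slope -3.3219, E = 1).
#'
#' @param standards Data frame with columns `quantity` (> 0, at least two
#'   distinct values) and `cq`.
#' @return Object of class `standard_curve`: list with `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n`.
#' @examples
#' std <- data.frame(quantity = c(1, 10, 100), cq = c(30, 26.68, 23.36))
#' fit_standard_curve(std)$efficiency
#' @export
fit_standard_curve <- function(standards) {
  if (!all(c("quantity", "cq") %in% names(standards))) {
    stop_invalid("standards need columns 'quantity' and 'cq'")
  }
  q <- standards$quantity
  if (any(q <= 0)) stop_invalid("standard quantities must be positive")
  if (length(unique(q)) < 2) {
    stop_invalid("unfittable: need >= 2 distinct standard quantities")
  }
  fit <- stats::lm(cq ~ log10(quantity), data = standards)
  slope <- unname(stats::coef(fit)[2])
  sst <- sum((standards$cq - mean(standards$cq))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 n = nrow(standards)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope %.4f Cq/log10, intercept %.2f, R^2 %.4f, efficiency %.1f%% (n=%d)\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency, x$n))
  invisible(x)
}

#' Quantify samples against a standard curve with LOD censoring
#'
#' Inverts the fitted line, `mass = 10^((cq - intercept)/slope)`, and censors
#' any result below the assay's limit of detection. A missing Cq (no
#' amplification) is censored as well. Censored results report the LOD as
#' their bound.
#'
#' @param cq Numeric Cq values; `NA` means no amplification.
#' @param curve A [fit_standard_curve()] result.
#' @param lod Limit of detection in the curve's mass units.
#' @return Data frame of class `quant_result` with columns `cq`, `mass`
#'   (`NA` when censored), `censored`, `lod`.
#' @examples
#' cv <- fit_standard_curve(data.frame(quantity = c(1, 100),
#'                                     cq = c(30, 23.36)))
#' quantify(c(30, 45, NA), cv, lod = 0.35)
#' @export
quantify <- function(cq, curve, lod) {
  stopifnot(inherits(curve, "standard_curve"))
  if (lod <= 0) stop_invalid("lod must be positive")
  mass <- 10^((cq - curve$intercept) / curve$slope)
  censored <- is.na(cq) | mass < lod
  structure(data.frame(cq = cq,
                       mass = ifelse(censored, NA_real_, mass),
                       censored = censored,
                       lod = lod),
            class = c("quant_result", "data.frame"))
}

#' Construct censored/uncensored quantitation results directly
#'
#' For entering published quantities (e.g. below-limit-of-detection rows of a
#' decontamination table) without refitting a curve.
#'
#' @param mass Masses in pg; `NA` for censored replicates.
#' @param censored Logical; defaults to `is.na(mass)`.
#' @param lod Assay limit of detection in pg.
#' @return A `quant_result` data frame.
#' @export
quant_result <- function(mass, censored = is.na(mass), lod) {
  if (lod <= 0) stop_invalid("lod must be positive")
  if (any(!censored & (is.na(mass) | mass <= 0))) {
    stop_invalid("uncensored masses must be positive")
  }
  structure(data.frame(cq = NA_real_,
                       mass = ifelse(censored, NA_real_, mass),
                       censored = censored, lod = lod),
            class = c("quant_result", "data.frame"))
}

#' Decontamination fold-reduction bounds
#'
#' When every treated replicate is below the limit of detection the true
#' fold reduction can only be bounded from below: the bound divides the
#' untreated mass by the LOD. Two conventions are reported — the mean of the
#' untreated replicates over the LOD, and the minimum over the LOD (the most
#' conservative bound). If any treated replicate amplified, observed masses
#' are used (censored replicates contribute their LOD) and the result is a
#' point estimate unless censoring remains.
#'
#' @param untreated Positive untreated masses in pg (use [parse_mass()] for
#'   suffixed units).
#' @param treated A `quant_result` data frame of treated replicates; all
#'   replicates must share one LOD (one assay).
#' @return List of class `fold_reduction` with `mean_based_bound`,
#'   `min_based_bound`, `is_lower_bound`, `lod`, `n_treated_censored`.
#' @examples
#' tips <- quant_result(rep(NA_real_, 15), lod = 0.350)
#' fold_reduction(parse_mass("21 ng"), tips)$mean_based_bound  # 6e4
#' @export
fold_reduction <- function(untreated, treated) {
  stopifnot(inherits(treated, "quant_result"))
  if (length(untreated) == 0 || any(untreated <= 0)) {
    stop_invalid("untreated masses must be non-empty and positive")
  }
  lod <- unique(treated$lod)
  if (length(lod) != 1) {
    stop_invalid("mixed LODs across treated replicates: one assay required")
  }
  all_censored <- all(treated$censored)
  denom <- if (all_censored) {
    lod
  } else {
    mean(ifelse(treated$censored, treated$lod, treated$mass))
  }
  structure(list(mean_based_bound = mean(untreated) / denom,
                 min_based_bound = min(untreated) / denom,
                 is_lower_bound = any(treated$censored),
                 lod = lod,
                 n_treated_censored = sum(treated$censored)),
            class = "fold_reduction")
}

#' @export
print.fold_reduction <- function(x, ...) {
  tag <- if (x$is_lower_bound) ">" else "="
  cat(sprintf(
    "<fold_reduction> mean-based %s%.3g, min-based %s%.3g (LOD %.3g pg, %d censored)\n",
    tag, x$mean_based_bound, tag, x$min_based_bound, x$lod,
    x$n_treated_censored))
  invisible(x)
}

#' Amplification fold and template fraction
#'
#' For a WGA reaction: the fold amplification of the template
#' (`template_yield / input_mass`) and the percent of the total product that
#' derives from the template (`100 * template_yield / total_yield`). A small
#' template fraction means most of the product is amplified contamination.
#'
#' @param input_mass Template input mass in pg.
#' @param template_yield Template-derived yield in pg.
#' @param total_yield Total reaction yield in pg; must be at least
#'   `template_yield`.
#' @return List with `fold_amplification` and `template_fraction` (percent).
#' @examples
#' amplification_metrics(1, parse_mass("37 ng"), parse_mass("10.9 ug"))
#' @export
amplification_metrics <- function(input_mass, template_yield, total_yield) {
  if (any(c(input_mass, template_yield, total_yield) <= 0)) {
    stop_invalid("all masses must be positive")
  }
  if (template_yield > total_yield) {
    stop_invalid("template_yield cannot exceed total_yield")
  }
  list(fold_amplification = template_yield / input_mass,
       template_fraction = 100 * template_yield / total_yield)
}
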