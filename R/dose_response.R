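#' Fit a linear salt-injury dose-response
#'
#' Ordinary least squares of the mean salt-injury index (SII) on NaCl
#' concentration. The SII of a growth trait rises approximately linearly
#' with concentration over the screening range, so the fitted line can be
#' inverted to find the concentration producing a target injury level.
#'
#' @param concentrations_mM Numeric vector of NaCl concentrations (mM), at
#'   least two distinct values.
#' @param mean_sii Numeric vector of mean SII values (panel means, one per
#'   concentration).
#' @param trait_name Optional label carried in the result.
#' @return Object of class `dose_response_fit`: list with `trait_name`,
#'   `intercept` (SII), `slope` (SII per mM), `r_squared`, `c50` (mM at
#'   SII = 0.5) and the underlying `lm` fit.
#' @export
fit_sii_line <- function(concentrations_mM, mean_sii, trait_name = NA_character_) {
  if (length(concentrations_mM) != length(mean_sii))
    stop("concentration and SII vectors must have equal length")
  if (length(unique(concentrations_mM)) < 2L)
    stop("degenerate design: need >= 2 distinct concentrations")
  fit <- stats::lm(mean_sii ~ concentrations_mM)
  co <- unname(stats::coef(fit))
  r2 <- if (stats::var(mean_sii) == 0) 1
        else suppressWarnings(summary(fit)$r.squared)
  out <- list(trait_name = trait_name, intercept = co[1L], slope = co[2L],
              r_squared = r2, lm = fit)
  out$c50 <- tryCatch(concentration_at_sii(out, 0.5), error = function(e) NA_real_)
  class(out) <- "dose_response_fit"
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> %s: SII = %.4f + %.6f * C (r^2 = %.3f), C50 = %.2f mM\n",
              ifelse(is.na(x$trait_name), "(unnamed)", x$trait_name),
              x$intercept, x$slope, x$r_squared, x$c50))
  invisible(x)
}

#' Concentration producing a target injury level
#'
#' Inverts a fitted SII line: C = (target - intercept) / slope.
#'
#' @param fit A [fit_sii_line()] result (or any list with `intercept` and
#'   `slope`).
#' @param target_sii Target salt-injury index, default 0.5 (50% injury, the
#'   conventional screening criterion).
#' @return Concentration in mM.
#' @export
concentration_at_sii <- function(fit, target_sii = 0.5) {
  if (is.null(fit$slope) || fit$slope == 0)
    stop("no solution: fitted slope is zero")
  (target_sii - fit$intercept) / fit$slope
}

#' Average per-genotype SII into panel means
#'
#' Equal-weight average of per-genotype SII values at each concentration,
#' the input expected by [fit_sii_line()].
#'
#' @param df Data frame with columns `concentration_mM` and `sii`
#'   (optionally `genotype_id`, ignored beyond grouping).
#' @return Data frame with columns `concentration_mM`, `mean_sii`.
#' @export
average_sii <- function(df) {
  ag <- stats::aggregate(sii ~ concentration_mM, data = df, FUN = mean)
  names(ag)[2L] <- "mean_sii"
  ag[order(ag$concentration_mM), , drop = FALSE]
}

#' Recommend a screening concentration
#'
#' Chooses, among the candidate NaCl levels actually applied, the level
#' closest on average to the per-trait concentrations producing the target
#' injury (50% by default). Ties are broken toward the level with the
#' greatest senescence-score variance, since a level that spreads the
#' senescence response widest discriminates genotypes best.
#'
#' @param fits List of [fit_sii_line()] results.
#' @param candidate_levels_mM Numeric vector of applied NaCl levels.
#' @param sen_by_level Optional named list mapping level (as character) to a
#'   vector of senescence scores observed at that level; used for the
#'   tie-break and reported per level.
#' @param target_sii Target injury level, default 0.5.
#' @return List with `recommended_mM`, `c_at_target` (named per-trait
#'   vector), `mean_abs_distance` (per candidate level) and `sen_variance`
#'   (per level, `NA` when scores are not supplied).
#' @export
recommend_concentration <- function(fits, candidate_levels_mM,
                                    sen_by_level = NULL, target_sii = 0.5) {
  if (length(candidate_levels_mM) == 0L) stop("no candidate levels supplied")
  cs <- vapply(fits, function(f)
    tryCatch(concentration_at_sii(f, target_sii), error = function(e) NA_real_),
    numeric(1))
  names(cs) <- vapply(fits, function(f) {
    if (is.null(f$trait_name) || is.na(f$trait_name)) "(unnamed)" else f$trait_name
  }, character(1))
  cs <- cs[is.finite(cs)]
  if (length(cs) == 0L)
    stop("recommendation undefined: no fit yields a finite target concentration")
  dist <- vapply(candidate_levels_mM, function(l) mean(abs(cs - l)), numeric(1))
  names(dist) <- as.character(candidate_levels_mM)
  sen_var <- vapply(as.character(candidate_levels_mM), function(l) {
    v <- sen_by_level[[l]]
    if (is.null(v) || length(v) < 2L) NA_real_ else stats::var(v)
  }, numeric(1))
  best <- which(dist == min(dist))
  if (length(best) > 1L) {
    sv <- sen_var[best]
    if (!all(is.na(sv))) best <- best[which.max(ifelse(is.na(sv), -Inf, sv))]
    else best <- best[1L]
  }
  list(recommended_mM = candidate_levels_mM[[best[1L]]],
       c_at_target = cs, mean_abs_distance = dist, sen_variance = sen_var)
}
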