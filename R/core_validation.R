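#' Per-trait core-vs-entire representativeness metrics
#'
#' For each trait, compares the core subset to the entire collection:
#' * MD% = |mean_core - mean_entire| / mean_entire x 100 (mean difference);
#' * CR% = range_core / range_entire x 100 (coincidence rate of range);
#' * VR% = CV_core / CV_entire x 100 (variable rate, CV = sd/mean);
#' * VD% = |CV_core - CV_entire| / CV_core x 100 (variance difference;
#'   equal to (VR - 100)/VR x 100 whenever CV_core > CV_entire).
#'
#' A well-representative core conventionally has MD% below 20 and CR%
#' above 80; large VR%/VD% indicate that the core concentrates the
#' collection's variability. Traits whose entire-set mean or range is zero
#' have undefined metrics and are reported as `NA` with a warning.
#'
#' @param entire,core [trait_table()]s over the same traits; core genotype
#'   ids must be a subset of the entire set's.
#' @return List of class `representativeness_report`: `per_trait` data
#'   frame (trait, MD, VD, CR, VR, H_core, H_entire, p_mean, p_levene,
#'   p_wilcoxon), `summary` (mean MD/CR/VR, mean Shannon indices,
#'   diversity-loss %) and `verdict` (`md_below_20`, `cr_above_80`).
#' @param shannon_scheme Scheme passed to [shannon_weaver()].
#' @export
representativeness_metrics <- function(entire, core,
                                       shannon_scheme = "distinct_values") {
  xe <- trait_values(entire)
  xc <- trait_values(core)
  if (!identical(colnames(xe), colnames(xc)))
    stop("entire and core tables must share the same trait set")
  if (!all(rownames(xc) %in% rownames(xe)))
    stop("core genotype ids must be a subset of the entire set")
  rows <- lapply(colnames(xe), function(tr) {
    e <- xe[, tr]; c_ <- xc[, tr]
    me <- mean(e); mc <- mean(c_)
    re <- diff(range(e)); rc <- diff(range(c_))
    cve <- stats::sd(e) / me; cvc <- stats::sd(c_) / mc
    if (me == 0 || re == 0) {
      warning("entire-set mean or range is zero for trait ", tr,
              "; metrics undefined")
      return(data.frame(trait = tr, MD = NA_real_, VD = NA_real_,
                        CR = NA_real_, VR = NA_real_,
                        H_core = NA_real_, H_entire = NA_real_,
                        p_mean = NA_real_, p_levene = NA_real_,
                        p_wilcoxon = NA_real_))
    }
    tests <- distribution_tests(e, c_)
    data.frame(trait = tr,
               MD = abs(mc - me) / me * 100,
               VD = abs(cvc - cve) / cvc * 100,
               CR = rc / re * 100,
               VR = cvc / cve * 100,
               H_core = shannon_weaver(c_, scheme = shannon_scheme),
               H_entire = shannon_weaver(e, scheme = shannon_scheme),
               p_mean = tests$p_mean, p_levene = tests$p_levene,
               p_wilcoxon = tests$p_wilcoxon)
  })
  per_trait <- do.call(rbind, rows)
  h_core <- mean(per_trait$H_core, na.rm = TRUE)
  h_entire <- mean(per_trait$H_entire, na.rm = TRUE)
  summary <- list(mean_MD = mean(per_trait$MD, na.rm = TRUE),
                  mean_CR = mean(per_trait$CR, na.rm = TRUE),
                  mean_VR = mean(per_trait$VR, na.rm = TRUE),
                  mean_H_core = h_core, mean_H_entire = h_entire,
                  diversity_loss = (h_entire - h_core) / h_entire * 100)
  structure(list(per_trait = per_trait, summary = summary,
                 verdict = list(md_below_20 = all(per_trait$MD < 20,
                                                  na.rm = TRUE),
                                cr_above_80 = all(per_trait$CR > 80,
                                                  na.rm = TRUE))),
            class = "representativeness_report")
}

#' @export
print.representativeness_report <- function(x, ...) {
  cat("<representativeness_report>\n")
  print(x$per_trait, digits = 4)
  cat(sprintf("mean MD %.2f%%  mean CR %.2f%%  mean VR %.2f%%  diversity loss %.2f%%\n",
              x$summary$mean_MD, x$summary$mean_CR, x$summary$mean_VR,
              x$summary$diversity_loss))
  invisible(x)
}

#' Shannon-Weaver diversity index
#'
#' H = -sum(p_c * ln p_c) over class relative frequencies, in nats. The
#' default `distinct_values` scheme treats every unique value as its own
#' class, so H is bounded by ln(sample size) with equality when all values
#' are distinct; `fixed_bins` cuts the range into `bins` equal-width
#' classes, the more conventional convention for continuous traits.
#'
#' @param values Non-empty numeric vector.
#' @param scheme `"distinct_values"` (default) or `"fixed_bins"`.
#' @param bins Number of equal-width bins for `fixed_bins` (default 10).
#' @return H in nats.
#' @export
shannon_weaver <- function(values, scheme = c("distinct_values",
                                              "fixed_bins"), bins = 10L) {
  scheme <- match.arg(scheme)
  if (length(values) == 0L) stop("Shannon index undefined for empty vector")
  cls <- if (scheme == "distinct_values") factor(values)
         else if (diff(range(values)) == 0) factor(rep(1L, length(values)))
         else cut(values, breaks = bins, include.lowest = TRUE)
  p <- as.numeric(table(cls)) / length(values)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Distribution comparisons between entire and core samples
#'
#' Three complementary tests of whether a core sample is distributed like
#' the entire collection for a trait:
#' * mean: the studentized-range (Newman-Keuls) procedure specialized to
#'   two groups, q = t * sqrt(2) with the pooled-variance t statistic --
#'   algebraically equivalent to the pooled two-sample t-test;
#' * spread: the Brown-Forsythe variant of Levene's test (one-way F on
#'   absolute deviations from the group medians);
#' * location (nonparametric): Wilcoxon rank-sum, exact for small samples
#'   and normal-approximated with continuity correction when either sample
#'   exceeds 25 values (the [stats::wilcox.test()] switch).
#'
#' @param entire_col,core_col Numeric vectors with >= 3 values each.
#' @return List with `p_mean`, `p_levene`, `p_wilcoxon`.
#' @export
distribution_tests <- function(entire_col, core_col) {
  if (length(entire_col) < 3L || length(core_col) < 3L)
    stop("need >= 3 values in each sample")
  n1 <- length(entire_col); n2 <- length(core_col)
  s2p <- ((n1 - 1) * stats::var(entire_col) +
          (n2 - 1) * stats::var(core_col)) / (n1 + n2 - 2)
  if (s2p == 0) {
    warning("zero variance in both samples; mean-test p set to 1")
    p_mean <- 1
  } else {
    tstat <- (mean(core_col) - mean(entire_col)) /
      sqrt(s2p * (1 / n1 + 1 / n2))
    q <- abs(tstat) * sqrt(2)
    p_mean <- stats::ptukey(q, nmeans = 2, df = n1 + n2 - 2,
                            lower.tail = FALSE)
  }
  grp <- factor(rep(c("entire", "core"), c(n1, n2)))
  vals <- c(entire_col, core_col)
  devs <- abs(vals - stats::ave(vals, grp, FUN = stats::median))
  p_levene <- if (stats::var(devs) == 0) 1 else
    stats::anova(stats::lm(devs ~ grp))[["Pr(>F)"]][1L]
  p_wilcoxon <- suppressWarnings(
    stats::wilcox.test(core_col, entire_col, exact = (n1 <= 25 && n2 <= 25),
                       correct = TRUE)$p.value)
  list(p_mean = p_mean, p_levene = p_levene, p_wilcoxon = p_wilcoxon)
}

#' Correlation preservation between entire and core sets
#'
#' Pearson correlation matrices of both tables, their element-wise
#' difference, the maximum absolute discrepancy, and the fraction of
#' off-diagonal pairs whose correlation sign agrees. Pairs involving a
#' constant column are undefined and masked as `NA`.
#'
#' @param entire,core [trait_table()]s over the same traits.
#' @return List with `r_entire`, `r_core`, `delta`, `max_abs_delta`,
#'   `sign_agreement`.
#' @export
correlation_preservation <- function(entire, core) {
  xe <- trait_values(entire); xc <- trait_values(core)
  if (!identical(colnames(xe), colnames(xc)))
    stop("entire and core tables must share the same trait set")
  mask_const <- function(x) {
    r <- suppressWarnings(stats::cor(x))
    const <- apply(x, 2L, stats::sd) == 0
    r[const, ] <- NA; r[, const] <- NA
    diag(r) <- 1
    r
  }
  re <- mask_const(xe); rc <- mask_const(xc)
  delta <- rc - re
  off <- upper.tri(delta)
  ok <- !is.na(delta[off])
  list(r_entire = re, r_core = rc, delta = delta,
       max_abs_delta = max(abs(delta[off][ok])),
       sign_agreement = mean(sign(re[off][ok]) == sign(rc[off][ok])))
}

#' Correlation-matrix PCA comparison of entire and core sets
#'
#' Standardizes traits within each set (zero mean, unit variance) and
#' eigendecomposes the correlation matrix; components are ordered by
#' decreasing eigenvalue, and each loading vector is oriented so its
#' largest-magnitude entry is positive.
#'
#' @param entire,core [trait_table()]s over the same traits.
#' @param n_components Number of leading components to keep, default 5;
#'   truncated with a warning when it exceeds the number of traits.
#' @return List with elements `entire` and `core`, each holding `loadings`
#'   (trait x component), `variance_explained` (%) and `cumulative` (%).
#' @export
pca_compare <- function(entire, core, n_components = 5L) {
  one <- function(x) {
    p <- ncol(x)
    nc <- n_components
    if (nc > p) {
      warning("n_components truncated to the number of traits (", p, ")")
      nc <- p
    }
    ev <- eigen(stats::cor(x), symmetric = TRUE)
    load <- ev$vectors[, seq_len(nc), drop = FALSE]
    for (j in seq_len(nc)) {
      i <- which.max(abs(load[, j]))
      if (load[i, j] < 0) load[, j] <- -load[, j]
    }
    dimnames(load) <- list(colnames(x), paste0("PC", seq_len(nc)))
    ve <- ev$values[seq_len(nc)] / p * 100
    list(loadings = load, variance_explained = ve, cumulative = cumsum(ve))
  }
  list(entire = one(trait_values(entire)), core = one(trait_values(core)))
}
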