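#' Default synthetic panel specification
#'
#' Target marginal moments (mean, CV, min, max, skewness sign) for the 14
#' salt-tolerance traits and the strong trait-trait correlations reported
#' for a 318-genotype Miscanthus seedling panel. The correlation pattern
#' encodes only the eight strong pairs (SWC-RWC +0.73, Sen-SNC +0.66,
#' SN/RN-SNC +0.58, SN/RN-Sen +0.55, SN/RN-RK/N +0.53, Sen-SK/N -0.54,
#' Sen-RNIL -0.52, Sen-RLER -0.45) with zeros elsewhere, repaired to the
#' nearest positive semi-definite matrix.
#'
#' @param n_genotypes Panel size, default 318.
#' @return List of class `synthetic_spec` with components `n_genotypes`,
#'   `marginals` (data frame: trait, mean, cv, min, max, skew) and
#'   `correlation` (14 x 14 matrix).
#' @export
default_synthetic_spec <- function(n_genotypes = 318L) {
  marginals <- data.frame(
    trait = trait_names(),
    mean = c(0.49, 0.47, 0.61, 6.33, 15.57, 11.10, 126.00, 45.22,
             3.13, 68.39, 26.20, 2.94, 0.59, 0.63),
    cv   = c(0.53, 0.33, 0.28, 0.16, 0.29, 0.32, 0.21, 0.24,
             0.24, 0.12, 0.21, 0.28, 0.26, 0.30),
    min  = c(0.03, 0.00, 0.19, 3.67, 4.37, 3.57, 53.20, 23.97,
             1.17, 44.32, 12.83, 1.60, 0.33, 0.26),
    max  = c(1.77, 0.94, 1.09, 8.78, 28.78, 22.62, 220.31, 82.13,
             5.68, 104.75, 39.50, 6.03, 1.33, 1.22),
    skew = c(1.09, 0.18, 0.19, -0.06, 0.42, 0.56, 0.33, 0.47,
             0.11, 0.22, 0.15, 1.13, 1.51, 0.48),
    stringsAsFactors = FALSE)
  pairs <- rbind(
    data.frame(a = "SWC",   b = "RWC",  r =  0.73),
    data.frame(a = "Sen",   b = "SNC",  r =  0.66),
    data.frame(a = "SN/RN", b = "SNC",  r =  0.58),
    data.frame(a = "SN/RN", b = "Sen",  r =  0.55),
    data.frame(a = "SN/RN", b = "RK/N", r =  0.53),
    data.frame(a = "Sen",   b = "SK/N", r = -0.54),
    data.frame(a = "Sen",   b = "RNIL", r = -0.52),
    data.frame(a = "Sen",   b = "RLER", r = -0.45))
  cor_mat <- diag(14)
  dimnames(cor_mat) <- list(trait_names(), trait_names())
  for (i in seq_len(nrow(pairs))) {
    cor_mat[pairs$a[i], pairs$b[i]] <- pairs$r[i]
    cor_mat[pairs$b[i], pairs$a[i]] <- pairs$r[i]
  }
  spec <- list(n_genotypes = as.integer(n_genotypes),
               marginals = marginals, correlation = cor_mat)
  class(spec) <- "synthetic_spec"
  spec
}

# Repair a correlation matrix to the nearest positive semi-definite one.
.ensure_psd <- function(m, tol = 0.2) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -1e-10) return(m)
  repaired <- as.matrix(Matrix::nearPD(m, corr = TRUE)$mat)
  if (max(abs(repaired - m)) > tol)
    stop("correlation matrix not repairable within tolerance")
  warning("correlation matrix repaired to nearest positive semi-definite")
  dimnames(repaired) <- dimnames(m)
  repaired
}

# Map standard-normal draws to a location-scale gamma marginal matching
# mean, CV and skewness (sign and magnitude), truncated to [lo, hi].
.marginal_from_normal <- function(z, mean, cv, skew, lo, hi) {
  s <- mean * cv
  if (abs(skew) < 0.05) {
    x <- mean + s * z
  } else {
    shape <- (2 / abs(skew))^2   # gamma skewness = 2 / sqrt(shape)
    # keep the transform monotone increasing in z so the copula correlation
    # signs survive: negative skew reflects the *marginal*, not the rank
    u <- stats::pnorm(if (skew < 0) -z else z)
    g <- stats::qgamma(u, shape = shape, rate = 1)
    gz <- (g - shape) / sqrt(shape)          # standardized gamma
    if (skew < 0) gz <- -gz
    x <- mean + s * gz
  }
  pmin(pmax(x, lo), hi)
}

#' Simulate a correlated genotype-by-trait panel
#'
#' Gaussian-copula draw: correlated standard normals with the spec's target
#' correlation (Cholesky factorization after nearest-PSD repair), mapped
#' through skewed location-scale gamma marginals matched to each trait's
#' target mean, CV and skewness, then truncated to the trait's \[min, max\]
#' interval. Deterministic given the seed.
#'
#' @param spec A [default_synthetic_spec()]-style specification.
#' @param seed Integer RNG seed.
#' @return A [trait_table()] with genotype ids `G001`, `G002`, ...
#' @export
simulate_trait_table <- function(spec = default_synthetic_spec(), seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec") || is.list(spec))
  m <- spec$marginals
  if (any(m$min >= m$max)) stop("spec error: need min < max for every trait")
  if (any(m$cv <= 0)) stop("spec error: need CV > 0 for every trait")
  n <- spec$n_genotypes
  cor_mat <- .ensure_psd(spec$correlation)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n * 14L), n, 14L) %*%
    chol(cor_mat + diag(1e-10, 14L))
  x <- matrix(NA_real_, n, 14L, dimnames = list(NULL, m$trait))
  for (j in seq_len(14L))
    x[, j] <- .marginal_from_normal(z[, j], m$mean[j], m$cv[j], m$skew[j],
                                    m$min[j], m$max[j])
  df <- data.frame(genotype_id = sprintf("G%03d", seq_len(n)),
                   as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  trait_table(df)
}

#' Simulate a raw hydroponic trial
#'
#' Generates long-format raw phenotype records (control and stress arms,
#' several replicates) whose growth series are scaled so that the true
#' stress/control ratio of GR, NIL and LER equals a planted per-genotype
#' STI profile; [assemble_trait_table()] on the output recovers the planted
#' profile up to replicate noise. Ion, senescence and biomass measures are
#' drawn from ranges typical of a 150 mM NaCl screen.
#'
#' @param n_genotypes Number of genotypes.
#' @param effect_profile Optional data frame with columns `genotype_id`,
#'   `RGR`, `RNIL`, `RLER` giving the true STI per genotype (all in
#'   (0, 1.8]); by default drawn uniformly from \[0.2, 1.1\].
#' @param replicates Replicates per arm, default 3.
#' @param noise_sd Multiplicative replicate noise SD on the growth rates
#'   (0 = exact recovery), default 0.05.
#' @param seed Integer RNG seed.
#' @return List with `records` (long data frame) and `effect_profile` (the
#'   planted truth).
#' @export
simulate_raw_trial <- function(n_genotypes = 10L, effect_profile = NULL,
                               replicates = 3L, noise_sd = 0.05, seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  ids <- sprintf("G%03d", seq_len(n_genotypes))
  if (is.null(effect_profile)) {
    effect_profile <- data.frame(genotype_id = ids,
                                 RGR = stats::runif(n_genotypes, 0.2, 1.1),
                                 RNIL = stats::runif(n_genotypes, 0.2, 1.1),
                                 RLER = stats::runif(n_genotypes, 0.2, 1.1))
  } else {
    stopifnot(all(c("genotype_id", "RGR", "RNIL", "RLER") %in%
                    names(effect_profile)))
    ids <- effect_profile$genotype_id
    n_genotypes <- length(ids)
  }
  sti <- as.matrix(effect_profile[, c("RGR", "RNIL", "RLER")])
  if (any(sti <= 0) || any(sti > 1.8))
    stop("profile error: true STI must lie in (0, 1.8]")
  rec <- list()
  emit <- function(g, trt, rep_, measure, das, value)
    rec[[length(rec) + 1L]] <<- data.frame(
      genotype_id = g, treatment = trt, replicate = rep_,
      measure = measure, das = das, value = value)
  for (i in seq_len(n_genotypes)) {
    g <- ids[i]
    gr_ck <- stats::runif(1, 0.2, 0.6)    # cm/day
    nil_ck <- stats::runif(1, 1.5, 3.0)   # leaves over 16 days
    ler_ck <- stats::runif(1, 0.8, 1.6)   # cm/day
    h2 <- stats::runif(1, 8, 15); l2 <- stats::runif(1, 4, 8)
    leaves1 <- round(stats::runif(1, 3, 6))
    for (trt in c("control", "stress")) {
      f <- if (trt == "control") c(1, 1, 1) else sti[i, ]
      for (r in seq_len(replicates)) {
        eps <- if (noise_sd > 0) stats::rnorm(3, 0, noise_sd) else c(0, 0, 0)
        gr <- gr_ck * f[1] * exp(eps[1])
        nil <- nil_ck * f[2] * exp(eps[2])
        ler <- ler_ck * f[3] * exp(eps[3])
        emit(g, trt, r, "height_cm", 2, h2)
        emit(g, trt, r, "height_cm", 7, h2 + 5 * gr)
        emit(g, trt, r, "height_cm", 17, h2 + 15 * gr)
        emit(g, trt, r, "leaf_count", 1, leaves1)
        emit(g, trt, r, "leaf_count", 17, leaves1 + nil)
        emit(g, trt, r, "leaf_length_cm", 2, l2)
        emit(g, trt, r, "leaf_length_cm", 7, l2 + 5 * ler)
        emit(g, trt, r, "leaf_length_cm", 12, l2 + 10 * ler)
        sf <- stats::runif(1, 2, 6); rf <- stats::runif(1, 1, 3)
        emit(g, trt, r, "shoot_fresh_g", NA, sf)
        emit(g, trt, r, "shoot_dry_g", NA, sf * stats::runif(1, 0.72, 0.95))
        emit(g, trt, r, "root_fresh_g", NA, rf)
        emit(g, trt, r, "root_dry_g", NA, rf * stats::runif(1, 0.78, 0.96))
        if (trt == "stress") {
          emit(g, trt, r, "senescence_score", NA,
               sample(seq(3, 9, 2), 1L))
          emit(g, trt, r, "shoot_na_mg_g", NA, stats::runif(1, 53, 220))
          emit(g, trt, r, "root_na_mg_g", NA, stats::runif(1, 24, 82))
          emit(g, trt, r, "shoot_k_mg_g", NA, stats::runif(1, 44, 105))
          emit(g, trt, r, "root_k_mg_g", NA, stats::runif(1, 13, 40))
        }
      }
    }
  }
  list(records = do.call(rbind, rec), effect_profile = effect_profile)
}

#' Simulate a mean salt-injury dose-response table
#'
#' Mean SII per NaCl concentration = intercept + slope * C plus seeded
#' Gaussian noise, clipped to \[0, 1\].
#'
#' @param intercept,slope Line parameters (slope > 0 for an injury curve).
#' @param concentrations NaCl levels (mM), default the screening design
#'   c(0, 100, 150, 200, 250).
#' @param noise_sd Gaussian noise SD on the mean SII (>= 0).
#' @param seed Integer RNG seed.
#' @return Data frame with columns `concentration_mM`, `mean_sii`.
#' @export
simulate_dose_response <- function(intercept, slope,
                                   concentrations = c(0, 100, 150, 200, 250),
                                   noise_sd = 0, seed = 1L) {
  if (slope <= 0) stop("slope must be > 0 for an injury curve")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  mu <- intercept + slope * concentrations
  sii <- mu + if (noise_sd > 0) stats::rnorm(length(mu), 0, noise_sd) else 0
  data.frame(concentration_mM = concentrations,
             mean_sii = pmin(pmax(sii, 0), 1))
}

#' Simulate a panel with planted cluster geometry
#'
#' Builds a trait table whose rows form `n_clusters` well-separated groups
#' in Gower space: cluster centroids are spread along every trait's range
#' so that centroid-to-centroid Gower distance is at least `separation`,
#' and within-cluster spread is at most a quarter of the separation. Used
#' to test that core selection places one entry per cluster.
#'
#' @param n_clusters Number of clusters (>= 1).
#' @param per_cluster Genotypes per cluster.
#' @param separation Minimum centroid Gower distance in (0, 1).
#' @param seed Integer RNG seed.
#' @return A [trait_table()] with attribute `cluster` (integer vector of
#'   true cluster memberships).
#' @export
simulate_clustered_panel <- function(n_clusters = 3L, per_cluster = 5L,
                                     separation = 0.5, seed = 1L) {
  if (separation <= 0) stop("separation must be > 0")
  if (n_clusters > 1L && (n_clusters - 1L) * separation > 1)
    stop("infeasible packing: (n_clusters - 1) * separation exceeds the unit Gower range")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  n <- n_clusters * per_cluster
  centers <- if (n_clusters == 1L) 0.5 else seq(0, 1, length.out = n_clusters)
  cluster <- rep(seq_len(n_clusters), each = per_cluster)
  jitter_hw <- separation / 8   # half-width: within-cluster spread <= sep/4
  u <- matrix(NA_real_, n, 14L, dimnames = list(NULL, trait_names()))
  for (j in seq_len(14L)) {
    off <- stats::runif(n, -jitter_hw, jitter_hw)
    u[, j] <- pmin(pmax(centers[cluster] + off, 0), 1)
  }
  # map unit-scale coordinates onto plausible trait scales
  m <- default_synthetic_spec()$marginals
  x <- sweep(sweep(u, 2L, m$max - m$min, "*"), 2L, m$min, "+")
  df <- data.frame(genotype_id = sprintf("G%03d", seq_len(n)),
                   as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  out <- trait_table(df)
  attr(out, "cluster") <- cluster
  out
}
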