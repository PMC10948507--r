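test_that("core identical to entire gives the identity metrics", {
  tab <- random_trait_table(20, seed = 1)
  rep_ <- representativeness_metrics(tab, tab)
  expect_equal(rep_$per_trait$MD, rep(0, 14))
  expect_equal(rep_$per_trait$VD, rep(0, 14))
  expect_equal(rep_$per_trait$CR, rep(100, 14))
  expect_equal(rep_$per_trait$VR, rep(100, 14))
  expect_true(all(rep_$per_trait$p_mean > 0.99))
  expect_true(all(rep_$per_trait$p_levene > 0.99))
  expect_true(all(rep_$per_trait$p_wilcoxon > 0.99))
  expect_true(rep_$verdict$md_below_20)
  expect_true(rep_$verdict$cr_above_80)
})

test_that("metrics match direct arithmetic on a toy pair", {
  # entire = 1..10, core = {1, 5, 10}
  e <- 1:10; c_ <- c(1, 5, 10)
  base <- random_trait_table(10, seed = 2)
  df <- as.data.frame(base); df$RGR <- e
  entire <- trait_table(df)
  core <- trait_table(df[c(1, 5, 10), ])  # rows carry RGR = 1, 5, 10
  r <- representativeness_metrics(entire, core)$per_trait
  row <- r[r$trait == "RGR", ]
  expect_equal(row$CR, 100)
  expect_equal(row$MD, abs(mean(c_) - mean(e)) / mean(e) * 100,
               tolerance = 1e-12)
  cve <- sd(e) / mean(e); cvc <- sd(c_) / mean(c_)
  expect_equal(row$VR, cvc / cve * 100, tolerance = 1e-12)
  expect_equal(row$VD, abs(cvc - cve) / cvc * 100, tolerance = 1e-12)
})

test_that("VD equals (VR - 100)/VR x 100 whenever the core is more variable", {
  tab <- random_trait_table(100, seed = 3)
  core <- trait_table(as.data.frame(tab)[seq(1, 100, by = 5), ])
  r <- representativeness_metrics(tab, core)$per_trait
  wider <- r$VR > 100
  expect_equal(r$VD[wider], (r$VR[wider] - 100) / r$VR[wider] * 100,
               tolerance = 1e-9)
  # a strict subset can never exceed the entire set's range
  expect_true(all(r$CR <= 100 + 1e-12))
})

test_that("Shannon index follows the distinct-value closed form", {
  expect_equal(shannon_weaver(rep(3.2, 50)), 0)
  expect_equal(shannon_weaver(1:318), log(318), tolerance = 1e-12)
  expect_equal(log(318), 5.762, tolerance = 5e-4)
  expect_equal(shannon_weaver(c(1, 1, 2, 3)), 1.0397, tolerance = 1e-4)
  # bounded by ln(n), equality iff all unique
  set.seed(4)
  v <- sample(1:40, 60, replace = TRUE)
  expect_lt(shannon_weaver(v), log(60))
  expect_equal(shannon_weaver(rnorm(60)), log(60), tolerance = 1e-12)
  # fixed-bin alternative stays defined and smaller
  expect_lt(shannon_weaver(rnorm(60), scheme = "fixed_bins", bins = 5),
            log(5) + 1e-12)
  expect_error(shannon_weaver(numeric(0)), "empty")
})

test_that("distribution tests are calibrated and powered", {
  set.seed(5)
  x <- rnorm(40)
  same <- distribution_tests(x, x)
  expect_gt(same$p_mean, 0.99)
  expect_gt(same$p_levene, 0.99)
  expect_gt(same$p_wilcoxon, 0.99)

  expect_warning(z <- distribution_tests(rep(1, 5), rep(1, 6)),
                 "zero variance")
  expect_equal(z$p_mean, 1)

  # shifted by 5 pooled SDs: decisive rejection
  shifted <- distribution_tests(rnorm(300), rnorm(64, mean = 5))
  expect_lt(shifted$p_mean, 1e-6)
  expect_lt(shifted$p_wilcoxon, 1e-6)

  # two-group Newman-Keuls q-test collapses to the pooled t-test
  a <- rnorm(30); b <- rnorm(25, 0.3)
  expect_equal(distribution_tests(a, b)$p_mean,
               t.test(b, a, var.equal = TRUE)$p.value, tolerance = 1e-10)

  skip_if_not_installed("car")
  grp <- factor(rep(c("e", "c"), c(30, 25)))
  expect_equal(distribution_tests(a, b)$p_levene,
               car::leveneTest(c(a, b), grp)[["Pr(>F)"]][1],
               tolerance = 1e-10)
})

test_that("null p-values are uniform under repeated equal-parameter sampling", {
  set.seed(6)
  reps <- 400
  ps <- t(sapply(seq_len(reps), function(i) {
    e <- rnorm(300); c_ <- rnorm(64)
    unlist(distribution_tests(e, c_))
  }))
  for (col in c("p_mean", "p_levene", "p_wilcoxon")) {
    ks <- suppressWarnings(ks.test(ps[, col], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("correlation structure is preserved in large random halves", {
  expect_equal(correlation_preservation(
    random_trait_table(30, seed = 7),
    random_trait_table(30, seed = 7))$max_abs_delta, 0)

  # planted r = 0.7 between two traits survives halving
  set.seed(8)
  n <- 120
  z <- rnorm(n)
  df <- as.data.frame(random_trait_table(n, seed = 8))
  df$SWC <- 15 + 3 * (sqrt(0.7) * z + sqrt(0.3) * rnorm(n))
  df$RWC <- 11 + 2 * (sqrt(0.7) * z + sqrt(0.3) * rnorm(n))
  entire <- trait_table(df)
  core <- trait_table(df[sample(n, 60), ])
  cp <- correlation_preservation(entire, core)
  expect_lt(abs(cp$r_entire["SWC", "RWC"] - 0.7), 0.15)
  expect_lt(abs(cp$r_core["SWC", "RWC"] - 0.7), 0.15)
  expect_equal(sign(cp$r_core["SWC", "RWC"]),
               sign(cp$r_entire["SWC", "RWC"]))

  # constant column masked
  df$Sen <- 5
  cp2 <- correlation_preservation(trait_table(df), trait_table(df))
  expect_true(all(is.na(cp2$r_entire["Sen", setdiff(trait_names(), "Sen")])))
})

test_that("correlation-matrix PCA has the stated spectral properties", {
  tab <- random_trait_table(80, seed = 9)
  pc <- pca_compare(tab, tab, n_components = 5)
  ve <- pc$entire$variance_explained
  expect_true(all(diff(ve) <= 1e-12))
  expect_lte(pc$entire$cumulative[5], 100 + 1e-9)
  expect_equal(crossprod(pc$entire$loadings), diag(5), tolerance = 1e-9,
               ignore_attr = TRUE)
  # sign convention: largest loading positive
  for (j in 1:5) {
    col <- pc$entire$loadings[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
  # affine rescale of a column leaves correlation PCA unchanged
  df <- as.data.frame(tab); df$SNC <- df$SNC * 100 - 7
  pc2 <- pca_compare(trait_table(df), trait_table(df), n_components = 5)
  expect_equal(pc2$entire$variance_explained, ve, tolerance = 1e-9)

  # two correlated traits: PC1 share is (1 + r) / 2
  set.seed(10)
  z <- rnorm(500); y <- sqrt(0.9) * z + sqrt(0.1) * rnorm(500)
  x2 <- cbind(a = z, b = y)
  r <- cor(x2)[1, 2]
  ev <- eigen(cor(x2))$values
  expect_equal(ev[1] / 2, (1 + r) / 2, tolerance = 1e-12)
  # both sets warn once about truncation
  expect_warning(expect_warning(pca_compare(tab, tab, n_components = 20),
                                "truncated"), "truncated")
})
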