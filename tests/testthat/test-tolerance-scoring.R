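test_that("membership values hit the stated boundaries and midpoint", {
  dirs <- c(up = "positive", down = "negative")
  x <- cbind(up = c(1, 3, 5), down = c(10, 30, 50))
  m <- membership_matrix(x, directions = dirs)
  expect_equal(unname(m$F[1, "up"]), 0)   # trait minimum, positive direction
  expect_equal(unname(m$F[3, "up"]), 1)
  expect_equal(unname(m$F[3, "down"]), 0) # trait maximum, negative direction
  expect_equal(unname(m$F[1, "down"]), 1)
  expect_equal(unname(m$F[2, ]), c(0.5, 0.5))  # midpoint either direction
  # hand-computed toy: F = (x - min) / range, flipped for 'down'
  x2 <- cbind(up = c(2, 4, 8), down = c(1, 2, 5))
  m2 <- membership_matrix(x2, directions = dirs)
  expect_equal(unname(m2$F[, "up"]), c(0, 2 / 6, 1), tolerance = 1e-12)
  expect_equal(unname(m2$F[, "down"]), 1 - c(0, 1 / 4, 1), tolerance = 1e-12)
})

test_that("degenerate traits score 0.5 with a warning, not an error", {
  x <- cbind(a = c(1, 2, 3), b = c(7, 7, 7))
  expect_warning(m <- membership_matrix(
    x, directions = c(a = "positive", b = "positive")), "degenerate")
  expect_equal(unname(m$F[, "b"]), rep(0.5, 3))
})

test_that("D is the row mean of memberships and lies in [0, 1]", {
  expect_equal(unname(comprehensive_d(rbind(c(1, 1, 1)))), 1)
  expect_equal(unname(comprehensive_d(rbind(c(0, 0, 0)))), 0)
  expect_equal(unname(comprehensive_d(rbind(c(0.2, 0.4, 0.9)))), 0.5)
  expect_error(comprehensive_d(matrix(numeric(0), nrow = 2)), "empty")
  tab <- random_trait_table(40, seed = 9)
  d <- comprehensive_d(membership_matrix(tab))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("membership and D respect the stated invariances", {
  tab <- random_trait_table(30, seed = 5)
  f0 <- membership_matrix(tab)$F
  d0 <- comprehensive_d(f0)
  # strictly increasing affine rescale of one column leaves D unchanged
  df <- as.data.frame(tab)
  df$SNC <- 3.7 * df$SNC + 12
  d1 <- comprehensive_d(membership_matrix(trait_table(df)))
  expect_equal(d1, d0, tolerance = 1e-12)
  # flipping one trait's direction maps F -> 1 - F and shifts D by delta/n
  dirs <- default_trait_directions()
  dirs["RGR"] <- "negative"
  f2 <- membership_matrix(trait_values(tab), directions = dirs)$F
  expect_equal(f2[, "RGR"], 1 - f0[, "RGR"], tolerance = 1e-12)
  d2 <- comprehensive_d(f2)
  expect_equal(d2 - d0, (f2[, "RGR"] - f0[, "RGR"]) / 14, tolerance = 1e-12)
})

test_that("one-dimensional clustering cuts into ranked grade groups", {
  d <- c(a = 0.9, b = 0.89, c = 0.6, e = 0.61, f = 0.3)
  # brute-force single-linkage on 1-D points: gaps > 0.12 split at 0.61/0.89
  cls <- classify_tolerance(d, cut_height = 0.12, linkage = "single")
  expect_equal(length(unique(cls$cluster)), 3L)
  expect_equal(as.character(cls$labels[c("a", "c", "f")]),
               c("HST", "MST", "HSS"))
  expect_equal(as.character(cls$labels[["b"]]), "HST")
  expect_equal(as.character(cls$labels[["e"]]), "MST")

  expect_warning(one <- classify_tolerance(rep(0.5, 4)), "identical")
  expect_true(all(one$labels == "MST"))

  # two well-separated groups: exactly 2 labels, means ordered
  d2 <- c(rep(0.8, 3) + c(0, 0.01, 0.02), rep(0.2, 3) + c(0, 0.01, 0.02))
  cls2 <- classify_tolerance(d2, cut_height = 0.12)
  expect_equal(nlevels(droplevels(cls2$labels)), 2L)
  means <- tapply(d2, cls2$labels[drop = TRUE], mean)
  expect_true(all(diff(means) < 0))  # grade order HST..HSS is descending D
})

test_that("grade labels are ordered by descending within-cluster mean D", {
  set.seed(21)
  d <- c(runif(5, 0.8, 0.85), runif(5, 0.5, 0.55), runif(5, 0.1, 0.15))
  names(d) <- sprintf("g%02d", 1:15)
  cls <- classify_tolerance(d, cut_height = 0.12)
  means <- tapply(d, cls$labels[drop = TRUE], mean)
  expect_true(all(diff(means) < 0))
})

test_that("a noiseless affine D is recovered exactly by the fixed fit", {
  tab <- random_trait_table(60, seed = 13)
  ref <- reference_tolerance_model()
  d <- predict_tolerance(ref, as.data.frame(tab))$Y
  fit <- fit_tolerance_model(tab, d)
  expect_equal(fit$intercept, ref$intercept, tolerance = 1e-8)
  expect_equal(fit$coefficients[ref$predictors],
               ref$coefficients[ref$predictors], tolerance = 1e-8)
  expect_equal(fit$diagnostics$r_squared, 1, tolerance = 1e-10)
})

test_that("forward stepwise selects exactly the planted signal traits", {
  tab <- random_trait_table(200, seed = 31)
  set.seed(32)
  x <- trait_values(tab)
  d <- 0.3 + 0.004 * x[, "RWC"] + 0.15 * x[, "RNIL"] + rnorm(200, 0, 0.005)
  fit <- fit_tolerance_model(tab, d, mode = "stepwise")
  expect_setequal(fit$predictors, c("RWC", "RNIL"))
})

test_that("prediction matches the published verification panel", {
  model <- reference_tolerance_model()
  vp <- verification_panel()
  pred <- predict_tolerance(model, vp)
  expect_true(all(abs(pred$Y_rounded - vp$Y) <= 5e-4))
  # intercept identity
  zero <- setNames(rep(0, 7), model$predictors)
  expect_identical(predict_tolerance(model, zero)$Y, 0.6895)
  expect_error(predict_tolerance(model, c(SNC = 1)), "RNIL")
})

test_that("tolerance model YAML round-trips", {
  m <- tolerance_model(0.5, c(A = 1.25, B = -0.5),
                       diagnostics = list(r_squared = 0.9))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_tolerance_model(m, path)
  back <- load_tolerance_model(path)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$coefficients, m$coefficients)
})
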