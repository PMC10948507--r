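#' Fuzzy membership function values for a trait table
#'
#' Min-max normalizes every trait column to \[0, 1\]. For traits positively
#' associated with tolerance, F = (X - min) / (max - min); for
#' negative-direction traits the scale is flipped, F = 1 - (X - min) /
#' (max - min), so that a higher membership value always means more
#' tolerant. The per-trait minimum and maximum are taken over the rows of
#' the supplied table.
#'
#' A trait whose maximum equals its minimum carries no information; its
#' column is set to 0.5 with a warning.
#'
#' @param table A [trait_table()] with at least two genotypes, or a plain
#'   numeric matrix (genotypes x traits) with named columns.
#' @param directions Direction map for matrix input; ignored for a
#'   `trait_table`, which carries its own.
#' @return Object of class `membership_matrix`: list with `F` (genotype x
#'   trait matrix), `xmin`, `xmax` (named per-trait vectors) and
#'   `directions`.
#' @export
membership_matrix <- function(table, directions = NULL) {
  if (inherits(table, "trait_table")) {
    x <- trait_values(table)
    dirs <- trait_directions(table)
  } else {
    x <- as.matrix(table)
    if (is.null(colnames(x))) stop("matrix input needs column names")
    dirs <- directions
    if (is.null(dirs) || !all(colnames(x) %in% names(dirs)))
      stop("directions must be supplied and cover every column")
  }
  if (nrow(x) < 2L) stop("need >= 2 genotypes for membership scaling")
  if (anyNA(x)) stop("trait table contains missing values")
  xmin <- apply(x, 2L, min)
  xmax <- apply(x, 2L, max)
  f <- x
  for (j in seq_len(ncol(x))) {
    rng <- xmax[j] - xmin[j]
    if (rng == 0) {
      warning("degenerate trait (max = min): ", colnames(x)[j],
              "; membership set to 0.5")
      f[, j] <- 0.5
      next
    }
    fj <- (x[, j] - xmin[j]) / rng
    f[, j] <- if (dirs[[colnames(x)[j]]] == "negative") 1 - fj else fj
  }
  structure(list(F = f, xmin = xmin, xmax = xmax, directions = dirs),
            class = "membership_matrix")
}

#' Comprehensive salt-tolerance score (D value)
#'
#' The D value of a genotype is the arithmetic mean of its membership
#' function values across the supplied traits; D lies in \[0, 1\] and higher
#' D means more salt tolerant.
#'
#' @param mfv A [membership_matrix()] or a plain numeric matrix of
#'   membership values.
#' @return Named numeric vector of D values (one per genotype).
#' @export
comprehensive_d <- function(mfv) {
  f <- if (inherits(mfv, "membership_matrix")) mfv$F else as.matrix(mfv)
  if (ncol(f) == 0L) stop("undefined mean: empty trait set")
  if (anyNA(f)) stop("membership matrix contains missing values")
  rowMeans(f)
}

.tolerance_grades <- c("HST", "ST", "MST", "SS", "HSS")

#' Classify genotypes into tolerance grades
#'
#' Agglomerative hierarchical clustering of the one-dimensional D values
#' (Euclidean distance), with the tree cut at a fixed height. Clusters are
#' ranked by mean D and mapped onto the five tolerance grades HST (highly
#' salt tolerant), ST, MST, SS, HSS (highly salt sensitive) in descending
#' order of mean D. When the cut yields fewer than five clusters the grades
#' are spread evenly across the five-point scale (e.g. three clusters map
#' to HST/MST/HSS, a single cluster to MST); when it yields more than five,
#' the two clusters with the closest mean D are merged until five remain.
#'
#' @param d_values Named numeric vector of D values.
#' @param cut_height Tree cut height on the D (Euclidean) scale; default
#'   0.12.
#' @param linkage Agglomeration method, one of `"complete"` (default),
#'   `"single"`, `"average"`, `"ward.D2"`.
#' @return Object of class `tolerance_classification`: list with `labels`
#'   (named factor over the grades), `cluster` (integer assignment),
#'   `cluster_mean_d`, `cut_height`, `linkage` and the `hclust` tree.
#' @export
classify_tolerance <- function(d_values, cut_height = 0.12,
                               linkage = c("complete", "single", "average",
                                           "ward.D2")) {
  linkage <- match.arg(linkage)
  n <- length(d_values)
  if (n < 2L) stop("need >= 2 genotypes to classify")
  ids <- if (is.null(names(d_values))) as.character(seq_len(n))
         else names(d_values)
  if (stats::var(d_values) == 0) {
    warning("all D values identical: single MST cluster")
    labels <- factor(rep("MST", n), levels = .tolerance_grades)
    names(labels) <- ids
    return(structure(list(labels = labels, cluster = rep(1L, n),
                          cluster_mean_d = c(`1` = mean(d_values)),
                          cut_height = cut_height, linkage = linkage,
                          tree = NULL),
                     class = "tolerance_classification"))
  }
  tree <- stats::hclust(stats::dist(d_values), method = linkage)
  cl <- stats::cutree(tree, h = cut_height)
  means <- tapply(d_values, cl, mean)
  # merge closest-mean clusters until at most five remain
  while (length(means) > 5L) {
    o <- order(means)
    gaps <- diff(means[o])
    i <- which.min(gaps)
    from <- as.integer(names(means)[o][i + 1L])
    to <- as.integer(names(means)[o][i])
    cl[cl == from] <- to
    means <- tapply(d_values, cl, mean)
  }
  k <- length(means)
  grade_idx <- round(seq(1, 5, length.out = k))
  rank_desc <- order(means, decreasing = TRUE)  # position in descending mean D
  grade_of_cluster <- stats::setNames(.tolerance_grades[grade_idx],
                                      names(means)[rank_desc])
  labels <- factor(grade_of_cluster[as.character(cl)],
                   levels = .tolerance_grades)
  names(labels) <- ids
  structure(list(labels = labels, cluster = cl, cluster_mean_d = means,
                 cut_height = cut_height, linkage = linkage, tree = tree),
            class = "tolerance_classification")
}

#' @export
print.tolerance_classification <- function(x, ...) {
  cat("<tolerance_classification>", length(x$labels), "genotypes;",
      "cut height", x$cut_height, "(", x$linkage, "linkage )\n")
  print(table(x$labels))
  invisible(x)
}

#' Construct a tolerance model
#'
#' An affine predictive model of the comprehensive salt-tolerance score:
#' Y = mu + sum(beta_i * X_i) over the named predictor traits.
#'
#' @param intercept Model constant mu.
#' @param coefficients Named numeric vector of per-predictor coefficients.
#' @param diagnostics Optional list (e.g. `r_squared`, coefficient table,
#'   collinearity flag).
#' @return Object of class `tolerance_model`.
#' @export
tolerance_model <- function(intercept, coefficients, diagnostics = list()) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coefficients), !is.null(names(coefficients)))
  structure(list(intercept = unname(intercept),
                 predictors = names(coefficients),
                 coefficients = coefficients,
                 diagnostics = diagnostics),
            class = "tolerance_model")
}

#' @export
print.tolerance_model <- function(x, ...) {
  cat("<tolerance_model> Y =", format(x$intercept),
      paste(sprintf("%+g*%s", x$coefficients, x$predictors), collapse = " "),
      "\n")
  if (!is.null(x$diagnostics$r_squared))
    cat("  R^2 =", format(x$diagnostics$r_squared), "\n")
  invisible(x)
}

# OLS of y on the columns `sel` of X, returning RSS and the fit pieces.
.ols_fit <- function(X, y, sel) {
  Xm <- cbind(`(Intercept)` = 1, X[, sel, drop = FALSE])
  fit <- stats::lm.fit(Xm, y)
  rss <- sum(fit$residuals^2)
  list(fit = fit, rss = rss, df_resid = length(y) - ncol(Xm))
}

#' Fit the predictive tolerance regression
#'
#' Ordinary least squares of the comprehensive D value on trait columns. In
#' `"fixed_predictors"` mode (default) the regression uses a named predictor
#' subset -- by default the seven traits SNC, RNIL, RWC, RGR, RKC, Sen, RNC
#' of the published seedling model. In `"stepwise"` mode forward selection
#' adds, at each step, the candidate with the largest partial F statistic
#' until no candidate enters at p < `alpha_enter`.
#'
#' @param table A [trait_table()].
#' @param d Numeric vector of D values, one per table row.
#' @param mode `"fixed_predictors"` or `"stepwise"`.
#' @param predictors Predictor trait names for fixed mode.
#' @param alpha_enter Forward-selection entry threshold (default 0.05).
#' @return A [tolerance_model()] with diagnostics: `r_squared`,
#'   `coefficient_table` (estimate, se, t, p) and `collinearity_warning`
#'   (TRUE when the standardized design's condition number exceeds 30).
#' @export
fit_tolerance_model <- function(table, d,
                                mode = c("fixed_predictors", "stepwise"),
                                predictors = c("SNC", "RNIL", "RWC", "RGR",
                                               "RKC", "Sen", "RNC"),
                                alpha_enter = 0.05) {
  mode <- match.arg(mode)
  X <- trait_values(table)
  if (nrow(X) != length(d))
    stop("length of d must equal the number of table rows")
  if (mode == "fixed_predictors") {
    bad <- setdiff(predictors, colnames(X))
    if (length(bad) > 0L)
      stop("unknown predictor(s): ", paste(bad, collapse = ", "))
    sel <- predictors
  } else {
    sel <- character(0)
    cand <- colnames(X)[apply(X, 2L, stats::var) > 0]
    base <- .ols_fit(X, d, sel)
    repeat {
      rest <- setdiff(cand, sel)
      if (length(rest) == 0L) break
      ps <- vapply(rest, function(v) {
        trial <- .ols_fit(X, d, c(sel, v))
        if (trial$df_resid <= 0) return(NA_real_)
        f <- (base$rss - trial$rss) / (trial$rss / trial$df_resid)
        stats::pf(f, 1, trial$df_resid, lower.tail = FALSE)
      }, numeric(1))
      if (all(is.na(ps)) || min(ps, na.rm = TRUE) >= alpha_enter) break
      pick <- rest[which.min(ps)]
      sel <- c(sel, pick)
      base <- .ols_fit(X, d, sel)
    }
    if (length(sel) == 0L)
      stop("stepwise selection admitted no predictor at p < ", alpha_enter)
  }
  if (nrow(X) < length(sel) + 2L)
    stop("need at least ", length(sel) + 2L, " rows to fit ", length(sel),
         " predictors")

  res <- .ols_fit(X, d, sel)
  fit <- res$fit
  if (any(is.na(fit$coefficients))) stop("singular design: fit failed")
  co <- fit$coefficients
  sigma2 <- res$rss / res$df_resid
  Xm <- cbind(`(Intercept)` = 1, X[, sel, drop = FALSE])
  XtXinv <- chol2inv(chol(crossprod(Xm)))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- co / se
  pval <- 2 * stats::pt(abs(tval), res$df_resid, lower.tail = FALSE)
  tss <- sum((d - mean(d))^2)
  r2 <- if (tss == 0) 1 else 1 - res$rss / tss
  Z <- scale(X[, sel, drop = FALSE])
  cond <- kappa(Z, exact = TRUE)
  diagnostics <- list(
    r_squared = r2,
    sigma = sqrt(sigma2),
    coefficient_table = data.frame(estimate = co, se = se, t = tval,
                                   p = pval),
    condition_number = cond,
    collinearity_warning = is.finite(cond) && cond > 30,
    mode = mode)
  tolerance_model(co[[1L]], co[-1L], diagnostics)
}

#' Predict the comprehensive tolerance score from a model
#'
#' Evaluates Y = mu + sum(beta_i * X_i) for one or more genotypes.
#'
#' @param model A [tolerance_model()].
#' @param traits Named numeric vector (one genotype) or data frame / matrix
#'   with one column per model predictor.
#' @return List with `Y` (full precision) and `Y_rounded` (4 decimals,
#'   matching the reporting precision of the published tables).
#' @export
predict_tolerance <- function(model, traits) {
  if (is.null(dim(traits))) traits <- t(as.matrix(traits))
  traits <- as.data.frame(traits)
  missing_p <- setdiff(model$predictors, colnames(traits))
  if (length(missing_p) > 0L)
    stop("missing predictor(s): ", paste(missing_p, collapse = ", "))
  Xm <- as.matrix(traits[, model$predictors, drop = FALSE])
  storage.mode(Xm) <- "double"
  y <- drop(model$intercept + Xm %*% model$coefficients[model$predictors])
  list(Y = y, Y_rounded = round(y, 4L))
}

#' Read / write a tolerance model as YAML
#'
#' @param model A [tolerance_model()].
#' @param path YAML file path.
#' @return `load_tolerance_model`: a [tolerance_model()].
#' @export
write_tolerance_model <- function(model, path) {
  yaml::write_yaml(list(intercept = model$intercept,
                        coefficients = as.list(model$coefficients),
                        r_squared = model$diagnostics$r_squared), path)
  invisible(path)
}

#' @rdname write_tolerance_model
#' @export
load_tolerance_model <- function(path) {
  obj <- yaml::read_yaml(path)
  tolerance_model(obj$intercept, unlist(obj$coefficients),
                  diagnostics = list(r_squared = obj$r_squared))
}
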