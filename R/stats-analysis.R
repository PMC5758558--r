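#' Cross-tabulate cell records by two factors
#'
#' @param records data frame of cell records.
#' @param factor_row,factor_col column names to tabulate.
#' @return contingency table (class `table`) of counts.
#' @export
crosstab <- function(records, factor_row, factor_col) {
  stopifnot(factor_row %in% names(records), factor_col %in% names(records))
  table(records[[factor_row]], records[[factor_col]],
        dnn = c(factor_row, factor_col))
}

#' Pearson chi-square test of independence
#'
#' Classical Pearson statistic `sum((O - E)^2 / E)` with
#' `df = (r - 1)(c - 1)` and no continuity correction.
#'
#' @param tab matrix/table of non-negative counts.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi2_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin: expected counts undefined")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

#' Bonett's test for equality of two variances
#'
#' Kurtosis-adjusted ratio-of-variances procedure of Bonett (2006): the log
#' variance ratio, with a small-sample correction factor, is compared
#' against a standard-error built from a pooled kurtosis estimate.  The
#' kurtosis is estimated about trimmed means with trim proportion
#' `1/(2*sqrt(n - 4))`; for n <= 4 (where that proportion is undefined) the
#' untrimmed mean is used.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param alpha significance level used in the correction factor.
#' @return list with `statistic` (z), `p_value`, `ratio` (var(x)/var(y)).
#' @export
bonett_test <- function(x, y, alpha = 0.05) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs n >= 2")
  trim_mean <- function(v) {
    n <- length(v)
    if (n <= 4) return(mean(v))
    mean(v, trim = 1 / (2 * sqrt(n - 4)))
  }
  m1 <- trim_mean(x); m2 <- trim_mean(y)
  s1 <- stats::var(x); s2 <- stats::var(y)
  if (s1 == 0 || s2 == 0) stop("zero-variance sample")
  pk <- (n1 + n2) * (sum((x - m1)^4) + sum((y - m2)^4)) /
    (sum((x - m1)^2) + sum((y - m2)^2))^2
  se <- sqrt((pk - (n1 - 3) / n1) / (n1 - 1) +
             (pk - (n2 - 3) / n2) / (n2 - 1))
  za <- stats::qnorm(1 - alpha / 2)
  cc <- (n1 / (n1 - za)) / (n2 / (n2 - za))
  z <- log(cc * s1 / s2) / se
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)), ratio = s1 / s2)
}

#' Compare two means with a variance-test-gated t test
#'
#' Runs Bonett's variance-equality test first; if equality is rejected at
#' `alpha`, Welch's unequal-variance t test is used, otherwise the pooled
#' t test.  The Welch degrees of freedom are truncated to the integer below
#' (the convention of common commercial statistics software, which this
#' battery reproduces so that printed p values can be compared directly).
#'
#' @param x,y numeric samples (n >= 2 each).
#' @param alpha significance level for the variance gate.
#' @return list with the variance-test result, the test used
#'   (`"welch"`/`"pooled"`), `t`, `df`, `p_value` and the mean difference.
#' @export
compare_two_means <- function(x, y, alpha = 0.05) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    # degenerate: no within-sample variability at all
    return(list(variance_test = NULL, test = "degenerate",
                t = if (mean(x) == mean(y)) 0 else Inf,
                df = NA_real_,
                p_value = if (mean(x) == mean(y)) 1 else 0,
                mean_diff = mean(x) - mean(y)))
  }
  vt <- bonett_test(x, y, alpha)
  n1 <- length(x); n2 <- length(y)
  d <- mean(x) - mean(y)
  if (vt$p_value < alpha) {
    v1 <- stats::var(x) / n1; v2 <- stats::var(y) / n2
    tstat <- d / sqrt(v1 + v2)
    df <- floor((v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1)))
    used <- "welch"
  } else {
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
      (n1 + n2 - 2)
    tstat <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    used <- "pooled"
  }
  p <- if (tstat == 0) 1 else 2 * stats::pt(-abs(tstat), df)
  list(variance_test = vt, test = used, t = tstat, df = df, p_value = p,
       mean_diff = d)
}

# compact letter display via insert-and-absorb over the significance matrix
.letter_display <- function(sig, names) {
  k <- length(names)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    for (s in seq_along(sets)) {
      if (i %in% sets[[s]] && j %in% sets[[s]]) {
        sets[[length(sets) + 1]] <- setdiff(sets[[s]], i)
        sets[[s]] <- setdiff(sets[[s]], j)
      }
    }
    # absorb empty sets and subsets of other kept sets
    sets <- sets[lengths(sets) > 0]
    keep <- rep(TRUE, length(sets))
    for (a in seq_along(sets)) for (b in seq_along(sets)) {
      if (a != b && keep[a] && keep[b] &&
          all(sets[[a]] %in% sets[[b]])) keep[a] <- FALSE
    }
    sets <- sets[keep]
  }
  sets <- sets[order(vapply(sets, min, 1L))]
  letters_out <- character(k)
  for (s in seq_along(sets)) {
    for (i in sets[[s]]) {
      letters_out[i] <- paste0(letters_out[i], letters[s])
    }
  }
  stats::setNames(letters_out, names)
}

#' Welch's ANOVA with Games-Howell pairwise comparisons
#'
#' Heteroscedastic one-way comparison: Welch's F test for equality of group
#' means, followed (when >= 2 groups survive) by Games-Howell pairwise
#' comparisons using studentized-range quantiles with Welch-type pairwise
#' degrees of freedom, and a compact letter display (groups sharing a
#' letter are not significantly different).
#'
#' @param values numeric response vector.
#' @param groups group labels (coerced to factor).
#' @param alpha significance level for the letter display.
#' @return list with `welch` (F statistic, dfs, p), `pairwise` data frame
#'   and `letters`.
#' @export
welch_anova_gameshowell <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  ns <- tapply(values, groups, length)
  small <- names(ns)[ns < 2]
  if (length(small)) {
    warning("excluding groups with n < 2: ", paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- droplevels(groups[keep])
    ns <- tapply(values, groups, length)
  }
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups with n >= 2")
  ow <- stats::oneway.test(values ~ groups, var.equal = FALSE)
  means <- tapply(values, groups, mean)
  vars <- tapply(values, groups, stats::var)
  lev <- levels(groups)
  pw <- NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    vi <- vars[i] / ns[i]; vj <- vars[j] / ns[j]
    se <- sqrt((vi + vj) / 2)            # studentized-range scaling
    df <- (vi + vj)^2 / (vi^2 / (ns[i] - 1) + vj^2 / (ns[j] - 1))
    q <- abs(means[i] - means[j]) / se
    p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    pw <- rbind(pw, data.frame(
      group1 = lev[i], group2 = lev[j],
      diff = unname(means[i] - means[j]), se = unname(se * sqrt(2)),
      df = unname(df), q = unname(q), p_value = unname(p)))
  }
  sig <- matrix(FALSE, k, k)
  for (r in seq_len(nrow(pw))) {
    i <- match(pw$group1[r], lev); j <- match(pw$group2[r], lev)
    sig[i, j] <- sig[j, i] <- pw$p_value[r] < alpha
  }
  list(
    welch = list(statistic = unname(ow$statistic),
                 df1 = unname(ow$parameter[1]),
                 df2 = unname(ow$parameter[2]),
                 p_value = ow$p.value),
    pairwise = pw,
    letters = .letter_display(sig, lev))
}

#' Quadratic discriminant allocation
#'
#' Fits a quadratic discriminant function (group-specific Gaussian
#' densities with unequal covariance matrices) and reports the
#' resubstitution allocation matrix with overall and per-group percent
#' correct.  Priors default to group proportions.  Predictor sets whose
#' pooled, scaled design matrix is ill-conditioned (near-collinear) are
#' refused.
#'
#' @param records data frame.
#' @param predictors character vector of numeric predictor columns.
#' @param group column name of the grouping factor.
#' @param prior `"proportions"` (default) or a numeric vector summing to 1.
#' @param max_condition condition-number bound above which the predictor
#'   set is refused as collinear.
#' @return list of class `qda_model` with the fitted [MASS::qda] object,
#'   `allocation` matrix (rows = true group), `overall_correct` and
#'   `per_group_correct` in percent.
#' @export
qda_allocation <- function(records, predictors, group,
                           prior = "proportions", max_condition = 1e4) {
  stopifnot(all(predictors %in% names(records)), group %in% names(records))
  g <- droplevels(factor(records[[group]]))
  X <- as.matrix(records[predictors])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  ns <- table(g)
  if (any(ns <= length(predictors) + 1))
    stop("each group needs n > number of predictors + 1")
  # collinearity guard on the scaled pooled design
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    # a constant predictor makes every within-group covariance singular
    stop("singular covariance: predictor(s) constant: ",
         paste(predictors[sds == 0], collapse = ", "))
  }
  if (length(predictors) > 1) {
    cn <- kappa(scale(X), exact = TRUE)
    if (cn > max_condition)
      stop(sprintf("predictor set refused: condition number %.3g > %.3g",
                   cn, max_condition))
  }
  for (lv in levels(g)) {
    cv <- stats::cov(X[g == lv, , drop = FALSE])
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= .Machine$double.eps * max(ev) * nrow(cv))
      stop("singular covariance matrix in group '", lv, "'")
  }
  pr <- if (identical(prior, "proportions")) as.numeric(ns) / sum(ns)
        else prior
  fit <- MASS::qda(X, grouping = g, prior = pr)
  pred <- stats::predict(fit, X)$class
  alloc <- table(truth = g, allocated = pred)
  per_group <- 100 * diag(alloc) / rowSums(alloc)
  structure(list(
    fit = fit, predictors = predictors, group = group,
    allocation = alloc,
    overall_correct = 100 * sum(diag(alloc)) / sum(alloc),
    per_group_correct = per_group), class = "qda_model")
}

#' @export
print.qda_model <- function(x, ...) {
  cat("Quadratic discriminant allocation (resubstitution)\n")
  cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  cat(sprintf("  overall %% correct: %.1f\n", x$overall_correct))
  print(x$allocation)
  invisible(x)
}

#' Group summaries of morphometric variables
#'
#' n, mean, standard deviation and coefficient of variation (percent) per
#' variable for each condition x phase x budded group, mirroring the usual
#' descriptive table for yeast morphometry studies.
#'
#' @param records cell-record data frame with `condition`, `phase`,
#'   `budded` columns.
#' @param variables numeric columns to summarize.
#' @return data frame, one row per group x variable.
#' @export
summarize_groups <- function(records,
                             variables = c("area_um2", "perimeter_um",
                                           "dmin_um", "dmax_um",
                                           "elongation", "circularity")) {
  stopifnot(all(c("condition", "phase", "budded") %in% names(records)))
  variables <- intersect(variables, names(records))
  key <- interaction(records$condition, records$phase, records$budded,
                     drop = TRUE, sep = "-")
  out <- NULL
  for (v in variables) {
    n <- tapply(records[[v]], key, function(z) sum(is.finite(z)))
    m <- tapply(records[[v]], key, mean, na.rm = TRUE)
    s <- tapply(records[[v]], key, stats::sd, na.rm = TRUE)
    out <- rbind(out, data.frame(
      group = names(n), variable = v, n = as.integer(n),
      mean = as.numeric(m), sd = as.numeric(s),
      cv_pct = 100 * as.numeric(s) / as.numeric(m)))
  }
  rownames(out) <- NULL
  out
}
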