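#' Group comparison and discriminant classification
#'
#' Statistics for per-subject metric tables: descriptive summaries,
#' normality-driven dispatch between the Welch t-test and the Mann-Whitney
#' test, Welch tests recomputed from printed group summaries, and stepwise
#' linear discriminant analysis driven by Wilks' lambda.
#'
#' @name stats_module
NULL

#' Mean and sample standard deviation
#'
#' @param values numeric vector, `n >= 2`.
#' @return named vector `c(mean =, sd =)`; SD uses the n-1 denominator.
#' @export
describe <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  c(mean = mean(values), sd = stats::sd(values))
}

new_test_result <- function(variable, test_used, statistic, df, p_value,
                            note = NULL) {
  structure(list(variable = variable, test_used = test_used,
                 statistic = statistic, df = df, p_value = p_value,
                 note = note),
            class = "sbp_test")
}

#' @export
print.sbp_test <- function(x, ...) {
  cat(sprintf("%s: %s, statistic = %.4g%s, p = %.4g%s\n",
              x$variable, x$test_used, x$statistic,
              if (!is.null(x$df)) sprintf(", df = %.2f", x$df) else "",
              x$p_value,
              if (!is.null(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

# Lilliefors-type normality screen (Kolmogorov-Smirnov against a normal
# with estimated moments). Groups too small for the test (n < 5) or with
# zero variance cannot pass the screen.
passes_normality <- function(x, alpha) {
  if (length(x) < 5L || stats::sd(x) == 0) return(FALSE)
  nortest::lillie.test(x)$p.value > alpha
}

#' Normality-dispatched two-group test
#'
#' Applies a Kolmogorov-Smirnov normality screen (Lilliefors variant, i.e.
#' with estimated mean and SD) to each group; if both pass at
#' `alpha_normality` the groups are compared with the Welch t-test,
#' otherwise with the two-sided Mann-Whitney test. Mann-Whitney p-values use
#' exact enumeration for small samples (both n <= 8, no ties) and the
#' tie-corrected normal approximation otherwise.
#'
#' @param groupA,groupB numeric vectors, each with `n >= 2`.
#' @param alpha_normality significance level of the normality screen.
#' @param variable label carried into the result.
#' @return an `sbp_test` result: `test_used` (`"t_welch"` or
#'   `"mann_whitney"`), `statistic`, `df` (Welch only), `p_value`.
#' @export
dispatch_test <- function(groupA, groupB, alpha_normality = 0.05,
                          variable = "value") {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0 &&
      isTRUE(all.equal(mean(groupA), mean(groupB)))) {
    message("degenerate input: both groups identical and constant; p = 1")
    return(new_test_result(variable, "degenerate", 0, NULL, 1,
                           note = "identical constant groups"))
  }
  normal <- passes_normality(groupA, alpha_normality) &&
            passes_normality(groupB, alpha_normality)
  if (normal) {
    tt <- stats::t.test(groupA, groupB, var.equal = FALSE)
    new_test_result(variable, "t_welch", unname(tt$statistic),
                    unname(tt$parameter), tt$p.value)
  } else {
    exact <- length(groupA) <= 8L && length(groupB) <= 8L &&
             !any(duplicated(c(groupA, groupB)))
    wt <- suppressWarnings(
      stats::wilcox.test(groupA, groupB, exact = exact, correct = !exact))
    new_test_result(variable, "mann_whitney", unname(wt$statistic), NULL,
                    wt$p.value)
  }
}

#' Welch t-test from printed group summaries
#'
#' Computes the Welch statistic
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value, allowing published group
#' means and SDs to be re-tested without raw data.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @param variable label carried into the result.
#' @return an `sbp_test` result.
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               variable = "value") {
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  if (n1 < 2L || n2 < 2L) stop("group sizes must be >= 2")
  se2 <- sd1^2 / n1 + sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  new_test_result(variable, "t_welch", t, df, p)
}

# Wilks' lambda of a variable subset for a two-group (or g-group) design:
# det(W) / det(T), with W the pooled within-group and T the total
# cross-product matrix.
wilks_lambda <- function(X, groups) {
  X <- as.matrix(X)
  gl <- unique(groups)
  Tm <- crossprod(scale(X, center = TRUE, scale = FALSE))
  Wm <- matrix(0, ncol(X), ncol(X))
  for (g in gl) {
    Xg <- X[groups == g, , drop = FALSE]
    Wm <- Wm + crossprod(scale(Xg, center = TRUE, scale = FALSE))
  }
  det(Wm) / det(Tm)
}

# partial F for adding one variable to a p-variable model (g groups, n obs):
# F = (n - g - p) / (g - 1) * (lambda_p / lambda_{p+1} - 1)
partial_F <- function(lambda_p, lambda_p1, n, g, p) {
  (n - g - p) / (g - 1) * (lambda_p / lambda_p1 - 1)
}

partial_F_p <- function(lambda_p, lambda_p1, n, g, p) {
  F <- partial_F(lambda_p, lambda_p1, n, g, p)
  stats::pf(F, g - 1, n - g - p, lower.tail = FALSE)
}

#' Stepwise Wilks'-lambda discriminant analysis
#'
#' Forward selection with backward removal: at each step the candidate
#' variable minimising Wilks' lambda enters if its partial-F p-value is
#' below `p_enter`; after each entry, any selected variable whose removal
#' p-value exceeds `p_remove` leaves again. A linear discriminant with
#' equal priors is then fitted on the selected variables and resubstitution
#' (or optionally leave-one-out) classification accuracy is reported.
#'
#' @param data data.frame of candidate predictor columns (numeric).
#' @param groups factor or character vector of group labels (2 groups).
#' @param p_enter,p_remove stepwise thresholds.
#' @param loo use leave-one-out instead of resubstitution classification.
#' @return list of class `sbp_lda`: `selected_variables`, `wilks_lambda`,
#'   `p_value` (overall lambda F-test), `confusion` (2x2 table),
#'   `accuracy_overall`, `accuracy_per_group` (percent), `lda_fit`.
#' @export
stepwise_lda <- function(data, groups, p_enter = 0.05, p_remove = 0.10,
                         loo = FALSE) {
  data <- as.data.frame(data)
  stopifnot(ncol(data) >= 1L)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) stop("exactly two groups required")
  n <- nrow(data); g <- 2L
  # variables with no within-group variance make the pooled covariance
  # singular (SPSS-style tolerance exclusion)
  ok_var <- vapply(names(data), function(v)
    all(tapply(data[[v]], groups, stats::sd) > 0), NA)
  vars <- names(data)[ok_var]
  selected <- character(0)
  repeat {
    moved <- FALSE
    # entry step
    lam0 <- if (length(selected)) wilks_lambda(data[selected], groups) else 1
    cand <- setdiff(vars, selected)
    if (length(cand)) {
      lams <- vapply(cand, function(v)
        wilks_lambda(data[c(selected, v)], groups), 0)
      best <- cand[which.min(lams)]
      pv <- partial_F_p(lam0, min(lams), n, g, length(selected))
      if (is.finite(pv) && pv < p_enter) {
        selected <- c(selected, best)
        moved <- TRUE
      }
    }
    # removal step
    if (length(selected) > 1L) {
      repeat {
        lam_full <- wilks_lambda(data[selected], groups)
        pvals <- vapply(selected, function(v) {
          lam_red <- wilks_lambda(data[setdiff(selected, v)], groups)
          partial_F_p(lam_red, lam_full, n, g, length(selected) - 1L)
        }, 0)
        worst <- which.max(pvals)
        if (pvals[worst] > p_remove) {
          selected <- selected[-worst]
          moved <- TRUE
        } else break
        if (length(selected) <= 1L) break
      }
    }
    if (!moved) break
  }
  if (!length(selected)) {
    # no informative variable: majority-class assignment
    tab <- table(groups)
    maj <- names(tab)[which.max(tab)]
    confusion <- table(truth = groups, predicted = factor(rep(maj, n),
                                                          levels = levels(groups)))
    acc <- 100 * sum(diag(confusion)) / n
    return(structure(list(selected_variables = character(0),
                          wilks_lambda = 1, p_value = 1,
                          confusion = confusion, accuracy_overall = acc,
                          accuracy_per_group = 100 * diag(confusion) /
                            rowSums(confusion),
                          lda_fit = NULL),
                     class = "sbp_lda"))
  }
  lam <- wilks_lambda(data[selected], groups)
  p_overall <- partial_F_p(1, lam, n, g, 0)  # overall lambda F (approx.)
  cls <- lda_classify(data[selected], groups, loo = loo)
  structure(list(selected_variables = selected, wilks_lambda = lam,
                 p_value = p_overall, confusion = cls$confusion,
                 accuracy_overall = cls$accuracy_overall,
                 accuracy_per_group = cls$accuracy_per_group,
                 lda_fit = cls$fit),
            class = "sbp_lda")
}

#' Equal-prior linear discriminant classification
#'
#' Fits a two-class linear discriminant with equal prior probabilities on
#' the given predictors and reports resubstitution (or leave-one-out)
#' classification performance.
#'
#' @param data data.frame of numeric predictors.
#' @param groups two-level grouping vector.
#' @param loo leave-one-out instead of resubstitution.
#' @return list with `fit`, `confusion`, `accuracy_overall` and
#'   `accuracy_per_group` (percent).
#' @export
lda_classify <- function(data, groups, loo = FALSE) {
  groups <- as.factor(groups)
  fit <- MASS::lda(x = data, grouping = groups, prior = c(0.5, 0.5),
                   CV = loo)
  pred <- if (loo) fit$class else stats::predict(fit, data)$class
  confusion <- table(truth = groups, predicted = pred)
  list(fit = fit, confusion = confusion,
       accuracy_overall = 100 * sum(diag(confusion)) / length(groups),
       accuracy_per_group = 100 * diag(confusion) / rowSums(confusion))
}

#' @export
print.sbp_lda <- function(x, ...) {
  cat("Stepwise Wilks'-lambda discriminant analysis\n")
  cat("  selected:", if (length(x$selected_variables))
    paste(x$selected_variables, collapse = ", ") else "(none)", "\n")
  cat(sprintf("  Wilks' lambda = %.4f, p = %.4g\n", x$wilks_lambda, x$p_value))
  cat(sprintf("  overall accuracy = %.1f%%\n", x$accuracy_overall))
  print(x$confusion)
  invisible(x)
}

#' Simulate a cohort from per-variable group summaries
#'
#' Draws independent per-subject values from normal distributions with the
#' given means and SDs, truncated at zero (negative draws are redrawn), as
#' a stand-in for an unpublished raw cohort.
#'
#' @param summary named list: for each group label, a named list of
#'   `c(mean, sd)` per variable (same variables in every group).
#' @param n_per_group named integer vector of group sizes.
#' @param seed RNG seed.
#' @return data.frame with a `group` column and one column per variable.
#' @export
simulate_cohort <- function(summary, n_per_group, seed = 1L) {
  if (any(n_per_group < 0)) stop("group sizes must be non-negative")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  out <- NULL
  for (grp in names(summary)) {
    n <- n_per_group[[grp]]
    cols <- lapply(summary[[grp]], function(ms) {
      x <- stats::rnorm(n, ms[1], ms[2])
      while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), ms[1], ms[2])
      x
    })
    df <- data.frame(group = rep(grp, n), as.data.frame(cols))
    out <- rbind(out, df)
  }
  out
}

#' Two-group comparison report for a metrics table
#'
#' Runs [dispatch_test()] on every numeric metric column and a two-variable
#' or full stepwise discriminant analysis.
#'
#' @param df metrics data.frame (as from [read_metrics_csv()]).
#' @param group_col name of the group label column.
#' @param variables columns to test; default all numeric metric columns.
#' @return list with `tests` (list of `sbp_test`) and `lda` (`sbp_lda`).
#' @export
compare_groups <- function(df, group_col = "group", variables = NULL) {
  if (!group_col %in% names(df)) stop("missing group column: ", group_col)
  groups <- df[[group_col]]
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two groups required, found ", length(lv))
  if (is.null(variables))
    variables <- setdiff(names(df)[vapply(df, is.numeric, NA)],
                         c(group_col, "normalized", "image_area_mm2"))
  tests <- lapply(variables, function(v)
    dispatch_test(df[[v]][groups == lv[1]], df[[v]][groups == lv[2]],
                  variable = v))
  names(tests) <- variables
  keep <- variables[vapply(variables, function(v) stats::sd(df[[v]]) > 0, NA)]
  lda <- if (length(keep) >= 1L) stepwise_lda(df[keep], groups) else NULL
  list(tests = tests, lda = lda)
}
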