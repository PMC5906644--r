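#' One-way ANOVA with Bonferroni post-hoc comparisons
#'
#' Omnibus one-way ANOVA across tumour groups for one parameter, followed by
#' all pairwise comparisons using pooled-variance t tests with
#' Bonferroni-adjusted p values (raw p multiplied by the number of pairs,
#' capped at 1). The ANOVA assumptions are checked advisorily: equality of
#' variances by the Brown-Forsythe test (ANOVA on absolute deviations from
#' group medians) and normality per group by Shapiro-Wilk, both at the 0.01
#' level; the checks annotate the result and never gate the computation.
#'
#' @param table data.frame with a `group` column and parameter columns.
#' @param parameter name of the parameter column to analyse.
#' @param alpha significance level for reporting (default 0.05).
#' @return object of class `anova_bonferroni`: list(omnibus_p, pairwise
#'   data.frame (group1, group2, p_raw, p_adjusted, significant),
#'   assumptions, parameter).
#' @export
anova_bonferroni <- function(table, parameter, alpha = 0.05) {
  g <- factor(table$group)
  x <- table[[parameter]]
  if (is.null(x)) stopf("no column '%s'", parameter)
  if (nlevels(g) < 2) stopf("need >= 2 groups")
  if (any(tabulate(g) < 2)) stopf("need >= 2 observations per group")
  if (all(vapply(split(x, g), var, numeric(1)) == 0)) {
    stopf("zero within-group variance in all groups: ANOVA degenerate")
  }
  fit <- aov(x ~ g)
  omni <- summary(fit)[[1]][["Pr(>F)"]][1]
  pw <- pairwise.t.test(x, g, p.adjust.method = "none", pool.sd = TRUE)$p.value
  pairs <- which(!is.na(pw), arr.ind = TRUE)
  n_pairs <- nlevels(g) * (nlevels(g) - 1) / 2
  pairwise <- data.frame(
    group1 = rownames(pw)[pairs[, 1]],
    group2 = colnames(pw)[pairs[, 2]],
    p_raw = pw[pairs]
  )
  pairwise$p_adjusted <- pmin(1, pairwise$p_raw * n_pairs)
  pairwise$significant <- pairwise$p_adjusted < alpha
  # advisory assumption checks
  med_dev <- abs(x - stats::ave(x, g, FUN = median))
  bf_p <- summary(aov(med_dev ~ g))[[1]][["Pr(>F)"]][1]
  sw_p <- vapply(split(x, g), function(v) {
    if (length(unique(v)) < 3) return(NA_real_)
    shapiro.test(v)$p.value
  }, numeric(1))
  structure(
    list(omnibus_p = omni, pairwise = pairwise,
         assumptions = list(brown_forsythe_p = bf_p, shapiro_p = sw_p,
                            alpha = 0.01,
                            ok = isTRUE(bf_p > 0.01) &&
                              all(sw_p > 0.01, na.rm = TRUE)),
         parameter = parameter),
    class = "anova_bonferroni"
  )
}

#' @export
print.anova_bonferroni <- function(x, ...) {
  cat(sprintf("one-way ANOVA on '%s': omnibus p = %.4g\n",
              x$parameter, x$omnibus_p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Nearest-neighbour leave-one-out classification
#'
#' Exhaustive leave-one-out cross-validation of the 1-nearest-neighbour
#' classifier: each tumour is assigned the group of its nearest neighbour
#' (Euclidean distance on z-scored parameter columns) among all other
#' tumours, and actual versus predicted groups are tabulated in a confusion
#' matrix. Distance ties are broken by the smallest row index, which makes
#' the procedure deterministic and invariant to row order up to that rule.
#'
#' @param table data.frame with a `group` column and parameter columns.
#' @param parameters character vector of parameter column names.
#' @param standardize z-score columns over the cohort first (default TRUE;
#'   irrelevant for a single parameter).
#' @return object of class `confusion_matrix`: list(labels, counts,
#'   accuracy, predicted).
#' @export
nn_loocv_confusion <- function(table, parameters, standardize = TRUE) {
  g <- factor(table$group)
  if (any(tabulate(g) < 2)) stopf("need >= 2 tumours per group")
  X <- as.matrix(table[, parameters, drop = FALSE])
  if (anyNA(X)) stopf("missing values in analysed columns")
  if (standardize) {
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0
  }
  n <- nrow(X)
  pred <- character(n)
  ord <- seq_len(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(X) - X[i, ])^2)
    d2[i] <- Inf
    j <- ord[which.min(d2)] # which.min takes the first minimum: smallest index
    pred[i] <- as.character(g[j])
  }
  pred <- factor(pred, levels = levels(g))
  counts <- table(actual = g, predicted = pred)
  structure(
    list(labels = levels(g), counts = unclass(counts),
         accuracy = sum(diag(counts)) / n, predicted = pred),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("NN-LOOCV confusion matrix (accuracy %.1f%%):\n",
              100 * x$accuracy))
  print(x$counts)
  invisible(x)
}

#' Pearson correlation matrix of parameters
#'
#' Pairwise Pearson correlation coefficients between parameter columns;
#' zero-variance columns yield NA entries with a warning. Low correlation
#' between discriminative parameters marks them as candidates for a
#' complementary multi-parameter readout.
#'
#' @param table data.frame of parameter values.
#' @param parameters character vector of column names (>= 2).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table, parameters) {
  X <- as.matrix(table[, parameters, drop = FALSE])
  if (nrow(X) < 3) stopf("need >= 3 rows")
  zero_var <- apply(X, 2, sd) == 0
  if (any(zero_var)) {
    warnf("zero-variance column(s): %s",
          paste(parameters[zero_var], collapse = ", "))
  }
  suppressWarnings(r <- cor(X))
  diag(r) <- ifelse(zero_var, NA_real_, 1)
  r
}
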