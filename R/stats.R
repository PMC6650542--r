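#' Mann-Whitney U test for two groups
#'
#' U is computed from rank sums; the p-value is exact (distribution of U
#' under full enumeration of group labelings) when the pooled sample size
#' is at most 24 and no ties are present, otherwise the normal
#' approximation with tie and continuity correction is used.
#'
#' @param a,b numeric vectors (each non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return A list of class `group_comparison`: test, statistic (U of the
#'   first group), p_value, n, method.
#' @export
mann_whitney <- function(a, b, alternative = "two.sided") {
  if (length(a) < 1 || length(b) < 1) {
    stopf("precondition_error", "both groups must be non-empty")
  }
  nA <- length(a)
  nB <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  ties <- any(duplicated(c(a, b)))
  exact <- (nA + nB) <= 24 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = TRUE))
  structure(list(test = "Mann-Whitney U", statistic = U,
                 p_value = if (ties && length(unique(c(a, b))) == 1) 1
                 else wt$p.value,
                 n = c(nA, nB),
                 method = if (exact) "exact" else "normal-approximation",
                 correction = "none"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<%s> statistic=%.4g p=%.4g (n=%s, %s)\n", x$test,
              x$statistic, x$p_value, paste(x$n, collapse = "/"), x$method))
  invisible(x)
}

#' One-way ANOVA with Bonferroni-corrected pairwise t-tests
#'
#' @param values numeric vector of observations.
#' @param groups grouping factor (>= 2 levels, each n >= 2).
#' @return list of class `anova_result`: `anova` (a `group_comparison`
#'   with the F statistic) and `pairwise` (list of `group_comparison`
#'   objects with Bonferroni-multiplied p-values capped at 1).
#' @export
anova_bonferroni <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) {
    stopf("precondition_error", "need >= 2 groups")
  }
  ns <- table(groups)
  if (any(ns < 2)) stopf("precondition_error", "each group needs n >= 2")
  for (g in levels(groups)) {
    if (stats::var(values[groups == g]) == 0 && ns[[g]] == 2) {
      warning(sprintf("group `%s` has zero variance with n = 2", g),
              call. = FALSE)
    }
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  an <- structure(list(test = "one-way ANOVA", statistic = tab$`F value`[1],
                       p_value = tab$`Pr(>F)`[1],
                       n = as.integer(ns), method = "F",
                       correction = "none"),
                  class = "group_comparison")
  lv <- levels(groups)
  prs <- utils::combn(lv, 2, simplify = FALSE)
  m <- length(prs)
  pw <- lapply(prs, function(p) {
    x <- values[groups == p[1]]
    y <- values[groups == p[2]]
    tt <- stats::t.test(x, y, var.equal = TRUE)
    structure(list(test = paste("t:", p[1], "vs", p[2]),
                   statistic = unname(tt$statistic),
                   p_value = min(1, m * tt$p.value),
                   n = c(length(x), length(y)), method = "pooled t",
                   correction = "bonferroni"),
              class = "group_comparison")
  })
  structure(list(anova = an, pairwise = pw), class = "anova_result")
}

#' Mean +/- SEM summary with attached group comparisons
#'
#' @param values numeric vector.
#' @param groups grouping factor.
#' @param test `"mannwhitney"` (all pairwise), `"anova"` or `"none"`.
#' @return data.frame of class `summary_table` (group, n, mean, sem) with
#'   a `comparisons` attribute.
#' @export
summarize_groups <- function(values, groups,
                             test = c("mannwhitney", "anova", "none")) {
  test <- match.arg(test)
  groups <- factor(groups)
  if (any(table(groups) < 1)) {
    stopf("precondition_error", "each group needs >= 1 record")
  }
  rows <- lapply(levels(groups), function(g) {
    v <- values[groups == g]
    n <- length(v)
    if (n == 1) warning(sprintf("group `%s` has n = 1: SEM set to 0", g),
                        call. = FALSE)
    data.frame(group = g, n = n, mean = mean(v),
               sem = if (n == 1) 0 else sd(v) / sqrt(n))
  })
  out <- do.call(rbind, rows)
  comps <- NULL
  if (test == "mannwhitney" && nlevels(groups) >= 2) {
    prs <- utils::combn(levels(groups), 2, simplify = FALSE)
    comps <- lapply(prs, function(p) {
      mann_whitney(values[groups == p[1]], values[groups == p[2]])
    })
    names(comps) <- vapply(prs, paste, "", collapse = " vs ")
  } else if (test == "anova") {
    comps <- anova_bonferroni(values, groups)
  }
  structure(out, comparisons = comps,
            class = c("summary_table", "data.frame"))
}
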