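#' Shapiro-Wilk normality gate
#'
#' Tests each group for normality; the comparison family is parametric
#' (one-way ANOVA + Bonferroni pairwise t-tests) only if every group passes
#' at `alpha`, otherwise non-parametric (Kruskal-Wallis + Dunn). Constant
#' groups are rejected with an error (normality is undefined for them).
#'
#' @param groups named list of numeric vectors, each of length >= 3.
#' @param alpha gate level. Default 0.05.
#' @return list with `p` (per-group Shapiro-Wilk p-values) and
#'   `parametric` (TRUE iff all p >= alpha).
#' @export
normalityGate <- function(groups, alpha = 0.05) {
  checkGroups(groups, minN = 3L)
  p <- vapply(groups, function(g) {
    if (length(unique(g)) == 1L) {
      stop("normalityGate: constant group; normality test undefined")
    }
    shapiro.test(g)$p.value
  }, numeric(1L))
  list(p = p, parametric = all(p >= alpha))
}

checkGroups <- function(groups, minN = 2L, minGroups = 2L) {
  if (!is.list(groups) || length(groups) < minGroups) {
    stop(sprintf("need at least %d groups", minGroups))
  }
  ns <- lengths(groups)
  if (any(ns < minN)) stop(sprintf("each group needs n >= %d", minN))
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups
}

groupPairs <- function(nms) {
  cmb <- utils::combn(nms, 2L)
  data.frame(group_a = cmb[1L, ], group_b = cmb[2L, ])
}

#' Parametric multi-group comparison (one-way ANOVA + Bonferroni t-tests)
#'
#' Global one-way ANOVA (classic equal-variance F) followed by pairwise
#' t-tests (Welch by default) with Bonferroni correction: raw p multiplied
#' by the number of pairs, capped at 1.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha significance level. Default 0.05.
#' @param varEqual use Student's pooled-variance pairwise t-tests instead
#'   of Welch. Default FALSE.
#' @param normalityPs optional per-group Shapiro-Wilk p-values to record.
#' @return a [GroupComparison-class].
#' @export
compareParametric <- function(groups, alpha = 0.05, varEqual = FALSE,
                              normalityPs = numeric(0)) {
  groups <- checkGroups(groups, minN = 2L)
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  av <- oneway.test(vals ~ fac, var.equal = TRUE)
  pw <- groupPairs(names(groups))
  nPairs <- nrow(pw)
  res <- lapply(seq_len(nPairs), function(i) {
    safeTTest(groups[[pw$group_a[i]]], groups[[pw$group_b[i]]], varEqual)
  })
  pw$statistic <- vapply(res, `[[`, numeric(1L), "statistic")
  pw$p_raw <- vapply(res, `[[`, numeric(1L), "p")
  pw$p_adjusted <- pmin(pw$p_raw * nPairs, 1)
  pw$significant <- pw$p_adjusted < alpha
  new("GroupComparison", testName = "oneway_anova_bonferroni",
      globalStatistic = unname(av$statistic), globalP = unname(av$p.value),
      pairwise = pw, alpha = alpha, normalityPs = normalityPs)
}

# t-test that treats elementwise-identical inputs as "no evidence" (p = 1)
# rather than erroring on zero variance.
safeTTest <- function(a, b, varEqual = FALSE) {
  res <- tryCatch(t.test(a, b, var.equal = varEqual),
                  error = function(e) NULL)
  if (is.null(res)) {
    if (isTRUE(all.equal(sort(a), sort(b)))) {
      return(list(statistic = 0, p = 1))
    }
    stop("t-test failed: degenerate input with unequal groups")
  }
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Non-parametric multi-group comparison (Kruskal-Wallis + Dunn)
#'
#' Global tie-corrected Kruskal-Wallis H, then Dunn's pairwise z-tests on
#' mean ranks with the same tie correction, Bonferroni-adjusted (raw p
#' multiplied by the number of pairs, capped at 1).
#'
#' @inheritParams compareParametric
#' @return a [GroupComparison-class].
#' @export
compareNonparametric <- function(groups, alpha = 0.05,
                                 normalityPs = numeric(0)) {
  groups <- checkGroups(groups, minN = 1L)
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kw <- kruskal.test(vals, fac)
  N <- length(vals)
  rk <- rank(vals)
  meanRank <- tapply(rk, fac, mean)
  ns <- tapply(rk, fac, length)
  ties <- table(vals)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tieCorr
  pw <- groupPairs(names(groups))
  nPairs <- nrow(pw)
  z <- vapply(seq_len(nPairs), function(i) {
    ga <- pw$group_a[i]; gb <- pw$group_b[i]
    (meanRank[[ga]] - meanRank[[gb]]) /
      sqrt(s2 * (1 / ns[[ga]] + 1 / ns[[gb]]))
  }, numeric(1L))
  pw$statistic <- z
  pw$p_raw <- 2 * pnorm(-abs(z))
  pw$p_adjusted <- pmin(pw$p_raw * nPairs, 1)
  pw$significant <- pw$p_adjusted < alpha
  new("GroupComparison", testName = "kruskal_wallis_dunn",
      globalStatistic = unname(kw$statistic), globalP = unname(kw$p.value),
      pairwise = pw, alpha = alpha, normalityPs = normalityPs)
}

#' Two-group t-test
#'
#' Two-sided Welch t-test by default (Student's pooled-variance via
#' `varEqual = TRUE`); elementwise-identical groups return p = 1 under the
#' documented ties policy.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @param varEqual pooled-variance variant. Default FALSE (Welch).
#' @return the two-sided p-value.
#' @export
twoGroupTTest <- function(a, b, varEqual = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  safeTTest(a, b, varEqual)$p
}

#' Gated multi-group comparison
#'
#' The full comparison procedure: a Shapiro-Wilk gate sends the family to
#' one-way ANOVA with Bonferroni pairwise t-tests when every group passes
#' normality at `alpha`, and to Kruskal-Wallis with Dunn's pairwise test
#' otherwise. `force` overrides the gate.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 3).
#' @param alpha significance level (also the gate level). Default 0.05.
#' @param force `"auto"` (gate), `"parametric"` or `"nonparametric"`.
#' @param varEqual passed to the parametric branch.
#' @return a [GroupComparison-class] with `normalityPs` filled in.
#' @export
compareGroups <- function(groups, alpha = 0.05,
                          force = c("auto", "parametric", "nonparametric"),
                          varEqual = FALSE) {
  force <- match.arg(force)
  gate <- normalityGate(groups, alpha)
  parametric <- switch(force,
    auto = gate$parametric,
    parametric = TRUE,
    nonparametric = FALSE
  )
  if (parametric) {
    compareParametric(groups, alpha, varEqual, normalityPs = gate$p)
  } else {
    compareNonparametric(groups, alpha, normalityPs = gate$p)
  }
}
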