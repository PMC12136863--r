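#' Test result container
#'
#' Every statistical routine in the package returns an `lo_test` object with
#' a common shape: the statistic, its degrees of freedom, the two-sided p
#' value, the per-group sample sizes and the test name, plus optional fields
#' (Monte-Carlo standard error, normality flag).
#'
#' @param test_name Short test identifier.
#' @param statistic Test statistic.
#' @param df Degrees of freedom (scalar or pair).
#' @param p_value Two-sided (or upper-tail, for F) p value in [0, 1].
#' @param n Per-group sample size(s).
#' @param ... Extra named fields stored verbatim.
#' @return Object of class `lo_test`.
#' @keywords internal
lo_test <- function(test_name, statistic, df, p_value, n, ...) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test_name = test_name, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value), n = unname(n), ...),
            class = "lo_test")
}

#' @export
print.lo_test <- function(x, ...) {
  cat(sprintf("<lo_test> %s: statistic = %.4f, df = %s, p = %.4g (n = %s)\n",
              x$test_name, x$statistic, paste(round(x$df, 2), collapse = ", "),
              x$p_value, paste(x$n, collapse = ", ")))
  if (!is.null(x$mc_se)) cat(sprintf("  Monte-Carlo p, se = %.2g\n", x$mc_se))
  invisible(x)
}

#' Paired t test for matched region pairs
#'
#' Two-sided paired Student t test, the within-patient comparison used for
#' affected vs contralateral masses and compositions:
#' `t = mean(d) / (sd(d)/sqrt(n))` with `df = n - 1` on the differences
#' `d = x - y`.
#'
#' @param x,y Equal-length numeric vectors of matched observations, n >= 2.
#' @return An `lo_test`.
#' @export
#' @examples
#' paired_t_test(c(1, 2, 3), c(2, 4, 6))
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch between x and y", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (sd(d) == 0) stop("zero variance of paired differences", call. = FALSE)
  ht <- t.test(x, y, paired = TRUE)
  lo_test("paired_t", ht$statistic, ht$parameter, ht$p.value, length(x),
          mean_difference = mean(d))
}

#' Unpaired two-sample t test
#'
#' Classic pooled-variance (Student) two-sample t test by default; Welch's
#' unequal-variance form is available with `welch = TRUE`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch-Satterthwaite correction instead of pooling.
#' @return An `lo_test`.
#' @export
#' @examples
#' unpaired_t_test(c(1, 2, 3, 4), c(3, 4, 5, 6))
unpaired_t_test <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(lo_test(if (welch) "welch_t" else "student_t", 0,
                     length(a) + length(b) - 2, 1, c(length(a), length(b))))
    }
    stop("zero variance in both groups with unequal means: t undefined",
         call. = FALSE)
  }
  ht <- t.test(a, b, var.equal = !welch)
  lo_test(if (welch) "welch_t" else "student_t", ht$statistic, ht$parameter,
          ht$p.value, c(length(a), length(b)))
}

#' One-way analysis of variance
#'
#' Fixed-effects one-way ANOVA: `F = MS_between / MS_within` on
#' `(k - 1, N - k)` degrees of freedom with the upper-tail p value. Intended
#' for k >= 3 diagnostic subgroups; k = 2 is accepted, where F equals the
#' square of the pooled two-sample t statistic.
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return An `lo_test` with `df` of length 2.
#' @export
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
one_way_anova <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  n <- lengths(groups)
  if (any(n < 2L)) stop("every group needs at least 2 observations", call. = FALSE)
  if (all(vapply(groups, sd, numeric(1)) == 0)) {
    mu <- vapply(groups, mean, numeric(1))
    if (all(mu == mu[1])) {
      return(lo_test("anova_f", 0, c(length(groups) - 1, sum(n) - length(groups)),
                     1, n))
    }
    stop("zero within-group variance: F undefined", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), n))
  ht <- oneway.test(x ~ g, var.equal = TRUE)
  lo_test("anova_f", ht$statistic, ht$parameter, ht$p.value, n)
}

#' Fisher's exact test for r x c contingency tables
#'
#' Exact test of independence on a table of non-negative integer counts.
#' 2 x 2 tables use the hypergeometric distribution; larger tables the exact
#' network (Freeman-Halton) enumeration. If exact enumeration exhausts its
#' workspace the p value is estimated by Monte Carlo under a fixed seed and
#' the estimate's standard error is reported alongside.
#'
#' @param table Integer matrix of counts, at least 2 x 2, positive margins.
#' @param mc_reps Monte-Carlo replicates used by the fallback (default 1e5).
#' @param mc_seed Seed for the Monte-Carlo fallback, fixed for
#'   reproducibility.
#' @return An `lo_test` (statistic is `NA`; Fisher's test has no canonical
#'   statistic). `mc_se` is non-`NULL` only when Monte Carlo was used.
#' @export
#' @examples
#' fisher_exact_rxc(matrix(c(3, 1, 1, 3), 2))
fisher_exact_rxc <- function(table, mc_reps = 1e5, mc_seed = 20250201) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)) || anyNA(table)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("need at least a 2 x 2 table", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all row and column margins must be positive", call. = FALSE)
  }
  storage.mode(table) <- "integer"
  ht <- tryCatch(fisher.test(table, workspace = 2e7),
                 error = function(e) NULL)
  if (!is.null(ht)) {
    # the network algorithm can overshoot 1 by rounding error
    return(lo_test("fisher_exact", NA_real_, NA_real_, min(1, ht$p.value),
                   sum(table)))
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(mc_seed)
  ht <- fisher.test(table, simulate.p.value = TRUE, B = mc_reps)
  p <- ht$p.value
  lo_test("fisher_mc", NA_real_, NA_real_, p, sum(table),
          mc_se = sqrt(p * (1 - p) / mc_reps), mc_reps = mc_reps)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Shapiro-Wilk normality annotation
#'
#' Computes the Shapiro-Wilk W statistic and p value. The result annotates
#' parametric tests downstream with a normality flag; it never switches the
#' analysis to a nonparametric method silently.
#'
#' @param x Numeric vector, 3 <= n <= 5000, non-constant.
#' @return An `lo_test` with `normal_flag` (TRUE when p >= 0.05).
#' @export
normality_gate <- function(x) {
  n <- length(x)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk supports 3 <= n <= 5000 (got ", n, ")", call. = FALSE)
  }
  if (sd(x) == 0) stop("zero variance: normality test undefined", call. = FALSE)
  ht <- shapiro.test(x)
  lo_test("shapiro_wilk", ht$statistic, NA_real_, ht$p.value, n,
          normal_flag = ht$p.value >= 0.05)
}
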