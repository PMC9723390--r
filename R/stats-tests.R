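#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test of two independent groups. For small problems
#' (`n_a + n_b <= exact_limit`) the null distribution of U is obtained by
#' full enumeration of the `choose(n, n_a)` assignments of the pooled
#' mid-ranks (so ties are handled exactly); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' The two-sided p-value is `P(|U - mu| >= |u_obs - mu|)` under the null,
#' with `mu = n_a * n_b / 2`.
#'
#' @param group_a,group_b Numeric vectors, each nonempty.
#' @param exact_limit Largest pooled size enumerated exactly.
#' @return A one-row tibble: `statistic` (U of `group_a`), `p_value`,
#'   `method` (`"exact"` or `"normal_approx"`), `n_a`, `n_b`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
mann_whitney_u <- function(group_a, group_b, exact_limit = 12L) {
  if (!length(group_a) || !length(group_b))
    abort("both groups must be nonempty")
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  pooled <- c(group_a, group_b)
  r <- rank(pooled)  # mid-ranks for ties
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  if (n <= exact_limit) {
    splits <- utils::combn(n, na)
    rank_sums <- colSums(matrix(r[splits], nrow = na))
    u_null <- rank_sums - na * (na + 1) / 2
    p <- mean(abs(u_null - mu) >= abs(u_a - mu) - 1e-9)
    method <- "exact"
  } else {
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u_a - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  tibble(statistic = u_a, p_value = p, method = method, n_a = na, n_b = nb)
}

#' Two-sided two-sample t test
#'
#' Student (pooled-variance) or Welch t test via [stats::t.test()], with
#' explicit handling of the degenerate zero-variance cases: both groups
#' constant with equal means gives `t = 0, p = 1`; constant with unequal
#' means is flagged degenerate (`t` infinite, `p = 0`).
#'
#' @param group_a,group_b Numeric vectors, each of length `>= 2`.
#' @param welch Use the Welch (unequal-variance) variant. Default pooled.
#' @return A one-row tibble: `statistic`, `p_value`, `df`, `method`,
#'   `degenerate`.
#' @export
two_sample_t <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    abort("each group needs at least 2 observations")
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    eq <- mean(group_a) == mean(group_b)
    return(tibble(statistic = if (eq) 0 else
                    Inf * sign(mean(group_a) - mean(group_b)),
                  p_value = if (eq) 1 else 0,
                  df = NA_real_,
                  method = if (welch) "welch" else "student",
                  degenerate = TRUE))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = !welch)
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         df = unname(ht$parameter),
         method = if (welch) "welch" else "student",
         degenerate = FALSE)
}

#' Compare a metric between two groups
#'
#' Applies [mann_whitney_u()] (the package default, matching the study's
#' nonparametric analysis) and/or [two_sample_t()] to a per-sample metric,
#' and flags significance at `alpha` (default 0.1, the study's threshold).
#' Group summaries are mean +/- SEM.
#'
#' @param data A data frame with one row per sample.
#' @param metric Name of the numeric column to compare.
#' @param group Name of the grouping column (exactly two levels).
#' @param tests Character subset of `c("mann_whitney_u", "t_test")`.
#' @param alpha Significance threshold; `p < alpha` is flagged.
#' @param welch Passed to [two_sample_t()].
#' @return A tibble with one row per test: metric name, group labels and
#'   sizes, per-group mean and SEM, test name, statistic, `p_value`,
#'   `significant`.
#' @export
compare_groups <- function(data, metric, group = "group",
                           tests = "mann_whitney_u", alpha = 0.1,
                           welch = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  tests <- match.arg(tests, c("mann_whitney_u", "t_test"),
                     several.ok = TRUE)
  g <- data[[group]]
  levs <- sort(unique(g))
  if (length(levs) != 2L) abort("compare_groups needs exactly two groups")
  va <- data[[metric]][g == levs[1]]
  vb <- data[[metric]][g == levs[2]]
  sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  purrr::map_dfr(tests, function(tst) {
    res <- if (tst == "mann_whitney_u") mann_whitney_u(va, vb)
           else two_sample_t(va, vb, welch = welch)
    tibble(metric = metric,
           group_a = as.character(levs[1]), group_b = as.character(levs[2]),
           n_a = length(va), n_b = length(vb),
           mean_a = mean(va), sem_a = sem(va),
           mean_b = mean(vb), sem_b = sem(vb),
           test = tst,
           statistic = res$statistic,
           p_value = res$p_value,
           significant = res$p_value < alpha)
  })
}
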