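#' Exact Mann-Whitney U test by full enumeration
#'
#' Computes the Mann-Whitney U statistic from mid-rank sums and, for small
#' samples, its exact two-sided p-value by enumerating all
#' `choose(n1 + n2, n1)` group labelings of the observed pooled values -
#' which handles ties correctly, since the null distribution is built on the
#' observed multiset. The two-sided p doubles the smaller tail,
#' \eqn{p = \min(1, 2 P(U \le \min(U, n_1 n_2 - U)))}, the convention of
#' common statistical packages; with equal sixes the attainable floor is
#' 2/924, printing as 0.002. Above `exact_limit` total observations a
#' normal approximation with continuity and tie correction is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact_limit Largest `n1 + n2` for which full enumeration is used,
#'   default 14.
#' @return A `group_comparison` object (named list): `U` (for `x`), `n1`,
#'   `n2`, `p_two_sided`, `method` (`"exact"` or `"normal-approx"`), `ties`.
#' @examples
#' mann_whitney_exact(1:6, 7:12)$p_two_sided # 2/924
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 14L) {
  if (length(x) < 1L || length(y) < 1L) abort("both samples must be non-empty.")
  if (!is.numeric(x) || !is.numeric(y)) abort("samples must be numeric.")
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled) # mid-ranks under ties
  u_stat <- function(rank_sum_x) rank_sum_x - n1 * (n1 + 1) / 2
  U <- u_stat(sum(r[seq_len(n1)]))
  ties <- anyDuplicated(pooled) > 0
  if (n1 + n2 <= exact_limit) {
    idx <- combn(n1 + n2, n1)
    u_null <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    u_min <- min(U, n1 * n2 - U)
    # enumeration counts ranks <= u_min with a tolerance for mid-rank halves
    p <- min(1, 2 * mean(u_null <= u_min + 1e-9))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-approx"
  }
  structure(list(U = U, n1 = n1, n2 = n2, p_two_sided = p,
                 method = method, ties = ties),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> U = %g (n = %d, %d), p = %.4g [%s%s]\n",
              x$U, x$n1, x$n2, x$p_two_sided, x$method,
              if (x$ties) ", ties" else ""))
  invisible(x)
}

#' Kruskal-Wallis omnibus test with exact post hoc pairs
#'
#' The omnibus H (tie-corrected, chi-squared reference) comes from
#' [stats::kruskal.test()]; post hoc pairwise comparisons use
#' [mann_whitney_exact()]. Post hoc p-values are unadjusted by default,
#' with an optional [stats::p.adjust()] method.
#'
#' @param groups A named list of numeric samples (>= 2 groups, all
#'   non-empty).
#' @param p_adjust A [stats::p.adjust()] method, or `"none"` (default).
#' @return A list with `H`, `df`, `p`, and `posthoc` (a tibble with one row
#'   per pair: `group1`, `group2`, `U`, `p`, `p_adjusted`, `method`).
#' @export
kruskal_wallis <- function(groups, p_adjust = "none") {
  if (!is.list(groups) || length(groups) < 2L) abort("need at least 2 groups.")
  if (any(vapply(groups, length, integer(1)) == 0L)) abort("all groups must be non-empty.")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  kt <- kruskal.test(unname(groups))
  pairs <- combn(names(groups), 2)
  posthoc <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]
    g2 <- pairs[2, j]
    cmp <- mann_whitney_exact(groups[[g1]], groups[[g2]])
    tibble(group1 = g1, group2 = g2, U = cmp$U, p = cmp$p_two_sided,
           method = cmp$method)
  })
  posthoc$p_adjusted <- if (identical(p_adjust, "none")) posthoc$p else
    stats::p.adjust(posthoc$p, method = p_adjust)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, posthoc = posthoc)
}

#' Mean and standard error of a sample
#'
#' @param x Numeric sample.
#' @return A one-row tibble with `n`, `mean`, `se` (`NA` when `n < 2`).
#' @export
summarize_mean_se <- function(x) {
  if (!is.numeric(x) || length(x) < 1L) abort("`x` must be a non-empty numeric sample.")
  tibble(n = length(x), mean = mean(x),
         se = if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_)
}

#' Longitudinal pairwise comparisons of a cohort table
#'
#' For every study week, compares body weight and week-over-week weight gain
#' between each pair of groups with the exact Mann-Whitney test, and runs
#' the within-week Kruskal-Wallis omnibus across all groups. Weight gain is
#' undefined in week 1 (no prior week). Significance stars mark p < 0.05.
#'
#' @param cohort A [generate_cohort()]-shaped tibble (`animal_id`, `group`,
#'   `week`, `body_weight_g`).
#' @param alpha Significance level for starring, default 0.05.
#' @return A list with `pairwise` (tibble: `week`, `measure`, `group1`,
#'   `group2`, `U`, `p`, `significant`) and `omnibus` (tibble: `week`,
#'   `measure`, `H`, `p`).
#' @export
longitudinal_report <- function(cohort, alpha = 0.05) {
  cohort <- as_tibble(cohort)
  need <- c("animal_id", "group", "week", "body_weight_g")
  if (!all(need %in% names(cohort))) {
    abort(paste("`cohort` needs columns", paste(need, collapse = ", ")))
  }
  wide <- cohort %>%
    group_by(.data$animal_id) %>%
    arrange(.data$week, .by_group = TRUE) %>%
    mutate(gain_g = .data$body_weight_g - dplyr::lag(.data$body_weight_g)) %>%
    ungroup()
  weeks <- sort(unique(wide$week))
  grps <- sort(unique(wide$group))
  if (length(grps) < 2L) abort("at least two groups are required.")
  pairs <- combn(grps, 2)
  measures <- c(BW = "body_weight_g", WG = "gain_g")
  pairwise <- purrr::map_dfr(weeks, function(w) {
    purrr::map_dfr(names(measures), function(m) {
      col <- measures[[m]]
      purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
        x <- wide[[col]][wide$week == w & wide$group == pairs[1, j]]
        y <- wide[[col]][wide$week == w & wide$group == pairs[2, j]]
        if (anyNA(x) || anyNA(y)) {
          return(tibble(week = w, measure = m, group1 = pairs[1, j],
                        group2 = pairs[2, j], U = NA_real_, p = NA_real_,
                        significant = NA))
        }
        cmp <- mann_whitney_exact(x, y)
        tibble(week = w, measure = m, group1 = pairs[1, j],
               group2 = pairs[2, j], U = cmp$U, p = cmp$p_two_sided,
               significant = cmp$p_two_sided < alpha)
      })
    })
  })
  omnibus <- purrr::map_dfr(weeks, function(w) {
    purrr::map_dfr(names(measures), function(m) {
      col <- measures[[m]]
      samples <- lapply(grps, function(g) {
        v <- wide[[col]][wide$week == w & wide$group == g]
        v[!is.na(v)]
      })
      names(samples) <- grps
      if (any(vapply(samples, length, integer(1)) == 0L)) {
        return(tibble(week = w, measure = m, H = NA_real_, p = NA_real_))
      }
      kt <- kruskal.test(unname(samples))
      tibble(week = w, measure = m, H = unname(kt$statistic), p = kt$p.value)
    })
  })
  list(pairwise = pairwise, omnibus = omnibus)
}
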