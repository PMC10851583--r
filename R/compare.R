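SKEW_FALLBACK_THRESHOLD <- 2

#' Summarize clinical variables and test group differences
#'
#' For each variable and each pair of groups: continuous variables are
#' summarized as mean (+/- SD) and compared with Welch's t-test, falling
#' back to the Mann-Whitney U test when either group's sample skewness
#' exceeds 2 in magnitude; categorical (logical) variables are
#' summarized as n (%) and compared with Pearson's chi-squared test,
#' falling back to Fisher's exact test when any expected cell count is
#' below 5. All tests are two-tailed; no multiple-testing correction is
#' applied, but the number of tests performed is reported by
#' [glance.group_comparison()].
#'
#' @param data Patient tibble.
#' @param group Name of the grouping column (character); must have at
#'   least two non-empty levels.
#' @param variables Character vector of clinical columns to compare.
#'   Numeric columns are treated as continuous, logical/character/factor
#'   columns as categorical.
#' @param alpha Significance level used only for annotation stars.
#' @return A `group_comparison` object with `summary` (per-group
#'   descriptive statistics) and `tests` (one row per variable and group
#'   pair). Use [tidy()], [glance()] and [autoplot()] on it.
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 1)
#' cmp <- compare_groups(cohort$patients, "arm", c("age", "tg", "diabetes"))
#' tidy(cmp)
#' @export
compare_groups <- function(data, group, variables, alpha = 0.05) {
  stopifnot(group %in% names(data), all(variables %in% names(data)))
  g <- as.factor(data[[group]])
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes == 0L)) stop("empty group: ", names(sizes)[sizes == 0L][1],
                             call. = FALSE)

  summaries <- purrr::map_dfr(variables, function(v) {
    summarize_variable(data[[v]], g, v)
  })
  pairs <- utils::combn(levels(g), 2L, simplify = FALSE)
  tests <- purrr::map_dfr(variables, function(v) {
    purrr::map_dfr(pairs, function(p) {
      test_pair(data[[v]], g, v, p, alpha)
    })
  })
  structure(list(summary = summaries, tests = tests,
                 group = group, alpha = alpha, n_tests = nrow(tests)),
            class = "group_comparison")
}

is_continuous <- function(x) is.numeric(x)

as_event <- function(x, v) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) stop("internal: numeric passed to as_event")
  f <- as.factor(x)
  if (nlevels(f) != 2L) {
    stop("categorical variable '", v, "' must have exactly two levels ",
         "for n (%) summaries; got ", nlevels(f), call. = FALSE)
  }
  f == levels(f)[2]   # second level counted as the event
}

summarize_variable <- function(x, g, v) {
  if (is_continuous(x)) {
    purrr::map_dfr(levels(g), function(lev) {
      xi <- x[g == lev]
      tibble::tibble(
        variable = v, group = lev, type = "continuous",
        n = length(xi), mean = mean(xi), sd = stats::sd(xi),
        n_event = NA_integer_, pct_event = NA_real_,
        label = sprintf("%.2f ± %.2f", mean(xi), stats::sd(xi))
      )
    })
  } else {
    ev <- as_event(x, v)
    purrr::map_dfr(levels(g), function(lev) {
      xi <- ev[g == lev]
      tibble::tibble(
        variable = v, group = lev, type = "categorical",
        n = length(xi), mean = NA_real_, sd = NA_real_,
        n_event = sum(xi), pct_event = pct(sum(xi), length(xi), 1),
        label = sprintf("%d (%s%%)", sum(xi),
                        formatC(pct(sum(xi), length(xi), 1),
                                format = "fg"))
      )
    })
  }
}

test_pair <- function(x, g, v, pair, alpha) {
  sel <- g %in% pair
  xi <- x[sel]
  gi <- droplevels(g[sel])
  if (is_continuous(x)) {
    res <- continuous_test(xi, gi)
  } else {
    res <- categorical_test(as_event(x, v), sel, gi, v)
  }
  tibble::tibble(
    variable = v, group1 = pair[1], group2 = pair[2],
    type = res$type, test = res$test,
    statistic = res$statistic, p.value = res$p,
    p_label = format_p(res$p), stars = p_stars(res$p)
  )
}

continuous_test <- function(xi, gi) {
  skews <- vapply(split(xi, gi), e1071::skewness, numeric(1), type = 2)
  if (any(abs(skews) > SKEW_FALLBACK_THRESHOLD, na.rm = TRUE)) {
    ht <- stats::wilcox.test(xi ~ gi, exact = FALSE)
    list(type = "continuous", test = "mann_whitney_u",
         statistic = unname(ht$statistic), p = ht$p.value)
  } else {
    ht <- stats::t.test(xi ~ gi)
    list(type = "continuous", test = "welch_t",
         statistic = unname(ht$statistic), p = ht$p.value)
  }
}

categorical_test <- function(ev, sel, gi, v) {
  tab <- table(gi, factor(ev[sel], levels = c(FALSE, TRUE)))
  if (identical(tab[1, ], tab[2, ])) {
    # identical groups: no evidence of difference by construction
    return(list(type = "categorical", test = "pearson_chisq",
                statistic = 0, p = 1))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ht <- stats::fisher.test(tab)
    list(type = "categorical", test = "fisher_exact",
         statistic = NA_real_, p = ht$p.value)
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(type = "categorical", test = "pearson_chisq",
         statistic = unname(ht$statistic), p = ht$p.value)
  }
}

format_p <- function(p) {
  ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p))
}

p_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison on '", x$group, "': ",
      length(unique(x$tests$variable)), " variables, ",
      x$n_tests, " two-group tests (alpha = ", x$alpha,
      ", no multiplicity correction)\n", sep = "")
  print(x$tests[, c("variable", "group1", "group2", "test", "p_label",
                    "stars")], n = 20)
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return The per-variable, per-pair test tibble.
#' @export
tidy.group_comparison <- function(x, ...) x$tests

#' One-row summary of a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Tibble with numbers of variables, tests, and tests below
#'   `alpha`.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    n_variables = length(unique(x$tests$variable)),
    n_tests = x$n_tests,
    n_significant = sum(x$tests$p.value < x$alpha),
    alpha = x$alpha
  )
}

#' Plot a group comparison
#'
#' Dot plot of p-values per variable and group pair on a -log10 scale,
#' with the significance threshold marked.
#'
#' @param object A `group_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_comparison <- function(object, ...) {
  df <- object$tests
  df$pair <- paste(df$group1, "vs", df$group2)
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p.value),
                                   y = .data$variable,
                                   colour = .data$pair)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = -log10(object$alpha),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ p), y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
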