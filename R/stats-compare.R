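#' Unpaired two-tailed Student's t-test
#'
#' Pooled-variance (equal-variance) Student's t with `df = n_a + n_b - 2`
#' and a two-tailed p-value evaluated through the regularized incomplete
#' beta function, `p = I_{df/(df+t^2)}(df/2, 1/2)`. A difference is flagged
#' significant at `alpha` (default 0.05).
#'
#' @param a,b Numeric vectors of replicate values, each of length >= 2.
#' @param alpha Significance level.
#' @return A list of class `md_ttest`: `statistic`, `df`, `p_value`,
#'   `significant`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @examples
#' ttest_unpaired(c(1, 2, 3), c(2, 3, 4))
#' @export
ttest_unpaired <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) {
    abort("Each group needs at least 2 replicates for a t-test.",
          class = "btkloop_insufficient_replicates")
  }
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  dm <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (abs(dm) < .Machine$double.eps^0.5) {
      tstat <- 0; p <- 1
    } else {
      abort("Zero pooled variance with unequal means: t is undefined.",
            class = "btkloop_degenerate_variance")
    }
  } else {
    tstat <- dm / sqrt(sp2 * (1 / na + 1 / nb))
    # two-tailed p via the regularized incomplete beta function
    p <- stats::pbeta(df / (df + tstat^2), df / 2, 0.5)
  }
  structure(list(statistic = tstat, df = df, p_value = p,
                 significant = p < alpha, mean_a = mean(a),
                 mean_b = mean(b), n_a = na, n_b = nb, alpha = alpha),
            class = "md_ttest")
}

#' @export
print.md_ttest <- function(x, ...) {
  cat(sprintf("Student's t = %.4f, df = %d, two-tailed p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.md_ttest <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         significant = x$significant,
         estimate = x$mean_a - x$mean_b)
}

.run_scalars <- function(data, unit) {
  data <- as_tibble(data)
  need <- c("run", "metric", "value")
  if (!all(need %in% names(data))) {
    abort("Group data needs columns run, metric, value.",
          class = "btkloop_comparison_error")
  }
  if (unit == "run_mean") {
    dplyr::summarise(dplyr::group_by(data, .data$metric, .data$run),
                     value = mean(.data$value), .groups = "drop")
  } else {
    data[, c("metric", "run", "value")]
  }
}

#' Compare two groups of runs, metric by metric
#'
#' Aggregates each run of each group to a scalar per metric (the run's time
#' mean, by default) and compares the groups with the unpaired two-tailed
#' Student's t-test. The difference of means is reported as B minus A. With
#' `unit = "frame"` every frame is treated as a replicate instead; that
#' inflates the sample size (frames are autocorrelated, not independent),
#' so the report carries an explicit pseudo-replication warning.
#'
#' @param a,b Long tibbles for groups A and B with columns `run`, `metric`,
#'   `value` (one row per frame, or per run for pre-aggregated scalars such
#'   as occupancies).
#' @param unit `"run_mean"` (default; each run contributes its mean) or
#'   `"frame"`.
#' @param alpha Significance level (default 0.05).
#' @param labels Length-2 character vector naming the groups.
#' @return An object of class `md_comparison`; see [tidy.md_comparison()].
#' @examples
#' a <- tibble::tibble(run = rep(1:3, each = 5), metric = "rgyr",
#'                     value = rnorm(15, 10, 0.1))
#' b <- tibble::tibble(run = rep(1:3, each = 5), metric = "rgyr",
#'                     value = rnorm(15, 10.6, 0.1))
#' tidy(compare_groups(a, b))
#' @export
compare_groups <- function(a, b, unit = c("run_mean", "frame"),
                           alpha = 0.05, labels = c("A", "B")) {
  unit <- match.arg(unit)
  sa <- .run_scalars(a, unit)
  sb <- .run_scalars(b, unit)
  ma <- unique(sa$metric); mb <- unique(sb$metric)
  if (!setequal(ma, mb)) {
    abort(sprintf("Metric sets differ between groups (only in one: %s).",
                  paste(union(setdiff(ma, mb), setdiff(mb, ma)),
                        collapse = ", ")),
          class = "btkloop_comparison_error")
  }
  rows <- purrr::map(sort(ma), function(m) {
    va <- sa$value[sa$metric == m]
    vb <- sb$value[sb$metric == m]
    tt <- ttest_unpaired(va, vb, alpha = alpha)
    tibble(metric = m,
           mean_a = mean(va), sd_a = sd(va), n_a = length(va),
           mean_b = mean(vb), sd_b = sd(vb), n_b = length(vb),
           difference = mean(vb) - mean(va),
           statistic = -tt$statistic + 0, df = tt$df, p_value = tt$p_value,
           significant = tt$significant)
  })
  structure(list(table = dplyr::bind_rows(rows), unit = unit,
                 alpha = alpha, labels = labels,
                 pseudo_replication = unit == "frame"),
            class = "md_comparison")
}

#' @export
print.md_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%s vs %s), unit = %s, alpha = %g\n",
              x$labels[1], x$labels[2], x$unit, x$alpha))
  if (x$pseudo_replication) {
    cat("WARNING: frame-level replicates are pseudo-replicated",
        "(frames are autocorrelated); p-values are anti-conservative.\n")
  }
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x An `md_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return The per-metric comparison table as a tibble: group summaries
#'   (mean, sd, n), difference of means (B - A), t statistic (sign follows
#'   the difference), degrees of freedom, two-tailed p-value and the
#'   significance flag.
#' @exportS3Method generics::tidy
tidy.md_comparison <- function(x, ...) x$table

#' @rdname tidy.md_comparison
#' @return `glance()` returns a one-row summary: number of metrics, number
#'   significant, inference unit and alpha.
#' @exportS3Method generics::glance
glance.md_comparison <- function(x, ...) {
  tibble(n_metrics = nrow(x$table),
         n_significant = sum(x$table$significant),
         unit = x$unit, alpha = x$alpha,
         pseudo_replication = x$pseudo_replication)
}
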