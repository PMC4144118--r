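# Group-level statistics on subject metric tables.

check_metric_table <- function(table, cols) {
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    stop_rwenet(sprintf("metrics table is missing column(s): %s",
                        paste(missing, collapse = ", ")), "rwenet_data_error")
  }
  invisible(table)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' For each density (edge count) separately, fits a one-way ANOVA of the
#' chosen metric on group and computes all pairwise Tukey HSD comparisons;
#' when several densities are present a pooled two-way (group x density)
#' ANOVA is reported as well.
#'
#' @param table a subject metrics table (one row per subject x density) with
#'   columns `subject`, `group`, `K` and the outcome.
#' @param outcome name of the metric column to analyse (e.g. `"sigma"`,
#'   `"C"`, `"L"`, `"AHR"`).
#' @return list of class `rwe_anova`: `anova` (data.frame with K, F, df1, df2,
#'   p), `tukey` (per-density matrices of Tukey HSD results), `group_means`
#'   (per-density group means), and `pooled` (two-way ANOVA table or NULL).
#' @export
anova_with_posthoc <- function(table, outcome) {
  check_metric_table(table, c("group", "K", outcome))
  table$group <- droplevels(factor(table$group))
  if (nlevels(table$group) < 2) {
    stop_rwenet("need at least 2 groups", "rwenet_data_error")
  }
  cnt <- table(table$group, table$K)
  if (any(cnt < 2)) {
    stop_rwenet(sprintf("group(s) with fewer than 2 subjects: %s",
                        paste(rownames(cnt)[apply(cnt < 2, 1, any)],
                              collapse = ", ")), "rwenet_data_error")
  }
  ks <- sort(unique(table$K))
  rows <- list(); tukeys <- list(); means <- list()
  for (k in ks) {
    sub <- table[table$K == k, ]
    fit <- stats::aov(stats::reformulate("group", outcome), data = sub)
    at <- summary(fit)[[1]]
    rows[[as.character(k)]] <- data.frame(
      K = k, F = at[1, "F value"], df1 = at[1, "Df"], df2 = at[2, "Df"],
      p = at[1, "Pr(>F)"])
    tukeys[[as.character(k)]] <- stats::TukeyHSD(fit)$group
    means[[as.character(k)]] <- cbind(
      K = k, stats::aggregate(stats::reformulate("group", outcome), sub, mean))
  }
  pooled <- NULL
  if (length(ks) > 1) {
    table$K_f <- factor(table$K)
    pfit <- stats::aov(stats::reformulate(c("group", "K_f", "group:K_f"),
                                          outcome), data = table)
    pooled <- summary(pfit)[[1]]
  }
  structure(list(outcome = outcome,
                 anova = do.call(rbind, c(rows, make.row.names = FALSE)),
                 tukey = tukeys,
                 group_means = do.call(rbind, c(means, make.row.names = FALSE)),
                 pooled = pooled),
            class = "rwe_anova")
}

#' @export
print.rwe_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA of %s by group, per density:\n", x$outcome))
  print(x$anova, row.names = FALSE)
  cat("\nTukey HSD (lowest density):\n")
  print(round(x$tukey[[1]], 4))
  invisible(x)
}

#' Correlation of small-worldness with a cognitive score
#'
#' Pearson correlation between each subject's small-world coefficient --
#' averaged over the analysed densities -- and a cognitive screening score,
#' with `df = n - 2` and a two-sided p-value.
#'
#' @param table subject metrics table with columns `subject`, `sigma`, and the
#'   score.
#' @param score score column: `"MMSE"` or `"MoCA"` (any numeric column works).
#' @return list with `r`, `df`, `p`, `n`, and the underlying `htest`.
#' @export
correlate_cognition <- function(table, score = c("MMSE", "MoCA")) {
  score <- if (is.character(score)) match.arg(score) else score
  check_metric_table(table, c("subject", "sigma", score))
  agg <- stats::aggregate(table[c("sigma", score)],
                          by = list(subject = table$subject), mean)
  ok <- stats::complete.cases(agg[c("sigma", score)])
  agg <- agg[ok, ]
  if (nrow(agg) < 3) {
    stop_rwenet("need at least 3 subjects with both sigma and the score",
                "rwenet_data_error")
  }
  if (stats::sd(agg$sigma) == 0 || stats::sd(agg[[score]]) == 0) {
    stop_rwenet("zero variance in sigma or the score; correlation undefined",
                "rwenet_metric_error")
  }
  ht <- stats::cor.test(agg$sigma, agg[[score]], method = "pearson")
  list(r = unname(ht$estimate), df = unname(ht$parameter),
       p = ht$p.value, n = nrow(agg), test = ht)
}
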