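#' Two-way rank ANOVA of window means across arms and groups
#'
#' Window means are rank-transformed globally, then analysed with an
#' additive two-factor linear ANOVA (no interaction: interactions are not
#' interpretable on rank-transformed data), followed by Tukey HSD on each
#' factor.
#'
#' @param dt `data.table` with columns `value`, `arm`, `group` (group =
#'   population or pair).
#' @return List of class `rank_anova`: `anova` (the summary table),
#'   `p` (named vector for arm and group), `tukey` (TukeyHSD tables,
#'   reported only when the omnibus p < 0.05 for that factor).
#' @export
rank_anova <- function(dt) {
  dt <- data.table::as.data.table(dt)[!is.na(value)]
  if (length(unique(dt$arm)) < 2 || length(unique(dt$group)) < 2) {
    stop("need >= 2 levels in both factors")
  }
  cells <- dt[, .N, by = .(arm, group)]
  full <- data.table::CJ(arm = unique(dt$arm), group = unique(dt$group))
  missing_cells <- full[!cells, on = c("arm", "group")]
  if (nrow(missing_cells)) {
    stop("empty design cells: ",
         paste(missing_cells$arm, missing_cells$group, collapse = "; "))
  }
  if (stats::var(dt$value) == 0) stop("no variation in the response")
  dt[, r := rank(value)]
  fit <- stats::aov(r ~ arm + group, data = dt)
  sm <- summary(fit)[[1]]
  p <- stats::setNames(sm[["Pr(>F)"]][1:2],
                       trimws(rownames(sm)[1:2]))
  tk <- stats::TukeyHSD(fit)
  tk <- tk[names(p)[!is.na(p) & p < 0.05]]
  structure(list(anova = sm, p = p, tukey = tk), class = "rank_anova")
}

#' Kruskal-Wallis comparison of window values across groups
#'
#' Omnibus Kruskal-Wallis rank-sum test with pairwise two-sided Wilcoxon
#' rank-sum post hoc tests (Holm-adjusted), reported only when the omnibus
#' p < 0.05.
#'
#' @param dt `data.table` with columns `value`, `group`.
#' @param min_windows Minimum observations per group (default 5).
#' @return List: `statistic`, `p`, `posthoc` (matrix of pairwise p-values
#'   or NULL).
#' @export
kruskal_windows <- function(dt, min_windows = 5L) {
  dt <- data.table::as.data.table(dt)[!is.na(value)]
  sizes <- dt[, .N, by = group]
  if (nrow(sizes) < 2 || any(sizes$N < min_windows)) {
    stop("need >= 2 groups with >= ", min_windows, " windows each")
  }
  if (length(unique(dt$value)) == 1L) {
    return(list(statistic = 0, p = 1, posthoc = NULL))
  }
  kt <- stats::kruskal.test(dt$value, factor(dt$group))
  posthoc <- NULL
  if (kt$p.value < 0.05) {
    posthoc <- stats::pairwise.wilcox.test(dt$value, factor(dt$group),
                                           p.adjust.method = "holm",
                                           exact = FALSE)$p.value
  }
  list(statistic = unname(kt$statistic), p = kt$p.value, posthoc = posthoc)
}
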