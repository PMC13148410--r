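# Brood sex-ratio summaries and the treatment-group comparison: one-way
# ANOVA on per-brood female proportions plus Tukey HSD post-hoc pairs.
# In haplodiploid wasps a male-biased brood signals fertilization or
# paternal-genome failure, so the proportion of females per brood is the
# fertility readout. Model fitting is delegated to stats::aov/TukeyHSD
# (Tukey-Kramer for unbalanced groups) behind this module's interface.

.checkBroods <- function(broods) {
  need <- c("group", "brood", "females", "males")
  if (!is.data.frame(broods) || !all(need %in% colnames(broods)))
    stop("brood table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(broods$females < 0) || any(broods$males < 0) ||
      any(broods$females != round(broods$females)) ||
      any(broods$males != round(broods$males)))
    stop("female/male counts must be non-negative integers", call. = FALSE)
  if (any(broods$females + broods$males < 1))
    stop("every brood needs at least one scored individual", call. = FALSE)
  invisible(broods)
}

#' Per-brood sex ratios and per-group summaries
#'
#' @param broods Brood `data.frame` with columns `group`, `brood`,
#'   `females`, `males` (see [readBroodTable()]).
#' @return List with `per_brood` (input plus a `proportion` column,
#'   females / total) and `per_group` (`group`, `n_broods`, `median`,
#'   `min`, `max` of the proportions; medians interpolate on even counts).
#' @examples
#' b <- data.frame(group = "ctrl", brood = 1:3,
#'                 females = c(27, 10, 2), males = c(23, 2, 26))
#' broodSexRatios(b)$per_group
#' @export
broodSexRatios <- function(broods) {
  .checkBroods(broods)
  broods$proportion <- broods$females / (broods$females + broods$males)
  groups <- split(broods$proportion, broods$group)
  empty <- names(groups)[lengths(groups) == 0L]
  if (length(empty)) {
    warning("omitting empty group(s): ", paste(empty, collapse = ", "))
    groups <- groups[lengths(groups) > 0L]
  }
  per_group <- data.frame(
    group = names(groups),
    n_broods = lengths(groups),
    median = vapply(groups, stats::median, numeric(1)),
    min = vapply(groups, min, numeric(1)),
    max = vapply(groups, max, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(per_brood = broods, per_group = per_group)
}

.anovaData <- function(proportions, groups, arcsine = FALSE) {
  g <- factor(groups)
  if (nlevels(g) < 2L)
    stop("need at least two treatment groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2L))
    stop("every group needs at least two broods (group '",
         names(sizes)[sizes < 2L][1], "' has ", min(sizes), ")",
         call. = FALSE)
  y <- if (arcsine) asin(sqrt(proportions)) else proportions
  data.frame(y = y, g = g)
}

#' One-way ANOVA on brood sex-ratio proportions
#'
#' F-test of equal group means on raw per-brood female proportions (an
#' arcsine square-root transform is available as a sensitivity analysis,
#' off by default). When the within-group variance is numerically zero the
#' F statistic diverges and `status = "degenerate"` is flagged instead of
#' reporting a p value.
#'
#' @param proportions Numeric vector of per-brood female proportions.
#' @param groups Treatment group labels, one per brood.
#' @param arcsine Apply `asin(sqrt(p))` before testing.
#' @return List with `F`, `df_between`, `df_within`, `p` and `status`
#'   (`"ok"` or `"degenerate"`).
#' @export
sexRatioAnova <- function(proportions, groups, arcsine = FALSE) {
  d <- .anovaData(proportions, groups, arcsine)
  fit <- stats::aov(y ~ g, data = d)
  # degeneracy is handled explicitly below; silence the perfect-fit warning
  tab <- suppressWarnings(stats::anova(fit))
  msw <- tab$`Mean Sq`[2]
  if (!is.finite(msw) || msw < 1e-12) {
    return(list(F = Inf, df_between = tab$Df[1], df_within = tab$Df[2],
                p = NA_real_, status = "degenerate"))
  }
  list(F = tab$`F value`[1], df_between = tab$Df[1], df_within = tab$Df[2],
       p = tab$`Pr(>F)`[1], status = "ok")
}

#' Tukey HSD pairwise comparisons of brood sex ratios
#'
#' Studentized-range post-hoc test on the pooled within-group variance;
#' unbalanced designs use the Tukey-Kramer harmonic-mean adjustment. At
#' fixed variance the adjusted p value decreases monotonically in the
#' absolute mean difference.
#'
#' @inheritParams sexRatioAnova
#' @return `data.frame` with one row per group pair: `pair`, `diff`
#'   (difference of means), `lwr`, `upr` (95% family-wise interval) and
#'   `p_adj`.
#' @export
sexRatioTukey <- function(proportions, groups, arcsine = FALSE) {
  d <- .anovaData(proportions, groups, arcsine)
  if (suppressWarnings(stats::anova(stats::aov(y ~ g, data = d)))$`Mean Sq`[2] < 1e-12)
    stop("within-group variance is zero; Tukey HSD undefined", call. = FALSE)
  fit <- stats::aov(y ~ g, data = d)
  th <- stats::TukeyHSD(fit)$g
  data.frame(pair = rownames(th), diff = th[, "diff"], lwr = th[, "lwr"],
             upr = th[, "upr"], p_adj = th[, "p adj"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full sex-ratio analysis of a brood table
#'
#' Convenience wrapper: per-brood proportions and group summaries, the
#' one-way ANOVA, and (when the ANOVA is non-degenerate) the Tukey HSD
#' table.
#'
#' @param broods Brood `data.frame` (see [readBroodTable()]).
#' @param arcsine Apply the arcsine square-root transform.
#' @return List with `ratios`, `anova` and `tukey` components.
#' @export
sexRatioStats <- function(broods, arcsine = FALSE) {
  ratios <- broodSexRatios(broods)
  pb <- ratios$per_brood
  an <- sexRatioAnova(pb$proportion, pb$group, arcsine)
  tk <- if (identical(an$status, "ok"))
    sexRatioTukey(pb$proportion, pb$group, arcsine) else NULL
  list(ratios = ratios, anova = an, tukey = tk)
}
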