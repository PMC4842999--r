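# Cohort aggregation: per-mouse medians, group comparisons (one-way ANOVA
# with post-hoc Tukey), subtype fractions, distance-from-soma gradients,
# and the subtype-weighted whole-population diameter consistency check.
# The statistical unit throughout is the mouse (n = 3 design): structure
# measurements are reduced to a per-mouse median first, then summarised as
# mean +/- SD across mice.

#' Summarise a measure within a region
#'
#' Reduces per-structure values to per-mouse medians and reports their
#' across-mouse mean and SD. A single-mouse summary reports SD 0 and is
#' flagged.
#'
#' @param data Data frame of per-structure rows.
#' @param measure Name of the numeric measurement column.
#' @param mouse Name of the mouse-id column (default `"mouse"`).
#' @param region_label Optional label stored on the summary.
#' @return Object of class `region_summary`: list with `region_label`,
#'   `per_mouse_medians` (named), `group_mean`, `group_sd`, `n_mice`,
#'   `n_structures`, `single_mouse` flag.
#' @export
summarise_region <- function(data, measure, mouse = "mouse",
                             region_label = NULL) {
  stopifnot(is.data.frame(data), measure %in% names(data),
            mouse %in% names(data))
  groups <- split(data[[measure]], data[[mouse]])
  empty <- vapply(groups, function(g) all(is.na(g)) || !length(g), logical(1))
  if (any(empty)) {
    stop(sprintf("mouse '%s' has no measurements", names(groups)[empty][1]))
  }
  med <- vapply(groups, median, numeric(1), na.rm = TRUE)
  structure(list(
    region_label = region_label,
    per_mouse_medians = med,
    group_mean = mean(med),
    group_sd = if (length(med) > 1) sd(med) else 0,
    n_mice = length(med),
    n_structures = nrow(data),
    single_mouse = length(med) == 1L),
    class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("<region_summary>%s %.4g +/- %.3g (n = %d mice, %d structures)%s\n",
              if (is.null(x$region_label)) "" else paste0(" ", x$region_label),
              x$group_mean, x$group_sd, x$n_mice, x$n_structures,
              if (x$single_mouse) " [single mouse: SD not defined]" else ""))
  invisible(x)
}

#' Per-mouse subtype fractions
#'
#' Computes the percentage of 1NC / 2NC / 3+NC PSDs per mouse, then the
#' across-mouse mean and SD of each fraction (the
#' "63.7 +/- 1.6 %"-style summary).
#'
#' @param data Data frame with a `subtype` column (factor from
#'   [classify_subtype()]) and a mouse-id column.
#' @param mouse Name of the mouse-id column.
#' @return List with `per_mouse` (mice x subtypes matrix of percentages),
#'   `mean` and `sd` (named by subtype).
#' @export
subtype_fractions <- function(data, mouse = "mouse") {
  stopifnot("subtype" %in% names(data), mouse %in% names(data))
  tab <- table(data[[mouse]], data$subtype)
  pct <- 100 * prop.table(tab, margin = 1)
  pct <- matrix(pct, nrow = nrow(tab), dimnames = dimnames(tab))
  list(per_mouse = pct,
       mean = colMeans(pct),
       sd = if (nrow(pct) > 1) apply(pct, 2, sd)
            else setNames(rep(0, ncol(pct)), colnames(pct)))
}

#' Compare regions by one-way ANOVA with post-hoc Tukey
#'
#' Standard one-way ANOVA on per-mouse values (typically medians from
#' [summarise_region()]), followed by Tukey honest significant
#' differences for the pairwise region contrasts.
#'
#' @param data Data frame with one row per mouse x region.
#' @param value Name of the value column.
#' @param group Name of the grouping (region) column.
#' @return List with `F`, `p`, `anova` (the aov fit) and `tukey` (matrix
#'   of pairwise comparisons).
#' @export
compare_regions <- function(data, value = "value", group = "region") {
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("compare_regions needs at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2)) {
    stop(sprintf("group '%s' has fewer than 2 values",
                 names(sizes)[sizes < 2][1]))
  }
  d <- data.frame(y = data[[value]], g = g)
  fit <- aov(y ~ g, data = d)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       anova = fit, tukey = TukeyHSD(fit)$g)
}

#' Gradient of a measure with distance from the soma layer
#'
#' Bins image-level observations into distance bins (20 um steps over
#' 20-140 um by default) and computes Pearson's correlation between
#' distance and the measure over the individual observations in range.
#'
#' @param data Data frame with one row per image (or other sampling
#'   unit).
#' @param value Name of the measure column.
#' @param distance Name of the distance column (um).
#' @param bin_width Bin width in um.
#' @param range `(min, max)` distance range analysed, inclusive.
#' @return Object of class `gradient_result`: list with `distance_bins`
#'   (bin centres, um), `bin_means`, `pearson_r`, `p_value`, `n_obs`.
#' @export
gradient_analysis <- function(data, value = "value", distance = "distance_um",
                              bin_width = 20, range = c(20, 140)) {
  stopifnot(is.data.frame(data), value %in% names(data),
            distance %in% names(data))
  d <- data[data[[distance]] >= range[1] & data[[distance]] <= range[2], ]
  if (!nrow(d)) stop("no observations in the distance range")
  edges <- seq(range[1] - bin_width / 2, range[2] + bin_width / 2,
               by = bin_width)
  bin <- cut(d[[distance]], edges, include.lowest = TRUE)
  means <- tapply(d[[value]], bin, mean, na.rm = TRUE)
  if (sum(!is.na(means)) < 3) {
    stop("fewer than 3 distance bins populated")
  }
  ct <- if (sd(d[[value]]) == 0) list(estimate = 0, p.value = 1)
        else cor.test(d[[distance]], d[[value]], method = "pearson")
  structure(list(
    distance_bins = edges[-length(edges)] + bin_width / 2,
    bin_means = as.numeric(means),
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    n_obs = nrow(d)),
    class = "gradient_result")
}

#' @export
print.gradient_result <- function(x, ...) {
  cat(sprintf("<gradient_result> r = %.3f (p = %.3g, n = %d)\n",
              x$pearson_r, x$p_value, x$n_obs))
  invisible(x)
}

#' Subtype-weighted whole-population diameter
#'
#' Consistency check relating per-subtype PSD diameters and subtype
#' fractions to the whole-population figure: the fraction-weighted mean
#' diameter, normalised by the fraction sum and rounded to the nearest
#' nm.
#'
#' @param diameters Per-subtype diameters (nm), e.g. for 1NC / 2NC /
#'   3+NC PSDs.
#' @param fractions Matching non-negative subtype fractions (any scale).
#' @return Weighted mean diameter, nearest nm.
#' @export
subtype_consistency_report <- function(diameters, fractions) {
  stopifnot(length(diameters) == length(fractions))
  if (any(fractions < 0)) stop("fractions must be >= 0")
  if (sum(fractions) == 0) stop("fractions must not all be zero")
  round(sum(diameters * fractions) / sum(fractions))
}
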