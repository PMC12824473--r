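#' Normalize raw viability readouts to surviving fractions
#'
#' Divides every readout by the untreated (activity 0) readout of the same
#' (cell line, replicate), so the surviving fraction at activity 0 is exactly
#' 1. Normalization absorbs readout units: rescaling all raw values of a
#' replicate by a positive constant leaves the fractions unchanged.
#'
#' @param table data frame with columns `cell_line`, `replicate`,
#'   `activity_mbq_per_ml`, and `readout` (or `fraction`, treated as the raw
#'   value).
#' @return the table with a `fraction` column of surviving fractions.
#' @export
normalize_viability <- function(table) {
  value_col <- if ("readout" %in% names(table)) "readout" else "fraction"
  stop_if(!all(c("cell_line", "replicate", "activity_mbq_per_ml") %in%
                 names(table)) || !value_col %in% names(table),
          "viability table must have cell_line, replicate, ",
          "activity_mbq_per_ml and readout/fraction columns")
  key <- interaction(table$cell_line, table$replicate, drop = TRUE)
  out <- lapply(split(table, key), function(d) {
    stop_if(anyDuplicated(d$activity_mbq_per_ml) > 0,
            "duplicate activities for (", d$cell_line[1], ", replicate ",
            d$replicate[1], ")")
    i0 <- which(d$activity_mbq_per_ml == 0)
    stop_if(length(i0) == 0 || d[[value_col]][i0] <= 0,
            "missing or nonpositive untreated control for (",
            d$cell_line[1], ", replicate ", d$replicate[1], ")")
    d$fraction <- d[[value_col]] / d[[value_col]][i0]
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Trapezoidal area under a curve
#'
#' Composite trapezoid rule over sorted (x, y) knots: sum of
#' 0.5 * (y_i + y_{i+1}) * (x_{i+1} - x_i). Exact for piecewise-linear
#' curves evaluated on their knot grid.
#'
#' @param x strictly increasing abscissae (activities, MBq/mL).
#' @param y ordinates (surviving fractions).
#' @return area (MBq/mL x fraction units).
#' @export
trapezoid_auc <- function(x, y) {
  stop_if(length(x) < 2, "need at least 2 points")
  stop_if(length(x) != length(y), "x and y lengths differ")
  stop_if(is.unsorted(x, strictly = TRUE),
          "activities must be strictly increasing (no duplicates)")
  sum(0.5 * (y[-length(y)] + y[-1]) * diff(x))
}

#' Normalized AUC (nAUC)
#'
#' Ratio of a curve's area to the area of the flat 100%-survival reference
#' over the same activity span: nAUC = AUC_curve / span. 1 means fully
#' resistant (flat survival at 1); lower values mean greater sensitivity.
#' Values above 1 can arise from replicate noise; they are reported as-is
#' (see `exceeds_one` flags downstream), never clamped.
#'
#' @param curve_auc area under the normalized viability curve.
#' @param span activity span `A_max - A_min` (the flat-1 reference area).
#' @return unitless nAUC.
#' @export
nauc <- function(curve_auc, span) {
  stop_if(span <= 0, "activity span must be > 0")
  curve_auc / span
}

#' Per-replicate nAUC from a raw viability table
#'
#' Normalizes readouts, integrates each (line, replicate) curve by the
#' trapezoid rule, and divides by the activity span. Warns when a replicate
#' lacks the panel-wide top activity, since that changes the reference span.
#'
#' @param table raw viability table (see [normalize_viability()]).
#' @return data frame: `cell_line`, `replicate`, `nauc`, `exceeds_one`.
#' @export
compute_replicate_nauc <- function(table) {
  norm <- normalize_viability(table)
  a_top <- max(norm$activity_mbq_per_ml)
  key <- interaction(norm$cell_line, norm$replicate, drop = TRUE)
  out <- lapply(split(norm, key), function(d) {
    d <- d[order(d$activity_mbq_per_ml), ]
    if (max(d$activity_mbq_per_ml) < a_top)
      warning("(", d$cell_line[1], ", replicate ", d$replicate[1],
              ") lacks the top activity ", a_top,
              "; nAUC uses its own span", call. = FALSE)
    span <- diff(range(d$activity_mbq_per_ml))
    v <- nauc(trapezoid_auc(d$activity_mbq_per_ml, d$fraction), span)
    data.frame(cell_line = d$cell_line[1], replicate = d$replicate[1],
               nauc = v, exceeds_one = v > 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$cell_line, out$replicate), ]
}

#' Summarize replicate nAUC values per line
#'
#' Mean and standard error (sample SD / sqrt(n)) per cell line. A line with a
#' single replicate gets SEM 0 with a warning.
#'
#' @param replicate_nauc data frame with `cell_line` and `nauc` columns.
#' @return data frame: `cell_line`, `n`, `mean_nauc`, `sem`.
#' @export
summarize_nauc <- function(replicate_nauc) {
  stop_if(nrow(replicate_nauc) == 0, "empty replicate nAUC table")
  out <- lapply(split(replicate_nauc, replicate_nauc$cell_line), function(d) {
    n <- nrow(d)
    sem <- if (n == 1) {
      warning("line ", d$cell_line[1],
              " has a single replicate; SEM set to 0", call. = FALSE)
      0
    } else sd(d$nauc) / sqrt(n)
    data.frame(cell_line = d$cell_line[1], n = n, mean_nauc = mean(d$nauc),
               sem = sem, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Assign resistance groups from nAUC Z-scores
#'
#' Z-scores the per-line mean nAUC values (sample SD, n - 1) and labels each
#' line resistant (z >= `resistant_z`), sensitive (z <= `sensitive_z`), or
#' intermediate. The defaults (0 and -0.45) reproduce the a-priori
#' 5 resistant / 3 sensitive / 2 intermediate partition of the study panel's
#' printed mean nAUC values; both are configurable since grouping in practice
#' also weighed expression-space clustering.
#'
#' @param profile data frame with `cell_line` and `mean_nauc` (e.g. from
#'   [summarize_nauc()]), or a named numeric of means.
#' @param resistant_z Z threshold at/above which a line is resistant.
#' @param sensitive_z Z threshold at/below which a line is sensitive.
#' @return the profile with `z` and `group` columns.
#' @export
assign_groups <- function(profile, resistant_z = 0, sensitive_z = -0.45) {
  if (is.numeric(profile) && !is.null(names(profile)))
    profile <- data.frame(cell_line = names(profile), mean_nauc = profile,
                          stringsAsFactors = FALSE, row.names = NULL)
  stop_if(nrow(profile) < 2, "need at least 2 lines")
  stop_if(resistant_z <= sensitive_z,
          "resistant_z must exceed sensitive_z")
  s <- sd(profile$mean_nauc)
  stop_if(s == 0, "zero variance across line means; groups undefined")
  profile$z <- (profile$mean_nauc - mean(profile$mean_nauc)) / s
  profile$group <- ifelse(profile$z >= resistant_z, "resistant",
                          ifelse(profile$z <= sensitive_z, "sensitive",
                                 "intermediate"))
  profile
}

#' One-way ANOVA with Tukey HSD across cell lines
#'
#' Classical one-way ANOVA of replicate nAUC values grouped by line,
#' followed by Tukey's studentized-range adjustment for all pairwise
#' comparisons.
#'
#' @param values numeric replicate values.
#' @param groups grouping factor/character, same length as `values`.
#' @return list with `f` (F statistic), `p` (ANOVA p-value), `df_between`,
#'   `df_within`, and `tukey` (data frame: `comparison`, `diff`, `p_adj`).
#' @export
compare_lines_anova <- function(values, groups) {
  groups <- factor(groups)
  stop_if(nlevels(groups) < 2, "need at least 2 groups")
  stop_if(any(table(groups) < 2), "every group needs >= 2 replicates")
  fit <- aov(values ~ groups)
  an <- anova(fit)
  tk <- TukeyHSD(fit)$groups
  list(f = an[1, "F value"], p = an[1, "Pr(>F)"],
       df_between = an[1, "Df"], df_within = an[2, "Df"],
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE))
}
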