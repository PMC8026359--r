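# Cohort-level statistics: Pearson correlations with Bonferroni families,
# Welch and paired t contrasts, and the full structure-function battery.

#' Pearson correlation with two-sided p value
#'
#' Product-moment correlation; the p value comes from the t transform with
#' n - 2 degrees of freedom (as in [stats::cor.test()], which is used
#' internally).
#'
#' @param x,y numeric vectors of equal length (n >= 3, finite, non-constant).
#' @return list with `r`, `n`, `p`.
#' @examples
#' pearson(1:4, c(2, 4, 6, 8))$r # 1
#' @export
pearson <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3)
    knob_stop("need >= 3 complete pairs", "knobmap_analysis_error")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    knob_stop("zero variance: correlation undefined", "knobmap_analysis_error")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = n, p = ct$p.value)
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite (possibly
#' fractional) degrees of freedom.
#'
#' @param group_a,group_b numeric vectors (each n >= 2).
#' @return list with `statistic`, `dof`, `p`, `kind = "welch"`.
#' @export
welch_t <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2)
    knob_stop("each group needs >= 2 values", "knobmap_analysis_error")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0)
    knob_stop("zero variance in both groups", "knobmap_analysis_error")
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), dof = unname(tt$parameter),
       p = tt$p.value, kind = "welch")
}

#' Welch t test from group summaries
#'
#' Same statistic as [welch_t()] but computed from means, SDs and group
#' sizes, e.g. when reconstructing a published contrast from printed
#' mean +/- SEM values (SD = SEM * sqrt(n)).
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries.
#' @return list with `statistic`, `dof`, `p`, `kind = "welch"`.
#' @export
welch_t_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
  t <- (mean_a - mean_b) / sqrt(va + vb)
  dof <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  list(statistic = t, dof = dof, p = 2 * stats::pt(-abs(t), dof),
       kind = "welch")
}

#' Paired t test
#'
#' @param before,after numeric vectors of equal length (paired).
#' @return list with `statistic`, `dof`, `p`, `kind = "paired"`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after))
    knob_stop("paired samples must have equal length", "knobmap_analysis_error")
  keep <- is.finite(before) & is.finite(after)
  d <- before[keep] - after[keep]
  if (length(d) < 2)
    knob_stop("need >= 2 complete pairs", "knobmap_analysis_error")
  if (stats::var(d) == 0)
    knob_stop("zero-variance differences: paired t undefined", "knobmap_analysis_error")
  tt <- stats::t.test(d)
  list(statistic = unname(tt$statistic), dof = unname(tt$parameter),
       p = tt$p.value, kind = "paired")
}

#' Bonferroni adjustment with an explicit family size
#'
#' `min(1, p * m)`. The family size `m` may exceed the number of p values
#' supplied (tests from the same family can be adjusted in batches).
#'
#' @param p numeric vector of p values.
#' @param m family size (default: number of p values).
#' @return adjusted p values.
#' @examples
#' bonferroni(c(0.01, 0.03), 2)
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p))
    knob_stop("family size m must be >= number of p values", "knobmap_input_error")
  pmin(1, p * m)
}

# one battery row, errors captured so a degenerate column never poisons the
# other rows
battery_row <- function(tab, set, xcol, ycol) {
  res <- tryCatch(pearson(tab[[xcol]], tab[[ycol]]),
                  error = function(e) e)
  if (inherits(res, "error"))
    data.frame(set = set, x = xcol, y = ycol, r = NA_real_, n = NA_integer_,
               p = NA_real_, error = conditionMessage(res))
  else
    data.frame(set = set, x = xcol, y = ycol, r = res$r, n = res$n,
               p = res$p, error = NA_character_)
}

#' Structure-function correlation battery
#'
#' Runs the fixed set of cohort-level Pearson correlations with per-set
#' Bonferroni families:
#'
#' * `rostrocaudal` (family size 2): hotspot y-coordinate vs shortest MEP
#'   latency, per muscle.
#' * `structure_function` (family size 6): whole-knob R1 vs rostrality index
#'   (both muscles), task-related BOLD (both fingers) and intermovement CV
#'   (both fingers). Subjects without a valid R1 are excluded from R1 rows.
#' * `structure_function_subroi` (family size 12): the same six functional
#'   readouts against the caudal and rostral sub-ROI R1 means.
#' * `thickness_curvature` (family size 4): mean cortical thickness and mean
#'   curvature vs the rostrality index, per muscle (specificity control).
#'
#' Rostrality indices are computed on the fly from the hotspot columns via
#' [rostrality_index()]. Rows whose inputs are degenerate (constant column,
#' too few subjects) carry `NA` results and an `error` message; other rows
#' are unaffected. Muscles absent from the table are skipped, shrinking the
#' affected family accordingly.
#'
#' @param cohort a cohort table (see [simulate_cohort()]) with columns
#'   `r1_mean`, `r1_caudal`, `r1_rostral`, `bold_index`, `bold_little`,
#'   `cv_index`, `cv_little`, `thickness_caudal`, `thickness_rostral`,
#'   `curvature_caudal`, `curvature_rostral`, and per-muscle hotspot columns
#'   `fdi_hotspot_y`, `fdi_latency`, `fdi_hotspot_line` (and `adm_*`).
#' @return data frame with one row per correlation: `set`, `x`, `y`, `r`,
#'   `n`, `p`, `p_adjusted`, `family_size`, `error`.
#' @export
run_correlation_battery <- function(cohort) {
  tab <- as.data.frame(cohort)
  muscles <- c(fdi = "fdi", adm = "adm")
  muscles <- muscles[paste0(muscles, "_hotspot_y") %in% names(tab)]
  if (!length(muscles))
    knob_stop("no hotspot columns (fdi_* or adm_*) in the cohort table",
              "knobmap_input_error")
  if (nrow(tab) < 3)
    warning("fewer than 3 subjects: correlation battery will be degenerate",
            call. = FALSE)

  # per-muscle rostrality, cohort-wide normalization
  for (m in muscles) {
    long <- data.frame(subject = seq_len(nrow(tab)), muscle = toupper(m),
                       hotspot_y = tab[[paste0(m, "_hotspot_y")]],
                       shortest_latency = tab[[paste0(m, "_latency")]],
                       hotspot_line = tab[[paste0(m, "_hotspot_line")]])
    ri <- tryCatch(rostrality_index(long), error = function(e) NULL)
    tab[[paste0(m, "_rostrality")]] <-
      if (is.null(ri)) NA_real_ else ri$rostrality_index
  }
  tab$thickness_mean <- (tab$thickness_caudal + tab$thickness_rostral) / 2
  tab$curvature_mean <- (tab$curvature_caudal + tab$curvature_rostral) / 2

  rows <- list()
  for (m in muscles)
    rows[[length(rows) + 1L]] <-
      battery_row(tab, "rostrocaudal", paste0(m, "_hotspot_y"), paste0(m, "_latency"))

  functional <- c(paste0(muscles, "_rostrality"),
                  "bold_index", "bold_little", "cv_index", "cv_little")
  for (ycol in functional)
    rows[[length(rows) + 1L]] <- battery_row(tab, "structure_function", "r1_mean", ycol)
  for (xcol in c("r1_caudal", "r1_rostral"))
    for (ycol in functional)
      rows[[length(rows) + 1L]] <-
        battery_row(tab, "structure_function_subroi", xcol, ycol)
  for (xcol in c("thickness_mean", "curvature_mean"))
    for (m in muscles)
      rows[[length(rows) + 1L]] <-
        battery_row(tab, "thickness_curvature", xcol, paste0(m, "_rostrality"))

  out <- do.call(rbind, rows)
  fam <- table(out$set)
  out$family_size <- as.integer(fam[out$set])
  out$p_adjusted <- NA_real_
  # adjust within each family, not across
  for (s in unique(out$set)) {
    i <- which(out$set == s & !is.na(out$p))
    if (length(i))
      out$p_adjusted[i] <- bonferroni(out$p[i],
                                      m = out$family_size[out$set == s][1])
  }
  rownames(out) <- NULL
  out
}

#' Paired ROI contrasts (caudal vs rostral precentral gyrus)
#'
#' Paired t tests comparing the caudal and rostral precentral sub-ROIs on
#' R1 (myelination), cortical thickness, curvature and task-related BOLD,
#' Bonferroni-corrected as one family.
#'
#' @param cohort a cohort table with `*_caudal` / `*_rostral` column pairs
#'   for `r1`, `thickness`, `curvature`, `bold`.
#' @return data frame with `measure`, `mean_caudal`, `mean_rostral`,
#'   `statistic`, `dof`, `p`, `p_adjusted`, `n`.
#' @export
roi_contrasts <- function(cohort) {
  tab <- as.data.frame(cohort)
  measures <- c("r1", "thickness", "curvature", "bold")
  measures <- measures[paste0(measures, "_caudal") %in% names(tab)]
  rows <- lapply(measures, function(m) {
    a <- tab[[paste0(m, "_caudal")]]
    b <- tab[[paste0(m, "_rostral")]]
    keep <- is.finite(a) & is.finite(b)
    res <- paired_t(a[keep], b[keep])
    data.frame(measure = m, mean_caudal = mean(a[keep]),
               mean_rostral = mean(b[keep]), statistic = res$statistic,
               dof = res$dof, p = res$p, n = sum(keep))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p, m = nrow(out))
  out
}

#' Rostral vs caudal hotspot-group comparisons
#'
#' Welch t tests comparing the caudal and rostral hotspot groups (defined by
#' the FDI hotspot line, see [assign_group()]) on electrophysiological and
#' spatial readouts, in the style of a cohort characterization table.
#'
#' @param cohort a cohort table with a `group` column plus any of `rmt`,
#'   `fdi_latency`, `adm_latency`, `fdi_hotspot_amp`, `adm_hotspot_amp`,
#'   `fdi_hotspot_y`, `adm_hotspot_y`.
#' @return data frame with `measure`, group means, `statistic`, `dof`, `p`.
#' @export
group_tests <- function(cohort) {
  tab <- as.data.frame(cohort)
  if (!"group" %in% names(tab))
    knob_stop("cohort table needs a group column", "knobmap_input_error")
  vars <- intersect(c("rmt", "fdi_latency", "adm_latency", "fdi_hotspot_amp",
                      "adm_hotspot_amp", "fdi_hotspot_y", "adm_hotspot_y"),
                    names(tab))
  rows <- lapply(vars, function(v) {
    a <- tab[[v]][tab$group == "caudal"]
    b <- tab[[v]][tab$group == "rostral"]
    res <- tryCatch(welch_t(a, b), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(measure = v, mean_caudal = mean(a, na.rm = TRUE),
               mean_rostral = mean(b, na.rm = TRUE),
               statistic = res$statistic, dof = res$dof, p = res$p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(measure = character(0), mean_caudal = numeric(0),
                      mean_rostral = numeric(0), statistic = numeric(0),
                      dof = numeric(0), p = numeric(0))
  rownames(out) <- NULL
  out
}
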