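#' Class-level and clinical-variable group comparisons
#'
#' Per-lipid (or per-clinical-variable) comparisons in the style of the
#' study's summary figures: paired t tests for within-group before/after
#' change, one-way ANOVA or Kruskal-Wallis for between-group contrasts at
#' one time point, with group means and standard errors of the mean.  A
#' p-value below 0.05 is conventionally considered significant; no
#' multiple-testing correction is applied by default because per-lipid raw
#' p-values are reported (Benjamini-Hochberg is available via `adjust`).
#'
#' @param table A [peak_table()] of concentrations (or any numeric matrix
#'   with sample columns), or a data frame with a `patient_id`, `group`,
#'   `time` and variable columns (clinical layout).
#' @param design A [sample_design()]; ignored for the clinical data-frame
#'   layout.
#' @param variable Row name (peak id) or column name (clinical variable) to
#'   compare.
#' @param contrast One of `"low_vs_placebo"`, `"low_vs_high"` (between-group
#'   at one time), `"intra_group_before_after"` (paired within one group).
#' @param time Time point for between-group contrasts (default `"after"`,
#'   the close-out comparison).
#' @param group Group for the paired contrast (default `"feno_low_hcy"`).
#' @param test Between-group test: `"anova"` or `"kruskal_wallis"`.
#' @param adjust P-value adjustment method (default `"none"`).
#' @return A list of class `group_comparison`: `variable`, `contrast`,
#'   `test`, `groups` (data frame group/n/mean/sem), `p_value`, `stars`.
#' @export
compare_groups <- function(table, design = NULL, variable, contrast,
                           time = "after", group = "feno_low_hcy",
                           test = c("anova", "kruskal_wallis"),
                           adjust = "none") {
  test <- match.arg(test)
  contrast <- match.arg(contrast, c("low_vs_placebo", "low_vs_high",
                                    "intra_group_before_after"))
  if (is.data.frame(table) && all(c("group", "time") %in% names(table))) {
    if (!variable %in% names(table)) {
      stop("variable '", variable, "' not found", call. = FALSE)
    }
    obs <- data.frame(value = table[[variable]],
                      patient_id = table$patient_id,
                      group = table$group, time = table$time,
                      stringsAsFactors = FALSE)
  } else {
    x <- if (inherits(table, "peak_table")) table$values else as.matrix(table)
    if (!variable %in% rownames(x)) {
      stop("variable '", variable, "' not found", call. = FALSE)
    }
    idx <- match(colnames(x), design$sample_id)
    obs <- data.frame(value = x[variable, ],
                      patient_id = design$patient_id[idx],
                      group = design$group[idx], time = design$time[idx],
                      stringsAsFactors = FALSE)
  }

  if (contrast == "intra_group_before_after") {
    sub <- obs[obs$group == group, ]
    wide <- merge(sub[sub$time == "before", c("patient_id", "value")],
                  sub[sub$time == "after", c("patient_id", "value")],
                  by = "patient_id", suffixes = c("_before", "_after"))
    if (nrow(wide) < 2) {
      stop("fewer than 2 paired observations in group '", group, "'",
           call. = FALSE)
    }
    diffs <- wide$value_after - wide$value_before
    p <- if (stats::sd(diffs) == 0) {
      if (all(diffs == 0)) 1 else 0
    } else {
      stats::t.test(wide$value_after, wide$value_before, paired = TRUE)$p.value
    }
    groups_df <- data.frame(
      group = c("before", "after"),
      n = nrow(wide),
      mean = c(mean(wide$value_before), mean(wide$value_after)),
      sem = c(stats::sd(wide$value_before), stats::sd(wide$value_after)) /
        sqrt(nrow(wide)),
      stringsAsFactors = FALSE)
    used <- "paired_t"
  } else {
    keep_groups <- if (contrast == "low_vs_placebo") {
      c("feno_low_hcy", "placebo_low_hcy")
    } else c("feno_low_hcy", "feno_high_hcy")
    sub <- obs[obs$group %in% keep_groups & obs$time == time, ]
    ns <- base::table(sub$group)
    if (any(ns < 2) || length(ns) < 2) {
      stop("each group needs at least 2 observations at time '", time, "'",
           call. = FALSE)
    }
    sub$group <- factor(sub$group, levels = keep_groups)
    p <- if (test == "anova") {
      stats::anova(stats::aov(value ~ group, data = sub))[["Pr(>F)"]][1]
    } else {
      stats::kruskal.test(value ~ group, data = sub)$p.value
    }
    groups_df <- do.call(rbind, lapply(keep_groups, function(g) {
      v <- sub$value[sub$group == g]
      data.frame(group = g, n = length(v), mean = mean(v),
                 sem = stats::sd(v) / sqrt(length(v)),
                 stringsAsFactors = FALSE)
    }))
    used <- test
  }
  p <- stats::p.adjust(p, method = adjust)
  structure(
    list(variable = variable, contrast = contrast, test = used,
         groups = groups_df, p_value = p, stars = star_code(p, contrast)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$variable, ": ", x$contrast, " (", x$test,
      ")\n", sep = "")
  print(x$groups, row.names = FALSE)
  cat("  p = ", format.pval(x$p_value, digits = 3),
      if (nzchar(x$stars)) paste0("  ", x$stars) else "", "\n", sep = "")
  invisible(x)
}

#' Significance star code for a contrast
#'
#' The figure annotation scheme: the low-Hcy vs placebo contrast uses
#' asterisks (`*` p<0.05, `**` p<0.01) and the low-Hcy vs high-Hcy contrast
#' uses hashes (`#` p<0.05, `##` p<0.01, `###` p<0.001).  The paired
#' within-group contrast uses asterisks with a `***` tier at p<0.001.
#'
#' @param p P-value in `[0, 1]`.
#' @param contrast Contrast name as in [compare_groups()].
#' @return A string (empty when p >= 0.05).
#' @examples
#' star_code(0.03, "low_vs_placebo")   # "*"
#' star_code(0.0005, "low_vs_high")    # "###"
#' star_code(0.5, "low_vs_placebo")    # ""
#' @export
star_code <- function(p, contrast) {
  stopifnot(is.finite(p), p >= 0, p <= 1)
  sym <- if (contrast == "low_vs_high") "#" else "*"
  if (contrast == "low_vs_placebo") {
    if (p < 0.01) strrep(sym, 2) else if (p < 0.05) sym else ""
  } else {
    if (p < 0.001) strrep(sym, 3) else if (p < 0.01) strrep(sym, 2)
    else if (p < 0.05) sym else ""
  }
}

#' Run a contrast across many variables
#'
#' Applies [compare_groups()] to every row of a concentration table (or
#' every clinical variable) and returns a tidy report suitable for CSV
#' export.
#'
#' @inheritParams compare_groups
#' @param variables Variables to test; defaults to all.
#' @return A data frame with one row per variable: group means/SEMs,
#'   `test`, `p_value`, `stars`.
#' @export
compare_groups_all <- function(table, design = NULL, contrast,
                               variables = NULL, time = "after",
                               group = "feno_low_hcy",
                               test = c("anova", "kruskal_wallis"),
                               adjust = "none") {
  test <- match.arg(test)
  if (is.null(variables)) {
    variables <- if (is.data.frame(table) && "group" %in% names(table)) {
      setdiff(names(table), c("patient_id", "group", "time"))
    } else if (inherits(table, "peak_table")) {
      rownames(table$values)
    } else rownames(table)
  }
  rows <- lapply(variables, function(v) {
    cmp <- compare_groups(table, design, v, contrast, time = time,
                          group = group, test = test)
    g <- cmp$groups
    out <- data.frame(variable = v, test = cmp$test, p_value = cmp$p_value,
                      stars = cmp$stars, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(g))) {
      out[[paste0("mean_", g$group[i])]] <- g$mean[i]
      out[[paste0("sem_", g$group[i])]] <- g$sem[i]
    }
    out
  })
  res <- do.call(rbind, rows)
  if (adjust != "none") {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = adjust)
  }
  res
}
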