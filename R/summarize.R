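#' Classify an effect from its posterior draws
#'
#' An effect is called when its posterior mass lies above or below zero:
#' *significant* when the equal-tailed 95% credible interval excludes 0,
#' *almost significant* when the 90% interval excludes 0 but the 95%
#' interval does not (the reporting convention used for the red/blue
#' highlighting of the effect box plots; the interval levels are
#' configurable).
#'
#' @param draws Numeric vector of posterior draws (at least 100).
#' @param level Credible level for "significant" (default 0.95).
#' @param almost_level Credible level for "almost significant" (default
#'   0.90).
#' @return A list with `classification` (one of `"sig_up"`, `"sig_down"`,
#'   `"almost_up"`, `"almost_down"`, `"none"`), `ci` and `almost_ci`
#'   (2-vectors).
#' @export
classify_effect <- function(draws, level = 0.95, almost_level = 0.90) {
  stopifnot(length(draws) >= 100, almost_level < level)
  ci <- unname(stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2)))
  aci <- unname(stats::quantile(draws, c((1 - almost_level) / 2,
                                         1 - (1 - almost_level) / 2)))
  classification <- if (ci[1] > 0) "sig_up" else if (ci[2] < 0) "sig_down"
    else if (aci[1] > 0) "almost_up" else if (aci[2] < 0) "almost_down"
    else "none"
  list(classification = classification, ci = ci, almost_ci = aci)
}

effect_direction <- function(class) {
  switch(class, sig_up = , almost_up = "up",
         sig_down = , almost_down = "down", "none")
}

#' Interpret a (fenofibrate, interaction) classification pair
#'
#' Maps the sign pattern of the fenofibrate main effect and the
#' fenofibrate-by-Hcy interaction to its reading in terms of the two treated
#' groups: a positive fenofibrate effect upregulates both Hcy groups; a
#' positive interaction adds to the high-Hcy group (stronger there); a
#' negative interaction cancels the fenofibrate effect in the high-Hcy
#' group, so only the low-Hcy group is upregulated; and so on.
#'
#' @param f_class,i_class Classifications from [classify_effect()].
#' @return A short interpretation string.
#' @examples
#' interpret_combination("sig_up", "sig_down")  # only Low Hcy upregulated
#' @export
interpret_combination <- function(f_class, i_class) {
  f <- effect_direction(f_class)
  i <- effect_direction(i_class)
  key <- paste(f, i, sep = ".")
  switch(key,
    up.none = "upregulated in both groups",
    up.up = "upregulated in both groups, stronger in High Hcy",
    up.down = "upregulated in Low Hcy only",
    down.none = "downregulated in both groups",
    down.down = "downregulated in both groups, stronger in High Hcy",
    down.up = "downregulated in Low Hcy only",
    none.up = "upregulated in High Hcy only",
    none.down = "downregulated in High Hcy only",
    none.none = "no effect"
  )
}

#' Maximum-a-posteriori partition
#'
#' The cluster assignment of the retained draw with the highest joint log
#' density; used to define cluster membership and to align label-switching
#' draws.
#'
#' @param samples A `posterior_samples`.
#' @return Integer vector of cluster labels per lipid.
#' @export
map_partition <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  as.integer(samples$z[samples$map_draw, ])
}

#' Number of non-empty clusters
#'
#' Clusters with at least one assigned lipid in the MAP partition (the
#' requested number of clusters is an upper bound; unused clusters simply
#' attract no lipids).
#'
#' @param samples A `posterior_samples`.
#' @return Integer count.
#' @export
count_nonempty <- function(samples) {
  length(unique(map_partition(samples)))
}

# greedy label matching of one draw's partition onto the reference
# partition; returns perm with perm[k_ref] = draw label matched to k_ref
match_labels <- function(z_draw, z_ref, K) {
  C <- matrix(0L, K, K)
  tab <- table(factor(z_draw, levels = seq_len(K)),
               factor(z_ref, levels = seq_len(K)))
  C[] <- tab
  perm <- integer(K)
  used <- logical(K)
  ord <- order(C, decreasing = TRUE)
  for (o in ord) {
    l <- (o - 1) %% K + 1          # draw label
    k <- (o - 1) %/% K + 1         # reference label
    if (perm[k] == 0L && !used[l] && C[o] > 0L) {
      perm[k] <- l
      used[l] <- TRUE
    }
  }
  free <- which(!used)
  perm[perm == 0L] <- free[seq_len(sum(perm == 0L))]
  perm
}

#' Align posterior draws to the MAP partition
#'
#' Cluster labels are exchangeable, so draws may use permuted labels
#' (label switching).  Each draw's labels are greedily matched to the MAP
#' partition by maximum assignment overlap, and the effect draws are
#' permuted accordingly.
#'
#' @param samples A `posterior_samples`.
#' @return The `posterior_samples` with `beta_f`, `beta_p`, `beta_i` (and
#'   `z`) relabeled; the MAP partition is unchanged.
#' @export
align_to_map <- function(samples) {
  z_ref <- map_partition(samples)
  K <- ncol(samples$beta_f)
  n <- nrow(samples$beta_f)
  for (d in seq_len(n)) {
    perm <- match_labels(samples$z[d, ], z_ref, K)
    samples$beta_f[d, ] <- samples$beta_f[d, perm]
    samples$beta_p[d, ] <- samples$beta_p[d, perm]
    samples$beta_i[d, ] <- samples$beta_i[d, perm]
    inv <- integer(K)
    inv[perm] <- seq_len(K)
    samples$z[d, ] <- inv[samples$z[d, ]]
    if (!is.null(samples$v)) {
      # loadings and variances are per lipid, no relabeling needed
    }
  }
  samples
}

#' Summarize the covariate effects per cluster
#'
#' Posterior quantiles (2.5, 25, 50, 75, 97.5%) and classification of the
#' fenofibrate, placebo and interaction effect for every cluster, computed
#' from draws aligned to the MAP partition, plus the combined
#' fenofibrate/interaction interpretation.
#'
#' @param samples A `posterior_samples`.
#' @param align Align draws to the MAP partition first (default `TRUE`).
#' @param level,almost_level Interval levels, see [classify_effect()].
#' @return A data frame of class `effect_summary` with one row per
#'   (cluster, effect): `cluster`, `effect` (`"F"`, `"P"`, `"I"`),
#'   `n_lipids` (MAP membership), `q2.5` ... `q97.5`, `classification`;
#'   attribute `"interpretation"` holds the per-cluster F-I interpretation.
#' @export
effect_summary <- function(samples, align = TRUE, level = 0.95,
                           almost_level = 0.90) {
  if (align) samples <- align_to_map(samples)
  K <- ncol(samples$beta_f)
  zmap <- map_partition(samples)
  counts <- tabulate(zmap, K)
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  mats <- list(F = samples$beta_f, P = samples$beta_p, I = samples$beta_i)
  rows <- list()
  for (eff in names(mats)) {
    qm <- t(apply(mats[[eff]], 2, stats::quantile, probs = qs))
    cls <- vapply(seq_len(K), function(k) {
      classify_effect(mats[[eff]][, k], level, almost_level)$classification
    }, character(1))
    df <- data.frame(cluster = seq_len(K), effect = eff, n_lipids = counts,
                     stringsAsFactors = FALSE)
    colnames(qm) <- paste0("q", qs * 100)
    rows[[eff]] <- cbind(df, qm)
    rows[[eff]]$classification <- cls
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  interp <- vapply(seq_len(K), function(k) {
    interpret_combination(
      rows$F$classification[k], rows$I$classification[k])
  }, character(1))
  structure(out, interpretation = interp,
            class = c("effect_summary", "data.frame"))
}

#' Describe the lipid clusters
#'
#' Builds the per-cluster description from the MAP partition: total member
#' count (identified plus unidentified peaks), number identified,
#' representative lipids (the top identified members by absolute
#' posterior-mean loading), and a mechanical class tag (a class contributing
#' at least half of the identified members names the cluster, e.g.
#' `"SM-rich"`).
#'
#' @param samples A `posterior_samples`.
#' @param peaks A [peak_table()] (or its `peaks` data frame) whose rows line
#'   up with the fitted lipids.
#' @param n_representatives Representatives listed per cluster (default 2).
#' @return A data frame of class `cluster_table` with one row per non-empty
#'   cluster: `cluster`, `n_lipids`, `n_identified`, `representatives`
#'   (comma-joined labels, `"-"` when no member is identified),
#'   `class_summary`.
#' @export
cluster_table <- function(samples, peaks, n_representatives = 2) {
  peaks_df <- if (inherits(peaks, "peak_table")) peaks$peaks else peaks
  zmap <- map_partition(samples)
  D <- length(zmap)
  stopifnot(nrow(peaks_df) == D)
  vbar <- if (!is.null(samples$v)) colMeans(samples$v) else rep(1, D)
  classes <- vapply(peaks_df$parsed, function(p) p$lipid_class, character(1))
  nonempty <- sort(unique(zmap))
  rows <- lapply(nonempty, function(k) {
    idx <- which(zmap == k)
    id_idx <- idx[peaks_df$identified[idx]]
    reps <- if (length(id_idx)) {
      top <- id_idx[order(abs(vbar[id_idx]), decreasing = TRUE)]
      paste(peaks_df$name[utils::head(top, n_representatives)],
            collapse = " and ")
    } else "-"
    tag <- if (length(id_idx)) {
      tab <- sort(table(classes[id_idx]), decreasing = TRUE)
      if (tab[1] / length(id_idx) >= 0.5) paste0(names(tab)[1], "-rich")
      else "mixed"
    } else "not identified"
    data.frame(cluster = k, n_lipids = length(idx),
               n_identified = length(id_idx), representatives = reps,
               class_summary = tag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("cluster_table", "data.frame"))
}

#' Box-plot style figure of the cluster effects
#'
#' Quartiles and 95% posterior intervals of the fenofibrate (F), placebo (P)
#' and interaction (I) effects per cluster, colored by classification
#' (significant red, almost significant blue).  Requires ggplot2.
#'
#' @param summary An [effect_summary()].
#' @return A ggplot object.
#' @export
plot_effect_summary <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_effect_summary requires the ggplot2 package", call. = FALSE)
  }
  df <- as.data.frame(summary)
  df$highlight <- ifelse(grepl("^sig", df$classification), "significant",
                         ifelse(grepl("^almost", df$classification),
                                "almost significant", "none"))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster))) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5,
                   color = .data$highlight), width = 0.2) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$q50, ymin = .data$q25, ymax = .data$q75,
                   color = .data$highlight), width = 0.6, fatten = 1.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~effect, ncol = 1) +
    ggplot2::scale_color_manual(values = c(
      significant = "red3", `almost significant` = "blue3", none = "grey40")) +
    ggplot2::labs(x = "lipid cluster", y = "effect (standardized units)",
                  color = NULL) +
    ggplot2::theme_minimal()
}
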