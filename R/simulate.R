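#' Configuration for the synthetic study generator
#'
#' Describes a synthetic fenofibrate/placebo HDL-lipidomics study drawn
#' exactly from the multi-way model's generative form: cluster-structured
#' lipids, additive latent treatment effects acting after treatment only,
#' per-patient offsets shared by a patient's before and after samples,
#' Gaussian residual noise, and the structurally missing high-Hcy placebo
#' cell.  Defaults reproduce the study's dimensions: 17 low-Hcy fenofibrate,
#' 16 high-Hcy fenofibrate and 14 placebo patients, 615 lipid peaks of which
#' 249 are identified.
#'
#' @param n_patients Integer vector of patients per group, in the order
#'   (feno_low_hcy, feno_high_hcy, placebo_low_hcy).
#' @param n_lipids Total number of lipid peaks D.
#' @param n_identified How many peaks carry parseable lipid names; the rest
#'   are unidentified peaks with retention times drawn uniformly from
#'   `[60, 840]` s.
#' @param n_clusters True number of lipid clusters K*.
#' @param beta_feno,beta_placebo,beta_interaction Numeric vectors of length
#'   `n_clusters`: true fenofibrate, placebo and fenofibrate-by-Hcy
#'   interaction effects per cluster (0 = no effect).
#' @param sigma_patient Patient-effect standard deviation (>= 0).
#' @param sigma_residual Residual standard deviation per lipid (scalar or
#'   length `n_lipids`).
#' @param mu Per-lipid grand mean on the latent (log-concentration) scale.
#' @param sigma_latent Latent-factor noise standard deviation.  The model
#'   fixes this at 1 for identifiability; the generator exposes it only so
#'   degenerate (noise-free) studies can be produced for checks.
#' @param loading_offset Loadings are drawn `|N(0,1)| + loading_offset` so
#'   every lipid loads positively on its cluster and "upregulated cluster"
#'   has an unambiguous sign.
#' @param placebo_has_baseline If `FALSE`, placebo patients have close-out
#'   samples only (the clinical-arm layout); if `TRUE` (default) they are
#'   sampled before and after like the fenofibrate arms.
#' @param seed Integer seed; the same seed reproduces the study bit-exactly.
#' @return A list of class `generator_config`.
#' @seealso [generate_study()], [generator_config_small()]
#' @export
generator_config <- function(n_patients = c(17, 16, 14),
                             n_lipids = 615,
                             n_identified = 249,
                             n_clusters = 25,
                             beta_feno = rep(0, n_clusters),
                             beta_placebo = rep(0, n_clusters),
                             beta_interaction = rep(0, n_clusters),
                             sigma_patient = 1,
                             sigma_residual = 0.5,
                             mu = 0,
                             sigma_latent = 1,
                             loading_offset = 0.5,
                             placebo_has_baseline = TRUE,
                             seed = 1L) {
  stopifnot(length(n_patients) == 3, all(n_patients >= 1),
            n_lipids >= 1, n_identified <= n_lipids,
            n_clusters >= 1, n_clusters <= n_lipids,
            length(beta_feno) == n_clusters,
            length(beta_placebo) == n_clusters,
            length(beta_interaction) == n_clusters,
            sigma_patient >= 0, all(sigma_residual >= 0), sigma_latent >= 0,
            loading_offset >= 0)
  structure(
    list(n_patients = as.integer(n_patients), n_lipids = as.integer(n_lipids),
         n_identified = as.integer(n_identified),
         n_clusters = as.integer(n_clusters),
         beta_feno = beta_feno, beta_placebo = beta_placebo,
         beta_interaction = beta_interaction,
         sigma_patient = sigma_patient,
         sigma_residual = rep_len(sigma_residual, n_lipids),
         sigma_latent = sigma_latent,
         mu = rep_len(mu, n_lipids),
         loading_offset = loading_offset,
         placebo_has_baseline = isTRUE(placebo_has_baseline),
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Scaled-down generator configuration for fast checks
#'
#' Same generative process as [generator_config()] at a size suitable for
#' unit tests and quick experiments: 60 lipids (40 identified), 5 true
#' clusters, 10 patients per group.
#'
#' @param ... Overrides passed on to [generator_config()].
#' @export
generator_config_small <- function(...) {
  args <- list(n_patients = c(10, 10, 10), n_lipids = 60, n_identified = 40,
               n_clusters = 5)
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}

# deterministic pool of plausible identified lipid labels
synthetic_lipid_labels <- function(n) {
  templates <- list(
    function(c2, db) sprintf("PC(%d:%d)", 30 + c2, db),
    function(c2, db) sprintf("TG(%d:%d)", 44 + c2, db),
    function(c2, db) sprintf("SM(d18:1/%d:%d)", 14 + c2, db %% 3),
    function(c2, db) sprintf("PE(P-16:0/%d:%d)", 18 + c2, db),
    function(c2, db) sprintf("LysoPC(%d:%d)", 14 + c2, db %% 4),
    function(c2, db) sprintf("ChoE(%d:%d)", 14 + c2, db %% 7),
    function(c2, db) sprintf("Cer(d18:1/%d:%d)", 16 + c2, db %% 2),
    function(c2, db) sprintf("PE(%d:%d)", 32 + c2, db),
    function(c2, db) sprintf("PC(%d:%de)", 30 + c2, db)
  )
  labs <- character(n)
  for (i in seq_len(n)) {
    f <- templates[[((i - 1) %% length(templates)) + 1]]
    labs[i] <- f(((i - 1) %/% length(templates)) * 2 %% 14,
                 ((i - 1) %/% length(templates)) %% 7)
  }
  make.unique(labs, sep = "_")
}

#' Generate a synthetic study with known ground truth
#'
#' Draws one complete study from the multi-way model's generative form.  For
#' patient j in cluster k, the latent trajectory is
#' `x_lat = alpha_pat[j,k] + f*beta_F[k] + p*beta_P[k] + i*beta_I[k] + eta`,
#' with `eta ~ N(0, 1)` and the design indicators of the sample's
#' (group, time) cell; the observed log-concentration of lipid d is
#' `mu_d + v_d * x_lat[z*_d] + eps`, `eps ~ N(0, sigma_residual_d^2)`.
#' Concentrations are stored as `exp()` of the Gaussian field, so values are
#' positive (lognormal) and [standardize()] with `log_z` recovers the
#' Gaussian field exactly.
#'
#' @param config A [generator_config()].
#' @return A list with elements `table` (a [peak_table()] of
#'   concentrations), `design` (a [sample_design()]), and `truth` (class
#'   `ground_truth`: `z` true cluster per lipid, `loadings`, `beta_feno`,
#'   `beta_placebo`, `beta_interaction`, `patient_effects` (patients x
#'   clusters), `sigma_residual`, `mu`, `latent` (clusters x samples), and
#'   the `config`).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  D <- config$n_lipids
  K <- config$n_clusters

  grp <- c("feno_low_hcy", "feno_high_hcy", "placebo_low_hcy")
  pats <- data.frame(
    patient_id = sprintf("P%02d", seq_len(sum(config$n_patients))),
    group = rep(grp, config$n_patients),
    stringsAsFactors = FALSE
  )
  times_of <- function(g) {
    if (g == "placebo_low_hcy" && !config$placebo_has_baseline) "after"
    else c("before", "after")
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(pats)), function(i) {
    tt <- times_of(pats$group[i])
    data.frame(sample_id = paste0(pats$patient_id[i], "_", tt),
               patient_id = pats$patient_id[i], group = pats$group[i],
               time = tt, stringsAsFactors = FALSE)
  }))
  design <- sample_design(rows$sample_id, rows$patient_id, rows$group,
                          rows$time)
  S <- nrow(design)

  # true parameters
  z <- rep_len(seq_len(K), D)           # balanced true partition
  v <- abs(stats::rnorm(D)) + config$loading_offset
  alpha <- matrix(stats::rnorm(nrow(pats) * K, sd = config$sigma_patient),
                  nrow(pats), K,
                  dimnames = list(pats$patient_id, NULL))
  beta <- cbind(f = config$beta_feno, p = config$beta_placebo,
                i = config$beta_interaction)

  dmat <- t(vapply(seq_len(S), function(s) {
    design_vector(design$group[s], design$time[s])[c("f", "p", "i")]
  }, numeric(3)))
  jidx <- match(design$patient_id, pats$patient_id)

  latent <- t(alpha[jidx, , drop = FALSE]) + beta %*% t(dmat)
  latent <- latent + matrix(stats::rnorm(K * S, sd = config$sigma_latent), K, S)
  colnames(latent) <- design$sample_id

  eps <- matrix(stats::rnorm(D * S, sd = config$sigma_residual), D, S)
  logx <- config$mu + v * latent[z, , drop = FALSE] + eps

  # names, identification and retention times
  ident <- seq_len(config$n_identified)
  labels <- character(D)
  labels[ident] <- synthetic_lipid_labels(config$n_identified)
  if (config$n_identified < D) {
    labels[-ident] <- sprintf("peak_%04d", seq_len(D - config$n_identified))
  }
  rt <- stats::runif(D, 60, 840)
  peak_ids <- sprintf("L%04d", seq_len(D))

  tab <- peak_table(exp(logx), peak_ids = peak_ids,
                    sample_ids = design$sample_id, names = labels,
                    retention_time = rt, unit = "concentration")

  truth <- structure(
    list(z = z, loadings = v, beta_feno = config$beta_feno,
         beta_placebo = config$beta_placebo,
         beta_interaction = config$beta_interaction,
         patient_effects = alpha, sigma_residual = config$sigma_residual,
         mu = config$mu, latent = latent, config = config),
    class = "ground_truth"
  )
  list(table = tab, design = design, truth = truth)
}

#' Synthetic clinical covariate fixture
#'
#' Draws per-patient clinical and biochemical variables (BMI, Hcy, total
#' cholesterol, HDL-C, triglycerides, apoA-I, apoA-II, apoA-I/apoA-II ratio,
#' HDL size, PLTP activity, PON-1 mass) from independent Gaussians whose
#' cell means and SDs match the study's group summary statistics, e.g.
#' high-Hcy close-out Hcy 27.4 (6.5) µmol/L.  This is a *synthetic* fixture
#' for exercising the one-factor-per-variable analysis; it reproduces
#' marginal cell summaries only, not between-variable correlations.
#'
#' @param n_patients Patients per group (feno_low, feno_high, placebo).
#' @param placebo_has_baseline Placebo arm sampled at close-out only when
#'   `FALSE` (default, the study layout).
#' @param seed Integer seed.
#' @return A data frame with columns `patient_id`, `group`, `time`, and one
#'   column per clinical variable.  Zero patients yields an empty table.
#' @export
clinical_covariate_fixture <- function(n_patients = c(17, 16, 14),
                                       placebo_has_baseline = FALSE,
                                       seed = 1L) {
  set.seed(seed)
  ref <- clinical_reference_table()
  grp <- c("feno_low_hcy", "feno_high_hcy", "placebo_low_hcy")
  out <- list()
  pid <- 0L
  for (g in seq_along(grp)) {
    times <- if (grp[g] == "placebo_low_hcy" && !placebo_has_baseline) {
      "after"
    } else c("before", "after")
    for (i in seq_len(n_patients[g])) {
      pid_chr <- sprintf("P%02d", pid + i)
      for (tm in times) {
        cell <- paste(grp[g], tm, sep = ".")
        vals <- stats::rnorm(nrow(ref), ref[[paste0(cell, ".mean")]],
                             ref[[paste0(cell, ".sd")]])
        row <- as.list(vals)
        names(row) <- ref$variable
        out[[length(out) + 1L]] <- c(list(patient_id = pid_chr,
                                          group = grp[g], time = tm), row)
      }
    }
    pid <- pid + n_patients[g]
  }
  if (!length(out)) {
    return(data.frame(patient_id = character(0), group = character(0),
                      time = character(0)))
  }
  do.call(rbind, lapply(out, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

# group-cell means (sd) of the clinical variables; placebo was sampled at
# close-out only, so its "before" cell reuses the close-out summaries when a
# baseline is requested.
clinical_reference_table <- function() {
  df <- data.frame(
    variable = c("bmi", "hcy", "total_cholesterol", "hdl_c", "triglycerides",
                 "apoa1", "apoa2", "apoa1_apoa2_ratio", "hdl_size", "pltp",
                 "pon1"),
    feno_low_hcy.before.mean  = c(29.5, 9.9, 5.2, 1.1, 1.6, 102, 24.3, 4.2, 9.1, 5700, 16.5),
    feno_low_hcy.before.sd    = c(5.8, 2.3, 0.5, 0.2, 0.7, 13.5, 3.5, 0.4, 2.7, 1649, 8.9),
    feno_low_hcy.after.mean   = c(29.5, 13.2, 4.6, 1.1, 1.4, 102.4, 29.9, 3.4, 9.0, 5985, 11.5),
    feno_low_hcy.after.sd     = c(4.2, 2.0, 0.9, 0.3, 0.8, 15.5, 6.5, 0.3, 3.4, 1917, 11.2),
    feno_high_hcy.before.mean = c(32.1, 13.0, 5.0, 1.1, 1.9, 103, 25.5, 4.1, 9.1, 6018, 16.3),
    feno_high_hcy.before.sd   = c(5.1, 3.0, 0.4, 0.2, 0.7, 13.3, 4.9, 0.6, 2.7, 1675, 5.7),
    feno_high_hcy.after.mean  = c(30.4, 27.4, 4.2, 1.0, 1.4, 106, 31.5, 3.3, 9.0, 5902, 18.5),
    feno_high_hcy.after.sd    = c(5.4, 6.5, 0.6, 0.2, 0.6, 22.6, 5.1, 0.5, 3.7, 1890, 6.0),
    placebo_low_hcy.after.mean = c(31.4, 13.3, 4.9, 1.2, 1.6, 102, 24.8, 4.1, 9.0, 7334, 24.9),
    placebo_low_hcy.after.sd   = c(5.9, 0.7, 0.4, 0.3, 0.6, 22.3, 5.2, 0.5, 6.2, 1683, 14.6),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  df[["placebo_low_hcy.before.mean"]] <- df[["placebo_low_hcy.after.mean"]]
  df[["placebo_low_hcy.before.sd"]] <- df[["placebo_low_hcy.after.sd"]]
  df
}

#' Write a generated study to disk
#'
#' Writes the peak table (CSV), design (CSV) and ground truth (JSON) of a
#' [generate_study()] result into a directory.
#'
#' @param study The list returned by [generate_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_peak_table(study$table, file.path(dir, "peaks.csv"))
  write_sample_design(study$design, file.path(dir, "design.csv"))
  truth <- study$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(unclass(truth), file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Convert a concentration table to synthetic raw intensities
#'
#' Produces the raw-intensity view of a generated study so the
#' internal-standard normalization step can be exercised end to end: each
#' sample receives a lognormal instrument-drift factor, standard rows with
#' known spiked concentrations are appended, and every lipid's intensity is
#' the drift-scaled ratio of its concentration to its standard's
#' concentration.  [normalize_peaks()] applied to the result recovers the
#' input concentrations (up to floating-point rounding) and is invariant to
#' the drift by construction.
#'
#' @param table A [peak_table()] with `unit = "concentration"`.
#' @param map A `standard_map` (spiked concentrations taken from it).
#' @param base_intensity Mean standard intensity (arbitrary MS counts).
#' @param drift_sd Log-scale SD of the per-sample drift factor.
#' @param seed Integer seed for the drift draws.
#' @return A [peak_table()] of raw intensities with the standard rows
#'   appended (peak ids `STD1` ...).
#' @export
as_raw_intensities <- function(table, map = default_standard_map(),
                               base_intensity = 1000, drift_sd = 0.3,
                               seed = 1L) {
  stopifnot(inherits(table, "peak_table"), table$unit == "concentration")
  set.seed(seed)
  S <- length(table$sample_ids)
  drift <- exp(stats::rnorm(S, 0, drift_sd))
  std <- map$standards
  std_int <- outer(rep(base_intensity, nrow(std)), drift)  # std x S
  rownames(std_int) <- std$standard_id
  assigned <- vapply(seq_len(nrow(table$values)), function(i) {
    assign_standard(table$peaks$parsed[[i]], map,
                    table$peaks$retention_time[i])
  }, character(1))
  conc_std <- std$concentration[match(assigned, std$standard_id)]
  raw <- table$values / conc_std * std_int[assigned, , drop = FALSE]
  # representative retention times per standard family
  std_rt <- c(monoacyl = 180, diacyl = 350, ceramide = 380,
              ethanolamine = 360, tg_sterol = 600)[std$rule]
  peak_table(
    rbind(raw, std_int),
    peak_ids = c(table$peaks$peak_id, sprintf("STD%d", seq_len(nrow(std)))),
    sample_ids = table$sample_ids,
    names = c(table$peaks$name, std$standard_id),
    retention_time = c(table$peaks$retention_time, unname(std_rt)),
    unit = "raw_intensity"
  )
}
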