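#' Held-out predictive likelihood
#'
#' Fits the multi-way model on the samples of the training patients and
#' scores the held-out patients with [heldout_log_density()]: each held-out
#' patient's samples are scored jointly, integrating the latent factors,
#' their noise and the unknown patient effect analytically (a new patient's
#' factor value has variance `s2_patient + 1` around its design effects and
#' covariance `s2_patient` between that patient's before and after samples).
#' The returned value is the mean log density per held-out patient.
#'
#' @param x Standardized lipid-by-sample matrix (or `scaled_matrix`)
#'   covering both training and test samples.
#' @param design A [sample_design()] for all samples.
#' @param test_patients Character vector of held-out patient ids; must be a
#'   non-empty proper subset of the design's patients.
#' @param config A [model_config()] used for the training fit.
#' @param n_draws Number of (evenly thinned) posterior draws to score with.
#' @return Scalar mean held-out log density per patient; the fitted training
#'   `posterior_samples` are attached as attribute `"fit"`.
#' @export
predictive_likelihood <- function(x, design, test_patients,
                                  config = model_config(), n_draws = 200) {
  if (inherits(x, "scaled_matrix")) x <- x$x
  all_pat <- unique(design$patient_id)
  test_patients <- unique(as.character(test_patients))
  if (length(test_patients) == 0L) stop("empty test set", call. = FALSE)
  if (!all(test_patients %in% all_pat)) {
    stop("unknown test patient(s): ",
         paste(setdiff(test_patients, all_pat), collapse = ", "),
         call. = FALSE)
  }
  train_patients <- setdiff(all_pat, test_patients)
  if (length(train_patients) == 0L) {
    stop("train and test sets must be disjoint and non-empty; ",
         "cannot hold out every patient", call. = FALSE)
  }
  in_test <- design$patient_id %in% test_patients
  train_design <- design[!in_test, ]
  class(train_design) <- class(design)
  test_design <- design[in_test, ]
  x_train <- x[, design$sample_id[!in_test], drop = FALSE]
  x_test <- x[, design$sample_id[in_test], drop = FALSE]
  fit <- fit_multiway(x_train, train_design, config)
  ll <- heldout_log_density(fit, x_test, test_design, n_draws = n_draws)
  structure(ll, fit = fit)
}

#' Score new samples under a fitted model
#'
#' Evaluates the log posterior predictive density of held-out samples.  A
#' held-out patient's before and after samples are scored *jointly*: the
#' shared patient effect induces a cross-sample covariance `s2_patient v v'`
#' within each cluster block on top of the per-sample
#' `Lambda + (s2_patient + 1) v v'`, and both are integrated analytically
#' with the Woodbury identity (the patient-sample pair is a rank-2 update of
#' the diagonal residual covariance).  Patients with a single sample reduce
#' to the marginal formula.  Per-draw densities are combined by
#' log-mean-exp.
#'
#' @param samples A `posterior_samples` with saved loadings and variances.
#' @param x_new Standardized matrix of new samples (same lipids, same order
#'   as the training data).
#' @param design_new Design rows for the new samples.
#' @param n_draws Number of evenly thinned draws.
#' @return Mean log predictive density per held-out patient; attribute
#'   `"per_patient"` holds the per-patient values, `"n_samples"` the number
#'   of scored samples.
#' @export
heldout_log_density <- function(samples, x_new, design_new, n_draws = 200) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (is.null(samples$v)) {
    stop("posterior samples were stored without loadings; ",
         "fit with save_loadings = TRUE", call. = FALSE)
  }
  n_avail <- nrow(samples$beta_f)
  use <- unique(round(seq(1, n_avail, length.out = min(n_draws, n_avail))))
  D <- ncol(samples$z)
  St <- ncol(x_new)
  K <- ncol(samples$beta_f)
  dmat_new <- t(vapply(seq_len(nrow(design_new)), function(s) {
    design_vector(design_new$group[s], design_new$time[s])[c("f", "p", "i")]
  }, numeric(3)))                                       # St x 3
  has_patient <- samples$config$patient_effects
  blocks <- split(seq_len(St), design_new$patient_id)
  ll_draws <- matrix(NA_real_, length(use), length(blocks))
  for (ii in seq_along(use)) {
    d <- use[ii]
    z <- samples$z[d, ]
    v <- samples$v[d, ]
    lam <- samples$lambda[d, ]
    beta <- cbind(samples$beta_f[d, ], samples$beta_p[d, ],
                  samples$beta_i[d, ])                  # K x 3
    s2p <- if (has_patient) samples$s2pat[d] else 0
    c1 <- s2p + 1                                       # same-sample factor var
    c0 <- s2p                                           # cross-sample (shared alpha)
    db <- beta %*% t(dmat_new)                          # K x St
    M <- v * db[z, , drop = FALSE]                      # D x St
    R <- x_new - M
    ind <- matrix(0, K, D)
    ind[cbind(z, seq_len(D))] <- 1
    Sk <- drop(ind %*% (v^2 / lam))
    Tm <- ind %*% (R * (v / lam))                       # K x St
    q1 <- colSums(R^2 / lam)
    sumloglam <- sum(log(lam))
    for (bi in seq_along(blocks)) {
      ss <- blocks[[bi]]
      if (length(ss) == 1L) {
        denom <- 1 + c1 * Sk
        ll <- -0.5 * (D * log(2 * pi) + sumloglam + sum(log(denom)) +
                        q1[ss] - sum(c1 * Tm[, ss]^2 / denom))
      } else {
        # joint density of the before/after pair (rank-2 Woodbury per cluster)
        t1 <- Tm[, ss[1]]
        t2 <- Tm[, ss[2]]
        det2 <- (1 + c1 * Sk)^2 - (c0 * Sk)^2
        dC <- c1^2 - c0^2                               # det of the 2x2 C
        a <- c1 / dC + Sk
        b <- -c0 / dC
        corr <- (a * (t1^2 + t2^2) - 2 * b * t1 * t2) / (a^2 - b^2)
        ll <- -0.5 * (2 * D * log(2 * pi) + 2 * sumloglam + sum(log(det2)) +
                        q1[ss[1]] + q1[ss[2]] - sum(corr))
      }
      ll_draws[ii, bi] <- ll
    }
  }
  # log-mean-exp over draws, per patient block
  mx <- apply(ll_draws, 2, max)
  lme <- mx + log(colMeans(exp(sweep(ll_draws, 2, mx, "-"))))
  structure(mean(lme), per_patient = lme, n_samples = St)
}

#' Choose the number of clusters by predictive likelihood
#'
#' Holds out a fraction of patients (stratified by group, deterministically
#' under the seed), fits the model for each candidate K on the training
#' patients, and scores the held-out samples.  Ties break toward smaller K:
#' because the held-out score plateaus once K reaches the number of clusters
#' the data support (extra clusters simply stay empty), near-ties are
#' resolved by the one-standard-error parsimony rule — the smallest K whose
#' mean held-out log density lies within one standard error (over test
#' samples) of the best candidate is selected.  The study selected its
#' cluster count from the range 20-25 this way.
#'
#' @param x Standardized matrix (or `scaled_matrix`).
#' @param design A [sample_design()].
#' @param grid Candidate cluster counts, default `20:25`.
#' @param config Base [model_config()]; its `K` is overridden per candidate.
#' @param test_fraction Fraction of patients per group to hold out.
#' @param n_draws Draws used to score (see [predictive_likelihood()]).
#' @return The selected K, with attribute `"scores"` (named numeric of mean
#'   held-out log densities per candidate).
#' @export
select_num_clusters <- function(x, design, grid = 20:25,
                                config = model_config(),
                                test_fraction = 0.25, n_draws = 200) {
  stopifnot(length(grid) >= 1, all(grid >= 1))
  grid <- sort(unique(as.integer(grid)))
  pat <- unique(design[c("patient_id", "group")])
  set.seed(config$seed)
  test_patients <- unlist(lapply(split(pat$patient_id, pat$group), function(p) {
    n_hold <- max(1L, floor(length(p) * test_fraction))
    sample(p, n_hold)
  }), use.names = FALSE)
  per_sample <- lapply(grid, function(K) {
    cfg <- config
    cfg$K <- as.integer(K)
    pl <- predictive_likelihood(x, design, test_patients, cfg,
                                n_draws = n_draws)
    attr(pl, "per_patient")
  })
  scores <- vapply(per_sample, mean, numeric(1))
  names(scores) <- grid
  best <- which.max(scores)
  se_best <- stats::sd(per_sample[[best]]) / sqrt(length(per_sample[[best]]))
  chosen <- min(grid[scores >= scores[best] - se_best])
  structure(chosen, scores = scores, se_best = se_best)
}
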