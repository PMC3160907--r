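#' Configuration of the multivariate multi-way model
#'
#' The model clusters lipids and estimates covariate effects simultaneously.
#' For lipid d in sample s (patient j at time t) the observed standardized
#' value is `x[d,s] = v_d * x_lat[z_d, s] + eps`, `eps ~ N(0, Lambda_d)`,
#' where `z_d` is the lipid's cluster and `v_d > 0` its loading (a projection
#' matrix with one nonzero entry per row).  The latent factor of cluster k is
#' `x_lat[k,s] = alpha_pat[j,k] + f*beta_F[k] + p*beta_P[k] + i*beta_I[k] +
#' eta`, `eta ~ N(0, 1)`, with the (group, time) design indicators of
#' [design_vector()]: before-treatment samples carry only the
#' patient-specific effect, after-treatment samples add the fenofibrate,
#' placebo, or fenofibrate-plus-interaction effect of their arm.  The
#' high-Hcy placebo cell does not exist.  All priors are conjugate:
#' `beta ~ N(0, effect_var)` per effect and cluster, loadings positive
#' half-Gaussian `N(0, loading_var)`, `Lambda_d ~ InvGamma(lambda_shape,
#' lambda_rate)`, patient effects `N(0, s2_patient)` with `s2_patient ~
#' InvGamma(s2pat_shape, s2pat_rate)`, cluster probabilities
#' `Dirichlet(dirichlet_alpha)`.  The latent noise variance is fixed at 1
#' and the data are standardized per lipid, so the grand mean is fixed at 0
#' in the sampler.
#'
#' @param K Requested number of clusters (some may end up empty).
#' @param n_burnin,n_samples Discarded and retained Gibbs sweeps.
#' @param dirichlet_alpha Dirichlet concentration for cluster probabilities.
#' @param effect_var Gaussian prior variance of the three effects.
#' @param loading_var Prior variance of the (positive) loadings.
#' @param lambda_shape,lambda_rate Inverse-gamma prior of residual variances.
#' @param s2pat_shape,s2pat_rate Inverse-gamma hyperprior of the
#'   patient-effect variance.
#' @param patient_effects Include the repeated-measures patient term
#'   (default `TRUE`); `FALSE` fits the no-patient-term variant used for
#'   predictive comparisons.
#' @param one_factor_per_variable Fix the partition to one cluster per
#'   variable (the clinical-covariate analysis); implies `K = D`.
#' @param init `"kmeans"` (deterministic seeded k-means partition) or
#'   `"random"`.
#' @param fix_loadings,fix_lambda,fix_s2pat Optional fixed values (scalar or
#'   per-lipid) that switch off the corresponding update; used for reduced
#'   conjugate checks.
#' @param save_loadings Keep per-draw loadings and residual variances in the
#'   output (default `TRUE`).
#' @param progress_every Print the joint log density every this many sweeps
#'   (0 = silent).
#' @param seed Integer seed controlling the whole chain.
#' @return A list of class `model_config`.
#' @export
model_config <- function(K = 25, n_burnin = 2000, n_samples = 2000,
                         dirichlet_alpha = 1, effect_var = 100,
                         loading_var = 1, lambda_shape = 2, lambda_rate = 1,
                         s2pat_shape = 2, s2pat_rate = 1,
                         patient_effects = TRUE,
                         one_factor_per_variable = FALSE,
                         init = c("kmeans", "random"),
                         fix_loadings = NULL, fix_lambda = NULL,
                         fix_s2pat = NULL, save_loadings = TRUE,
                         progress_every = 0, seed = 1L) {
  init <- match.arg(init)
  stopifnot(K >= 1, n_burnin >= 0, n_samples >= 1, dirichlet_alpha > 0,
            effect_var > 0, loading_var > 0, lambda_shape > 0,
            lambda_rate > 0, s2pat_shape > 0, s2pat_rate > 0)
  structure(
    list(K = as.integer(K), n_burnin = as.integer(n_burnin),
         n_samples = as.integer(n_samples),
         dirichlet_alpha = dirichlet_alpha, effect_var = effect_var,
         loading_var = loading_var, lambda_shape = lambda_shape,
         lambda_rate = lambda_rate, s2pat_shape = s2pat_shape,
         s2pat_rate = s2pat_rate,
         patient_effects = isTRUE(patient_effects),
         one_factor_per_variable = isTRUE(one_factor_per_variable),
         init = init, fix_loadings = fix_loadings, fix_lambda = fix_lambda,
         fix_s2pat = fix_s2pat, save_loadings = isTRUE(save_loadings),
         progress_every = as.integer(progress_every), seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Design indicators for one (group, time) cell
#'
#' Returns the indicator coefficients of the linear predictor of a sample's
#' latent factor: the patient effect is always active; before-treatment
#' samples carry no treatment term; after-treatment samples activate the
#' fenofibrate effect (both fenofibrate arms), the placebo effect (placebo
#' arm) or additionally the fenofibrate-by-Hcy interaction (high-Hcy arm).
#' The high-Hcy placebo cell is unrepresentable.
#'
#' @param group One of `"feno_low_hcy"`, `"feno_high_hcy"`,
#'   `"placebo_low_hcy"`.
#' @param time `"before"` or `"after"`.
#' @return Named numeric vector `c(patient = 1, f, p, i)`.
#' @examples
#' design_vector("feno_high_hcy", "after")   # f = 1, p = 0, i = 1
#' design_vector("placebo_low_hcy", "after") # f = 0, p = 1, i = 0
#' design_vector("feno_low_hcy", "before")   # patient effect only
#' @export
design_vector <- function(group, time) {
  group <- match.arg(group,
                     c("feno_low_hcy", "feno_high_hcy", "placebo_low_hcy"))
  time <- match.arg(time, c("before", "after"))
  if (time == "before") return(c(patient = 1, f = 0, p = 0, i = 0))
  switch(group,
    feno_low_hcy = c(patient = 1, f = 1, p = 0, i = 0),
    feno_high_hcy = c(patient = 1, f = 1, p = 0, i = 1),
    placebo_low_hcy = c(patient = 1, f = 0, p = 1, i = 0)
  )
}

#' Prepare data and design for the sampler
#'
#' Packs the standardized lipid-by-sample matrix with the per-sample design
#' indicators and patient index into the working object the update functions
#' share.  Called automatically by [fit_multiway()]; exposed for use with the
#' individual update functions.
#'
#' @param x A numeric matrix (lipids x samples, standardized per lipid), or
#'   a `scaled_matrix` from [standardize()].
#' @param design A [sample_design()] covering the matrix columns.
#' @return A list of class `model_data`.
#' @export
prepare_model_data <- function(x, design) {
  if (inherits(x, "scaled_matrix")) x <- x$x
  x <- as.matrix(x)
  stopifnot(inherits(design, "sample_design"))
  sid <- colnames(x)
  if (is.null(sid)) {
    stopifnot(ncol(x) == nrow(design))
    sid <- design$sample_id
    colnames(x) <- sid
  }
  idx <- match(sid, design$sample_id)
  if (anyNA(idx)) {
    stop("sample(s) not in design: ",
         paste(utils::head(sid[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  des <- design[idx, ]
  dmat <- t(vapply(seq_len(nrow(des)), function(s) {
    design_vector(des$group[s], des$time[s])[c("f", "p", "i")]
  }, numeric(3)))
  patients <- unique(des$patient_id)
  jidx <- match(des$patient_id, patients)
  structure(
    list(x = x, D = nrow(x), S = ncol(x), dmat = dmat, jidx = jidx,
         patients = patients, P = length(patients),
         n_per_patient = tabulate(jidx, length(patients)),
         design = des, peak_ids = rownames(x)),
    class = "model_data"
  )
}

#' Initialize a Gibbs state
#'
#' Cluster assignments come from a seeded k-means partition of the lipid
#' profiles (or a random multinomial), loadings start at +1, residual and
#' patient-effect variances at 1, all effects at 0, and the latent factors at
#' their cluster mean profiles.
#'
#' @param data A `model_data` (or matrix plus `design`).
#' @param design A [sample_design()] when `data` is a plain matrix.
#' @param config A [model_config()].
#' @return A list of class `model_state`.
#' @export
init_state <- function(data, design = NULL, config = model_config()) {
  md <- if (inherits(data, "model_data")) data else prepare_model_data(data, design)
  K <- config$K
  D <- md$D
  if (config$one_factor_per_variable) K <- D
  if (K > D) stop("K = ", K, " exceeds the number of lipids (", D, ")",
                  call. = FALSE)
  z <- if (config$one_factor_per_variable) {
    seq_len(D)
  } else if (K == 1L) {
    rep(1L, D)
  } else if (config$init == "kmeans") {
    km <- tryCatch(stats::kmeans(md$x, centers = K, nstart = 10,
                                 iter.max = 50),
                   error = function(e) NULL)
    if (is.null(km)) sample.int(K, D, replace = TRUE) else km$cluster
  } else {
    sample.int(K, D, replace = TRUE)
  }
  xlat <- matrix(0, K, md$S)
  for (k in seq_len(K)) {
    rows <- which(z == k)
    if (length(rows)) xlat[k, ] <- colMeans(md$x[rows, , drop = FALSE])
  }
  state <- list(
    z = as.integer(z),
    v = if (is.null(config$fix_loadings)) rep(1, D)
        else rep_len(config$fix_loadings, D),
    lambda = if (is.null(config$fix_lambda)) rep(1, D)
             else rep_len(config$fix_lambda, D),
    pi = rep(1 / K, K),
    xlat = xlat,
    alpha = matrix(0, md$P, K),
    beta = matrix(0, K, 3, dimnames = list(NULL, c("f", "p", "i"))),
    s2pat = if (is.null(config$fix_s2pat)) 1 else config$fix_s2pat,
    K = K
  )
  class(state) <- "model_state"
  state
}

# positive-truncated normal draws; tail-robust via inverse-cdf on the
# upper tail probability
rtnorm_pos <- function(n, mean, sd) {
  p_neg <- stats::pnorm(0, mean, sd)
  u <- stats::runif(n)
  out <- stats::qnorm(p_neg + u * (1 - p_neg), mean, sd)
  bad <- !is.finite(out) | out <= 0
  if (any(bad)) {
    # deep negative mean: exponential proposal at the truncation point
    # (Robert 1995), applied only to the offending entries
    for (ii in which(bad)) {
      a <- -mean[ii] / sd[ii]
      lam <- (a + sqrt(a^2 + 4)) / 2
      repeat {
        e <- stats::rexp(1, lam) + a
        if (stats::runif(1) <= exp(-(e - lam)^2 / 2)) break
      }
      out[ii] <- mean[ii] + sd[ii] * e
    }
  }
  out
}

#' Gibbs updates of the multi-way model
#'
#' Each function draws one block from its full conditional given the rest of
#' the state: cluster assignments `z` (categorical, proportional to the
#' cluster probability times the Gaussian likelihood of the lipid's profile
#' under each factor trajectory) together with the Dirichlet cluster
#' probabilities; loadings (positive-truncated Gaussian) and residual
#' variances (inverse gamma); latent factors (Gaussian, pooling the prior
#' trajectory with the loaded lipid profiles); patient effects (Gaussian
#' shrinkage pooling a patient's before/after latent residuals) and their
#' variance (inverse gamma); and the three effects (joint trivariate
#' Gaussian per cluster, the placebo effect informed only by placebo
#' after-treatment samples and the interaction only by high-Hcy
#' after-treatment samples, through the design indicators).
#'
#' Randomness comes from the R session RNG; seed it (or use
#' [fit_multiway()], which seeds from its config) for reproducible chains.
#'
#' @param state A `model_state`.
#' @param data A `model_data` from [prepare_model_data()].
#' @param config A [model_config()].
#' @return The updated `model_state`.
#' @name gibbs_updates
NULL

#' @rdname gibbs_updates
#' @export
update_cluster_assignments <- function(state, data, config = model_config()) {
  if (config$one_factor_per_variable || state$K == 1L) return(state)
  K <- state$K
  cross <- data$x %*% t(state$xlat)                    # D x K
  fk <- rowSums(state$xlat^2)                          # K
  w <- state$v / state$lambda
  ll <- w * cross - 0.5 * outer(state$v^2 / state$lambda, fk)
  ll <- sweep(ll, 2, log(state$pi), "+")
  ll <- ll - apply(ll, 1, max)
  p <- exp(ll)
  cs <- p
  for (k in seq_len(K)[-1]) cs[, k] <- cs[, k - 1] + p[, k]
  u <- stats::runif(data$D) * cs[, K]
  state$z <- as.integer(rowSums(cs < u) + 1L)
  state
}

update_cluster_probs <- function(state, data, config = model_config()) {
  if (config$one_factor_per_variable) return(state)
  counts <- tabulate(state$z, state$K)
  g <- stats::rgamma(state$K, shape = config$dirichlet_alpha + counts, rate = 1)
  state$pi <- g / sum(g)
  state
}

#' @rdname gibbs_updates
#' @export
update_loadings_and_variances <- function(state, data, config = model_config()) {
  G <- state$xlat[state$z, , drop = FALSE]             # D x S
  if (is.null(config$fix_loadings)) {
    a <- rowSums(G * G)
    b <- rowSums(G * data$x)
    prec <- 1 / config$loading_var + a / state$lambda
    mu <- (b / state$lambda) / prec
    state$v <- rtnorm_pos(data$D, mu, 1 / sqrt(prec))
  }
  if (is.null(config$fix_lambda)) {
    resid <- data$x - state$v * G
    state$lambda <- 1 / stats::rgamma(
      data$D, shape = config$lambda_shape + data$S / 2,
      rate = config$lambda_rate + rowSums(resid^2) / 2)
  }
  state
}

# conditional moments of the latent factors (exported through
# latent_conditional_moments for property checks)
latent_moments <- function(state, data) {
  K <- state$K
  ind <- matrix(0, K, data$D)
  ind[cbind(state$z, seq_len(data$D))] <- 1
  pk <- drop(ind %*% (state$v^2 / state$lambda))       # K
  contrib <- ind %*% (data$x * (state$v / state$lambda))  # K x S
  prior_mean <- t(state$alpha[data$jidx, , drop = FALSE]) +
    state$beta %*% t(data$dmat)                        # K x S
  prec <- 1 + pk
  list(mean = (prior_mean + contrib) / prec, prec = prec)
}

#' Conditional moments of the latent factors
#'
#' The Gaussian full-conditional mean and precision each latent factor value
#' is drawn from in [update_latent_factors()]; mainly for diagnostics and
#' invariance checks.
#'
#' @inheritParams gibbs_updates
#' @return List with `mean` (clusters x samples) and `prec` (per cluster).
#' @export
latent_conditional_moments <- function(state, data) latent_moments(state, data)

#' @rdname gibbs_updates
#' @export
update_latent_factors <- function(state, data, config = model_config()) {
  m <- latent_moments(state, data)
  K <- state$K
  state$xlat <- m$mean +
    matrix(stats::rnorm(K * data$S), K, data$S) / sqrt(m$prec)
  state
}

#' @rdname gibbs_updates
#' @export
update_patient_effects <- function(state, data, config = model_config()) {
  if (!config$patient_effects) return(state)
  K <- state$K
  deff <- state$beta %*% t(data$dmat)                  # K x S
  E <- state$xlat - deff                               # K x S
  pind <- matrix(0, data$S, data$P)
  pind[cbind(seq_len(data$S), data$jidx)] <- 1
  sums <- t(E %*% pind)                                # P x K
  prec <- data$n_per_patient + 1 / state$s2pat         # latent noise var 1
  state$alpha <- sums / prec +
    matrix(stats::rnorm(data$P * K), data$P, K) / sqrt(prec)
  state
}

#' @rdname gibbs_updates
#' @export
update_patient_variance <- function(state, data, config = model_config()) {
  if (!config$patient_effects || !is.null(config$fix_s2pat)) return(state)
  n <- length(state$alpha)
  state$s2pat <- 1 / stats::rgamma(
    1, shape = config$s2pat_shape + n / 2,
    rate = config$s2pat_rate + sum(state$alpha^2) / 2)
  state
}

#' @rdname gibbs_updates
#' @export
update_effects <- function(state, data, config = model_config()) {
  A <- crossprod(data$dmat) + diag(1 / config$effect_var, 3)
  U <- chol(A)
  E <- state$xlat - t(state$alpha[data$jidx, , drop = FALSE])  # K x S
  B <- E %*% data$dmat                                 # K x 3
  mean_beta <- B %*% chol2inv(U)
  K <- state$K
  noise <- backsolve(U, matrix(stats::rnorm(3 * K), 3, K))
  state$beta <- mean_beta + t(noise)
  colnames(state$beta) <- c("f", "p", "i")
  state
}

#' One full Gibbs sweep
#'
#' Applies all updates in the fixed documented order: cluster assignments,
#' (loadings, residual variances), latent factors, patient effects,
#' patient-effect variance, effects, cluster probabilities.  A fixed order
#' makes chains reproducible under a seed.
#'
#' @inheritParams gibbs_updates
#' @return The updated `model_state`.
#' @export
gibbs_sweep <- function(state, data, config = model_config()) {
  state <- update_cluster_assignments(state, data, config)
  state <- update_loadings_and_variances(state, data, config)
  state <- update_latent_factors(state, data, config)
  state <- update_patient_effects(state, data, config)
  state <- update_patient_variance(state, data, config)
  state <- update_effects(state, data, config)
  update_cluster_probs(state, data, config)
}

#' Joint log density of a state
#'
#' Unnormalized log posterior density (likelihood times all priors) of a
#' `model_state`; used for progress logging, selecting the
#' maximum-a-posteriori draw, and label-permutation checks.
#'
#' @inheritParams gibbs_updates
#' @return A scalar.
#' @export
log_joint <- function(state, data, config = model_config()) {
  G <- state$xlat[state$z, , drop = FALSE]
  ll <- sum(stats::dnorm(data$x, state$v * G, sqrt(state$lambda), log = TRUE))
  prior_mean <- t(state$alpha[data$jidx, , drop = FALSE]) +
    state$beta %*% t(data$dmat)
  ll <- ll + sum(stats::dnorm(state$xlat, prior_mean, 1, log = TRUE))
  if (config$patient_effects) {
    ll <- ll + sum(stats::dnorm(state$alpha, 0, sqrt(state$s2pat), log = TRUE))
    ll <- ll + dinvgamma_log(state$s2pat, config$s2pat_shape, config$s2pat_rate)
  }
  ll <- ll + sum(stats::dnorm(state$beta, 0, sqrt(config$effect_var),
                              log = TRUE))
  ll <- ll + sum(stats::dnorm(state$v, 0, sqrt(config$loading_var),
                              log = TRUE) + log(2))  # positive half-normal
  ll <- ll + sum(dinvgamma_log(state$lambda, config$lambda_shape,
                               config$lambda_rate))
  ll <- ll + sum(log(state$pi[state$z]))
  ll + sum((config$dirichlet_alpha - 1) * log(state$pi))
}

dinvgamma_log <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

#' Fit the multivariate multi-way model by Gibbs sampling
#'
#' Runs `n_burnin` discarded plus `n_samples` retained sweeps of
#' [gibbs_sweep()] from [init_state()], seeded from the configuration so the
#' chain is bit-reproducible.  The study defaults are 2000 burn-in and 2000
#' retained samples.
#'
#' @param x Standardized lipid-by-sample matrix (or `scaled_matrix`, or a
#'   prepared `model_data`).
#' @param design A [sample_design()] (ignored when `x` is a `model_data`).
#' @param config A [model_config()].
#' @return An object of class `posterior_samples`: a list with matrices
#'   `beta_f`, `beta_p`, `beta_i` (draws x clusters), `z` (draws x lipids),
#'   optional `v` and `lambda`, vectors `s2pat` and `log_joint`, the
#'   index `map_draw` of the highest-log-density retained draw, and the
#'   echoed `config`, `peak_ids` and `design`.
#' @export
fit_multiway <- function(x, design = NULL, config = model_config()) {
  md <- if (inherits(x, "model_data")) x else prepare_model_data(x, design)
  set.seed(config$seed)
  state <- init_state(md, config = config)
  K <- state$K
  n <- config$n_samples
  out <- list(
    beta_f = matrix(NA_real_, n, K), beta_p = matrix(NA_real_, n, K),
    beta_i = matrix(NA_real_, n, K),
    z = matrix(NA_integer_, n, md$D),
    v = if (config$save_loadings) matrix(NA_real_, n, md$D),
    lambda = if (config$save_loadings) matrix(NA_real_, n, md$D),
    s2pat = numeric(n), log_joint = numeric(n)
  )
  total <- config$n_burnin + n
  for (it in seq_len(total)) {
    state <- gibbs_sweep(state, md, config)
    if (config$progress_every > 0 && it %% config$progress_every == 0) {
      message(sprintf("sweep %d/%d  log joint %.2f", it, total,
                      log_joint(state, md, config)))
    }
    if (it > config$n_burnin) {
      i <- it - config$n_burnin
      if (!all(is.finite(state$beta)) || !all(is.finite(state$xlat))) {
        stop("non-finite values in sweep ", it,
             "; state: ", paste(utils::capture.output(utils::str(
               state[c("s2pat", "pi")])), collapse = " "), call. = FALSE)
      }
      out$beta_f[i, ] <- state$beta[, "f"]
      out$beta_p[i, ] <- state$beta[, "p"]
      out$beta_i[i, ] <- state$beta[, "i"]
      out$z[i, ] <- state$z
      if (config$save_loadings) {
        out$v[i, ] <- state$v
        out$lambda[i, ] <- state$lambda
      }
      out$s2pat[i] <- state$s2pat
      out$log_joint[i] <- log_joint(state, md, config)
    }
  }
  out$map_draw <- which.max(out$log_joint)
  out$config <- config
  out$peak_ids <- md$peak_ids
  out$design <- md$design
  out$final_state <- state
  class(out) <- "posterior_samples"
  out
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("<posterior_samples> ", nrow(x$beta_f), " draws, ",
      ncol(x$beta_f), " clusters, ", ncol(x$z), " lipids (",
      count_nonempty(x), " non-empty clusters at the MAP draw)\n", sep = "")
  invisible(x)
}
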