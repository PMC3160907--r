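test_that("design vectors encode the six cells and the missing cell", {
  expect_equal(design_vector("feno_low_hcy", "before"),
               c(patient = 1, f = 0, p = 0, i = 0))
  expect_equal(design_vector("feno_high_hcy", "before"),
               c(patient = 1, f = 0, p = 0, i = 0))
  expect_equal(design_vector("placebo_low_hcy", "before"),
               c(patient = 1, f = 0, p = 0, i = 0))
  expect_equal(design_vector("feno_low_hcy", "after"),
               c(patient = 1, f = 1, p = 0, i = 0))
  expect_equal(design_vector("feno_high_hcy", "after"),
               c(patient = 1, f = 1, p = 0, i = 1))
  expect_equal(design_vector("placebo_low_hcy", "after"),
               c(patient = 1, f = 0, p = 1, i = 0))
  # the high-Hcy placebo cell is unrepresentable
  expect_error(design_vector("placebo_high_hcy", "after"))
  # invariant: i = 1 only with f = 1; p = 1 only with f = 0
  for (g in c("feno_low_hcy", "feno_high_hcy", "placebo_low_hcy")) {
    for (tm in c("before", "after")) {
      d <- design_vector(g, tm)
      if (d["i"] == 1) expect_equal(unname(d["f"]), 1)
      if (d["p"] == 1) expect_equal(unname(d["f"]), 0)
    }
  }
})

test_that("initial states are valid, deterministic, and respect K", {
  st <- generate_study(generator_config_small(seed = 8))
  sc <- standardize(st$table, design = st$design, center = "before")
  md <- prepare_model_data(sc, st$design)
  cfg <- model_config(K = 5, seed = 3)
  set.seed(3); s1 <- init_state(md, config = cfg)
  set.seed(3); s2 <- init_state(md, config = cfg)
  expect_identical(s1, s2)
  expect_true(all(s1$z %in% 1:5))
  expect_equal(length(unique(init_state(md, config = model_config(K = 1))$z)), 1)
  expect_error(init_state(md, config = model_config(K = 100)), "exceeds")
})

test_that("latent factor conditionals match the normal-normal posterior", {
  # single lipid per cluster, loading 1, known residual variance, flat state
  des <- toy_design(c(2, 2, 2))
  set.seed(5)
  x <- matrix(rnorm(2 * nrow(des)), 2, nrow(des),
              dimnames = list(c("l1", "l2"), des$sample_id))
  md <- prepare_model_data(x, des)
  cfg <- model_config(K = 2, fix_loadings = 1, fix_lambda = 0.5)
  state <- init_state(md, config = cfg)
  state$z <- c(1L, 2L)
  state$alpha[] <- 0.3
  state$beta[] <- 0.2
  m <- latent_conditional_moments(state, md)
  # closed form: prec = 1 + 1/lambda; mean = (prior + x/lambda)/prec
  prior <- t(state$alpha[md$jidx, ]) + state$beta %*% t(md$dmat)
  expect_equal(m$prec, rep(1 + 1 / 0.5, 2))
  expect_equal(m$mean, (prior + x / 0.5) / (1 + 1 / 0.5), ignore_attr = TRUE)

  # residual variance -> infinity: conditional mean -> prior mean
  state$lambda <- rep(1e12, 2)
  m2 <- latent_conditional_moments(state, md)
  expect_equal(m2$mean, prior, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("latent conditional moments are equivariant to sample order", {
  st <- generate_study(generator_config_small(n_patients = c(3, 3, 3),
                                              n_lipids = 12, n_identified = 6,
                                              n_clusters = 2, seed = 21))
  sc <- standardize(st$table, design = st$design, center = "before")
  md <- prepare_model_data(sc, st$design)
  cfg <- model_config(K = 2, seed = 1)
  set.seed(1)
  state <- init_state(md, config = cfg)
  m <- latent_conditional_moments(state, md)
  perm <- rev(seq_len(md$S))
  md_perm <- prepare_model_data(sc$x[, perm], st$design)
  m_perm <- latent_conditional_moments(state, md_perm)
  expect_equal(m_perm$mean, m$mean[, perm])
  expect_equal(m_perm$prec, m$prec)
})

test_that("effects revert to the prior without after-treatment samples", {
  grp <- rep(c("feno_low_hcy", "feno_high_hcy", "placebo_low_hcy"), 2)
  pid <- sprintf("P%d", 1:6)
  des <- sample_design(paste0(pid, "_before"), pid, grp, rep("before", 6))
  set.seed(2)
  x <- matrix(rnorm(4 * 6), 4, 6, dimnames = list(paste0("l", 1:4),
                                                  des$sample_id))
  md <- prepare_model_data(x, des)
  cfg <- model_config(K = 2, effect_var = 100, seed = 1)
  state <- init_state(md, config = cfg)
  set.seed(9)
  draws <- replicate(4000, update_effects(state, md, cfg)$beta[1, "f"])
  expect_lt(abs(mean(draws)), 3 * 10 / sqrt(4000))
  expect_lt(abs(sd(draws) - 10), 0.5)
})

test_that("placebo effect draws depend only on placebo after-treatment data", {
  st <- generate_study(generator_config_small(n_patients = c(3, 3, 3),
                                              n_lipids = 10, n_identified = 5,
                                              n_clusters = 2, seed = 14))
  sc <- standardize(st$table, design = st$design, center = "before")
  md <- prepare_model_data(sc, st$design)
  cfg <- model_config(K = 2, seed = 1)
  set.seed(1)
  state <- init_state(md, config = cfg)
  state <- update_latent_factors(state, md, cfg)
  # perturb latent factors of all fenofibrate samples
  state2 <- state
  feno <- md$design$group != "placebo_low_hcy"
  state2$xlat[, feno] <- state2$xlat[, feno] + 5
  set.seed(7); b1 <- update_effects(state, md, cfg)$beta
  set.seed(7); b2 <- update_effects(state2, md, cfg)$beta
  expect_equal(b1[, "p"], b2[, "p"])
  expect_false(isTRUE(all.equal(b1[, "f"], b2[, "f"])))

  # interaction given the fenofibrate effect depends only on high-Hcy
  # after-treatment residuals: its conditional row of the joint precision
  # has no placebo or feno-low support
  A <- crossprod(md$dmat) + diag(1 / cfg$effect_var, 3)
  n_high_after <- sum(md$design$group == "feno_high_hcy" &
                        md$design$time == "after")
  expect_equal(A[3, 3], n_high_after + 1 / cfg$effect_var)
  expect_equal(A[3, 1], n_high_after)  # couples only through beta_F
  expect_equal(A[3, 2], 0)             # never through beta_P
})

test_that("effect recovery: a strong fenofibrate effect is found with its sign", {
  st <- generate_study(generator_config_small(
    n_patients = c(20, 20, 20), n_lipids = 20, n_identified = 10,
    n_clusters = 2, beta_feno = c(2, 0), sigma_patient = 0.5,
    sigma_residual = 0.3, seed = 17))
  sc <- standardize(st$table, design = st$design, center = "before")
  fit <- fit_multiway(sc, st$design,
                      model_config(K = 2, n_burnin = 300, n_samples = 300,
                                   seed = 2))
  fit <- align_to_map(fit)
  truth_of <- match_to_truth(map_partition(fit), st$truth$z)
  k_hit <- which(truth_of == 1)[1]
  draws <- fit$beta_f[, k_hit]
  # the realized latent contrast itself fluctuates around the true effect
  # with variance ~ 2/n_patients (shared cluster-level noise), so allow for
  # both posterior and generator dispersion
  gen_sd <- sqrt(2 / 20)
  expect_lt(abs(mean(draws) - 2), 3 * sqrt(sd(draws)^2 + gen_sd^2))
  expect_gt(quantile(draws, 0.025), 0)
})

test_that("patient-effect conditionals shrink as the closed form dictates", {
  des <- toy_design(c(2, 2, 2))
  x <- matrix(0, 1, nrow(des), dimnames = list("l1", des$sample_id))
  md <- prepare_model_data(x, des)
  cfg <- model_config(K = 1, fix_s2pat = 0.8, seed = 1)
  state <- init_state(md, config = cfg)
  state$beta[] <- 0
  r <- 1.7  # identical latent residual at both time points
  state$xlat[1, ] <- r
  set.seed(11)
  draws <- replicate(4000, update_patient_effects(state, md, cfg)$alpha[1, 1])
  # posterior: prec = 2/1 + 1/s2pat, mean = 2 r / prec
  prec <- 2 + 1 / 0.8
  expect_lt(abs(mean(draws) - 2 * r / prec), 3 * (1 / sqrt(prec)) / sqrt(4000))
  expect_lt(abs(sd(draws) - 1 / sqrt(prec)), 0.02)

  # a patient with a single (after-only) sample still gets a proper,
  # more strongly shrunk conditional
  des1 <- toy_design(c(2, 2, 2), placebo_baseline = FALSE)
  x1 <- matrix(0, 1, nrow(des1), dimnames = list("l1", des1$sample_id))
  md1 <- prepare_model_data(x1, des1)
  state1 <- init_state(md1, config = cfg)
  state1$xlat[1, ] <- r
  placebo_j <- which(md1$n_per_patient == 1)[1]
  set.seed(12)
  d1 <- replicate(4000, update_patient_effects(state1, md1, cfg)$alpha[placebo_j, 1])
  prec1 <- 1 + 1 / 0.8
  expect_lt(abs(mean(d1) - r / prec1), 3 * (1 / sqrt(prec1)) / sqrt(4000))
  expect_lt(abs(mean(d1)), abs(2 * r / prec))  # stronger shrinkage
})

test_that("patient variance concentrates low when no patient effect exists", {
  st <- generate_study(generator_config_small(sigma_patient = 0, seed = 23))
  sc <- standardize(st$table, design = st$design, center = "before")
  fit <- fit_multiway(sc, st$design,
                      model_config(K = 5, n_burnin = 200, n_samples = 200,
                                   seed = 3))
  # posterior mean of s2pat stays near the prior's lower range, far below
  # the sigma_pat = 1 regime
  expect_lt(mean(fit$s2pat), 0.3)
})

test_that("identical lipid profiles get exchangeable cluster assignments", {
  des <- toy_design(c(2, 2, 2))
  set.seed(6)
  base <- rnorm(nrow(des))
  x <- rbind(l1 = base, l2 = base, l3 = -base + rnorm(nrow(des), sd = 0.1))
  colnames(x) <- des$sample_id
  md <- prepare_model_data(x, des)
  cfg <- model_config(K = 3, seed = 1)
  set.seed(1)
  state <- init_state(md, config = cfg)
  state <- update_latent_factors(state, md, cfg)
  freq <- matrix(0, 2, 3)
  for (i in 1:600) {
    z <- update_cluster_assignments(state, md, cfg)$z
    freq[1, z[1]] <- freq[1, z[1]] + 1
    freq[2, z[2]] <- freq[2, z[2]] + 1
  }
  # identical profiles => identical conditional distributions (within MC noise)
  p1 <- freq[1, ] / 600
  p2 <- freq[2, ] / 600
  expect_lt(max(abs(p1 - p2)), 0.07)
})

test_that("two well-separated blocks are recovered as the mode partition", {
  st <- generate_study(generator_config_small(
    n_lipids = 20, n_identified = 10, n_clusters = 2,
    n_patients = c(5, 5, 5), sigma_residual = 0.2, seed = 19))
  sc <- standardize(st$table, design = st$design, center = "before")
  fit <- fit_multiway(sc, st$design,
                      model_config(K = 2, n_burnin = 200, n_samples = 200,
                                   seed = 4))
  ari <- mclust::adjustedRandIndex(map_partition(fit), st$truth$z)
  expect_equal(ari, 1)
  # K = 1 assignment is a no-op
  md <- prepare_model_data(sc, st$design)
  cfg1 <- model_config(K = 1)
  s1 <- init_state(md, config = cfg1)
  expect_identical(update_cluster_assignments(s1, md, cfg1)$z, s1$z)
})

test_that("a sweep preserves all state invariants", {
  st <- generate_study(generator_config_small(seed = 25))
  sc <- standardize(st$table, design = st$design, center = "before")
  md <- prepare_model_data(sc, st$design)
  cfg <- model_config(K = 5, seed = 2)
  set.seed(2)
  state <- init_state(md, config = cfg)
  for (i in 1:5) {
    state <- gibbs_sweep(state, md, cfg)
    expect_true(all(state$z %in% seq_len(5)))
    expect_true(all(state$lambda > 0))
    expect_true(all(state$v > 0))
    expect_gt(state$s2pat, 0)
    expect_equal(sum(state$pi), 1)
    expect_equal(dim(state$alpha), c(md$P, 5))
  }
})

test_that("the joint log density is invariant to cluster relabeling", {
  st <- generate_study(generator_config_small(seed = 26))
  sc <- standardize(st$table, design = st$design, center = "before")
  md <- prepare_model_data(sc, st$design)
  cfg <- model_config(K = 5, seed = 2)
  set.seed(2)
  state <- init_state(md, config = cfg)
  state <- gibbs_sweep(state, md, cfg)
  ll <- log_joint(state, md, cfg)
  # new label perm[k] holds old cluster k; reorder all cluster-indexed blocks
  perm <- c(3L, 1L, 5L, 2L, 4L)
  state4 <- state
  state4$z <- perm[state$z]
  reord <- integer(5)
  reord[perm] <- seq_len(5)
  state4$xlat <- state$xlat[reord, , drop = FALSE]
  state4$alpha <- state$alpha[, reord, drop = FALSE]
  state4$beta <- state$beta[reord, , drop = FALSE]
  state4$pi <- state$pi[reord]
  expect_equal(log_joint(state4, md, cfg), ll, tolerance = 1e-10)
})

test_that("fitting is bit-reproducible under a seed and echoes its config", {
  st <- generate_study(generator_config_small(n_lipids = 12, n_identified = 6,
                                              n_clusters = 2,
                                              n_patients = c(3, 3, 3),
                                              seed = 27))
  sc <- standardize(st$table, design = st$design, center = "before")
  cfg <- model_config(K = 3, n_burnin = 50, n_samples = 120, seed = 99)
  f1 <- fit_multiway(sc, st$design, cfg)
  f2 <- fit_multiway(sc, st$design, cfg)
  f1$final_state <- f2$final_state <- NULL
  expect_identical(f1[c("beta_f", "beta_p", "beta_i", "z", "v", "lambda",
                        "s2pat", "log_joint")],
                   f2[c("beta_f", "beta_p", "beta_i", "z", "v", "lambda",
                        "s2pat", "log_joint")])
  expect_equal(nrow(f1$beta_f), 120)
  # defaults echo the study protocol: 2000 burn-in, 2000 retained, 25 clusters
  dflt <- model_config()
  expect_equal(dflt$n_burnin, 2000L)
  expect_equal(dflt$n_samples, 2000L)
  expect_equal(dflt$K, 25L)
  # single retained draw is allowed
  f3 <- fit_multiway(sc, st$design,
                     model_config(K = 2, n_burnin = 10, n_samples = 1,
                                  seed = 1))
  expect_equal(nrow(f3$beta_f), 1)
})
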