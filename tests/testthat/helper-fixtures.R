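# shared builders and independent oracles for the test suite

# tiny balanced paired design: n patients per group, before+after each
toy_design <- function(n_per_group = c(2, 2, 2), placebo_baseline = TRUE) {
  grp <- c("feno_low_hcy", "feno_high_hcy", "placebo_low_hcy")
  pats <- data.frame(patient_id = sprintf("P%02d", seq_len(sum(n_per_group))),
                     group = rep(grp, n_per_group), stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(pats)), function(i) {
    tt <- if (pats$group[i] == "placebo_low_hcy" && !placebo_baseline) {
      "after"
    } else c("before", "after")
    data.frame(sample_id = paste0(pats$patient_id[i], "_", tt),
               patient_id = pats$patient_id[i], group = pats$group[i],
               time = tt, stringsAsFactors = FALSE)
  }))
  sample_design(rows$sample_id, rows$patient_id, rows$group, rows$time)
}

toy_peak_table <- function(n_peaks = 3, n_samples = 4, seed = 1,
                           unit = "raw_intensity") {
  set.seed(seed)
  vals <- matrix(stats::runif(n_peaks * n_samples, 10, 1000),
                 n_peaks, n_samples)
  peak_table(vals, peak_ids = paste0("pk", seq_len(n_peaks)),
             sample_ids = paste0("s", seq_len(n_samples)), unit = unit)
}

# closed-form Gaussian posterior of (beta_f, beta_p, beta_i, alpha_1..P) for
# the single-lipid, single-cluster reduction with loading 1 and known
# residual variance: x_s = alpha_j + d_s beta + noise, noise var (1+lambda)
conjugate_oracle <- function(x, design, lambda, s2pat, effect_var) {
  dmat <- t(vapply(seq_len(nrow(design)), function(s) {
    design_vector(design$group[s], design$time[s])[c("f", "p", "i")]
  }, numeric(3)))
  pats <- unique(design$patient_id)
  J <- outer(design$patient_id, pats, "==") * 1
  W <- cbind(dmat, J)
  w <- 1 + lambda
  prec <- crossprod(W) / w +
    diag(c(rep(1 / effect_var, 3), rep(1 / s2pat, length(pats))))
  Sigma <- solve(prec)
  list(mean = drop(Sigma %*% crossprod(W, x) / w), cov = Sigma)
}

# batch-means Monte-Carlo standard error of a chain mean
mcse <- function(v, n_batches = 40) {
  m <- matrix(v[seq_len(n_batches * (length(v) %/% n_batches))],
              ncol = n_batches)
  stats::sd(colMeans(m)) / sqrt(n_batches)
}

# match fitted cluster labels to true labels by majority overlap:
# true_of[k_fit] = true cluster holding most of fit cluster k's lipids
match_to_truth <- function(z_fit, z_true) {
  sapply(sort(unique(z_fit)), function(k) {
    as.integer(names(which.max(table(z_true[z_fit == k]))))
  })
}
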