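#' Standardize a peak table for modeling
#'
#' Transforms the lipid-by-sample value matrix to the scale the multi-way
#' model expects: per-lipid mean 0 and variance 1 across samples.  The
#' default `log_z` transform logs concentrations first (they are positive
#' and right-skewed); exact zeros are replaced by half the smallest positive
#' value of that lipid before logging.  Lipids with zero variance across
#' samples carry no information for the model and are excluded with a
#' warning.
#'
#' @param table A [peak_table()] (or a plain numeric matrix).
#' @param transform `"log_z"` (log, then per-lipid z-score), `"z"` (z-score
#'   only) or `"none"`.
#' @param design Optional [sample_design()], required for
#'   `center = "before"`.
#' @param center `"all"` (per-lipid mean over every sample, the default) or
#'   `"before"` (per-lipid mean over before-treatment samples only).  The
#'   multi-way model fixes its grand mean at the before-treatment average,
#'   so model fits should center on before-treatment samples: centering on
#'   all samples folds part of the treatment effect into the location and
#'   biases the effect estimates toward zero.  The scale is always the
#'   full-sample standard deviation.
#' @return A list of class `scaled_matrix` with elements `x` (the
#'   transformed matrix, excluded rows removed), `scaler` (per-lipid
#'   `location`/`scale` and the transform tag, for [inverse_transform()]),
#'   `excluded` (peak ids of constant lipids).
#' @export
standardize <- function(table, transform = c("log_z", "z", "none"),
                        design = NULL, center = c("all", "before")) {
  transform <- match.arg(transform)
  center <- match.arg(center)
  x <- if (inherits(table, "peak_table")) table$values else as.matrix(table)
  if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
  if (transform == "log_z") {
    if (any(x < 0)) stop("log transform requires nonnegative values",
                         call. = FALSE)
    x <- t(apply(x, 1, function(r) {
      if (any(r == 0)) {
        pos <- r[r > 0]
        if (length(pos)) r[r == 0] <- min(pos) / 2
        else r[] <- 1  # all-zero lipid: constant, excluded below
      }
      r
    }))
    x <- log(x)
  }
  if (transform == "none") {
    scaler <- list(location = setNames(rep(0, nrow(x)), rownames(x)),
                   scale = setNames(rep(1, nrow(x)), rownames(x)),
                   transform = transform)
    return(structure(list(x = x, scaler = scaler, excluded = character(0)),
                     class = "scaled_matrix"))
  }
  loc <- if (center == "before") {
    if (is.null(design)) {
      stop("center = \"before\" requires a sample design", call. = FALSE)
    }
    before_ids <- design$sample_id[design$time == "before"]
    cols <- intersect(colnames(x), before_ids)
    if (length(cols) == 0L) {
      stop("no before-treatment samples to center on", call. = FALSE)
    }
    rowMeans(x[, cols, drop = FALSE])
  } else {
    rowMeans(x)
  }
  sc <- apply(x, 1, stats::sd)
  const <- !is.finite(sc) | sc <= 0
  if (any(const)) {
    warning(sum(const), " constant lipid(s) excluded from standardization: ",
            paste(utils::head(rownames(x)[const], 5), collapse = ", "),
            if (sum(const) > 5) ", ..." else "", call. = FALSE)
  }
  keep <- !const
  out <- (x[keep, , drop = FALSE] - loc[keep]) / sc[keep]
  scaler <- list(location = loc[keep], scale = sc[keep], transform = transform)
  structure(list(x = out, scaler = scaler,
                 excluded = rownames(x)[const]),
            class = "scaled_matrix")
}

#' Invert a standardization
#'
#' Maps a standardized matrix back to the original scale:
#' `x * scale + location`, exponentiated if the forward transform logged.
#' Zeros replaced by the half-minimum pseudo-count are not restored.
#'
#' @param scaled A `scaled_matrix` (or the `scaler` element of one).
#' @param x Optional matrix to back-transform; defaults to `scaled$x`.
#' @return A numeric matrix on the original scale.
#' @export
inverse_transform <- function(scaled, x = NULL) {
  scaler <- if (!is.null(scaled$scaler)) scaled$scaler else scaled
  if (is.null(x)) x <- scaled$x
  out <- x * scaler$scale + scaler$location
  if (scaler$transform == "log_z") out <- exp(out)
  out
}
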