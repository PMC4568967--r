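#' Log-transform raw feature intensities
#'
#' Feature counts from high-resolution LC-MS are heavily right-skewed;
#' a log transform brings them close to Gaussian before any linear
#' modelling. Missing cells are preserved.
#'
#' @param ft a raw-scale feature table.
#' @param base logarithm base (default 2).
#' @param pseudocount added before taking logs so zero intensities map to 0.
#' @return the feature table on the log scale.
#' @export
log_transform <- function(ft, base = 2, pseudocount = 1) {
  assert_scale(ft, "raw", "log_transform")
  m <- ft_matrix(ft)
  if (any(m < 0, na.rm = TRUE)) abort("negative intensities cannot be log-transformed")
  ft_replace(ft, log(m + pseudocount, base = base), scale = "log")
}

#' Invert [log_transform()]
#' @inheritParams log_transform
#' @export
unlog_transform <- function(ft, base = 2, pseudocount = 1) {
  assert_scale(ft, "log", "unlog_transform")
  ft_replace(ft, base^ft_matrix(ft) - pseudocount, scale = "raw")
}

#' Detect outlier samples by standardized network connectivity
#'
#' Builds the sample network used for metabolomic/expression QC: sample-sample
#' affinity `a_ij = (1 + cor(i, j)) / 2` over features with no missing values,
#' per-sample connectivity `k_i = sum_{j != i} a_ij`, and its z-score
#' `Z_k = (k - mean k) / sd k`. Samples with `Z_k` below `z_cut` are flagged;
#' a sample that disagrees with the rest of the experiment has low
#' connectivity and a strongly negative `Z_k`.
#'
#' @param ft a log-scale feature table with at least 3 samples.
#' @param z_cut flagging threshold (default -3).
#' @return an `outlier_report`: tibble with `sample_id`, `connectivity`,
#'   `z_k`, `flagged`; the threshold is stored in the `"z_cut"` attribute.
#' @export
detect_outlier_samples <- function(ft, z_cut = -3) {
  assert_scale(ft, c("log", "centered"), "detect_outlier_samples")
  m <- ft_matrix(ft)
  if (ncol(m) < 3) abort("need at least 3 samples to detect outliers")
  complete <- stats::complete.cases(m)
  if (!any(complete)) abort("no features without missing values")
  a <- (1 + stats::cor(m[complete, , drop = FALSE])) / 2
  k <- colSums(a) - diag(a)
  s <- stats::sd(k)
  z <- if (is.na(s) || s == 0) rep(0, length(k)) else (k - mean(k)) / s
  out <- tibble(sample_id = colnames(m), connectivity = unname(k),
                z_k = unname(z), flagged = unname(z < z_cut))
  structure(out, z_cut = z_cut, class = c("outlier_report", class(out)))
}

#' Per-feature signal-to-noise statistics and filter
#'
#' The noise of an untargeted feature is estimated from its technical
#' replicates: for each biological sample, the standard deviation among that
#' sample's technical replicates; `sigma_tech` summarises these as their mean
#' (or as a pooled sd with `sigma = "pooled"`). SNR is the feature's mean
#' value divided by `sigma_tech`; features below `threshold` are removed.
#' A feature with `sigma_tech = 0` is noiseless (SNR infinite) and kept.
#'
#' @param ft a feature table (computed on whatever scale it is given;
#'   typically the log scale, after [log_transform()]).
#' @param design design tibble with `sample_id` and `bio_id` defining
#'   technical-replicate groups.
#' @param threshold minimum SNR retained (default 20).
#' @param sigma `"mean"` (mean of within-replicate sds) or `"pooled"`.
#' @return list with `features` (filtered table) and `stats`, a tibble of
#'   `feature_id`, `mean_intensity`, `sigma_tech`, `snr`, `missing_frac`,
#'   `removed` for every input feature.
#' @export
snr_filter <- function(ft, design, threshold = 20, sigma = c("mean", "pooled")) {
  sigma <- match.arg(sigma)
  m <- ft_matrix(ft)
  design <- design[match(colnames(m), design$sample_id), ]
  if (anyNA(design$bio_id)) abort("design does not cover all samples")
  groups <- split(seq_len(ncol(m)), design$bio_id)
  n_tech <- vapply(groups, length, integer(1))
  if (max(n_tech) < 2) abort("no technical replicates defined in the design")

  # per-group within-technical-replicate sd and observation count, per feature
  sds <- matrix(NA_real_, nrow(m), length(groups))
  ns <- matrix(0L, nrow(m), length(groups))
  for (g in seq_along(groups)) {
    x <- m[, groups[[g]], drop = FALSE]
    n_obs <- rowSums(!is.na(x))
    mu <- rowMeans(x, na.rm = TRUE)
    ss <- rowSums((x - mu)^2, na.rm = TRUE)
    v <- ifelse(n_obs >= 2, ss / (n_obs - 1), NA_real_)
    sds[, g] <- sqrt(v)
    ns[, g] <- n_obs
  }
  sigma_tech <- if (sigma == "mean") {
    rowMeans(sds, na.rm = TRUE)
  } else {
    df <- ifelse(is.na(sds), 0, ns - 1)
    sqrt(rowSums(sds^2 * df, na.rm = TRUE) / pmax(rowSums(df), 1))
  }
  mean_intensity <- rowMeans(m, na.rm = TRUE)
  snr <- ifelse(is.na(sigma_tech) | sigma_tech == 0, Inf, mean_intensity / sigma_tech)
  stats_tbl <- tibble(feature_id = rownames(m),
                      mean_intensity = unname(mean_intensity),
                      sigma_tech = unname(sigma_tech),
                      snr = unname(snr),
                      missing_frac = unname(rowMeans(is.na(m))),
                      removed = unname(snr < threshold))
  list(features = ft_subset(ft, !stats_tbl$removed), stats = stats_tbl)
}

#' Collapse technical replicates to biological samples
#'
#' Each biological sample becomes one column holding the mean of its
#' technical replicates, ignoring missing cells; the collapsed cell is
#' missing only when every technical replicate is missing.
#'
#' @inheritParams snr_filter
#' @return feature table with one column per `bio_id`.
#' @export
collapse_tech_reps <- function(ft, design) {
  m <- ft_matrix(ft)
  design <- design[match(colnames(m), design$sample_id), ]
  bio_ids <- unique(design$bio_id)
  out <- vapply(bio_ids, function(b) {
    rowMeans(m[, design$bio_id == b, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m)))
  out[is.nan(out)] <- NA
  colnames(out) <- bio_ids
  ft_replace(ft, out)
}

#' Remove features with too many missing samples
#' @param ft a feature table (typically after [collapse_tech_reps()]).
#' @param max_frac maximum tolerated fraction of missing samples (default 0.10).
#' @export
missingness_filter <- function(ft, max_frac = 0.10) {
  frac <- rowMeans(is.na(ft_matrix(ft)))
  ft_subset(ft, frac <= max_frac)
}

#' Impute remaining missing values
#'
#' `method = "knn"` imputes each missing cell from the `k` features most
#' correlated with the incomplete feature (absolute Pearson, pairwise
#' complete): each neighbour's value for that sample is mapped through the
#' least-squares line relating the two features, and predictions are averaged
#' with weights `|r|`. `method = "em"` iterates regression of each incomplete
#' feature on its most-correlated complete features, refining imputed values
#' until the largest change drops below `tol`.
#'
#' @param ft feature table after [missingness_filter()].
#' @param method `"knn"` or `"em"`.
#' @param k number of neighbour (or regressor) features.
#' @param tol,max_iter convergence controls for `method = "em"`.
#' @return the feature table with no missing cells.
#' @export
impute_missing <- function(ft, method = c("knn", "em"), k = 10,
                           tol = 1e-6, max_iter = 50) {
  method <- match.arg(method)
  m <- ft_matrix(ft)
  if (!anyNA(m)) return(ft)
  if (any(colSums(!is.na(m)) == 0)) abort("a sample has all cells missing; cannot impute")
  if (any(rowSums(!is.na(m)) < 3)) abort("a feature has fewer than 3 observed values; filter first")
  out <- if (method == "knn") .impute_knn(m, k) else .impute_em(m, k, tol, max_iter)
  ft_replace(ft, out)
}

.impute_knn <- function(m, k) {
  cc <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  diag(cc) <- NA
  out <- m
  incomplete <- which(rowSums(is.na(m)) > 0)
  for (f in incomplete) {
    r <- cc[f, ]
    ord <- order(abs(r), decreasing = TRUE, na.last = NA)
    miss_cols <- which(is.na(m[f, ]))
    preds <- matrix(NA_real_, 0, length(miss_cols))
    wts <- numeric(0)
    for (g in ord) {
      if (length(wts) >= k) break
      if (any(is.na(m[g, miss_cols]))) next
      obs <- !is.na(m[f, ]) & !is.na(m[g, ])
      if (sum(obs) < 3 || stats::sd(m[g, obs]) == 0) next
      b <- stats::cov(m[f, obs], m[g, obs]) / stats::var(m[g, obs])
      a <- mean(m[f, obs]) - b * mean(m[g, obs])
      preds <- rbind(preds, a + b * m[g, miss_cols])
      wts <- c(wts, abs(r[g]))
    }
    out[f, miss_cols] <- if (length(wts)) {
      colSums(preds * wts) / sum(wts)
    } else {
      mean(m[f, ], na.rm = TRUE)  # no usable neighbour: fall back to the feature mean
    }
  }
  out
}

.impute_em <- function(m, k, tol, max_iter) {
  miss <- is.na(m)
  incomplete <- which(rowSums(miss) > 0)
  complete <- which(rowSums(miss) == 0)
  out <- m
  # initialize with feature means
  for (f in incomplete) out[f, miss[f, ]] <- mean(m[f, ], na.rm = TRUE)
  if (!length(complete)) return(out)
  comp_mat <- m[complete, , drop = FALSE]
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (f in incomplete) {
      r <- suppressWarnings(stats::cor(out[f, ], t(comp_mat)))[1, ]
      regs <- complete[order(abs(r), decreasing = TRUE, na.last = NA)]
      regs <- regs[seq_len(min(k, length(regs), ncol(m) - 2))]
      fit <- stats::lm.fit(cbind(1, t(m[regs, , drop = FALSE])), out[f, ])
      pred <- cbind(1, t(m[regs, , drop = FALSE])) %*% fit$coefficients
      new_vals <- pred[miss[f, ], 1]
      delta <- max(delta, max(abs(new_vals - out[f, miss[f, ]]), 0))
      out[f, miss[f, ]] <- new_vals
    }
    if (delta < tol) break
  }
  out
}

#' Center every feature at mean zero (no rescaling)
#'
#' Variances are left untouched so downstream correlation and effect-size
#' analyses see the original dispersion.
#' @param ft an imputed feature table.
#' @export
center_features <- function(ft) {
  m <- ft_matrix(ft)
  ft_replace(ft, m - rowMeans(m), scale = "centered")
}

#' Quantile-normalize samples
#'
#' Forces every sample (column) to share the same distribution: sorted values
#' are replaced by the across-sample mean of order statistics; ties share the
#' mean of their tied ranks. Used before comparing correlation structure
#' across ages.
#' @param ft a feature table with no missing cells.
#' @export
quantile_normalize <- function(ft) {
  m <- ft_matrix(ft)
  if (anyNA(m)) abort("quantile normalization requires a complete matrix; impute first")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  ft_replace(ft, out)
}

#' Run the full QC chain
#'
#' log transform -> outlier-sample removal -> SNR filter -> technical
#' replicate collapse -> missingness filter -> imputation -> mean-centering.
#'
#' @inheritParams snr_filter
#' @inheritParams detect_outlier_samples
#' @inheritParams missingness_filter
#' @inheritParams impute_missing
#' @param center whether to mean-center features at the end.
#' @return list with `features` (clean, centered table with one column per
#'   biological sample), `design` (collapsed), and `report`, a tibble listing
#'   every removed feature or sample with the reason and statistic.
#' @export
run_qc <- function(ft, design, threshold = 20, max_frac = 0.10, z_cut = -3,
                   method = "knn", k = 10, center = TRUE) {
  logged <- log_transform(ft)
  outliers <- detect_outlier_samples(logged, z_cut = z_cut)
  report <- tibble(id = outliers$sample_id[outliers$flagged], type = "sample",
                   reason = "low_connectivity",
                   statistic = outliers$z_k[outliers$flagged])
  logged <- ft_drop_samples(logged, outliers$sample_id[outliers$flagged])
  design <- design[design$sample_id %in% ft_samples(logged), ]

  snr <- snr_filter(logged, design, threshold = threshold)
  report <- dplyr::bind_rows(report, tibble(
    id = snr$stats$feature_id[snr$stats$removed], type = "feature",
    reason = "low_snr", statistic = snr$stats$snr[snr$stats$removed]))

  collapsed <- collapse_tech_reps(snr$features, design)
  bio_design <- collapse_design(design)

  miss_frac <- rowMeans(is.na(ft_matrix(collapsed)))
  kept <- missingness_filter(collapsed, max_frac = max_frac)
  removed <- setdiff(collapsed$feature_id, kept$feature_id)
  report <- dplyr::bind_rows(report, tibble(
    id = removed, type = "feature", reason = "missingness",
    statistic = miss_frac[match(removed, collapsed$feature_id)]))

  imputed <- impute_missing(kept, method = method, k = k)
  out <- if (center) center_features(imputed) else imputed
  list(features = out, design = bio_design, report = report)
}
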