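test_that("log transform maps counts as expected and round-trips", {
  m <- matrix(c(0, 7, 100, 3), 2, 2)
  ft <- toy_table(m, scale = "raw")
  lg <- log_transform(ft)
  expect_equal(unname(ft_matrix(lg)[1, 1]), 0)
  expect_equal(unname(ft_matrix(lg)[2, 1]), 3)  # log2(7 + 1)
  back <- unlog_transform(lg)
  expect_equal(ft_matrix(back), ft_matrix(ft), tolerance = 1e-9)
  expect_error(log_transform(toy_table(-m, scale = "raw")), "negative")
  expect_error(log_transform(lg), "scale")
})

test_that("outlier detection flags a discordant sample and respects the cutoff", {
  set.seed(1)
  base <- rnorm(200)
  m <- sapply(1:12, function(i) base + rnorm(200, 0, 0.05))
  m[, 12] <- -m[, 12]  # sign-flipped sample
  ft <- toy_table(m)
  rep <- detect_outlier_samples(ft, z_cut = -3)
  expect_identical(rep$sample_id[rep$flagged], "s12")
  expect_false(any(detect_outlier_samples(ft, z_cut = -Inf)$flagged))

  same <- toy_table(matrix(rep(rnorm(50), 5), ncol = 5))
  expect_false(any(detect_outlier_samples(same)$flagged))
  expect_error(detect_outlier_samples(toy_table(matrix(rnorm(20), 10, 2))), "3 samples")
})

test_that("SNR filter matches arithmetic and brute force", {
  # 2 bio samples x 2 tech reps; feature 1: mean 100, sigma_tech 10 -> SNR 10
  m <- rbind(c(90, 110, 90, 110),
             c(100, 100, 100, 100),
             c(50, 52, 50, 52))
  ft <- toy_table(m)
  design <- tibble::tibble(sample_id = ft_samples(ft),
                           bio_id = c("b1", "b1", "b2", "b2"))
  res <- snr_filter(ft, design, threshold = 20)
  expect_equal(res$stats$snr[1], 100 / sd(c(90, 110)), tolerance = 1e-12)
  expect_true(res$stats$removed[1])    # SNR ~ 7.07 < 20
  expect_equal(res$stats$snr[2], Inf)  # sigma_tech = 0 -> kept
  expect_false(res$stats$removed[2])
  expect_equal(nrow(res$features), 2)

  # brute-force oracle on a random table
  set.seed(7)
  p <- 30; nb <- 5; nt <- 3
  mm <- matrix(rnorm(p * nb * nt, 20, 4), p)
  mm[sample(length(mm), 20)] <- NA
  ft2 <- toy_table(mm)
  d2 <- tibble::tibble(sample_id = ft_samples(ft2),
                       bio_id = rep(sprintf("b%d", 1:nb), each = nt))
  res2 <- snr_filter(ft2, d2, threshold = 8)
  oracle_keep <- sapply(seq_len(p), function(i) {
    sds <- sapply(split(mm[i, ], d2$bio_id), function(x) sd(x[!is.na(x)]))
    st <- mean(sds, na.rm = TRUE)
    snr <- if (is.na(st) || st == 0) Inf else mean(mm[i, ], na.rm = TRUE) / st
    snr >= 8
  })
  expect_identical(res2$features$feature_id, ft2$feature_id[oracle_keep])
  expect_error(snr_filter(ft, tibble::tibble(sample_id = ft_samples(ft),
                                             bio_id = ft_samples(ft))),
               "technical replicates")
})

test_that("technical replicate collapse averages observed values", {
  m <- rbind(c(2, 4, 5, NA), c(1, 1, NA, NA))
  ft <- toy_table(m)
  design <- tibble::tibble(sample_id = ft_samples(ft),
                           bio_id = c("b1", "b1", "b2", "b2"))
  out <- ft_matrix(collapse_tech_reps(ft, design))
  expect_equal(unname(out[1, ]), c(3, 5))
  expect_equal(unname(out[2, ]), c(1, NA_real_))

  single <- tibble::tibble(sample_id = ft_samples(ft), bio_id = ft_samples(ft))
  expect_equal(ft_matrix(collapse_tech_reps(ft, single)), ft_matrix(ft))
})

test_that("missingness filter applies the 10% rule", {
  m <- matrix(rnorm(36), 3, 12)
  m[1, 1] <- NA               # 1/12 = 8.3% -> kept
  m[2, 1:2] <- NA             # 2/12 = 16.7% -> removed
  ft <- toy_table(m)
  kept <- missingness_filter(ft, max_frac = 0.10)
  expect_identical(kept$feature_id, c("f01", "f03"))
  expect_identical(missingness_filter(ft, max_frac = 0)$feature_id, "f03")
  # idempotence
  expect_identical(missingness_filter(kept, max_frac = 0.10), kept)
})

test_that("imputation honours correlation structure", {
  ft0 <- toy_table(matrix(rnorm(20), 4, 5))
  expect_identical(impute_missing(ft0), ft0)

  # feature 2 = 2 * feature 1 + 1 exactly; one missing cell recovered through
  # the fitted line
  y1 <- c(1, 2, 3, 4, 5, 6)
  m <- rbind(y1, 2 * y1 + 1, rnorm(6))
  dimnames(m) <- NULL
  m[2, 4] <- NA
  ft <- toy_table(m)
  imp <- impute_missing(ft, method = "knn", k = 1)
  expect_equal(unname(ft_matrix(imp)[2, 4]), 2 * 4 + 1, tolerance = 1e-6)
  imp_em <- impute_missing(ft, method = "em", k = 2)
  expect_equal(unname(ft_matrix(imp_em)[2, 4]), 2 * 4 + 1, tolerance = 1e-4)

  # on correlated data, knn beats per-feature mean imputation
  set.seed(3)
  latent <- rnorm(30)
  truth <- sapply(1:40, function(i) 0.9 * latent + rnorm(30, 0, 0.3))
  truth <- t(truth) + 15
  holed <- truth
  mask <- matrix(runif(length(truth)) < 0.1, nrow(truth))
  holed[mask] <- NA
  ftc <- toy_table(holed)
  knn_rec <- ft_matrix(impute_missing(ftc, "knn", k = 10))
  mean_rec <- holed
  for (i in seq_len(nrow(holed))) mean_rec[i, mask[i, ]] <- mean(holed[i, ], na.rm = TRUE)
  rmse <- function(x) sqrt(mean((x[mask] - truth[mask])^2))
  expect_lt(rmse(knn_rec), rmse(mean_rec))

  bad <- toy_table(rbind(c(NA, 1, 2), c(NA, 3, 4), c(NA, 4, 5)))
  expect_error(impute_missing(bad), "all cells missing|fewer than 3")
})

test_that("centering zeroes feature means without rescaling", {
  ft <- toy_table(rbind(c(1, 2, 3), c(-1, 0, 1)))
  out <- center_features(ft)
  expect_equal(unname(ft_matrix(out)[1, ]), c(-1, 0, 1))
  expect_equal(unname(ft_matrix(out)[2, ]), c(-1, 0, 1))
  expect_true(all(abs(rowMeans(ft_matrix(out))) < 1e-12))
  expect_equal(apply(ft_matrix(out), 1, var), apply(ft_matrix(ft), 1, var),
               ignore_attr = TRUE)
})

test_that("quantile normalization equalises sample distributions", {
  ft <- toy_table(cbind(c(1, 2, 3), c(4, 5, 6)))
  out <- ft_matrix(quantile_normalize(ft))
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))

  same <- toy_table(matrix(rep(c(5, 1, 3, 2), 4), ncol = 4))
  expect_equal(ft_matrix(quantile_normalize(same)), ft_matrix(same))

  set.seed(8)
  rnd <- toy_table(matrix(rnorm(60), 10, 6))
  qn <- ft_matrix(quantile_normalize(rnd))
  sorted <- apply(qn, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
})

test_that("the QC chain flags a planted outlier sample and is reproducible", {
  cfg <- synth_config(n_features = 300, ages = 10, n_bio_reps = 8,
                      n_outlier_samples = 1, outlier_shift_sd = 6, seed = 13)
  sim <- simulate_features(make_design(cfg), cfg)
  qc <- run_qc(sim$features, sim$design)
  planted <- sim$truth_samples$sample_id[sim$truth_samples$planted_outlier]
  flagged <- qc$report$id[qc$report$reason == "low_connectivity"]
  expect_true(planted %in% flagged)
  expect_false(anyNA(ft_matrix(qc$features)))
  expect_true(all(abs(rowMeans(ft_matrix(qc$features))) < 1e-10))
})
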