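test_that("single-feature OLS matches the normal-equations oracle", {
  set.seed(2)
  x <- rnorm(8); y <- 1.5 + 0.7 * x + rnorm(8, 0, 0.2)
  fit <- fit_feature_effect(y, x)
  X <- cbind(1, x)
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, beta_hat[1], tolerance = 1e-10)
  expect_equal(fit$beta, beta_hat[2], tolerance = 1e-10)

  const <- fit_feature_effect(rep(3, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(const$beta, 0)
  expect_equal(const$p, 1)

  perfect <- fit_feature_effect(1:6, 1:6)
  expect_equal(perfect$beta, 1, tolerance = 1e-12)
  expect_lt(perfect$p, 1e-6)

  expect_error(fit_feature_effect(rnorm(5), rep(1, 5)), "degenerate")
  expect_error(fit_feature_effect(rnorm(2), 1:2), "3 complete")
})

test_that("BH adjustment follows the step-up rule", {
  q <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), fdr = 0.05)
  expect_equal(q$q, rep(0.04, 4))
  expect_true(all(q$significant))
  expect_equal(bh_adjust(0.2)$q, 0.2)
  expect_equal(bh_adjust(rep(1, 5))$q, rep(1, 5))
  expect_false(any(bh_adjust(rep(1, 5))$significant))
  expect_error(bh_adjust(c(0.5, 1.3)), "0, 1")

  # independent step-up oracle on random vectors
  set.seed(4)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    m <- length(p)
    o <- order(p)
    q_or <- rev(cummin(rev(p[o] * m / seq_len(m))))
    oracle <- numeric(m); oracle[o] <- pmin(q_or, 1)
    expect_equal(bh_adjust(p)$q, oracle, tolerance = 1e-12)
  }
})

test_that("per-feature models are calibrated under the null generator", {
  cfg <- synth_config(n_features = 2000, ages = 10, frac_diet_affected = 0,
                      frac_age_affected = 0, frac_missing = 0, frac_low_snr = 0,
                      seed = 6)
  s <- sim_clean_bio(cfg)
  eff <- fit_feature_effects(s$features, s$design, "diet")
  frac <- mean(eff$p < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("batch adjustment removes shifts but preserves planted diet effects", {
  # single batch: identity
  ft1 <- toy_table(matrix(rnorm(60), 6, 10))
  d1 <- toy_design(ft1)
  expect_equal(ft_matrix(batch_adjust(ft1, d1)), ft_matrix(ft1), tolerance = 1e-9)

  # planted batch shift + diet effect
  set.seed(10)
  p <- 300; n <- 24
  diet <- rep(c("AL", "DR"), n / 2)
  batch <- rep(c("b1", "b1", "b2", "b2"), length.out = n)  # balanced against diet
  beta <- rnorm(p, 0, 1)
  shift <- rnorm(p, 0, 1.5)
  m <- 14 + outer(beta, as.numeric(diet == "DR")) +
    outer(shift, as.numeric(batch == "b2")) + matrix(rnorm(p * n, 0, 0.5), p)
  ft <- toy_table(m)
  d <- tibble::tibble(sample_id = ft_samples(ft), bio_id = sample_id,
                      diet = diet, age = 10, batch = batch)
  adj <- suppressMessages(batch_adjust(ft, d, covariates = "diet"))
  am <- ft_matrix(adj)
  resid_shift <- abs(rowMeans(am[, batch == "b2"]) - rowMeans(am[, batch == "b1"]))
  sds <- apply(am, 1, sd)
  expect_gt(mean(resid_shift < 0.05 * sds + 0.05), 0.95)
  # systematic bias of the diet slope: regression of estimate on truth
  eff <- fit_feature_effects(adj, d, "diet")
  slope <- unname(coef(lm(eff$beta ~ beta))[2])
  expect_lt(abs(slope - 1), 0.10)

  # batch confounded with diet
  d_conf <- dplyr::mutate(d, batch = ifelse(diet == "DR", "b1", "b2"))
  expect_error(batch_adjust(ft, d_conf, covariates = "diet"), "confounded")
})

test_that("reversal classification applies the quadrant rule", {
  rec <- function(id, beta, q) tibble::tibble(feature_id = id, predictor = "x",
                                              intercept = 0, beta = beta, p = q,
                                              q = q, significant = q <= 0.025, n = 12)
  diet <- dplyr::bind_rows(rec("a", 0.8, 0.001), rec("b", 0.8, 0.001), rec("c", 0.8, 0.001))
  age <- dplyr::bind_rows(rec("a", -0.5, 0.001), rec("b", 0.5, 0.001), rec("c", -0.5, 0.5))
  rv <- reversal_classification(diet, age, fdr = 0.025)
  expect_equal(rv$quadrant[rv$feature_id == "a"], "reversal")
  expect_equal(rv$class[rv$feature_id == "a"], "both")
  expect_equal(rv$quadrant[rv$feature_id == "b"], "exacerbation")
  expect_equal(rv$class[rv$feature_id == "c"], "diet-only")
  expect_error(reversal_classification(diet, age[1:2, ]), "different feature sets")
})

test_that("Venn region counts cover all membership patterns", {
  counts <- tissue_overlap_counts(list(A = c("a", "b"), B = c("b", "c")))
  get <- function(a, b) counts$n[counts$A == a & counts$B == b]
  expect_equal(get(TRUE, FALSE), 1)
  expect_equal(get(FALSE, TRUE), 1)
  expect_equal(get(TRUE, TRUE), 1)

  same <- tissue_overlap_counts(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same$n[same$A & !same$B], 0)
  expect_equal(same$n[same$A & same$B], 2)

  disj <- tissue_overlap_counts(list(A = letters[1:2], B = letters[3:5], C = letters[6:9]))
  expect_equal(sort(disj$n[rowSums(as.matrix(disj[1:3])) == 1]), c(2, 3, 4))
  expect_true(all(disj$n[rowSums(as.matrix(disj[1:3])) > 1] == 0))
  expect_error(tissue_overlap_counts(list(A = "a")), "2 sets")
})

test_that("PCA scores behave like a rotation-invariant spectral method", {
  # exact line: PC1 explains everything
  t_line <- seq(-1, 1, length.out = 10)
  m <- outer(c(1, 2, -0.5), t_line)
  pc <- pca_scores(toy_table(m), n_components = 2) |> suppressWarnings()
  expect_equal(pc$var_explained[1], 1, tolerance = 1e-12)

  set.seed(12)
  m2 <- matrix(rnorm(20 * 12), 20, 12)
  rot <- qr.Q(qr(matrix(rnorm(400), 20, 20)))
  dimnames_keep <- dimnames(m2)
  p1 <- pca_scores(toy_table(m2), 5)
  m2r <- rot %*% m2
  dimnames(m2r) <- NULL
  p2 <- pca_scores(toy_table(m2r), 5)
  expect_equal(p1$var_explained, p2$var_explained, tolerance = 1e-9)
  expect_warning(pca_scores(toy_table(matrix(rnorm(12), 3, 4)), 10), "truncating")

  # planted diet separation shows up on the leading components
  cfg <- synth_config(n_features = 300, ages = 10, frac_diet_affected = 0.5,
                      frac_age_affected = 0, effect_size_sd = 2, frac_missing = 0,
                      seed = 14)
  s <- sim_clean_bio(cfg)
  pc3 <- pca_scores(s$features, 2)
  sc <- as.matrix(pc3$scores[, c("PC1", "PC2")])
  lab <- as.integer(factor(s$design$diet[match(pc3$scores$sample_id, s$design$sample_id)]))
  sil <- cluster::silhouette(lab, dist(sc))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("reversal recovery matches the planted sign structure", {
  run_rev <- function(frac_rev, seed) {
    cfg <- synth_config(n_features = 500, frac_diet_affected = 0.6, frac_age_affected = 0.6,
                        frac_reversal = frac_rev, effect_size_sd = 2, frac_missing = 0,
                        frac_low_snr = 0, seed = seed)
    s <- sim_clean_bio(cfg)
    old <- max(s$design$age); young <- min(s$design$age)
    diet_eff <- fit_feature_effects(s$features, s$design, "diet", at_age = old, fdr = 0.025)
    age_eff <- fit_feature_effects(s$features, s$design, "age", on_diet = "AL",
                                   ages = c(young, old), fdr = 0.025)
    rv <- reversal_classification(diet_eff, age_eff, fdr = 0.025)
    both <- rv[rv$class == "both", ]
    mean(both$quadrant == "reversal")
  }
  expect_gte(run_rev(1, 20), 0.9)
  expect_lte(run_rev(0, 21), 0.1)
})
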