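cor_obj <- function(cc, n, condition = "X") list(condition = condition, cor = cc, n = n)

test_that("difference and constancy matrices follow the signed-square algebra", {
  mk <- function(r) {
    cc <- matrix(r, 2, 2); diag(cc) <- 1
    dimnames(cc) <- list(c("a", "b"), c("a", "b"))
    cc
  }
  d <- difference_matrix(cor_obj(mk(1), 10), cor_obj(mk(-1), 10), 6)
  expect_equal(d$matrix["a", "b"], 1)
  d2 <- difference_matrix(cor_obj(mk(0.8), 10), cor_obj(mk(0), 10), 6)
  expect_equal(d2$matrix["a", "b"], 0.032768, tolerance = 1e-12)
  same <- difference_matrix(cor_obj(mk(0.37), 10), cor_obj(mk(0.37), 10), 6)
  expect_true(all(same$matrix == 0))

  k1 <- constancy_matrix(cor_obj(mk(1), 10), cor_obj(mk(1), 10), 6)
  expect_equal(k1$matrix["a", "b"], 1)
  k0 <- constancy_matrix(cor_obj(mk(1), 10), cor_obj(mk(-1), 10), 6)
  expect_equal(k0$matrix["a", "b"], 0)
  # both constancy forms agree when c = c'
  for (meth in c("min_concordant", "signed_sum")) {
    kk <- constancy_matrix(cor_obj(mk(0.8), 10), cor_obj(mk(0.8), 10), 6, method = meth)
    expect_equal(kk$matrix["a", "b"], 0.262144, tolerance = 1e-12)
  }

  expect_error(difference_matrix(cor_obj(mk(0.5), 10), cor_obj(mk(0.5), 10), 5), "even")
})

test_that("difference/constancy transforms are exchange-symmetric and mutually exclusive", {
  set.seed(3)
  for (i in 1:10) {
    cc1 <- cor(matrix(rnorm(8 * 6), 8, 6))
    cc2 <- cor(matrix(rnorm(8 * 6), 8, 6))
    a <- cor_obj(cc1, 8); b <- cor_obj(cc2, 8)
    expect_equal(difference_matrix(a, b)$matrix, difference_matrix(b, a)$matrix)
    for (meth in c("min_concordant", "signed_sum")) {
      expect_equal(constancy_matrix(a, b, method = meth)$matrix,
                   constancy_matrix(b, a, method = meth)$matrix)
    }
  }
  # d = 1 forces k = 0 and conversely, for any beta
  grid <- expand.grid(c1 = seq(-1, 1, 0.25), c2 = seq(-1, 1, 0.25))
  mk <- function(r) { m <- matrix(r, 2, 2); diag(m) <- 1; m }
  for (i in seq_len(nrow(grid))) {
    a <- cor_obj(mk(grid$c1[i]), 5); b <- cor_obj(mk(grid$c2[i]), 5)
    dv <- difference_matrix(a, b, 6)$matrix[1, 2]
    for (meth in c("min_concordant", "signed_sum")) {
      kv <- constancy_matrix(a, b, 6, method = meth)$matrix[1, 2]
      if (dv == 1) expect_equal(kv, 0)
      if (kv == 1) expect_equal(dv, 0)
    }
  }
})

test_that("topological overlap matches the direct formula", {
  z <- matrix(0, 4, 4)
  expect_true(all(topological_overlap(z)[upper.tri(z)] == 0))
  ones <- matrix(1, 4, 4)
  expect_true(all(topological_overlap(ones) == 1))

  set.seed(4)
  a <- matrix(runif(16, 0, 0.9), 4, 4)
  a <- (a + t(a)) / 2; diag(a) <- 0
  tom <- topological_overlap(a)
  k <- colSums(a)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    num <- sum(a[i, ] * a[, j]) + a[i, j]
    den <- min(k[i], k[j]) + 1 - a[i, j]
    expect_equal(tom[i, j], num / den, tolerance = 1e-12)
  }
  expect_true(all(tom >= 0 & tom <= 1))
  expect_error(topological_overlap(matrix(c(0, -0.1, -0.1, 0), 2, 2)), "0, 1")
})

test_that("module extraction recovers planted blocks and degrades gracefully", {
  p <- 60
  dis <- matrix(0.9, p, p)
  dis[1:30, 1:30] <- 0.1
  dis[31:60, 31:60] <- 0.1
  diag(dis) <- 0
  rownames(dis) <- colnames(dis) <- sprintf("f%02d", 1:p)
  mods <- cluster_modules(dis, min_size = 10)
  lab <- tidy(mods)$module
  expect_equal(sum(mods$sizes$module != "grey"), 2)
  truth <- rep(c("A", "B"), each = 30)
  expect_equal(mclust::adjustedRandIndex(lab, truth), 1)

  # permuted feature order gives the same partition up to labels
  perm <- sample(p)
  mods_p <- cluster_modules(dis[perm, perm], min_size = 10)
  expect_equal(mclust::adjustedRandIndex(tidy(mods_p)$module, truth[perm]), 1)

  flat <- matrix(0.5, 30, 30); diag(flat) <- 0
  expect_true(all(tidy(cluster_modules(flat))$module == "grey"))

  tiny <- matrix(0.2, 5, 5); diag(tiny) <- 0
  expect_true(all(tidy(cluster_modules(tiny, min_size = 10))$module == "grey"))
})

test_that("condition correlations split samples and spot planted structure", {
  set.seed(6)
  m <- matrix(rnorm(30 * 100), 30, 100)
  ft <- toy_table(m)
  des <- toy_design(ft, diet = rep(c("AL", "DR"), each = 50))
  cors <- condition_correlations(ft, des, "diet")
  expect_equal(names(cors), c("AL", "DR"))
  expect_true(all(diag(cors$AL$cor) == 1))
  expect_lt(mean(abs(cors$AL$cor[upper.tri(cors$AL$cor)])), 0.2)

  expect_error(condition_correlations(ft, dplyr::mutate(des, diet = c(rep("AL", 97), rep("DR", 3))),
                                      "diet"), "need >= 4")

  cfg <- synth_config(n_features = 100, ages = 10, n_bio_reps = 20, n_tech_reps = 1,
                      frac_missing = 0, frac_diet_affected = 0, frac_age_affected = 0,
                      module_specs = list(list(size = 25, pattern = "DR-only", r = 0.7)),
                      seed = 7)
  s <- sim_clean_bio(cfg)
  cors2 <- condition_correlations(s$features, s$design, "diet")
  mod <- s$sim$truth_features$feature_id[!is.na(s$sim$truth_features$module)]
  wm <- function(cc) mean(cc[mod, mod][upper.tri(diag(length(mod)))])
  expect_gt(wm(cors2$DR$cor), wm(cors2$AL$cor) + 0.3)
})

test_that("module dispersion permutation test separates signal from null", {
  cfg <- synth_config(n_features = 80, ages = 10, n_bio_reps = 16, n_tech_reps = 1,
                      frac_missing = 0, frac_diet_affected = 0, frac_age_affected = 0,
                      module_specs = list(list(size = 20, pattern = "DR-only", r = 0.8)),
                      seed = 8)
  s <- sim_clean_bio(cfg)
  mod_ids <- s$sim$truth_features$feature_id[!is.na(s$sim$truth_features$module)]
  planted <- structure(list(
    modules = tibble::tibble(feature_id = s$features$feature_id,
                             module = ifelse(s$features$feature_id %in% mod_ids,
                                             "turquoise", "grey"))),
    class = "module_assignment")
  disp <- module_dispersion_test(s$features, s$design, planted, n_perm = 1000, seed = 1)
  expect_lte(disp$p, 0.01)
  expect_gte(disp$p, 1 / 1001)

  # null: random "modules" on exchangeable conditions are rarely significant
  set.seed(9)
  ftn <- toy_table(matrix(rnorm(60 * 24), 60, 24))
  desn <- toy_design(ftn, diet = rep(c("AL", "DR"), each = 12))
  rand_mods <- structure(list(
    modules = tibble::tibble(feature_id = ftn$feature_id,
                             module = sample(rep(c("m1", "m2", "m3", "m4", "m5", "m6",
                                                   "m7", "m8", "m9", "m10"), each = 6)))),
    class = "module_assignment")
  dn <- module_dispersion_test(ftn, desn, rand_mods, n_perm = 200, seed = 2)
  expect_gte(mean(dn$p >= 0.05), 0.9)

  expect_error(module_dispersion_test(s$features, s$design, planted, n_perm = 5), "at least 10")
  expect_warning(module_dispersion_test(s$features, s$design, planted, n_perm = 50, seed = 1),
                 "coarse")
})

test_that("correlation shift test measures distribution differences", {
  cc <- cor(matrix(rnorm(20 * 50), 20, 50))
  res <- correlation_shift_test(cor_obj(cc, 20), cor_obj(cc, 20), n_perm = 500, seed = 1)
  expect_equal(res$diff, 0)
  expect_gt(res$p, 0.9)
  expect_true(res$mean_a >= -1 && res$mean_a <= 1)
  expect_error(correlation_shift_test(cor_obj(cc[1:2, 1:2], 20), cor_obj(cc[1:2, 1:2], 20)),
               "3 features")
})

test_that("feature selection separates diet-specific from preserved correlations", {
  n <- 24
  cc_one <- diag(3); dimnames(cc_one) <- list(letters[1:3], letters[1:3])
  cc_one["a", "b"] <- cc_one["b", "a"] <- 0.9
  cc_zero <- diag(3); dimnames(cc_zero) <- dimnames(cc_one)
  sel <- differential_feature_selection(cor_obj(cc_one, n), cor_obj(cc_zero, n), alpha = 0.01)
  expect_equal(sel$status[sel$feature_id == "a"], "differential")
  expect_equal(sel$status[sel$feature_id == "c"], "neither")
  sel2 <- differential_feature_selection(cor_obj(cc_one, n), cor_obj(cc_one, n), alpha = 0.01)
  expect_equal(sel2$status[sel2$feature_id == "a"], "similar")
})

test_that("age-trajectory generator reproduces diet-specific connectivity ageing", {
  ok <- logical(50)
  for (i in seq_len(50)) {
    cfg <- synth_config(n_features = 60, ages = c(10, 40), n_bio_reps = 12, n_tech_reps = 1,
                        frac_missing = 0, frac_diet_affected = 0, frac_age_affected = 0,
                        frac_low_snr = 0,
                        module_specs = list(list(size = 30, pattern = "age-trajectory",
                                                 r_by_age = list(AL = c(0.6, 0.15),
                                                                 DR = c(0.15, 0.6)))),
                        seed = 100 + i)
    sim <- simulate_features(make_design(cfg), cfg)
    m <- ft_matrix(log_transform(sim$features))
    mod <- sim$truth_features$feature_id[!is.na(sim$truth_features$module)]
    mr <- function(diet, age) {
      ids <- sim$design$sample_id[sim$design$diet == diet & sim$design$age == age]
      cc <- cor(t(m[mod, ids]))
      mean(cc[upper.tri(cc)])
    }
    ok[i] <- mr("DR", 40) > mr("DR", 10) && mr("AL", 40) < mr("AL", 10)
  }
  expect_gte(mean(ok), 0.9)
})
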