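#' ANCOVA test for a diet-dependent correlation between two features
#'
#' Fits `y = mu + a*x + b*diet + c*(x * diet)` and F-tests the interaction
#' `c = 0` with df `(1, n - 4)`: a significant interaction means the slope
#' relating the two features differs between diets, i.e. their correlation
#' is diet-dependent. The model is asymmetric in which feature plays the
#' response; by convention the feature with the larger variance is the
#' covariate `x` and the other the response (ties keep `yi` as covariate),
#' so results are deterministic.
#'
#' @param yi,yj numeric feature vectors over the same samples, no missing
#'   values.
#' @param diet factor/character with two diet levels, >= 3 samples each.
#' @return one-row tibble: `F`, `df1`, `df2`, `p`, `response` (`"yi"` or
#'   `"yj"`).
#' @export
pair_ancova <- function(yi, yj, diet) {
  if (anyNA(yi) || anyNA(yj) || anyNA(diet)) abort("missing values are not allowed")
  diet <- as.factor(diet)
  if (nlevels(droplevels(diet)) != 2) abort("diet must have exactly 2 levels")
  if (min(table(droplevels(diet))) < 3) abort("need at least 3 samples per diet")
  # larger-variance feature is the covariate
  if (stats::var(yj) > stats::var(yi)) {
    x <- yj; y <- yi; response <- "yi"
  } else {
    x <- yi; y <- yj; response <- "yj"
  }
  g <- as.numeric(diet == levels(droplevels(diet))[2])
  for (lev in 0:1) {
    if (stats::sd(x[g == lev]) == 0) abort("covariate feature is constant within a diet")
  }
  n <- length(y)
  X_full <- cbind(1, x, g, x * g)
  X_red <- X_full[, 1:3, drop = FALSE]
  rss_full <- sum(stats::lm.fit(X_full, y)$residuals^2)
  rss_red <- sum(stats::lm.fit(X_red, y)$residuals^2)
  df2 <- n - 4
  Fstat <- (rss_red - rss_full) / (rss_full / df2)
  p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  tibble(F = Fstat, df1 = 1, df2 = df2, p = p, response = response)
}

# Fisher r-to-z test of equal correlations in two groups (descriptive cross-check)
fisher_z_test <- function(r1, n1, r2, n2) {
  z1 <- atanh(pmin(pmax(r1, -1 + 1e-12), 1 - 1e-12))
  z2 <- atanh(pmin(pmax(r2, -1 + 1e-12), 1 - 1e-12))
  z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

#' Screen for metabolite pairs with diet-dependent correlation
#'
#' Implements the differential-correlation screen: candidate features are
#' those whose *mean* level is unaffected by diet (unadjusted diet-effect
#' `p > mean_gate_alpha`), so any hit reflects a change in correlation, not
#' in abundance. Every candidate pair (optionally pre-filtered by
#' `|r_AL - r_DR| >= min_cor_diff` and capped at `max_pairs` by seeded
#' subsampling) is tested with [pair_ancova()]; BH-FDR is applied across all
#' tested pairs.
#'
#' @param ft a complete log-scale/centered feature table (one column per
#'   biological sample).
#' @param design matching design with `diet`.
#' @param mean_gate_alpha candidates must have diet-effect p above this
#'   (default 0.05, unadjusted).
#' @param fdr BH level for the `significant` flag.
#' @param min_cor_diff pre-filter on the absolute correlation difference
#'   (default 0 = test all candidate pairs).
#' @param max_pairs cap on tested pairs; excess pairs are dropped by seeded
#'   subsampling.
#' @param seed seed for the subsampling.
#' @param diet_effects optionally, precomputed diet effects from
#'   [fit_feature_effects()] (avoids refitting).
#' @return tibble sorted by `q`: `feature_i`, `feature_j`, `r_AL`, `r_DR`,
#'   `F`, `df2`, `p`, `q`, `significant`, `p_fisher_z`, plus the mean-gate
#'   p-values `gate_p_i`, `gate_p_j`. Empty (zero rows) when fewer than two
#'   features pass the gate.
#' @export
screen_differential_pairs <- function(ft, design, mean_gate_alpha = 0.05,
                                      fdr = 0.05, min_cor_diff = 0,
                                      max_pairs = Inf, seed = 1L,
                                      diet_effects = NULL) {
  design <- design[match(ft_samples(ft), design$sample_id), ]
  if (is.null(diet_effects)) {
    diet_effects <- fit_feature_effects(ft, design, predictor = "diet", at_age = NULL)
  }
  gate <- diet_effects$p > mean_gate_alpha
  empty <- tibble(feature_i = character(), feature_j = character(),
                  r_AL = numeric(), r_DR = numeric(), F = numeric(),
                  df2 = numeric(), p = numeric(), q = numeric(),
                  significant = logical(), p_fisher_z = numeric(),
                  gate_p_i = numeric(), gate_p_j = numeric())
  if (sum(gate) < 2) return(empty)
  ids <- diet_effects$feature_id[gate]
  gate_p <- stats::setNames(diet_effects$p[gate], ids)

  m <- ft_matrix(ft)[ids, , drop = FALSE]
  al <- design$diet == "AL"
  dr <- design$diet == "DR"
  n_al <- sum(al); n_dr <- sum(dr)
  r_al <- stats::cor(t(m[, al, drop = FALSE]))
  r_dr <- stats::cor(t(m[, dr, drop = FALSE]))

  pairs <- which(upper.tri(r_al), arr.ind = TRUE)
  dif <- abs(r_al[pairs] - r_dr[pairs])
  pairs <- pairs[dif >= min_cor_diff, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  if (nrow(pairs) > max_pairs) {
    set.seed(seed)
    pairs <- pairs[sort(sample.int(nrow(pairs), max_pairs)), , drop = FALSE]
  }

  # fast numeric path over all pairs: same model as pair_ancova() without
  # per-pair data-frame overhead
  g <- as.numeric(design$diet == sort(unique(design$diet))[2])
  n <- length(g)
  rv <- apply(m, 1, stats::var)
  np <- nrow(pairs)
  Fv <- pv <- numeric(np)
  for (k in seq_len(np)) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (rv[j] > rv[i]) { x <- m[j, ]; y <- m[i, ] } else { x <- m[i, ]; y <- m[j, ] }
    X_full <- cbind(1, x, g, x * g)
    rss_full <- sum(stats::.lm.fit(X_full, y)$residuals^2)
    rss_red <- sum(stats::.lm.fit(X_full[, 1:3, drop = FALSE], y)$residuals^2)
    Fv[k] <- (rss_red - rss_full) / (rss_full / (n - 4))
    pv[k] <- stats::pf(Fv[k], 1, n - 4, lower.tail = FALSE)
  }
  out <- tibble(F = Fv, df2 = n - 4, p = pv)
  out <- dplyr::mutate(out,
    feature_i = ids[pairs[, 1]], feature_j = ids[pairs[, 2]],
    r_AL = r_al[pairs], r_DR = r_dr[pairs],
    p_fisher_z = fisher_z_test(.data$r_AL, n_al, .data$r_DR, n_dr),
    gate_p_i = unname(gate_p[.data$feature_i]),
    gate_p_j = unname(gate_p[.data$feature_j]))
  adj <- bh_adjust(out$p, fdr = fdr)
  out$q <- adj$q
  out$significant <- adj$significant
  out <- dplyr::select(out, "feature_i", "feature_j", "r_AL", "r_DR", "F",
                       "df2", "p", "q", "significant", "p_fisher_z",
                       "gate_p_i", "gate_p_j")
  dplyr::arrange(out, .data$q, .data$p)
}
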