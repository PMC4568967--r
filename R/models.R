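#' Fit a single-feature linear effect model
#'
#' Ordinary least squares `y = mu + beta * x` with a two-sided t-test on
#' `beta = 0`. A constant response is reported as `beta = 0`, `p = 1`.
#'
#' @param y numeric feature values (log scale).
#' @param x numeric predictor codes: diet coded AL = 0 / DR = 1 (so positive
#'   `beta` means higher under dietary restriction), or age in days.
#' @return one-row tibble: `intercept`, `beta`, `se`, `p`, `n`.
#' @export
fit_feature_effect <- function(y, x) {
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3) abort("need at least 3 complete pairs")
  if (length(unique(x)) < 2) abort("degenerate predictor: x is constant")
  sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  mu <- mean(y) - beta * mean(x)
  rss <- sum((y - mu - beta * x)^2)
  if (stats::sd(y) == 0) return(tibble(intercept = mu, beta = 0, se = 0, p = 1, n = n))
  se <- sqrt(rss / (n - 2) / sxx)
  p <- if (se == 0) {
    if (beta == 0) 1 else 0
  } else {
    2 * stats::pt(abs(beta / se), df = n - 2, lower.tail = FALSE)
  }
  tibble(intercept = mu, beta = beta, se = se, p = p, n = n)
}

#' Per-feature diet or age effects across a feature table
#'
#' Fits the single-predictor model of [fit_feature_effect()] to every
#' feature. The two predictors are fitted on different sample subsets, each
#' one predictor at a time to avoid confounding: the diet effect contrasts
#' AL vs DR at a single age (`at_age`); the age effect is a slope over days
#' within one diet (`on_diet`, default the ad libitum arm), optionally
#' restricted to a two-age contrast via `ages`.
#'
#' @param ft a log-scale (or centered) feature table.
#' @param design matching design tibble (`sample_id`, `diet`, `age`).
#' @param predictor `"diet"` or `"age"`.
#' @param at_age for `predictor = "diet"`: the age (days) to test at;
#'   `NULL` uses all ages.
#' @param on_diet for `predictor = "age"`: the diet level to test within;
#'   `NULL` uses all diets.
#' @param ages for `predictor = "age"`: ages to contrast (e.g. `c(10, 40)`);
#'   `NULL` uses all.
#' @param fdr level at which the `significant` flag is set (BH q-value).
#' @return tibble: `feature_id`, `predictor`, `intercept`, `beta`, `p`,
#'   `q`, `significant`, `n`.
#' @export
fit_feature_effects <- function(ft, design, predictor = c("diet", "age"),
                                at_age = NULL, on_diet = "AL", ages = NULL,
                                fdr = 0.05) {
  predictor <- match.arg(predictor)
  design <- design[match(ft_samples(ft), design$sample_id), ]
  if (predictor == "diet") {
    keep <- if (is.null(at_age)) rep(TRUE, nrow(design)) else design$age %in% at_age
    x <- as.numeric(design$diet == "DR")
  } else {
    keep <- if (is.null(on_diet)) rep(TRUE, nrow(design)) else design$diet %in% on_diet
    if (!is.null(ages)) keep <- keep & design$age %in% ages
    x <- design$age
  }
  m <- ft_matrix(ft)[, keep, drop = FALSE]
  x <- x[keep]
  if (length(unique(x)) < 2) abort("degenerate predictor after subsetting")
  fits <- lapply(seq_len(nrow(m)), function(i) fit_feature_effect(m[i, ], x))
  out <- dplyr::bind_rows(fits)
  out <- dplyr::mutate(out, feature_id = rownames(m), predictor = predictor,
                       .before = 1)
  adj <- bh_adjust(out$p, fdr = fdr)
  out$q <- adj$q
  out$significant <- adj$significant
  dplyr::select(out, "feature_id", "predictor", "intercept", "beta", "p",
                "q", "significant", "n")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param fdr false-discovery-rate level for the `significant` flag.
#' @return tibble with `p`, `q`, `significant`.
#' @export
bh_adjust <- function(p, fdr = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  tibble(p = p, q = q, significant = q <= fdr)
}

#' Remove batch effects with empirical-Bayes location/scale adjustment
#'
#' Wraps parametric ComBat: per-feature standardization preserving the
#' covariate fit, shrinkage of per-batch mean and variance estimates toward
#' across-feature priors, then adjustment and restoration of the covariate
#' fit. Used when pooling tissues (e.g. thorax + whole body) before joint
#' modelling. With a single batch the data are returned unchanged.
#'
#' @param ft a log-scale or centered feature table.
#' @param design design tibble with a `batch` column.
#' @param covariates names of design columns whose effects must be
#'   preserved (e.g. `"diet"`); `NULL` for none.
#' @return the adjusted feature table.
#' @export
batch_adjust <- function(ft, design, covariates = "diet") {
  design <- design[match(ft_samples(ft), design$sample_id), ]
  batch <- design$batch
  if (length(unique(batch)) < 2) return(ft)
  if (any(table(batch) < 2)) abort("every batch needs at least 2 samples")
  mod <- NULL
  if (!is.null(covariates) && length(covariates)) {
    mod <- stats::model.matrix(
      stats::reformulate(covariates), data = as.data.frame(design))
    full <- cbind(mod, stats::model.matrix(~batch)[, -1, drop = FALSE])
    if (qr(full)$rank < ncol(full)) {
      abort("batch is confounded with a covariate; cannot adjust")
    }
  }
  m <- ft_matrix(ft)
  adj <- sva::ComBat(dat = m, batch = batch, mod = mod,
                     par.prior = TRUE, prior.plots = FALSE)
  ft_replace(ft, adj)
}

#' Classify features by joint diet and age response (reversal analysis)
#'
#' Joins per-feature diet and age effect records and asks, for each feature,
#' whether the diet effect opposes the age effect. Features with
#' opposite-sign slopes sit in the "reversal" quadrants of the diet-beta vs
#' age-beta plane: dietary restriction pushes them back toward their young
#' level. Same-sign features sit in the "exacerbation" quadrants.
#'
#' @param diet_effects,age_effects effect tibbles from
#'   [fit_feature_effects()] over the same features.
#' @param fdr marginal significance level applied to each predictor's
#'   q-values (default 0.025).
#' @return a `reversal_tbl` tibble: `feature_id`, `beta_diet`, `beta_age`,
#'   `q_diet`, `q_age`, `class` (`none`/`diet-only`/`age-only`/`both`) and
#'   `quadrant` (`reversal`/`exacerbation`/`none`).
#' @export
reversal_classification <- function(diet_effects, age_effects, fdr = 0.025) {
  if (!setequal(diet_effects$feature_id, age_effects$feature_id)) {
    abort("diet and age effect records cover different feature sets")
  }
  joined <- dplyr::inner_join(
    dplyr::select(diet_effects, "feature_id", beta_diet = "beta", q_diet = "q"),
    dplyr::select(age_effects, "feature_id", beta_age = "beta", q_age = "q"),
    by = "feature_id")
  joined <- dplyr::mutate(
    joined,
    sig_diet = .data$q_diet <= fdr,
    sig_age = .data$q_age <= fdr,
    class = dplyr::case_when(
      sig_diet & sig_age ~ "both",
      sig_diet ~ "diet-only",
      sig_age ~ "age-only",
      TRUE ~ "none"),
    quadrant = dplyr::case_when(
      class == "none" | beta_diet == 0 | beta_age == 0 ~ "none",
      sign(beta_diet) * sign(beta_age) == -1 ~ "reversal",
      TRUE ~ "exacerbation"))
  out <- dplyr::select(joined, "feature_id", "beta_diet", "beta_age",
                       "q_diet", "q_age", "class", "quadrant")
  structure(out, fdr = fdr, class = c("reversal_tbl", class(out)))
}

#' Summary counts for a reversal classification
#' @param rtbl result of [reversal_classification()].
#' @return tibble of counts by significance class and quadrant.
#' @export
reversal_counts <- function(rtbl) {
  dplyr::count(as_tibble(rtbl), .data$class, .data$quadrant, name = "n_features")
}

#' Venn region counts for named significant-feature sets
#'
#' @param sig_sets named list (>= 2 elements) of feature-id vectors, e.g.
#'   the features altered by diet in each tissue.
#' @return tibble with one logical membership column per set and the count
#'   `n` of features in each region (all non-empty membership patterns,
#'   including zero counts).
#' @export
tissue_overlap_counts <- function(sig_sets) {
  if (length(sig_sets) < 2) abort("need at least 2 sets")
  if (is.null(names(sig_sets)) || any(names(sig_sets) == "")) abort("sets must be named")
  universe <- unique(unlist(sig_sets))
  member <- vapply(sig_sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, names(sig_sets)))
  patterns <- do.call(tidyr::expand_grid,
                      stats::setNames(rep(list(c(TRUE, FALSE)), length(sig_sets)),
                                      names(sig_sets)))
  patterns <- patterns[rowSums(as.matrix(patterns)) > 0, , drop = FALSE]
  pat_key <- apply(as.matrix(patterns), 1, paste, collapse = "")
  obs_key <- apply(member, 1, paste, collapse = "")
  patterns$n <- as.integer(table(factor(obs_key, levels = pat_key)))
  as_tibble(patterns)
}

#' Principal component scores of samples
#'
#' @param ft a complete (imputed) feature table.
#' @param n_components number of leading components to return; truncated
#'   with a warning if it exceeds the matrix rank.
#' @return a `metab_pca` object: list with `scores` (tibble, one row per
#'   sample) and `var_explained` (fraction per returned component).
#' @export
pca_scores <- function(ft, n_components = 2) {
  m <- ft_matrix(ft)
  if (anyNA(m)) abort("PCA requires a complete matrix; impute first")
  fit <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  pos <- fit$sdev > max(fit$sdev) * 1e-10
  rank <- sum(pos)
  if (n_components > rank) {
    warn(sprintf("n_components = %d exceeds rank %d; truncating", n_components, rank))
    n_components <- rank
  }
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- as_tibble(fit$x[, seq_len(n_components), drop = FALSE])
  scores <- dplyr::mutate(scores, sample_id = colnames(m), .before = 1)
  structure(list(scores = scores, var_explained = ve[seq_len(n_components)]),
            class = "metab_pca")
}

#' @export
print.metab_pca <- function(x, ...) {
  cat(sprintf("<metab_pca> %d samples, %d components (%.1f%% variance)\n",
              nrow(x$scores), length(x$var_explained),
              100 * sum(x$var_explained)))
  invisible(x)
}
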