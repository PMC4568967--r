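#' Per-condition signed correlation matrices
#'
#' Splits the samples by a design factor and computes the signed Pearson
#' correlation (adjacency) matrix over the same feature set in each
#' condition. For age comparisons the samples are quantile-normalized first
#' (`qn = TRUE`) so distributional shifts between ages do not masquerade as
#' correlation changes.
#'
#' @param ft complete feature table (one column per biological sample).
#' @param design matching design tibble.
#' @param split_by design column to split on (e.g. `"diet"` or `"age"`).
#' @param qn apply [quantile_normalize()] before splitting.
#' @param min_samples minimum samples per level (default 4).
#' @return named list, one element per level: list with `condition`, `cor`
#'   (features x features), `n` (samples).
#' @export
condition_correlations <- function(ft, design, split_by = "diet", qn = FALSE,
                                   min_samples = 4) {
  design <- design[match(ft_samples(ft), design$sample_id), ]
  if (!split_by %in% names(design)) abort(sprintf("design has no column '%s'", split_by))
  if (qn) ft <- quantile_normalize(ft)
  m <- ft_matrix(ft)
  levels <- sort(unique(design[[split_by]]))
  out <- lapply(levels, function(lev) {
    cols <- design[[split_by]] == lev
    if (sum(cols) < min_samples) {
      abort(sprintf("condition '%s' has %d samples; need >= %d", lev, sum(cols), min_samples))
    }
    list(condition = as.character(lev),
         cor = stats::cor(t(m[, cols, drop = FALSE])),
         n = sum(cols))
  })
  stats::setNames(out, as.character(levels))
}

.cond_cor <- function(x) if (is.list(x)) x$cor else x

check_even_beta <- function(beta_soft) {
  if (beta_soft < 2 || beta_soft %% 2 != 0) {
    abort("beta_soft must be a positive even integer (signed squares stay monotone)")
  }
}

#' Difference matrix between two condition correlation networks (DiffCoEx)
#'
#' `d_ij = (1/2 * |sign(c_ij) c_ij^2 - sign(c'_ij) c'_ij^2|)^(beta_soft/2)`.
#' Entries are large only where the signed-square correlation changes between
#' the two conditions; the even soft power suppresses weak differences.
#' Clustering `1 - TOM(D)` finds modules of coordinated, condition-specific
#' correlation change.
#'
#' @param a,b condition elements from [condition_correlations()] (or bare
#'   correlation matrices) over identical feature sets.
#' @param beta_soft even soft-thresholding power (default 6).
#' @return a `difference_matrix` object: list with `matrix`, `beta_soft`,
#'   `conditions`.
#' @export
difference_matrix <- function(a, b, beta_soft = 6) {
  check_even_beta(beta_soft)
  ca <- .cond_cor(a); cb <- .cond_cor(b)
  if (!identical(dim(ca), dim(cb)) || !identical(rownames(ca), rownames(cb))) {
    abort("condition matrices cover different feature sets")
  }
  d <- (0.5 * abs(sign(ca) * ca^2 - sign(cb) * cb^2))^(beta_soft / 2)
  diag(d) <- 0
  structure(list(matrix = d, beta_soft = beta_soft,
                 conditions = c(if (is.list(a)) a$condition else "A",
                                if (is.list(b)) b$condition else "B")),
            class = "difference_matrix")
}

#' Constancy matrix between two condition correlation networks (SimCoEx)
#'
#' The preservation-seeking mirror of [difference_matrix()]: entries should
#' be large only for pairs strongly correlated with concordant sign in
#' *both* conditions. The default `"min_concordant"` form uses
#' `k_ij = min(|c|, |c'|)^beta_soft` when the signs agree and 0 otherwise,
#' so a pair correlated in a single condition scores essentially zero. The
#' alternative `"signed_sum"` form
#' `k_ij = (1/2 * |sign(c_ij) c_ij^2 + sign(c'_ij) c'_ij^2|)^(beta_soft/2)`
#' is the algebraic mirror of the difference matrix (sum replacing
#' difference); it cancels exactly on sign flips but still awards a
#' single-condition pair a fraction of the fully-preserved score, which
#' makes it leak condition-specific modules into the preserved clustering.
#' The two forms coincide whenever `c = c'`.
#'
#' @inheritParams difference_matrix
#' @param method `"min_concordant"` (default) or `"signed_sum"`.
#' @return a `constancy_matrix` object: list with `matrix`, `beta_soft`,
#'   `conditions`, `method`.
#' @export
constancy_matrix <- function(a, b, beta_soft = 6,
                             method = c("min_concordant", "signed_sum")) {
  method <- match.arg(method)
  check_even_beta(beta_soft)
  ca <- .cond_cor(a); cb <- .cond_cor(b)
  if (!identical(dim(ca), dim(cb)) || !identical(rownames(ca), rownames(cb))) {
    abort("condition matrices cover different feature sets")
  }
  k <- if (method == "signed_sum") {
    (0.5 * abs(sign(ca) * ca^2 + sign(cb) * cb^2))^(beta_soft / 2)
  } else {
    ifelse(sign(ca) == sign(cb), pmin(abs(ca), abs(cb))^beta_soft, 0)
  }
  diag(k) <- 0
  structure(list(matrix = k, beta_soft = beta_soft,
                 conditions = c(if (is.list(a)) a$condition else "A",
                                if (is.list(b)) b$condition else "B"),
                 method = method),
            class = "constancy_matrix")
}

#' Unsigned topological overlap matrix
#'
#' `t_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu`; the diagonal is 1 by convention. Shared-neighbour
#' smoothing of an adjacency in `[0, 1]` before clustering.
#'
#' @param adj symmetric non-negative matrix with entries in `[0, 1]`
#'   (e.g. the matrix of a [difference_matrix()]); the diagonal is ignored.
#' @return the TOM matrix.
#' @export
topological_overlap <- function(adj) {
  if (inherits(adj, c("difference_matrix", "constancy_matrix"))) adj <- adj$matrix
  if (any(adj < 0) || any(adj > 1)) abort("adjacency entries must lie in [0, 1]")
  if (!isSymmetric(unname(adj))) abort("adjacency must be symmetric")
  a <- adj
  diag(a) <- 0
  k <- colSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  t <- num / den
  diag(t) <- 1
  dimnames(t) <- dimnames(adj)
  t
}

# WGCNA-style size-ranked module color palette; "grey" = unassigned.
module_colors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow", "tan",
                   "salmon", "cyan", "midnightblue", "lightcyan")

#' Extract modules from a dissimilarity matrix
#'
#' A simplified dynamic-hybrid cut in the spirit of the tree-cutting used by
#' coexpression network packages. Average-linkage hierarchical clustering of
#' the dissimilarity (typically `1 - TOM` of a difference or constancy
#' matrix) is cut at the greatest height not exceeding `max_height` that
#' yields at least one informative branch (a branch of `min_size` or more
#' features that does not swallow the whole tree); these branches are module
#' *cores*. A medoid-style completion pass then reassigns every feature to
#' the module whose members it is closest to on average, provided it is
#' closer than the midpoint between that module's internal cohesion and the
#' background level — this recovers loosely attached members that only join
#' their branch near the top of the tree and expels accidental core members.
#' Clusters below `min_size` after completion are dissolved. Unassigned
#' features are labelled "grey"; modules are labelled by a size-ranked color
#' palette (the colors themselves are arbitrary).
#'
#' @param dis symmetric dissimilarity matrix with zero diagonal, feature ids
#'   as dimnames.
#' @param min_size minimum module size (default 10).
#' @param max_height maximum dendrogram cut height considered (default
#'   0.996, the conventional ceiling for differential-coexpression trees
#'   whose dissimilarities crowd toward 1).
#' @param completion_passes reassignment passes of the completion stage.
#' @return a `module_assignment` object: list with `modules` (tibble
#'   `feature_id`, `module`), `sizes`, `cut_height`, `mean_silhouette`
#'   (mean silhouette width over assigned features when two or more modules
#'   are found).
#' @export
cluster_modules <- function(dis, min_size = 10, max_height = 0.996,
                            completion_passes = 2) {
  if (is.null(rownames(dis))) rownames(dis) <- colnames(dis) <- paste0("f", seq_len(nrow(dis)))
  p <- nrow(dis)
  grey_out <- function() {
    modules <- tibble(feature_id = rownames(dis), module = "grey")
    structure(list(modules = modules,
                   sizes = dplyr::count(modules, .data$module, name = "size"),
                   cut_height = NA_real_, mean_silhouette = NA_real_),
              class = "module_assignment")
  }
  if (p < min_size) return(grey_out())
  hc <- stats::hclust(stats::as.dist(dis), method = "average")
  # ties can leave numerically non-monotone merge heights, which cutree rejects
  if (is.unsorted(hc$height)) hc$height <- cummax(hc$height)
  heights <- sort(unique(hc$height[hc$height <= max_height]), decreasing = TRUE)
  if (!length(heights)) return(grey_out())

  # greatest cut height whose branches include an informative core
  cl <- NULL
  cut_h <- NA_real_
  for (h in heights) {
    cand <- stats::cutree(hc, h = h)
    sizes <- table(cand)
    keep <- names(sizes)[sizes >= min_size]
    if (!length(keep)) break  # lower cuts only fragment further
    if (length(keep) == 1 && sizes[keep] == p) next  # everything in one branch
    cl <- ifelse(cand %in% as.integer(keep), cand, NA)
    cut_h <- h
    break
  }
  if (is.null(cl)) return(grey_out())

  # completion: assign each feature to its nearest module when closer than
  # the midpoint of that module's cohesion and the background level
  for (pass in seq_len(completion_passes)) {
    mods <- sort(unique(cl[!is.na(cl)]))
    if (!length(mods)) return(grey_out())
    mdist <- vapply(mods, function(mm) {
      members <- which(cl == mm & !is.na(cl))
      rowSums(dis[, members, drop = FALSE]) / length(members)
    }, numeric(p))
    mdist <- matrix(mdist, nrow = p)
    new_cl <- rep(NA_real_, p)
    for (ci in seq_along(mods)) {
      members <- which(cl == mods[ci] & !is.na(cl))
      within <- mean(dis[members, members][upper.tri(diag(length(members)))])
      outside <- mean(mdist[-members, ci])
      thresh <- (within + outside) / 2
      cand <- which(mdist[, ci] < thresh &
                      mdist[, ci] == apply(mdist, 1, min))
      new_cl[cand] <- mods[ci]
    }
    cl <- new_cl
    sizes <- table(cl)
    cl[cl %in% as.numeric(names(sizes)[sizes < min_size])] <- NA
    if (!any(!is.na(cl))) return(grey_out())
  }

  # size-ranked color labels
  ord <- names(sort(table(cl), decreasing = TRUE))
  labels <- stats::setNames(
    c(module_colors, paste0("module", seq_len(max(0, length(ord) - length(module_colors)))))[
      seq_along(ord)], ord)
  module <- ifelse(is.na(cl), "grey", labels[as.character(cl)])
  modules <- tibble(feature_id = rownames(dis), module = unname(module))
  assigned <- which(!is.na(cl))
  sil <- if (length(unique(cl[assigned])) >= 2) {
    mean(cluster::silhouette(cl[assigned],
                             dmatrix = dis[assigned, assigned])[, "sil_width"])
  } else NA_real_
  structure(list(modules = modules,
                 sizes = dplyr::count(modules, .data$module, name = "size", sort = TRUE),
                 cut_height = cut_h,
                 mean_silhouette = sil),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  n_mod <- sum(x$sizes$module != "grey")
  cat(sprintf("<module_assignment> %d features, %d modules (+%d grey)\n",
              nrow(x$modules), n_mod,
              sum(x$modules$module == "grey")))
  invisible(x)
}

#' Difference- or constancy-based module detection from data
#'
#' Convenience wrapper: per-condition correlations, difference (`mode =
#' "diffcoex"`) or constancy (`mode = "simcoex"`) matrix, TOM, then
#' [cluster_modules()] on `1 - TOM`. In difference mode, candidate modules
#' are by default screened two ways, and modules failing either screen are
#' dissolved to grey:
#'
#' 1. the label-permutation dispersion test (the differential-coexpression
#'    method's own significance step): at modest sample sizes the sampling
#'    variance of correlation estimates scales with the underlying
#'    correlation, so a strongly *preserved* module also shows mildly
#'    elevated difference-matrix entries — the permutation null, which
#'    keeps the pooled correlation structure while scrambling the
#'    condition labels, removes most such clusters;
#' 2. a constancy-dominance check: a module whose mean within-module
#'    constancy score exceeds its mean within-module difference score is
#'    shared structure whose *level* happens to differ between the
#'    realized samples, not a change in kind — significance alone cannot
#'    make that distinction, because a realized level difference is a
#'    genuine (if uninteresting) label effect. Comparing the package's two
#'    transforms head to head is parameter-free and keeps modules whose
#'    correlations flip sign, appear, or vanish, while dissolving those
#'    that are strong and sign-concordant in both conditions.
#'
#' @inheritParams condition_correlations
#' @param mode `"diffcoex"` or `"simcoex"`.
#' @param beta_soft even soft power.
#' @param min_size minimum module size.
#' @param conditions optionally, two level names to compare (defaults to the
#'   first two levels of `split_by`).
#' @param max_height passed to [cluster_modules()].
#' @param filter `"permutation"` (default; applied in difference mode only)
#'   or `"none"`.
#' @param filter_alpha significance level of the dispersion screen.
#' @param filter_n_perm permutations used by the screen.
#' @param seed seed for the permutation screen.
#' @return a `module_assignment`.
#' @export
coex_modules <- function(ft, design, split_by = "diet", mode = c("diffcoex", "simcoex"),
                         beta_soft = 6, min_size = 10, qn = FALSE, conditions = NULL,
                         max_height = 0.996, filter = c("permutation", "none"),
                         filter_alpha = 0.05, filter_n_perm = 200, seed = 1L) {
  mode <- match.arg(mode)
  filter <- match.arg(filter)
  cors <- condition_correlations(ft, design, split_by = split_by, qn = qn)
  if (is.null(conditions)) conditions <- names(cors)[1:2]
  a <- cors[[conditions[1]]]; b <- cors[[conditions[2]]]
  adj <- if (mode == "diffcoex") difference_matrix(a, b, beta_soft) else
    constancy_matrix(a, b, beta_soft)
  tom <- topological_overlap(adj$matrix)
  out <- cluster_modules(1 - tom, min_size = min_size, max_height = max_height)
  if (mode == "diffcoex" && filter == "permutation" &&
      any(out$modules$module != "grey")) {
    disp <- module_dispersion_test(ft, design, out, split_by = split_by,
                                   conditions = conditions, beta_soft = beta_soft,
                                   n_perm = filter_n_perm, seed = seed)
    drop <- disp$module[disp$p > filter_alpha]
    # constancy-dominance: preserved structure with a realized level
    # difference is not a change in kind
    kmat <- constancy_matrix(a, b, beta_soft)$matrix
    for (mod in setdiff(unique(out$modules$module), c("grey", drop))) {
      idx <- which(out$modules$module == mod)
      ut <- upper.tri(diag(length(idx)))
      if (mean(kmat[idx, idx][ut]) > mean(adj$matrix[idx, idx][ut])) {
        drop <- c(drop, mod)
      }
    }
    if (length(drop)) {
      out$modules$module[out$modules$module %in% drop] <- "grey"
      out$sizes <- dplyr::count(out$modules, .data$module, name = "size", sort = TRUE)
    }
  }
  out
}

#' Permutation test of module dispersion between conditions
#'
#' A module found on the difference matrix is significant when its members'
#' correlations really do change between conditions more than label noise
#' allows. The observed statistic per module is the dispersion
#' `sqrt(mean d_ij^2)` over within-module pairs; the null distribution is
#' built by permuting the condition labels across samples and recomputing.
#' `p = (1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param ft complete feature table.
#' @param design matching design.
#' @param modules a `module_assignment` (grey features are skipped).
#' @param split_by condition factor (default `"diet"`).
#' @param conditions two level names (defaults to first two).
#' @param beta_soft even soft power used for the difference matrix.
#' @param n_perm number of permutations (>= 10; < 100 draws a warning).
#' @param seed integer seed.
#' @return tibble: `module`, `size`, `dispersion`, `p`.
#' @export
module_dispersion_test <- function(ft, design, modules, split_by = "diet",
                                   conditions = NULL, beta_soft = 6,
                                   n_perm = 1000, seed = 1L) {
  if (n_perm < 10) abort("n_perm must be at least 10")
  if (n_perm < 100) warn("n_perm < 100 gives a coarse permutation p-value")
  design <- design[match(ft_samples(ft), design$sample_id), ]
  fac <- design[[split_by]]
  levs <- if (is.null(conditions)) sort(unique(fac))[1:2] else conditions
  keep <- fac %in% levs
  m <- ft_matrix(ft)[, keep, drop = FALSE]
  fac <- fac[keep]
  mod_tbl <- modules$modules[modules$modules$module != "grey", ]
  mods <- split(mod_tbl$feature_id, mod_tbl$module)
  if (!length(mods)) return(tibble(module = character(), size = integer(),
                                   dispersion = numeric(), p = numeric()))

  disp_one <- function(sub, grp) {
    ca <- stats::cor(t(sub[, grp == levs[1], drop = FALSE]))
    cb <- stats::cor(t(sub[, grp == levs[2], drop = FALSE]))
    d <- (0.5 * abs(sign(ca) * ca^2 - sign(cb) * cb^2))^(beta_soft / 2)
    sqrt(mean(d[upper.tri(d)]^2))
  }
  set.seed(seed)
  out <- lapply(names(mods), function(name) {
    feats <- mods[[name]]
    sub <- m[feats, , drop = FALSE]
    obs <- disp_one(sub, fac)
    null <- vapply(seq_len(n_perm), function(i) disp_one(sub, sample(fac)), numeric(1))
    tibble(module = name, size = length(feats), dispersion = obs,
           p = (1 + sum(null >= obs)) / (1 + n_perm))
  })
  dplyr::bind_rows(out)
}

#' Test for a shift in the correlation distribution between conditions
#'
#' Compares the mean off-diagonal correlation between two condition
#' networks. The pairwise correlations are heavily dependent (every pair
#' shares samples with every other), so significance comes from permutation.
#' When the per-condition sample matrices are supplied (`data_a`/`data_b`,
#' features x samples), the null is built by permuting the condition labels
#' across the pooled samples and recomputing both mean correlations — the
#' exact exchangeability argument, and the calibrated default. With only the
#' correlation matrices available, a paired sign-flip permutation over the
#' per-feature mean correlation differences is used instead; that null
#' ignores the common sampling component shared by all features and is
#' anti-conservative, so it is flagged in the `method` column. A naive
#' paired t-test over features is reported as `p_naive` for description
#' only.
#'
#' @param a,b condition elements from [condition_correlations()] or bare
#'   correlation matrices over identical feature sets.
#' @param features optional feature-id subset (>= 3 features).
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param data_a,data_b optional features x samples matrices the two
#'   correlation matrices were computed from (same feature order).
#' @return one-row tibble: `mean_a`, `mean_b`, `diff`, `p`, `p_naive`,
#'   `method`, `n_features`.
#' @export
correlation_shift_test <- function(a, b, features = NULL, n_perm = 1000, seed = 1L,
                                   data_a = NULL, data_b = NULL) {
  ca <- .cond_cor(a); cb <- .cond_cor(b)
  if (!identical(dim(ca), dim(cb))) abort("condition matrices cover different feature sets")
  if (!is.null(features)) {
    ca <- ca[features, features, drop = FALSE]
    cb <- cb[features, features, drop = FALSE]
    if (!is.null(data_a)) data_a <- data_a[features, , drop = FALSE]
    if (!is.null(data_b)) data_b <- data_b[features, , drop = FALSE]
  }
  nf <- nrow(ca)
  if (nf < 3) abort("need at least 3 features")
  off_mean <- function(x) mean(x[upper.tri(x)])
  mean_a <- off_mean(ca); mean_b <- off_mean(cb)
  obs <- mean_a - mean_b
  # per-feature mean correlation difference, for the descriptive t-test
  delta <- (rowSums(ca) - 1) / (nf - 1) - (rowSums(cb) - 1) / (nf - 1)
  set.seed(seed)
  if (!is.null(data_a) && !is.null(data_b)) {
    pooled <- cbind(data_a, data_b)
    na <- ncol(data_a)
    null <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(ncol(pooled))
      .mean_offdiag_cor(pooled[, idx[seq_len(na)], drop = FALSE]) -
        .mean_offdiag_cor(pooled[, idx[-seq_len(na)], drop = FALSE])
    }, numeric(1))
    method <- "label_permutation"
  } else {
    null <- vapply(seq_len(n_perm), function(i) {
      mean(delta * sample(c(-1, 1), nf, replace = TRUE))
    }, numeric(1))
    method <- "sign_flip"
  }
  p_perm <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm)
  p_naive <- tryCatch(stats::t.test(delta)$p.value, error = function(e) NA_real_)
  tibble(mean_a = mean_a, mean_b = mean_b, diff = obs, p = p_perm,
         p_naive = p_naive, method = method, n_features = nf)
}

# mean off-diagonal Pearson correlation without forming the full matrix:
# with rows standardized to unit norm, sum_{fg} cor_fg = ||colSums(z)||^2
.mean_offdiag_cor <- function(x) {
  z <- x - rowMeans(x)
  norms <- sqrt(rowSums(z^2))
  norms[norms == 0] <- Inf  # constant features contribute zero correlation
  z <- z / norms
  p <- nrow(z)
  (sum(colSums(z)^2) - sum(rowSums(z^2))) / (p * (p - 1))
}

#' Select features with diet-specific or diet-preserved correlations
#'
#' Per-pair correlation significance in each condition uses the t-statistic
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)`. A feature is `differential` when it
#' has at least one pair significant in exactly one condition and no pair
#' significant in both; `similar` when it has at least one pair significant
#' in both conditions with concordant sign. These subsets feed the
#' difference- and constancy-matrix clustering respectively.
#'
#' @param a,b condition elements from [condition_correlations()] (must carry
#'   sample counts `n`).
#' @param alpha per-pair significance level (default 0.01).
#' @return tibble: `feature_id`, `status` in
#'   `differential`/`similar`/`neither`.
#' @export
differential_feature_selection <- function(a, b, alpha = 0.01) {
  if (!is.list(a) || !is.list(b)) abort("a and b must be condition_correlations() elements")
  pa <- .cor_pmat(a$cor, a$n)
  pb <- .cor_pmat(b$cor, b$n)
  sig_a <- pa < alpha; sig_b <- pb < alpha
  diag(sig_a) <- diag(sig_b) <- FALSE
  both <- sig_a & sig_b
  one <- xor(sig_a, sig_b)
  concord <- both & (sign(a$cor) == sign(b$cor))
  differential <- rowSums(one) > 0 & rowSums(both) == 0
  similar <- rowSums(concord) > 0
  tibble(feature_id = rownames(a$cor),
         status = dplyr::case_when(differential ~ "differential",
                                   similar ~ "similar",
                                   TRUE ~ "neither"))
}

.cor_pmat <- function(r, n) {
  r2 <- pmin(abs(r), 1 - 1e-15)
  t <- r2 * sqrt(n - 2) / sqrt(1 - r2^2)
  2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
}

#' Edge list for graph export
#'
#' Pairs with `|r| > threshold` in either condition, with both conditions'
#' correlations. The threshold is a rendering choice, not part of inference.
#' @param a,b condition elements or matrices.
#' @param threshold minimum absolute correlation (default 0.5).
#' @param features optional feature subset.
#' @export
correlation_edges <- function(a, b, threshold = 0.5, features = NULL) {
  ca <- .cond_cor(a); cb <- .cond_cor(b)
  if (!is.null(features)) {
    ca <- ca[features, features, drop = FALSE]
    cb <- cb[features, features, drop = FALSE]
  }
  idx <- which(upper.tri(ca) & (abs(ca) > threshold | abs(cb) > threshold),
               arr.ind = TRUE)
  tibble(feature_i = rownames(ca)[idx[, 1]], feature_j = colnames(ca)[idx[, 2]],
         r_cond1 = ca[idx], r_cond2 = cb[idx])
}
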