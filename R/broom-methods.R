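#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a module assignment into a feature-module tibble
#' @param x a `module_assignment` from [cluster_modules()].
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.module_assignment <- function(x, ...) x$modules

#' One-row summary of a module assignment
#' @param x a `module_assignment`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.module_assignment <- function(x, ...) {
  tibble(n_features = nrow(x$modules),
         n_modules = sum(x$sizes$module != "grey"),
         n_grey = sum(x$modules$module == "grey"),
         largest_module = max(c(0L, x$sizes$size[x$sizes$module != "grey"])),
         cut_height = x$cut_height,
         mean_silhouette = x$mean_silhouette)
}

#' Tidy PCA sample scores
#' @param x a `metab_pca` from [pca_scores()].
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.metab_pca <- function(x, ...) x$scores

#' One-row summary of a PCA
#' @param x a `metab_pca`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.metab_pca <- function(x, ...) {
  tibble(n_components = length(x$var_explained),
         var_explained_total = sum(x$var_explained),
         var_explained_pc1 = x$var_explained[1])
}

#' Tidy a full pipeline run into its per-stage row counts
#' @param x a `metanet_run` from [run_full()].
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.metanet_run <- function(x, ...) {
  purrr::map_dfr(names(x$manifest$stages), function(nm) {
    s <- x$manifest$stages[[nm]]
    tibble(stage = nm,
           features_in = s$features_in, features_out = s$features_out,
           samples_in = s$samples_in, samples_out = s$samples_out)
  })
}

#' One-row summary of a full pipeline run
#' @param x a `metanet_run`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.metanet_run <- function(x, ...) {
  tibble(n_stages = length(x$manifest$stages),
         n_features_clean = nrow(x$qc$features),
         n_pairs_tested = nrow(x$pairs),
         n_reversal = if (is.null(x$reversal)) NA_integer_ else
           sum(x$reversal$quadrant == "reversal" & x$reversal$class == "both"),
         seed = x$manifest$seed)
}
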