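#' Default adduct table for m/z annotation
#'
#' Charge-carrying mass offsets (Da) relating a neutral monoisotopic mass M
#' to an observed singly-charged m/z: protonation/deprotonation, sodium and
#' potassium adducts, and the bare radical cation (electron loss).
#' @return tibble with `adduct` and `shift`.
#' @export
default_adducts <- function() {
  tibble(adduct = c("M+H", "M+Na", "M+K", "M-H", "M+"),
         shift = c(1.007276, 22.989218, 38.963158, -1.007276, -0.00054858))
}

#' Putative metabolite annotation by m/z matching
#'
#' A feature matches a reference metabolite when, for some allowed adduct,
#' the relative deviation of the observed m/z from the expected m/z
#' `M + shift` is within `ppm` parts per million. All candidates are kept
#' (annotation is many-to-many); ambiguity is resolved downstream by
#' collapsing to unique metabolites.
#'
#' @param features a feature table or a tibble with `feature_id` and `mz`.
#' @param reference tibble with `metabolite` and monoisotopic `mass` (Da).
#' @param adducts adduct table as from [default_adducts()].
#' @param ppm tolerance in parts per million (default 10).
#' @return tibble: `feature_id`, `mz`, `metabolite`, `adduct`,
#'   `expected_mz`, `ppm_error`.
#' @export
annotate_mz <- function(features, reference, adducts = default_adducts(), ppm = 10) {
  if (!nrow(reference)) abort("empty metabolite reference")
  if (any(reference$mass <= 0)) abort("reference masses must be positive")
  if (anyDuplicated(reference$metabolite)) abort("reference metabolite names must be unique")
  feats <- as_tibble(features)[c("feature_id", "mz")]
  cand <- tidyr::expand_grid(reference, adducts)
  cand$expected_mz <- cand$mass + cand$shift
  cand <- cand[cand$expected_mz > 0, ]
  out <- dplyr::cross_join(feats, cand)
  out$ppm_error <- 1e6 * abs(out$mz - out$expected_mz) / out$expected_mz
  out <- out[out$ppm_error <= ppm, ]
  dplyr::arrange(
    dplyr::select(out, "feature_id", "mz", "metabolite", "adduct",
                  "expected_mz", "ppm_error"),
    .data$feature_id, .data$ppm_error)
}

#' Hypergeometric metabolite-set enrichment
#'
#' The metabolomic analogue of gene-set over-representation: features are
#' collapsed to their unique putative metabolites (avoiding multiplicity
#' inflation from many-to-many annotation), and each named set is tested
#' with an upper-tail hypergeometric p-value on the metabolite-level
#' overlap, BH-adjusted across sets.
#'
#' @param query feature ids of interest (must be annotated; a subset of the
#'   universe).
#' @param annotation annotation tibble from [annotate_mz()].
#' @param sets named list of metabolite-id vectors (pathways).
#' @param universe feature ids forming the background; default all features
#'   in `annotation`.
#' @param fdr_level BH level for the `significant` flag.
#' @param direction optional label (`"increased"`/`"decreased"`) recorded on
#'   the result.
#' @return tibble sorted by `p`: `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `q`, `significant` (+ `direction` if given).
#' @export
set_enrichment <- function(query, annotation, sets, universe = NULL,
                           fdr_level = 0.05, direction = NULL) {
  if (is.null(universe)) universe <- unique(annotation$feature_id)
  if (!length(universe)) abort("empty annotation universe")
  if (!all(query %in% universe)) abort("query features must be contained in the universe")
  met_of <- function(ids) unique(annotation$metabolite[annotation$feature_id %in% ids])
  uni_mets <- met_of(universe)
  query_mets <- met_of(query)
  N <- length(uni_mets)
  n <- length(query_mets)
  res <- purrr::map_dfr(names(sets), function(nm) {
    set_mets <- intersect(unique(sets[[nm]]), uni_mets)
    K <- length(set_mets)
    k <- length(intersect(set_mets, query_mets))
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set = nm, overlap = k, set_size = K, query_size = n,
           universe_size = N, p = p)
  })
  adj <- bh_adjust(res$p, fdr = fdr_level)
  res$q <- adj$q
  res$significant <- adj$significant
  if (!is.null(direction)) res$direction <- direction
  dplyr::arrange(res, .data$p)
}

#' Cross-condition enrichment frequency table
#'
#' Given per-condition lists of enriched set names (e.g. head, abdomen,
#' thorax and whole body at several ages), marks each set's presence per
#' condition and counts the number of conditions in which it was enriched,
#' sorted by descending frequency. Sets enriched nowhere are omitted.
#'
#' @param per_condition named list: condition -> character vector of
#'   enriched set names.
#' @return tibble: `set`, one `"X"`/`""` column per condition, `frequency`.
#' @export
summarize_frequency <- function(per_condition) {
  if (is.null(names(per_condition)) || any(names(per_condition) == "")) {
    abort("conditions must be named")
  }
  all_sets <- unique(unlist(per_condition))
  if (!length(all_sets)) {
    return(tibble(set = character(), frequency = integer()))
  }
  marks <- vapply(per_condition, function(s) ifelse(all_sets %in% s, "X", ""),
                  character(length(all_sets)))
  marks <- matrix(marks, nrow = length(all_sets),
                  dimnames = list(NULL, names(per_condition)))
  out <- dplyr::bind_cols(tibble(set = all_sets), as_tibble(marks))
  out$frequency <- rowSums(marks == "X")
  dplyr::arrange(out, dplyr::desc(.data$frequency), .data$set)
}

#' Read and write GMT pathway-set files
#'
#' GMT is the tab-separated gene/metabolite set format: one set per line as
#' `name <tab> description <tab> member1 <tab> member2 ...`.
#' @param path file path.
#' @return named list of member-id vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(x) x[-(1:2)]),
                  vapply(parts, `[`, character(1), 1))
}

#' @rdname read_gmt
#' @param sets named list of member-id vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
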