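#' Assemble a pipeline configuration
#'
#' Bundles the tunable thresholds of every stage with their standard
#' defaults: SNR >= 20 and <= 10% missingness for QC with sample-outlier
#' cutoff Z_k = -3; P < 0.01 for the per-tissue Venn comparison; marginal
#' FDR = 0.025 for the reversal quadrant analysis and FDR = 0.05 elsewhere;
#' mean-gate p > 0.05 for the differential-pair screen; soft power 6,
#' minimum module size 10 and 1000 label permutations for the network
#' stage. A single global `seed` fans out to per-stage seeds by fixed
#' offsets so stages are independently re-runnable.
#'
#' @param synth a [synth_config()] used when simulating input data.
#' @param snr,max_missing,z_cut,impute_method QC parameters.
#' @param venn_p,reversal_fdr,default_fdr model-stage thresholds.
#' @param mean_gate,paircorr_min_cor_diff,paircorr_max_pairs
#'   differential-pair screen parameters.
#' @param beta_soft,min_module,n_perm,diff_alpha network parameters.
#' @param seed global integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            snr = 20, max_missing = 0.10, z_cut = -3,
                            impute_method = "knn",
                            venn_p = 0.01, reversal_fdr = 0.025, default_fdr = 0.05,
                            mean_gate = 0.05, paircorr_min_cor_diff = 0.3,
                            paircorr_max_pairs = 20000,
                            beta_soft = 6, min_module = 10, n_perm = 1000,
                            diff_alpha = 0.01,
                            seed = 1L) {
  cfg <- as.list(environment())
  cfg$synth$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv_out <- function(x, outdir, name) {
  path <- file.path(outdir, name)
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  path
}

#' Run the full analysis pipeline on synthetic (or supplied) data
#'
#' Executes, in order: data simulation (or loading), quality control,
#' per-feature diet and age effect models with the reversal-quadrant
#' analysis, Venn overlap counts and PCA, the differential-correlation pair
#' screen, diet- and age-split network analysis (difference and constancy
#' modules, dispersion permutation tests, correlation-distribution
#' summaries, edge export), and metabolite-set enrichment with the
#' cross-condition frequency table. Every stage logs features/samples in
#' and out; all artifacts are plain TSV/JSON in `outdir` plus a manifest
#' recording versions, seeds, parameters and per-stage row counts.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing).
#' @param sim optionally a precomputed `metab_sim`; default simulates from
#'   `config$synth`.
#' @param quiet suppress progress messages.
#' @return a `metanet_run` list with the manifest and the in-memory stage
#'   results.
#' @export
run_full <- function(config = pipeline_config(), outdir = tempfile("metacoex_run_"),
                     sim = NULL, quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(package = "metacoex",
                   version = as.character(utils::packageVersion("metacoex")),
                   seed = config$seed,
                   parameters = config[setdiff(names(config), "synth")],
                   synth = config$synth[setdiff(names(config$synth), "mz_ranges")],
                   started = format(Sys.time(), tz = "UTC"),
                   stages = list())
  stage <- function(name, features_in, samples_in, features_out, samples_out) {
    manifest$stages[[name]] <<- list(features_in = features_in, samples_in = samples_in,
                                     features_out = features_out, samples_out = samples_out)
    say("[%s] features %d -> %d, samples %d -> %d", name,
        features_in, features_out, samples_in, samples_out)
  }
  fail <- function(name, msg) abort(sprintf("stage '%s' failed: %s", name, msg))

  # -- synth ----------------------------------------------------------------
  if (is.null(sim)) sim <- simulate_features(make_design(config$synth), config$synth)
  ft <- sim$features
  write_feature_table(ft, file.path(outdir, "features_raw.tsv"))
  readr::write_tsv(sim$design, file.path(outdir, "metadata.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth_features, file.path(outdir, "truth_features.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth_samples, file.path(outdir, "truth_samples.tsv"), progress = FALSE)
  stage("synth", nrow(ft), length(ft_samples(ft)), nrow(ft), length(ft_samples(ft)))

  # -- qc -------------------------------------------------------------------
  qc <- run_qc(ft, sim$design, threshold = config$snr, max_frac = config$max_missing,
               z_cut = config$z_cut, method = config$impute_method)
  clean <- qc$features
  bio_design <- qc$design
  if (nrow(clean) == 0) fail("qc", "no features survive quality control")
  write_feature_table(clean, file.path(outdir, "qc_clean.tsv"))
  write_tsv_out(qc$report, outdir, "qc_report.tsv")
  stage("qc", nrow(ft), length(ft_samples(ft)), nrow(clean), length(ft_samples(clean)))

  # -- models ---------------------------------------------------------------
  if (nrow(clean) == 0) fail("models", "empty input")
  # remove measurement-batch effects before any pooled modelling or network
  # analysis, preserving the design factors that vary
  covs <- c("diet", "age")[c(length(unique(bio_design$diet)) > 1,
                             length(unique(bio_design$age)) > 1)]
  clean <- suppressMessages(
    batch_adjust(clean, bio_design, covariates = if (length(covs)) covs else NULL))
  young <- min(bio_design$age)
  old <- max(bio_design$age)
  diet_eff <- fit_feature_effects(clean, bio_design, "diet", at_age = old,
                                  fdr = config$reversal_fdr)
  age_eff <- if (old > young) {
    fit_feature_effects(clean, bio_design, "age", on_diet = "AL",
                        ages = c(young, old), fdr = config$reversal_fdr)
  } else NULL
  write_tsv_out(diet_eff, outdir, "effects_diet.tsv")
  if (!is.null(age_eff)) write_tsv_out(age_eff, outdir, "effects_age.tsv")
  stage("effects", nrow(clean), length(ft_samples(clean)), nrow(clean),
        length(ft_samples(clean)))
  rev_tbl <- NULL
  if (!is.null(age_eff)) {
    rev_tbl <- reversal_classification(diet_eff, age_eff, fdr = config$reversal_fdr)
    write_tsv_out(rev_tbl, outdir, "reversal.tsv")
  }
  # per-age significant sets at the Venn threshold (unadjusted p)
  per_age <- lapply(sort(unique(bio_design$age)), function(a) {
    eff <- fit_feature_effects(clean, bio_design, "diet", at_age = a)
    eff$feature_id[eff$p < config$venn_p]
  })
  names(per_age) <- paste0("age", sort(unique(bio_design$age)))
  venn <- if (length(per_age) >= 2) tissue_overlap_counts(per_age) else NULL
  if (!is.null(venn)) write_tsv_out(venn, outdir, "venn_counts.tsv")
  pca <- pca_scores(clean, n_components = 2)
  write_tsv_out(pca$scores, outdir, "pca_scores.tsv")
  stage("reversal", nrow(clean), length(ft_samples(clean)), nrow(clean),
        length(ft_samples(clean)))

  # -- paircorr -------------------------------------------------------------
  pairs <- screen_differential_pairs(
    clean, bio_design, mean_gate_alpha = config$mean_gate, fdr = config$default_fdr,
    min_cor_diff = config$paircorr_min_cor_diff,
    max_pairs = config$paircorr_max_pairs, seed = config$seed + 2L)
  write_tsv_out(pairs, outdir, "paircorr.tsv")
  stage("paircorr", nrow(clean), length(ft_samples(clean)), nrow(clean),
        length(ft_samples(clean)))
  manifest$stages$paircorr$n_pairs_tested <- nrow(pairs)

  # -- network (diet split) -------------------------------------------------
  diet_cors <- condition_correlations(clean, bio_design, split_by = "diet")
  selection <- differential_feature_selection(diet_cors$AL, diet_cors$DR,
                                              alpha = config$diff_alpha)
  write_tsv_out(selection, outdir, "network_feature_selection.tsv")
  net_results <- list(selection = selection)
  for (mode in c("diffcoex", "simcoex")) {
    subset_ids <- selection$feature_id[
      selection$status == if (mode == "diffcoex") "differential" else "similar"]
    if (length(subset_ids) < config$min_module) {
      say("[network] %s: %d selected features, fewer than min module size; skipping",
          mode, length(subset_ids))
      next
    }
    sub <- ft_subset(clean, clean$feature_id %in% subset_ids)
    mods <- coex_modules(sub, bio_design, split_by = "diet", mode = mode,
                         beta_soft = config$beta_soft, min_size = config$min_module)
    disp <- module_dispersion_test(sub, bio_design, mods, split_by = "diet",
                                   beta_soft = config$beta_soft,
                                   n_perm = config$n_perm, seed = config$seed + 3L)
    write_tsv_out(mods$modules, outdir, sprintf("network_modules_%s.tsv", mode))
    write_tsv_out(disp, outdir, sprintf("module_dispersion_%s.tsv", mode))
    net_results[[mode]] <- list(modules = mods, dispersion = disp)
  }
  edges <- correlation_edges(diet_cors$AL, diet_cors$DR, threshold = 0.5)
  write_tsv_out(edges, outdir, "edges_diet.tsv")
  write_graphml(edges, file.path(outdir, "edges_diet.graphml"))
  cm <- ft_matrix(clean)
  diet_of <- bio_design$diet[match(colnames(cm), bio_design$sample_id)]
  shift <- correlation_shift_test(
    diet_cors$DR, diet_cors$AL, n_perm = config$n_perm, seed = config$seed + 4L,
    data_a = cm[, diet_of == "DR", drop = FALSE],
    data_b = cm[, diet_of == "AL", drop = FALSE])
  corr_summary <- dplyr::mutate(shift, comparison = "DR_vs_AL", .before = 1)

  # -- network (age split, per diet, quantile-normalized) -------------------
  ages <- sort(unique(bio_design$age))
  if (length(ages) >= 2) {
    for (d in unique(bio_design$diet)) {
      keep <- bio_design$diet == d & bio_design$age %in% range(ages)
      sub_design <- bio_design[keep, ]
      sub <- new_feature_tbl(
        as_tibble(clean)[c(ft_key_cols, sub_design$sample_id)], ft_scale(clean))
      sub <- quantile_normalize(sub)
      age_cors <- condition_correlations(sub, sub_design, split_by = "age")
      old_lab <- as.character(max(ages)); young_lab <- as.character(min(ages))
      sm <- ft_matrix(sub)
      age_of <- sub_design$age[match(colnames(sm), sub_design$sample_id)]
      sh <- correlation_shift_test(
        age_cors[[old_lab]], age_cors[[young_lab]],
        n_perm = config$n_perm, seed = config$seed + 5L,
        data_a = sm[, age_of == max(ages), drop = FALSE],
        data_b = sm[, age_of == min(ages), drop = FALSE])
      corr_summary <- dplyr::bind_rows(
        corr_summary,
        dplyr::mutate(sh, comparison = sprintf("%s_age%s_vs_age%s", d, old_lab, young_lab),
                      .before = 1))
    }
  }
  write_tsv_out(corr_summary, outdir, "correlation_summary.tsv")
  stage("network", nrow(clean), length(ft_samples(clean)), nrow(clean),
        length(ft_samples(clean)))
  manifest$stages$network$n_selected <- sum(selection$status != "neither")

  # -- enrich ---------------------------------------------------------------
  ref <- simulate_pathway_reference(sim, seed = config$seed + 6L)
  ann <- annotate_mz(ft_keys(sim$features), ref$reference)
  per_condition <- list()
  enrich_all <- NULL
  for (a in sort(unique(bio_design$age))) {
    eff <- fit_feature_effects(clean, bio_design, "diet", at_age = a,
                               fdr = config$default_fdr)
    sig <- intersect(eff$feature_id[eff$significant], unique(ann$feature_id))
    cond <- paste0("age", a)
    if (!length(sig)) { per_condition[[cond]] <- character(0); next }
    er <- set_enrichment(sig, ann, ref$sets,
                         universe = intersect(clean$feature_id, unique(ann$feature_id)),
                         fdr_level = config$default_fdr)
    enrich_all <- dplyr::bind_rows(enrich_all, dplyr::mutate(er, condition = cond, .before = 1))
    per_condition[[cond]] <- er$set[er$significant]
  }
  freq <- summarize_frequency(per_condition)
  if (!is.null(enrich_all)) write_tsv_out(enrich_all, outdir, "enrichment.tsv")
  write_tsv_out(freq, outdir, "enrichment_frequency.tsv")
  stage("enrich", nrow(clean), length(ft_samples(clean)), nrow(clean),
        length(ft_samples(clean)))
  manifest$stages$enrich$n_sets_reported <- nrow(freq)

  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(manifest = manifest, outdir = outdir, sim = sim,
                 qc = qc, diet_effects = diet_eff, age_effects = age_eff,
                 reversal = rev_tbl, venn = venn, pca = pca, pairs = pairs,
                 network = net_results, correlation_summary = corr_summary,
                 enrichment = enrich_all, frequency = freq),
            class = "metanet_run")
}

#' @export
print.metanet_run <- function(x, ...) {
  cat(sprintf("<metanet_run> %d stages completed, outputs in %s\n",
              length(x$manifest$stages), x$outdir))
  invisible(x)
}

# GraphML export of an edge list; falls back to a no-op when igraph is absent.
write_graphml <- function(edges, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) return(invisible(NULL))
  if (!nrow(edges)) {
    g <- igraph::make_empty_graph()
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
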