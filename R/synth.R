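#' Configuration for the synthetic metabolome generator
#'
#' The generator emulates the design of a two-diet (ad libitum vs dietary
#' restriction) *Drosophila* aging study: a full factorial of diet x age x
#' tissue with six biological replicates per cell, each measured as several
#' technical replicates on an LC-MS platform, plus the imperfections that
#' drive quality control — batch shifts, missing values, low signal-to-noise
#' features, and optional outlier samples. Correlated metabolite modules are
#' planted through a latent-factor construction (loading `sqrt(r)` on a
#' shared per-condition factor, residual `sqrt(1 - r)`), which gives an
#' analytically known expected within-module correlation of `r`.
#'
#' @param n_features number of metabolomic features.
#' @param n_bio_reps biological replicates per diet x age x tissue cell.
#' @param n_tech_reps technical replicates per biological sample.
#' @param diets,ages,tissues factor levels; ages are numeric days.
#' @param n_batches number of measurement batches, assigned round-robin
#'   across biological samples.
#' @param frac_diet_affected,frac_age_affected fraction of features with a
#'   non-zero diet (resp. age) effect.
#' @param frac_reversal among features affected by both diet and age, the
#'   fraction whose diet effect has the opposite sign to the age effect
#'   (dietary restriction pushes the feature back toward its young level).
#' @param effect_size_sd sd of planted effects, log2-intensity units. Age
#'   effects are drawn as a total change over the age span and converted to
#'   a per-day slope.
#' @param module_specs list of module specifications, each a list with
#'   `size`, `pattern` (one of `"DR-only"`, `"AL-only"`, `"both-same-sign"`,
#'   `"both-opposite-sign"`), and latent correlation `r` in (-1, 1).
#'   A spec may instead carry `pattern = "age-trajectory"` with `r_by_age`,
#'   a list mapping diet level to a vector of latent correlations (one per
#'   age, in the order of `ages`), to emulate condition-specific changes of
#'   network connectivity with age.
#' @param frac_missing fraction of cells masked missing completely at random.
#' @param frac_low_snr fraction of features given inflated technical variance.
#' @param batch_shift_sd sd of per-feature, per-batch shifts (log2 units).
#' @param bio_sd,tech_sd,low_snr_tech_sd biological and technical noise sds
#'   (log2 units); `low_snr_tech_sd` replaces `tech_sd` for low-SNR features.
#' @param baseline_mean,baseline_sd distribution of per-feature baseline
#'   log2 intensities.
#' @param n_outlier_samples technical-replicate samples turned into planted
#'   outliers by adding independent per-feature noise of sd
#'   `outlier_shift_sd`.
#' @param outlier_shift_sd see above.
#' @param columns chromatography column ids features are split across.
#' @param mz_ranges named list of `c(min, max)` m/z ranges per column id.
#'   Defaults are the anion-exchange and C18 ranges typical of a
#'   high-resolution dual-column fly metabolome (AE 86.06-1738.35 Da,
#'   C18 85.03-1976.50 Da).
#' @param seed integer seed; identical config + seed gives bit-identical data.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_features = 2000,
                         n_bio_reps = 6,
                         n_tech_reps = 3,
                         diets = c("AL", "DR"),
                         ages = c(10, 20, 40),
                         tissues = "thorax",
                         n_batches = 2,
                         frac_diet_affected = 0.15,
                         frac_age_affected = 0.15,
                         frac_reversal = 0.8,
                         effect_size_sd = 1,
                         module_specs = list(),
                         frac_missing = 0.05,
                         frac_low_snr = 0.05,
                         batch_shift_sd = 0.3,
                         bio_sd = 0.5,
                         tech_sd = 0.2,
                         low_snr_tech_sd = 1.5,
                         baseline_mean = 14,
                         baseline_sd = 2,
                         n_outlier_samples = 0,
                         outlier_shift_sd = 6,
                         columns = "AE",
                         mz_ranges = list(AE = c(86.0605321, 1738.34568),
                                          C18 = c(85.0279778, 1976.50254)),
                         seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  fracs <- c(cfg$frac_diet_affected, cfg$frac_age_affected, cfg$frac_reversal,
             cfg$frac_missing, cfg$frac_low_snr)
  if (any(fracs < 0 | fracs > 1)) abort("all fractions must lie in [0, 1]")
  if (length(cfg$diets) < 1 || length(cfg$ages) < 1 || length(cfg$tissues) < 1) {
    abort("diets, ages and tissues must each have at least one level")
  }
  if (cfg$n_features < 1 || cfg$n_bio_reps < 1 || cfg$n_tech_reps < 1 || cfg$n_batches < 1) {
    abort("counts must be positive")
  }
  if (length(cfg$module_specs)) {
    sizes <- vapply(cfg$module_specs, function(m) m$size, numeric(1))
    pats <- vapply(cfg$module_specs, function(m) m$pattern, character(1))
    if (sum(sizes) > cfg$n_features) abort("module sizes must sum to at most n_features")
    ok <- c("DR-only", "AL-only", "both-same-sign", "both-opposite-sign", "age-trajectory")
    if (!all(pats %in% ok)) abort(paste("module pattern must be one of:", paste(ok, collapse = ", ")))
    for (m in cfg$module_specs) {
      rs <- if (identical(m$pattern, "age-trajectory")) unlist(m$r_by_age) else m$r
      if (is.null(rs)) abort("module spec lacks its latent correlation (r or r_by_age)")
      if (any(rs <= -1 | rs >= 1)) abort("module latent correlation r must lie in (-1, 1)")
      if (identical(m$pattern, "age-trajectory") &&
          !all(vapply(m$r_by_age, length, integer(1)) == length(cfg$ages))) {
        abort("r_by_age must give one r per age for each diet")
      }
    }
  }
  if (!all(cfg$columns %in% names(cfg$mz_ranges))) abort("every column id needs an mz range")
  invisible(cfg)
}

#' Build the sample design for a synthetic study
#'
#' Expands the full factorial diet x age x tissue x biological replicate,
#' then each biological sample into its technical replicates. Batches are
#' assigned round-robin across biological samples so that batch is balanced
#' over the experimental factors.
#'
#' @param config a [synth_config()].
#' @return a tibble with one row per technical-replicate sample and columns
#'   `sample_id`, `bio_id`, `diet`, `age`, `tissue`, `batch`, `bio_rep`,
#'   `tech_rep`.
#' @export
make_design <- function(config) {
  validate_synth_config(config)
  bio <- tidyr::expand_grid(diet = config$diets, age = config$ages,
                            tissue = config$tissues, bio_rep = seq_len(config$n_bio_reps))
  bio$batch <- paste0("batch", (seq_len(nrow(bio)) - 1L) %% config$n_batches + 1L)
  bio$bio_id <- sprintf("%s_%g_%s_r%d", bio$diet, bio$age, bio$tissue, bio$bio_rep)
  design <- tidyr::expand_grid(bio, tech_rep = seq_len(config$n_tech_reps))
  design$sample_id <- sprintf("%s_t%d", design$bio_id, design$tech_rep)
  dplyr::select(design, "sample_id", "bio_id", "diet", "age", "tissue",
                "batch", "bio_rep", "tech_rep")
}

#' Collapse a technical-replicate design to one row per biological sample
#'
#' After [collapse_tech_reps()] the feature-table columns are biological
#' sample ids; this gives the matching metadata, with `sample_id = bio_id`.
#' @param design a design tibble from [make_design()].
#' @export
collapse_design <- function(design) {
  design %>%
    dplyr::distinct(.data$bio_id, .data$diet, .data$age, .data$tissue,
                    .data$batch, .data$bio_rep) %>%
    dplyr::mutate(sample_id = .data$bio_id, .before = 1)
}

#' Simulate a synthetic feature table with known ground truth
#'
#' Log2-scale intensities are built additively: per-feature baseline + diet
#' effect + age slope x age + per-batch shift + correlated biological noise
#' (latent factors for planted modules) ; technical replicates add technical
#' noise (inflated for low-SNR features); a MCAR mask is applied; values are
#' exponentiated back to the intensity scale. m/z values are drawn uniformly
#' within the configured per-column ranges.
#'
#' @param design the design from [make_design()] with the same config.
#' @param config a [synth_config()].
#' @return a `metab_sim` list with elements `features` (raw-scale
#'   [feature_table()]), `design`, `truth_features` (per-feature true
#'   `beta_diet`, `beta_age`, `module`, `low_snr`), `truth_samples`
#'   (per-sample `batch`, `planted_outlier`) and `config`.
#' @export
simulate_features <- function(design, config) {
  validate_synth_config(config)
  set.seed(config$seed)
  p <- config$n_features
  feature_id <- sprintf("mzf%05d", seq_len(p))

  # feature keys: split features across columns, m/z uniform in column range
  column_id <- sort(rep_len(config$columns, p))
  mz <- numeric(p)
  for (cc in unique(column_id)) {
    idx <- which(column_id == cc)
    rng <- config$mz_ranges[[cc]]
    mz[idx] <- stats::runif(length(idx), rng[1], rng[2])
  }
  rt <- stats::runif(p, 10, 600)
  keys <- tibble(feature_id = feature_id, mz = mz, rt = rt, column_id = column_id)

  # planted mean effects
  beta_diet <- numeric(p)
  beta_age <- numeric(p)
  n_diet <- round(config$frac_diet_affected * p)
  n_age <- round(config$frac_age_affected * p)
  diet_set <- sample.int(p, n_diet)
  age_set <- sample.int(p, n_age)
  beta_diet[diet_set] <- stats::rnorm(n_diet, 0, config$effect_size_sd)
  age_span <- diff(range(config$ages))
  if (age_span > 0) {
    beta_age[age_set] <- stats::rnorm(n_age, 0, config$effect_size_sd) / age_span
  }
  # reversal structure among doubly-affected features
  doubly <- intersect(diet_set, age_set)
  if (length(doubly) && age_span > 0) {
    n_rev <- round(config$frac_reversal * length(doubly))
    rev_set <- if (n_rev > 0) doubly[sample.int(length(doubly), n_rev)] else integer(0)
    same_set <- setdiff(doubly, rev_set)
    beta_diet[rev_set] <- -sign(beta_age[rev_set]) * abs(beta_diet[rev_set])
    beta_diet[same_set] <- sign(beta_age[same_set]) * abs(beta_diet[same_set])
  }

  # module membership: prefer features without planted mean effects so that
  # correlation structure is not confounded with mean shifts
  module <- rep(NA_character_, p)
  if (length(config$module_specs)) {
    pool <- setdiff(seq_len(p), union(diet_set, age_set))
    if (sum(vapply(config$module_specs, function(m) m$size, numeric(1))) > length(pool)) {
      pool <- seq_len(p)
    }
    pool <- pool[sample.int(length(pool))]
    off <- 0L
    for (k in seq_along(config$module_specs)) {
      sz <- config$module_specs[[k]]$size
      module[pool[(off + 1L):(off + sz)]] <- paste0("M", k)
      off <- off + sz
    }
  }

  low_snr <- seq_len(p) %in% sample.int(p, round(config$frac_low_snr * p))

  bio <- collapse_design(design)
  nb <- nrow(bio)
  baseline <- stats::rnorm(p, config$baseline_mean, config$baseline_sd)
  batches <- sort(unique(bio$batch))
  batch_shift <- matrix(stats::rnorm(p * length(batches), 0, config$batch_shift_sd),
                        nrow = p, dimnames = list(NULL, batches))
  if (length(batches) == 1) batch_shift[] <- 0

  diet_code <- as.numeric(bio$diet == "DR")
  # biological-sample log2 values
  bio_mat <- baseline +
    outer(beta_diet, diet_code) +
    outer(beta_age, bio$age) +
    batch_shift[, bio$batch, drop = FALSE]
  noise <- matrix(stats::rnorm(p * nb), p, nb)
  if (length(config$module_specs)) {
    for (k in seq_along(config$module_specs)) {
      spec <- config$module_specs[[k]]
      feats <- which(module == paste0("M", k))
      latent <- stats::rnorm(nb)
      loading <- switch(spec$pattern,
        "DR-only" = ifelse(bio$diet == "DR", sqrt(spec$r), 0),
        "AL-only" = ifelse(bio$diet == "AL", sqrt(spec$r), 0),
        "both-same-sign" = rep(sqrt(spec$r), nb),
        "both-opposite-sign" = ifelse(bio$diet == "DR", sqrt(spec$r), -sqrt(spec$r)),
        "age-trajectory" = {
          r_s <- vapply(seq_len(nb), function(s) {
            spec$r_by_age[[bio$diet[s]]][match(bio$age[s], config$ages)]
          }, numeric(1))
          sqrt(pmax(r_s, 0))
        })
      resid_sd <- sqrt(1 - loading^2)
      noise[feats, ] <- outer(rep(1, length(feats)), loading * latent) +
        noise[feats, , drop = FALSE] * rep(resid_sd, each = length(feats))
    }
  }
  bio_mat <- bio_mat + config$bio_sd * noise

  # expand to technical replicates and add technical noise
  tech_sd_f <- ifelse(low_snr, config$low_snr_tech_sd, config$tech_sd)
  idx <- match(design$bio_id, bio$bio_id)
  log_mat <- bio_mat[, idx, drop = FALSE] +
    matrix(stats::rnorm(p * nrow(design)), p, nrow(design)) * tech_sd_f
  colnames(log_mat) <- design$sample_id

  # planted outlier samples: independent per-feature noise swamps the shared signal
  planted_outlier <- rep(FALSE, nrow(design))
  if (config$n_outlier_samples > 0) {
    out_idx <- sample.int(nrow(design), config$n_outlier_samples)
    planted_outlier[out_idx] <- TRUE
    log_mat[, out_idx] <- log_mat[, out_idx, drop = FALSE] +
      matrix(stats::rnorm(p * length(out_idx), 0, config$outlier_shift_sd), p)
  }

  # MCAR mask, then back to the intensity scale
  if (config$frac_missing > 0) {
    mask <- stats::runif(length(log_mat)) < config$frac_missing
    log_mat[mask] <- NA
  }
  values <- 2^log_mat

  structure(list(
    features = feature_table(values, keys, scale = "raw"),
    design = design,
    truth_features = tibble(feature_id = feature_id, beta_diet = beta_diet,
                            beta_age = beta_age, module = module, low_snr = low_snr),
    truth_samples = tibble(sample_id = design$sample_id, batch = design$batch,
                           planted_outlier = planted_outlier),
    config = config
  ), class = "metab_sim")
}

#' @export
print.metab_sim <- function(x, ...) {
  cat(sprintf("<metab_sim> %d features x %d samples (%d biological), seed %d\n",
              nrow(x$features), length(ft_samples(x$features)),
              length(unique(x$design$bio_id)), x$config$seed))
  invisible(x)
}

#' Build a synthetic metabolite reference and pathway sets matched to a simulation
#'
#' Constructs a reference of "metabolites" whose monoisotopic masses invert a
#' chosen adduct from the simulated features' m/z values, so that
#' [annotate_mz()] recovers them, plus named pathway sets. One planted set is
#' composed entirely of diet-affected features, giving a known positive for
#' enrichment testing. All outputs are synthetic stand-ins, not a curated
#' metabolome.
#'
#' @param sim a `metab_sim` from [simulate_features()].
#' @param n_sets number of background pathway sets.
#' @param set_size metabolites per background set.
#' @param frac_annotated fraction of features given a reference metabolite.
#' @param adduct adduct assumed when inverting m/z to neutral mass.
#' @param seed integer seed.
#' @return list with `reference` (tibble `metabolite`, `mass`),
#'   `sets` (named list of metabolite id vectors; includes
#'   `"planted_diet_response"`), and `annotated_features`.
#' @export
simulate_pathway_reference <- function(sim, n_sets = 10, set_size = 15,
                                       frac_annotated = 0.4, adduct = "M+H",
                                       seed = 1L) {
  set.seed(seed)
  keys <- ft_keys(sim$features)
  shift <- default_adducts()$shift[default_adducts()$adduct == adduct]
  if (!length(shift)) abort("unknown adduct")
  affected <- sim$truth_features$feature_id[sim$truth_features$beta_diet != 0]
  n_ann <- max(round(frac_annotated * nrow(keys)), min(length(affected), nrow(keys)))
  ann_ids <- union(affected, sample(keys$feature_id, n_ann))
  ann <- keys[match(ann_ids, keys$feature_id), ]
  reference <- tibble(metabolite = sprintf("met%05d", seq_len(nrow(ann))),
                      mass = ann$mz - shift)
  feature2met <- stats::setNames(reference$metabolite, ann$feature_id)

  planted <- unname(feature2met[affected])
  background <- lapply(seq_len(n_sets), function(i) {
    sample(reference$metabolite, min(set_size, nrow(reference)))
  })
  names(background) <- sprintf("background_set_%02d", seq_len(n_sets))
  sets <- c(list(planted_diet_response = planted), background)
  list(reference = reference, sets = sets, annotated_features = ann$feature_id)
}
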