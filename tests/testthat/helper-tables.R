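# Small constructors used across the suite.

toy_table <- function(mat, scale = "log", mz = NULL) {
  p <- nrow(mat)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("f%02d", seq_len(p))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  keys <- tibble::tibble(feature_id = rownames(mat),
                         mz = if (is.null(mz)) 100 + seq_len(p) else mz,
                         rt = as.numeric(seq_len(p)), column_id = "AE")
  feature_table(mat, keys, scale = scale)
}

# one-technical-replicate design over the columns of a feature table
toy_design <- function(ft, diet = NULL, age = 10) {
  ids <- ft_samples(ft)
  n <- length(ids)
  tibble::tibble(sample_id = ids, bio_id = ids,
                 diet = if (is.null(diet)) rep(c("AL", "DR"), length.out = n) else diet,
                 age = age, tissue = "thorax", batch = "batch1",
                 bio_rep = seq_len(n), tech_rep = 1L)
}

# clean biological-sample simulation: no missingness/outliers, tech reps
# collapsed, log scale
sim_clean_bio <- function(cfg) {
  sim <- simulate_features(make_design(cfg), cfg)
  logged <- log_transform(sim$features)
  collapsed <- collapse_tech_reps(logged, sim$design)
  list(features = collapsed, design = collapse_design(sim$design), sim = sim)
}
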