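#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Key columns that identify a metabolomic feature in a feature table.
ft_key_cols <- c("feature_id", "mz", "rt", "column_id")

#' Build a feature table from a matrix and feature keys
#'
#' A feature table is a tibble with one row per untargeted LC-MS feature.
#' The first four columns identify the feature (`feature_id`, `mz` in Da,
#' `rt` in seconds, `column_id` for the chromatography column); every
#' remaining column holds the intensities of one sample. The measurement
#' scale (`"raw"` intensities, `"log"` intensities, or mean-`"centered"`
#' log intensities) travels with the table as the `"scale"` attribute so
#' that each preprocessing step can check its precondition.
#'
#' @param values numeric matrix, features in rows, samples in columns;
#'   column names are sample ids.
#' @param keys data frame with columns `feature_id`, `mz`, `rt`,
#'   `column_id`, one row per row of `values`.
#' @param scale one of `"raw"`, `"log"`, `"centered"`.
#' @return a `feature_tbl` tibble.
#' @export
feature_table <- function(values, keys, scale = "raw") {
  scale <- match.arg(scale, c("raw", "log", "centered"))
  keys <- as_tibble(keys)
  if (!all(ft_key_cols %in% names(keys))) {
    abort(paste("keys must contain columns:", paste(ft_key_cols, collapse = ", ")))
  }
  if (nrow(keys) != nrow(values)) abort("keys and values disagree on the number of features")
  if (anyDuplicated(keys$feature_id)) abort("duplicate feature ids")
  if (any(keys$mz <= 0, na.rm = TRUE)) abort("m/z values must be positive")
  if (is.null(colnames(values))) abort("values must have sample ids as column names")
  out <- dplyr::bind_cols(keys[ft_key_cols], as_tibble(values))
  new_feature_tbl(out, scale)
}

new_feature_tbl <- function(df, scale) {
  structure(as_tibble(df), scale = scale,
            class = c("feature_tbl", class(as_tibble(df))))
}

#' @export
ft_scale <- function(ft) attr(ft, "scale") %||% "raw"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Extract the intensity matrix (features x samples) from a feature table
#' @param ft a feature table.
#' @return numeric matrix with feature ids as row names.
#' @export
ft_matrix <- function(ft) {
  m <- as.matrix(ft[, setdiff(names(ft), ft_key_cols), drop = FALSE])
  rownames(m) <- ft$feature_id
  m
}

#' @export
ft_samples <- function(ft) setdiff(names(ft), ft_key_cols)

#' @export
ft_keys <- function(ft) as_tibble(ft[ft_key_cols])

# Replace the sample block, keeping keys; optionally change sample set/scale.
ft_replace <- function(ft, values, scale = ft_scale(ft)) {
  stopifnot(nrow(values) == nrow(ft))
  out <- dplyr::bind_cols(ft_keys(ft), as_tibble(values))
  new_feature_tbl(out, scale)
}

# Subset features by a logical/index vector, preserving attributes.
ft_subset <- function(ft, i) new_feature_tbl(as_tibble(ft)[i, , drop = FALSE], ft_scale(ft))

#' Drop samples from a feature table by id
#' @param ft a feature table.
#' @param sample_ids character vector of sample columns to remove.
#' @export
ft_drop_samples <- function(ft, sample_ids) {
  keep <- setdiff(names(ft), sample_ids)
  new_feature_tbl(as_tibble(ft)[keep], ft_scale(ft))
}

assert_scale <- function(ft, expected, op) {
  if (!ft_scale(ft) %in% expected) {
    abort(sprintf("%s expects a feature table on the %s scale, got '%s'",
                  op, paste(expected, collapse = "/"), ft_scale(ft)))
  }
}

#' Read / write a feature table as TSV
#'
#' The TSV layout has the four key columns first, then one column per sample.
#' @param path file path.
#' @param scale measurement scale recorded on the returned table.
#' @export
read_feature_table <- function(path, scale = "raw") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  new_feature_tbl(df, match.arg(scale, c("raw", "log", "centered")))
}

#' @rdname read_feature_table
#' @param ft a feature table.
#' @export
write_feature_table <- function(ft, path) {
  readr::write_tsv(as_tibble(ft), path, progress = FALSE)
  invisible(path)
}
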