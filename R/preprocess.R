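#' Completeness filter across both timepoints
#'
#' Retains proteins measured at both timepoints with a missing fraction
#' strictly below `max_missing` at day 1 AND at day 4. Proteins present at
#' only one timepoint are dropped before counting. Correlated proteins are
#' deliberately not removed at this stage.
#'
#' @param day1,day4 `intensity_matrix` objects sharing a protein id namespace.
#' @param max_missing maximum tolerated missing fraction (default 0.30,
#'   exclusive: exactly 30% missing is excluded).
#' @return character vector of retained protein ids (day-1 order).
#' @export
filter_completeness <- function(day1, day4, max_missing = 0.30) {
  stopifnot(inherits(day1, "intensity_matrix"),
            inherits(day4, "intensity_matrix"),
            max_missing > 0, max_missing <= 1)
  shared <- intersect(day1$proteins$protein_id, day4$proteins$protein_id)
  f1 <- rowMeans(is.na(day1$values[match(shared, day1$proteins$protein_id), ,
                                   drop = FALSE]))
  f4 <- rowMeans(is.na(day4$values[match(shared, day4$proteins$protein_id), ,
                                   drop = FALSE]))
  keep <- shared[f1 < max_missing & f4 < max_missing]
  if (!length(keep))
    stop("no protein passes the completeness filter at max_missing = ",
         max_missing)
  keep
}

#' Median imputation within a matrix
#'
#' Replaces each missing cell by the median of that protein's observed values
#' within the same matrix (day-1 medians for day-1 data, day-4 medians for
#' day-4 data); observed cells are unchanged. Idempotent.
#'
#' @param x an `intensity_matrix`.
#' @return an `intensity_matrix` without missing values.
#' @export
impute_median <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  vals <- x$values
  n_obs <- rowSums(!is.na(vals))
  if (any(n_obs == 0))
    stop("protein(s) with no observed value: ",
         paste(rownames(vals)[n_obs == 0], collapse = ", "))
  if (!anyNA(vals)) return(x)
  med <- apply(vals, 1, stats::median, na.rm = TRUE)
  idx <- which(is.na(vals), arr.ind = TRUE)
  vals[idx] <- med[idx[, 1]]
  intensity_matrix(vals, x$proteins, x$samples)
}

#' Fit per-protein z-standardization parameters on day-1 data
#'
#' Computes the per-protein mean and population (ddof = 0) standard deviation
#' over the day-1 samples. The same frozen parameters are later applied to
#' day-4 data so both timepoints share one transformation.
#'
#' @param day1 a complete (imputed) day-1 `intensity_matrix`.
#' @return a `standardization_params` object (mean, sd, protein order).
#' @export
fit_standardizer <- function(day1) {
  stopifnot(inherits(day1, "intensity_matrix"))
  if (anyNA(day1$values)) stop("standardizer requires a complete matrix; impute first")
  m <- rowMeans(day1$values)
  s <- apply(day1$values, 1, sd_pop)
  if (any(s <= 0))
    stop("zero-variance protein(s) cannot be standardized: ",
         paste(rownames(day1$values)[s <= 0], collapse = ", "))
  structure(list(mean = m, sd = s,
                 protein_ids = day1$proteins$protein_id),
            class = "standardization_params")
}

#' Apply frozen standardization parameters
#'
#' Computes `z = (x - mean) / sd` elementwise with the day-1 parameters.
#' Day-4 columns are never re-centred on their own statistics: a global day-4
#' shift therefore shows up as a non-zero day-4 z mean, by design.
#'
#' @param x an `intensity_matrix` restricted to the parameters' proteins.
#' @param params a `standardization_params` object from [fit_standardizer()].
#' @return numeric matrix of z-scores, samples in rows, proteins in columns
#'   (the orientation used by PCA and clustering).
#' @export
apply_standardizer <- function(x, params) {
  stopifnot(inherits(x, "intensity_matrix"),
            inherits(params, "standardization_params"))
  if (!identical(x$proteins$protein_id, params$protein_ids))
    stop("protein set/order mismatch between matrix and standardizer")
  z <- (x$values - params$mean) / params$sd
  t(z)
}
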