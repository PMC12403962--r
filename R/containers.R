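#' Protein intensity matrix with sample metadata
#'
#' The central data container of the pipeline: a proteins x samples matrix of
#' log2-scale intensities (linear scale is defined as `2^x`), with missing
#' values stored as `NA`, a protein annotation table and a sample annotation
#' table. Intensities are assumed already batch-normalized; upstream raw-data
#' processing is out of scope.
#'
#' @param values numeric matrix, proteins in rows, samples in columns.
#' @param proteins data.frame with columns `protein_id` (unique) and `gene`.
#' @param samples data.frame with columns `sample_id` (unique), `patient_id`
#'   and `day` (1 or 4).
#' @return an object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, proteins, samples) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values),
            all(c("protein_id", "gene") %in% names(proteins)),
            all(c("sample_id", "patient_id", "day") %in% names(samples)),
            nrow(values) == nrow(proteins),
            ncol(values) == nrow(samples))
  if (anyDuplicated(proteins$protein_id))
    stop("duplicate protein_id: ",
         paste(unique(proteins$protein_id[duplicated(proteins$protein_id)]),
               collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  if (!all(samples$day %in% c(1L, 4L)))
    stop("sample day must be 1 or 4")
  rownames(values) <- proteins$protein_id
  colnames(values) <- samples$sample_id
  structure(list(values = values,
                 proteins = as.data.frame(proteins, stringsAsFactors = FALSE),
                 samples = as.data.frame(samples, stringsAsFactors = FALSE)),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d proteins x %d samples (day %s), %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              paste(sort(unique(x$samples$day)), collapse = "/"),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Restrict an intensity matrix to a protein subset
#'
#' @param x an `intensity_matrix`.
#' @param protein_ids character vector of protein ids to keep, in order.
#' @return an `intensity_matrix` restricted (and reordered) to `protein_ids`.
#' @export
subset_proteins <- function(x, protein_ids) {
  stopifnot(inherits(x, "intensity_matrix"))
  missing_ids <- setdiff(protein_ids, x$proteins$protein_id)
  if (length(missing_ids))
    stop("proteins absent from matrix: ", paste(missing_ids, collapse = ", "))
  idx <- match(protein_ids, x$proteins$protein_id)
  intensity_matrix(x$values[idx, , drop = FALSE],
                   x$proteins[idx, , drop = FALSE],
                   x$samples)
}
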