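intensity_schema <- "sepsubtype-intensity-v1"

#' Write an intensity matrix as TSV
#'
#' Canonical dialect: a `# sepsubtype-intensity-v1` schema header line, then
#' a header row `protein_id`, `gene`, sample ids, then one row per protein;
#' missing values are written as `NA`. Sample ids encode patient and day as
#' `<patient>_d<day>`.
#'
#' @param x an `intensity_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intensity_tsv <- function(x, path) {
  stopifnot(inherits(x, "intensity_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", intensity_schema), con)
  # full double precision so write -> read round-trips bit-exactly
  ch <- matrix(formatC(x$values, digits = 17, format = "g"),
               nrow(x$values), dimnames = dimnames(x$values))
  ch[is.na(x$values)] <- NA
  df <- data.frame(protein_id = x$proteins$protein_id,
                   gene = x$proteins$gene,
                   ch, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read an intensity matrix from TSV/CSV
#'
#' Accepts the canonical tab dialect (comma also tolerated), with missing
#' values encoded as `NA` or empty fields — both parse identically.
#' Duplicate protein ids, ragged rows and non-numeric cells raise errors
#' with coordinates.
#'
#' @param path input path.
#' @return an `intensity_matrix`.
#' @export
read_intensity_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("empty file: ", path)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  header <- parts[[1]]
  if (!identical(header[1:2], c("protein_id", "gene")))
    stop("expected key columns protein_id, gene in ", path)
  n_col <- length(header)
  body <- parts[-1]
  widths <- lengths(body)
  # trailing empty fields are dropped by strsplit; pad them back
  body <- lapply(body, function(r) c(r, rep("", n_col - length(r))))
  if (any(widths > n_col))
    stop("ragged row(s): ", paste(which(widths > n_col) + 1, collapse = ", "))
  mat_chr <- do.call(rbind, body)
  ids <- mat_chr[, 1]
  if (anyDuplicated(ids))
    stop("duplicate protein_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cells <- mat_chr[, -(1:2), drop = FALSE]
  cells[cells == "" | cells == "NA"] <- NA
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow(cells)))
  bad <- which(is.na(vals) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at row %d, column %s",
                 bad[1, 1] + 1, header[bad[1, 2] + 2]))
  sample_ids <- header[-(1:2)]
  m <- regmatches(sample_ids, regexec("^(.*)_d([14])$", sample_ids))
  if (any(lengths(m) != 3))
    stop("sample ids must look like <patient>_d<1|4>: ",
         paste(sample_ids[lengths(m) != 3], collapse = ", "))
  samples <- data.frame(sample_id = sample_ids,
                        patient_id = vapply(m, `[`, "", 2),
                        day = as.integer(vapply(m, `[`, "", 3)),
                        stringsAsFactors = FALSE)
  intensity_matrix(vals,
                   data.frame(protein_id = ids, gene = mat_chr[, 2],
                              stringsAsFactors = FALSE),
                   samples)
}

write_tsv_schema <- function(df, path, schema) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", schema), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv_schema <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a generated cohort to a directory of TSV files
#'
#' Emits the same formats the pipeline reads: day-1 and day-4 intensity
#' matrices, the clinical long table and registry, immunoglobulin
#' concentrations, and the ground-truth table.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_intensity_tsv(cohort$day1, file.path(dir, "day1.tsv"))
  write_intensity_tsv(cohort$day4, file.path(dir, "day4.tsv"))
  write_tsv_schema(cohort$clinical, file.path(dir, "clinical.tsv"),
                   "sepsubtype-clinical-v1")
  write_tsv_schema(cohort$registry, file.path(dir, "registry.tsv"),
                   "sepsubtype-registry-v1")
  write_tsv_schema(cohort$ig, file.path(dir, "ig.tsv"), "sepsubtype-ig-v1")
  write_tsv_schema(cohort$truth, file.path(dir, "truth.tsv"),
                   "sepsubtype-truth-v1")
  invisible(dir)
}

#' Pipeline run configuration
#'
#' Paths to the input tables, the analysis parameters (defaults are the
#' study's stated constants) and stage toggles.
#'
#' @param day1,day4,clinical,registry,ig paths to TSV inputs (as written by
#'   [write_cohort()]).
#' @param outdir output directory.
#' @param k subtype count (default 4).
#' @param max_missing completeness threshold (default 0.30).
#' @param variance_target PCA variance target (default 0.70).
#' @param n_init k-means restarts.
#' @param branches_day1,branches_day4 abundance-pattern branch counts.
#' @param cor_threshold correlation-pruning limit.
#' @param n_mccv MCCV iterations for the classifier stage.
#' @param num_trees forest size.
#' @param split MCCV training fraction.
#' @param grid_medical,grid_protein feature-count grids.
#' @param seed master seed.
#' @param run_ml toggle for the classifier stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(day1, day4, clinical, registry, ig, outdir,
                            k = 4L, max_missing = 0.30,
                            variance_target = 0.70, n_init = 25L,
                            branches_day1 = 5L, branches_day4 = 4L,
                            cor_threshold = 0.7, n_mccv = 100L,
                            num_trees = 500L, split = 0.8,
                            grid_medical = 0:3, grid_protein = 1:15,
                            seed = 1L, run_ml = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages mirror the analysis order: subtype discovery on day 1 with day-4
#' projection and trajectory tabulation, differential abundance per
#' timepoint, clinical characterization, and (optionally) the
#' feature-selection / panel-classifier stage. Every artifact is written
#' under `config$outdir` along with a JSON manifest (configuration echo,
#' seeds, package and R versions) that makes the run reproducible.
#'
#' @param config a [pipeline_config()].
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  day1 <- stage("read", read_intensity_tsv(cfg$day1))
  day4 <- stage("read", read_intensity_tsv(cfg$day4))
  clinical <- stage("read", read_tsv_schema(cfg$clinical))
  registry <- stage("read", read_tsv_schema(cfg$registry))
  ig <- stage("read", read_tsv_schema(cfg$ig))

  wide <- stage("clinical", aggregate_daily(clinical, registry))
  sofa <- stats::setNames(wide$sofa, wide$patient_id)

  model <- stage("cluster",
                 fit_subtype_model(day1, day4, sofa, k = cfg$k,
                                   max_missing = cfg$max_missing,
                                   variance_target = cfg$variance_target,
                                   seed = cfg$seed, n_init = cfg$n_init))
  write_subtype_model(model, file.path(cfg$outdir, "model.json"))
  labels1 <- model$labels_day1
  labels4 <- stage("assign", assign_matrix(day4, model))
  write_tsv_schema(data.frame(patient_id = names(labels1), label = labels1),
                   file.path(cfg$outdir, "labels_day1.tsv"),
                   "sepsubtype-labels-v1")
  write_tsv_schema(data.frame(patient_id = names(labels4), label = labels4),
                   file.path(cfg$outdir, "labels_day4.tsv"),
                   "sepsubtype-labels-v1")

  # trajectories need outcomes; take them from a truth table colocated with
  # the inputs (synthetic runs), else treat everyone as censored at day 30
  truth_path <- file.path(dirname(cfg$day1), "truth.tsv")
  dead30 <- if (file.exists(truth_path)) {
    tr <- read_tsv_schema(truth_path)
    stats::setNames(as.logical(tr$dead30), tr$patient_id)
  } else stats::setNames(rep(FALSE, length(labels1)), names(labels1))
  traj <- stage("trajectories", trajectories(labels1, labels4, dead30))
  write_tsv_schema(traj, file.path(cfg$outdir, "trajectories.tsv"),
                   "sepsubtype-trajectories-v1")

  d1f <- impute_median(subset_proteins(day1, model$protein_ids))
  d4f <- impute_median(subset_proteins(day4, model$protein_ids))
  diff1 <- stage("diffexp",
                 diff_abundance(d1f, labels1[d1f$samples$patient_id],
                                n_branches = cfg$branches_day1))
  diff4 <- stage("diffexp",
                 diff_abundance(d4f, labels4[d4f$samples$patient_id],
                                n_branches = cfg$branches_day4))
  write_tsv_schema(diff1, file.path(cfg$outdir, "diff_day1.tsv"),
                   "sepsubtype-diff-v1")
  write_tsv_schema(diff4, file.path(cfg$outdir, "diff_day4.tsv"),
                   "sepsubtype-diff-v1")

  tab1 <- stage("clinstats", clinical_summary_table(wide, registry, labels1))
  write_tsv_schema(tab1, file.path(cfg$outdir, "table1.tsv"),
                   "sepsubtype-table1-v1")
  if (file.exists(truth_path)) {
    tr <- read_tsv_schema(truth_path)
    times <- ifelse(as.logical(tr$dead30), tr$death_day, 30)
    km <- km_curve(times, as.logical(tr$dead30), labels1[tr$patient_id])
    write_tsv_schema(km$curves, file.path(cfg$outdir, "km.tsv"),
                     "sepsubtype-km-v1")
  }

  manifest <- list(schema = "sepsubtype-manifest-v1",
                   config = cfg[setdiff(names(cfg), "outdir")],
                   n_proteins_filtered = length(model$protein_ids),
                   pca_components = model$basis$m,
                   n_significant_day1 = sum(diff1$significant),
                   n_significant_day4 = sum(diff4$significant),
                   versions = list(package = as.character(utils::packageVersion("sepsubtype")),
                                   r = R.version.string))

  if (isTRUE(cfg$run_ml)) {
    ml <- stage("ml", {
      ft <- build_feature_table(day1, wide, ig, labels1,
                                cor_threshold = cfg$cor_threshold)
      ranks <- shap_rank(ft, n_mccv = cfg$n_mccv, split = cfg$split,
                         seed = cfg$seed, num_trees = cfg$num_trees)
      trace <- nested_selection(ft, ranks, grid_medical = cfg$grid_medical,
                                grid_protein = cfg$grid_protein,
                                n_mccv = cfg$n_mccv, split = cfg$split,
                                seed = cfg$seed, num_trees = cfg$num_trees)
      prot_curve <- trace$surface[trace$surface$n_medical == 0, ]
      knee <- knee_point(prot_curve$n_protein, prot_curve$recall_mean)
      n_star <- if (is.na(knee)) max(prot_curve$n_protein) else knee
      panel <- finalize_panel(trace, n_star)
      pm <- train_evaluate(ft, panel$panel, n_mccv = cfg$n_mccv,
                           split = cfg$split, seed = cfg$seed,
                           num_trees = cfg$num_trees)
      dir.create(file.path(cfg$outdir, "trace"), showWarnings = FALSE)
      write_tsv_schema(trace$surface,
                       file.path(cfg$outdir, "trace", "recall_surface.tsv"),
                       "sepsubtype-trace-v1")
      write_tsv_schema(panel$selection_freq,
                       file.path(cfg$outdir, "trace", "selection_freq.tsv"),
                       "sepsubtype-trace-v1")
      write_tsv_schema(pm$metrics, file.path(cfg$outdir, "metrics.tsv"),
                       "sepsubtype-metrics-v1")
      jsonlite::write_json(list(schema = "sepsubtype-panel-v1",
                                knee = n_star, panel = pm$panel,
                                overfitting = pm$overfitting),
                           file.path(cfg$outdir, "panel.json"),
                           digits = NA, auto_unbox = TRUE)
      list(knee = n_star, panel = pm$panel)
    })
    manifest$knee <- ml$knee
    manifest$panel <- ml$panel
  }

  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(manifest)
}
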