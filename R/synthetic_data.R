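#' Configuration for the synthetic sepsis cohort generator
#'
#' Defaults emulate the structure of a multicentre sepsis cohort: 333
#' patients, four latent plasma-proteome subtypes of graded severity with
#' realistic proportions (16/98/103/116), day-4 follow-up samples for 213/333
#' of patients with a mostly-diagonal subtype migration matrix, ~600 plasma
#' proteins organised in subtype-specific signature blocks (immunoglobulin,
#' acute-phase, cytosolic leakage, adhesion) plus a null block,
#' intensity-dependent (MNAR) missingness below the 30% completeness filter on
#' average, severity-linked clinical variables and ~40% 30-day mortality.
#'
#' @param n_patients number of patients.
#' @param n_proteins number of proteins.
#' @param n_clinical_numeric number of numeric clinical variables (the first
#'   three are severity-linked: a SOFA-like score, lactate-like and
#'   creatinine-like markers; the remainder are null).
#' @param n_clinical_categorical number of categorical clinical variables
#'   (focus of infection and sex style; independent of subtype).
#' @param subtype_props length-4 simplex of day-1 subtype proportions, in
#'   decreasing severity order (subtype 0 most severe).
#' @param day4_fraction fraction of patients with a day-4 sample.
#' @param migration 4x4 row-stochastic matrix of day-1 to day-4 subtype
#'   transition probabilities.
#' @param block_sizes named counts for the four signature blocks
#'   (`immunoglobulin`, `acute_phase`, `cytosolic`, `adhesion`); the null
#'   block takes the remaining proteins.
#' @param effect_size log2 shift scale applied to the block design.
#' @param noise_sd residual log2 standard deviation per protein.
#' @param missing_rate target marginal missingness fraction in `[0, 0.5]`.
#' @param mnar_strength logit slope tying missingness odds to (low) intensity.
#' @param mortality_logit length-2 `(intercept, slope)` linking latent
#'   severity to the 30-day death probability on the logit scale.
#' @param seed integer seed; identical configs with identical seeds reproduce
#'   bit-identical cohorts.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 333L,
                          n_proteins = 600L,
                          n_clinical_numeric = 10L,
                          n_clinical_categorical = 2L,
                          subtype_props = c(16, 98, 103, 116) / 333,
                          day4_fraction = 213 / 333,
                          migration = rbind(c(0.85, 0.05, 0.05, 0.05),
                                            c(0.05, 0.80, 0.10, 0.05),
                                            c(0.05, 0.10, 0.80, 0.05),
                                            c(0.02, 0.05, 0.13, 0.80)),
                          block_sizes = c(immunoglobulin = 100L,
                                          acute_phase = 60L,
                                          cytosolic = 60L,
                                          adhesion = 50L),
                          effect_size = 2,
                          noise_sd = 0.5,
                          missing_rate = 0.2,
                          mnar_strength = 0.8,
                          mortality_logit = c(-1.13, 0.61),
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_proteins = as.integer(n_proteins),
              n_clinical_numeric = as.integer(n_clinical_numeric),
              n_clinical_categorical = as.integer(n_clinical_categorical),
              subtype_props = subtype_props,
              day4_fraction = day4_fraction,
              migration = migration,
              block_sizes = as.integer(block_sizes),
              effect_size = effect_size,
              noise_sd = noise_sd,
              missing_rate = missing_rate,
              mnar_strength = mnar_strength,
              mortality_logit = mortality_logit,
              seed = as.integer(seed))
  names(cfg$block_sizes) <- names(block_sizes)
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_patients > 0, cfg$n_proteins > 0,
            cfg$n_clinical_numeric >= 3, cfg$n_clinical_categorical >= 0,
            length(cfg$subtype_props) == 4,
            all(cfg$subtype_props > 0),
            abs(sum(cfg$subtype_props) - 1) < 1e-8,
            cfg$day4_fraction >= 0, cfg$day4_fraction <= 1,
            is.matrix(cfg$migration), all(dim(cfg$migration) == c(4, 4)),
            all(cfg$migration >= 0),
            all(abs(rowSums(cfg$migration) - 1) < 1e-8),
            length(cfg$block_sizes) == 4, all(cfg$block_sizes > 0),
            cfg$missing_rate >= 0, cfg$missing_rate <= 0.5,
            cfg$noise_sd > 0,
            length(cfg$mortality_logit) == 2)
  if (sum(cfg$block_sizes) >= cfg$n_proteins)
    stop("block_sizes must leave room for a non-empty null block")
  expected <- cfg$subtype_props * cfg$n_patients
  if (any(expected < 1))
    stop("degenerate config: subtype ", which(expected < 1)[1] - 1,
         " has expected count below 1 patient")
  invisible(cfg)
}

# Log2 shift of each signature block in each subtype, in units of effect_size.
# Rows: blocks; columns: subtypes 0..3. Subtype 1 has high immunoglobulins and
# subtype 2 the lowest; acute-phase proteins peak in subtype 2 and are
# consumed in 0 and 1; cytosolic leakage marks the moribund subtype 0;
# adhesion molecules are lowest in the baseline subtype 3.
block_design <- function() {
  rbind(immunoglobulin = c(0,     1,    -1,    -0.25),
        acute_phase    = c(-0.75, -0.2,  1,     0),
        cytosolic      = c(1.5,   0.4,   0.4,   0),
        adhesion       = c(1.25,  1.15,  1.0,   0),
        null           = c(0,     0,     0,     0))
}

# Latent severity scale per subtype (subtype 0 moribund) and clinical anchor
# values used for the severity-linked variables.
severity_means <- function() c(8, 1.2, 0.95, 0.7)

synthetic_gene_names <- function(block_sizes, n_null) {
  seeds <- list(
    immunoglobulin = c("IGHG1", "IGHG2", "IGHG3", "IGHG4", "IGHA1", "IGHA2",
                       "IGHM", "IGKC", "IGLC1", "IGLC2", "JCHAIN"),
    acute_phase = c("SAA1", "SAA2", "HP", "CRP", "FGA", "FGB", "FGG",
                    "S100A8", "S100A9", "LBP"),
    cytosolic = c("LDHA", "GOT1", "GPT", "ALDOB", "CA1", "GAPDH", "PKM"),
    adhesion = c("ICAM1", "VCAM1", "CST3", "VSIG4", "SELE"))
  stub <- c(immunoglobulin = "IGHV%02d", acute_phase = "APR%03d",
            cytosolic = "CYT%03d", adhesion = "ADH%03d")
  out <- character(0)
  for (b in names(seeds)) {
    n <- block_sizes[[b]]
    g <- seeds[[b]][seq_len(min(n, length(seeds[[b]])))]
    if (n > length(g)) g <- c(g, sprintf(stub[[b]], seq_len(n - length(g))))
    out <- c(out, g)
  }
  c(out, sprintf("PLS%03d", seq_len(n_null)))
}

# Deterministic largest-remainder allocation of n patients to the 4 subtypes.
allocate_counts <- function(props, n) {
  raw <- props * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_frac <- order(raw - counts, decreasing = TRUE)
    counts[order_frac[seq_len(rem)]] <- counts[order_frac[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' Inject intensity-dependent missingness into an intensity matrix
#'
#' Each cell is masked by an independent Bernoulli draw whose logit is linear
#' in the latent log2 intensity: low-abundance measurements are more likely to
#' be missing when `mnar_strength > 0` (the missing-not-at-random regime
#' typical of DIA plasma data); `mnar_strength = 0` gives MCAR. The intercept
#' is calibrated by root-finding so the marginal missing fraction matches
#' `rate`.
#'
#' @param x an `intensity_matrix` (complete or partially missing; only
#'   observed cells can be masked).
#' @param rate target marginal missing fraction in `[0, 0.5]`.
#' @param mnar_strength non-negative logit slope per log2 unit.
#' @param seed integer seed.
#' @return an `intensity_matrix` with `NA`-masked cells; the pre-mask values
#'   are retained in `attr(, "premask")` for diagnostics.
#' @export
inject_missingness <- function(x, rate, mnar_strength = 0, seed = 1L) {
  stopifnot(inherits(x, "intensity_matrix"), rate >= 0, rate <= 0.5,
            mnar_strength >= 0)
  vals <- x$values
  if (rate == 0) {
    attr(x, "premask") <- vals
    return(x)
  }
  obs <- !is.na(vals)
  centred <- vals - mean(vals[obs])
  eta <- -mnar_strength * centred
  # calibrate intercept a so that mean(plogis(a + eta)) == rate
  f <- function(a) mean(stats::plogis(a + eta[obs])) - rate
  a <- stats::uniroot(f, lower = -50, upper = 50, tol = 1e-10)$root
  p_miss <- stats::plogis(a + eta)
  masked <- vals
  with_seed(seed, {
    u <- matrix(stats::runif(length(vals)), nrow(vals))
    masked[obs & (u < p_miss)] <- NA
  })
  out <- intensity_matrix(masked, x$proteins, x$samples)
  attr(out, "premask") <- vals
  out
}

#' Generate a synthetic sepsis cohort
#'
#' Draws a cohort under the latent-subtype block model described in
#' [cohort_config()]: per-protein log2 baselines, additive subtype-specific
#' block shifts, Gaussian residual noise, MNAR missingness, day-4 re-draws
#' under the migration matrix, severity-linked clinical variables,
#' immunoglobulin concentrations and Bernoulli 30-day mortality.
#'
#' @param config a [cohort_config()].
#' @return a list with elements `day1` and `day4` (`intensity_matrix`),
#'   `clinical` (long data.frame: patient_id, day, variable, value),
#'   `registry` (variable typing/aggregation table), `ig` (per-patient IgG,
#'   IgA, IgM in g/L), `truth` (ground-truth data.frame) and `latent`
#'   (pre-missingness matrices, for diagnostics).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  cfg <- config
  seeds <- derive_seeds(cfg$seed, 10L, salt = 101L)

  n <- cfg$n_patients
  p <- cfg$n_proteins
  counts <- allocate_counts(cfg$subtype_props, n)
  if (any(counts == 0))
    stop("degenerate config: subtype ", which(counts == 0)[1] - 1,
         " received 0 patients")

  block_sizes <- c(cfg$block_sizes, null = p - sum(cfg$block_sizes))
  block_of <- rep(rownames(block_design()), times = block_sizes)
  genes <- synthetic_gene_names(cfg$block_sizes, block_sizes[["null"]])
  proteins <- data.frame(protein_id = sprintf("SYN%04d", seq_len(p)),
                         gene = genes, stringsAsFactors = FALSE)

  patient_id <- sprintf("P%04d", seq_len(n))

  with_seed(seeds[1], {
    subtype <- sample(rep.int(0:3, counts))
    sev <- severity_means()[subtype + 1] + stats::rnorm(n, 0, 0.25)
  })

  # latent log2 intensity surfaces
  design <- block_design() * cfg$effect_size
  shift <- design[block_of, , drop = FALSE]  # proteins x 4 subtypes
  with_seed(seeds[2], baseline <- stats::rnorm(p, 20, 2))
  day1_mean <- baseline + shift[, subtype + 1, drop = FALSE]
  with_seed(seeds[3],
            day1_lat <- day1_mean + matrix(stats::rnorm(p * n, 0, cfg$noise_sd), p, n))

  samples1 <- data.frame(sample_id = paste0(patient_id, "_d1"),
                         patient_id = patient_id, day = 1L,
                         stringsAsFactors = FALSE)
  day1_full <- intensity_matrix(day1_lat, proteins, samples1)
  day1 <- inject_missingness(day1_full, cfg$missing_rate, cfg$mnar_strength,
                             seed = seeds[4])

  # day-4 follow-up subset and subtype migration
  n4 <- round(cfg$day4_fraction * n)
  with_seed(seeds[5], {
    followed <- sort(sample.int(n, n4))
    subtype4 <- rep(NA_integer_, n)
    for (i in followed)
      subtype4[i] <- sample(0:3, 1, prob = cfg$migration[subtype[i] + 1, ])
  })
  day4_mean <- baseline + shift[, subtype4[followed] + 1, drop = FALSE]
  with_seed(seeds[6],
            day4_lat <- day4_mean + matrix(stats::rnorm(p * n4, 0, cfg$noise_sd), p, n4))
  samples4 <- data.frame(sample_id = paste0(patient_id[followed], "_d4"),
                         patient_id = patient_id[followed], day = 4L,
                         stringsAsFactors = FALSE)
  day4_full <- intensity_matrix(day4_lat, proteins, samples4)
  day4 <- inject_missingness(day4_full, cfg$missing_rate, cfg$mnar_strength,
                             seed = seeds[7])

  # 30-day mortality from latent severity; early deaths in subtype 0
  with_seed(seeds[8], {
    p_death <- stats::plogis(cfg$mortality_logit[1] + cfg$mortality_logit[2] * sev)
    dead30 <- stats::runif(n) < p_death
    death_day <- rep(NA_integer_, n)
    d0 <- dead30 & subtype == 0
    death_day[d0] <- sample(1:14, sum(d0), replace = TRUE)
    death_day[dead30 & !d0] <- sample(1:30, sum(dead30 & !d0), replace = TRUE)
  })

  clin <- generate_clinical(cfg, patient_id, subtype, sev, seeds[9])
  ig <- generate_ig(patient_id, subtype, seeds[10])

  truth <- data.frame(patient_id = patient_id,
                      subtype_day1 = subtype,
                      subtype_day4 = subtype4,
                      severity = sev,
                      dead30 = dead30,
                      death_day = death_day,
                      stringsAsFactors = FALSE)

  list(day1 = day1, day4 = day4,
       clinical = clin$table, registry = clin$registry, ig = ig,
       truth = truth,
       latent = list(day1 = day1_lat, day4 = day4_lat),
       config = cfg)
}

generate_clinical <- function(cfg, patient_id, subtype, sev, seed) {
  n <- length(patient_id)
  sev_centered <- sev - severity_means()[subtype + 1]
  with_seed(seed, {
    sofa <- pmin(24, pmax(0, round(c(15, 10, 8, 7)[subtype + 1] +
                                     2 * sev_centered + stats::rnorm(n, 0, 2))))
    lactate <- exp(log(c(17, 2.6, 2.2, 1.8)[subtype + 1]) +
                     0.5 * sev_centered + stats::rnorm(n, 0, 0.35))
    creatinine <- exp(log(c(2.6, 1.6, 1.3, 1.1)[subtype + 1]) +
                        0.4 * sev_centered + stats::rnorm(n, 0, 0.3))
    n_null <- cfg$n_clinical_numeric - 3L
    nulls <- if (n_null > 0)
      matrix(stats::rnorm(n * n_null), n, n_null,
             dimnames = list(NULL, sprintf("clin_null_%02d", seq_len(n_null))))
    else NULL
    cats <- list()
    if (cfg$n_clinical_categorical >= 1) {
      foci <- c("intra-abdominal", "bloodstream", "urinary tract", "pneumonia",
                "CNS", "COVID-19", "other")
      cats$focus <- sample(foci, n, replace = TRUE,
                           prob = c(71, 15, 19, 103, 9, 74, 13) / 304)
    }
    if (cfg$n_clinical_categorical >= 2)
      cats$sex <- sample(c("female", "male"), n, replace = TRUE,
                         prob = c(0.38, 0.62))
    if (cfg$n_clinical_categorical > 2)
      for (j in seq_len(cfg$n_clinical_categorical - 2L))
        cats[[sprintf("cat_null_%02d", j)]] <-
          sample(c("A", "B", "C"), n, replace = TRUE)
  })
  num <- cbind(sofa = sofa, lactate = lactate, creatinine = creatinine, nulls)
  long_num <- data.frame(patient_id = rep(patient_id, ncol(num)),
                         day = 1L,
                         variable = rep(colnames(num), each = n),
                         value = as.character(as.vector(num)),
                         stringsAsFactors = FALSE)
  long_cat <- if (length(cats))
    data.frame(patient_id = rep(patient_id, length(cats)),
               day = 1L,
               variable = rep(names(cats), each = n),
               value = as.character(unlist(cats, use.names = FALSE)),
               stringsAsFactors = FALSE)
  else NULL
  registry <- data.frame(
    variable = c(colnames(num), names(cats)),
    type = c(rep("numeric", ncol(num)), rep("categorical", length(cats))),
    aggregation = c("max", "max", "max",
                    rep("median", ncol(num) - 3L),
                    rep(NA_character_, length(cats))),
    stringsAsFactors = FALSE)
  list(table = rbind(long_num, long_cat), registry = registry)
}

generate_ig <- function(patient_id, subtype, seed) {
  # g/L concentrations; complementary IgG/IgA levels high in subtype 1 and
  # low in subtype 2, lowest IgM in subtype 2
  igg_mu <- c(9.5, 14, 6, 9.5)
  iga_mu <- c(2.4, 3.6, 1.5, 2.4)
  igm_mu <- c(0.9, 1.2, 0.55, 0.9)
  n <- length(patient_id)
  with_seed(seed, {
    data.frame(patient_id = patient_id,
               IgG = exp(log(igg_mu[subtype + 1]) + stats::rnorm(n, 0, 0.25)),
               IgA = exp(log(iga_mu[subtype + 1]) + stats::rnorm(n, 0, 0.3)),
               IgM = exp(log(igm_mu[subtype + 1]) + stats::rnorm(n, 0, 0.3)),
               stringsAsFactors = FALSE)
  })
}

#' Generate a planted-signal feature cohort for classifier checks
#'
#' A small three-class cohort in classifier feature-table form with exactly
#' `s_signal` informative protein features, `n_noise` pure-noise proteins,
#' medical features (the first carries a weak class signal) and
#' immunoglobulin concentrations (IgG weakly separates classes 1 and 2, as
#' in the cohort the generator emulates). The signal proteins carry
#' complementary class contrasts (one-vs-rest, pairwise and one-vs-mean
#' patterns in rotation) with a total effect budget split as
#' `effect / sqrt(s_signal)` per protein, so the achievable recall grows
#' until the full planted set is included and then flattens — the regime in
#' which knee-point panel sizing is meaningful. With `grade < 1` the
#' per-protein effects decrease linearly to `grade` times the first
#' protein's effect, planting a known importance ordering.
#'
#' @param n_per_class patients per class (3 classes, labelled 1..3).
#' @param s_signal number of informative proteins.
#' @param n_noise number of noise proteins.
#' @param n_medical number of medical features (the first is informative).
#' @param effect total log2 effect budget across the planted set.
#' @param grade relative effect of the last signal protein (1 = equal
#'   effects; < 1 plants a recoverable importance ordering).
#' @param seed integer seed.
#' @return list with `table` (a `feature_table`-shaped data.frame),
#'   `signal_proteins` (column names of planted proteins, strongest first).
#' @export
simulate_feature_cohort <- function(n_per_class = 100L, s_signal = 5L,
                                    n_noise = 20L, n_medical = 4L,
                                    effect = 3, grade = 1, seed = 1L) {
  n <- 3L * n_per_class
  cls <- rep(1:3, each = n_per_class)
  patterns <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                   c(0.7, -0.7, 0), c(0, 0.7, -0.7), c(0.7, 0, -0.7),
                   c(0.8, -0.4, -0.4), c(-0.4, 0.8, -0.4))
  effects <- (effect / sqrt(s_signal)) * seq(1, grade, length.out = s_signal)
  with_seed(seed, {
    prot <- matrix(stats::rnorm(n * (s_signal + n_noise)), n)
    for (j in seq_len(s_signal))
      prot[, j] <- prot[, j] + effects[j] * patterns[[(j - 1) %% 8 + 1]][cls]
    med <- matrix(stats::rnorm(n * n_medical), n)
    if (n_medical >= 1)
      med[, 1] <- med[, 1] + 0.6 * c(-1, 0, 1)[cls]
    ig <- cbind(IgG = stats::rnorm(n, 9.5, 1) + 0.5 * (cls == 1) - 0.5 * (cls == 2),
                IgA = stats::rnorm(n, 2.4, 0.5),
                IgM = stats::rnorm(n, 0.9, 0.2))
  })
  colnames(prot) <- c(sprintf("SIG%02d", seq_len(s_signal)),
                      sprintf("NOISE%02d", seq_len(n_noise)))
  colnames(med) <- sprintf("med_%02d", seq_len(n_medical))
  tab <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                    label = cls, prot, med, ig,
                    stringsAsFactors = FALSE, check.names = FALSE)
  structure(list(table = tab,
                 protein_cols = colnames(prot),
                 medical_cols = colnames(med),
                 ig_cols = colnames(ig),
                 signal_proteins = colnames(prot)[seq_len(s_signal)]),
            class = c("feature_cohort", "feature_table"))
}
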