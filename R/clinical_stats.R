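#' Aggregate repeated same-day clinical observations
#'
#' Collapses multiple observations of a variable on the same patient-day by
#' the rule registered for that variable (`median`, `min` or `max` — the most
#' clinically informative value, e.g. maximum for creatinine). In ML mode
#' (`fill_days > 0`) a missing day-1 value is completed from the subsequent
#' `fill_days` days, nearest day first.
#'
#' @param clinical long data.frame: patient_id, day, variable, value
#'   (character; numeric variables are parsed per registry).
#' @param registry data.frame: variable, type (`numeric`/`categorical`),
#'   aggregation (`median`/`min`/`max` for numeric).
#' @param day target day (default 1).
#' @param fill_days how many subsequent days may fill a missing value
#'   (default 0; the ML feature table uses 2).
#' @return wide data.frame, one row per patient, one column per variable
#'   (numeric columns numeric, categorical columns character).
#' @export
aggregate_daily <- function(clinical, registry, day = 1L, fill_days = 0L) {
  stopifnot(all(c("patient_id", "day", "variable", "value") %in% names(clinical)),
            all(c("variable", "type", "aggregation") %in% names(registry)))
  unreg <- setdiff(unique(clinical$variable), registry$variable)
  if (length(unreg))
    stop("unregistered variable(s): ", paste(unreg, collapse = ", "))
  patients <- unique(clinical$patient_id)
  out <- data.frame(patient_id = patients, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(registry))) {
    v <- registry$variable[i]
    numeric_var <- registry$type[i] == "numeric"
    agg_fun <- switch(registry$aggregation[i] %||% "median",
                      median = stats::median, min = min, max = max,
                      stats::median)
    col <- rep(if (numeric_var) NA_real_ else NA_character_, length(patients))
    for (pi in seq_along(patients)) {
      for (d in day + seq.int(0L, fill_days)) {
        rows <- clinical$patient_id == patients[pi] & clinical$day == d &
          clinical$variable == v & !is.na(clinical$value)
        if (!any(rows)) next
        vals <- clinical$value[rows]
        if (numeric_var) col[pi] <- agg_fun(as.numeric(vals))
        else col[pi] <- vals[1]
        break
      }
    }
    out[[v]] <- col
  }
  out
}

#' Per-cluster summaries in publication-table form
#'
#' Numeric variables: 25th percentile, median and 75th percentile
#' (linear-interpolation quantiles, type 7). Categorical variables: counts
#' and percentages over non-missing values — denominators are always the
#' actual number of available data points per variable and cluster.
#'
#' @param values numeric vector or factor/character vector.
#' @param labels cluster label per element.
#' @return data.frame of per-cluster summaries; numeric: cluster, n, q25,
#'   median, q75; categorical: cluster, level, n, total, percent.
#' @export
summarize_by_cluster <- function(values, labels) {
  g <- factor(labels)
  if (is.numeric(values)) {
    do.call(rbind, lapply(levels(g), function(l) {
      v <- values[g == l & !is.na(values)]
      q <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)
           else rep(NA_real_, 3)
      data.frame(cluster = l, n = length(v),
                 q25 = q[[1]], median = q[[2]], q75 = q[[3]])
    }))
  } else {
    values <- factor(values)
    do.call(rbind, lapply(levels(g), function(l) {
      v <- values[g == l & !is.na(values)]
      tab <- table(v)
      data.frame(cluster = l, level = names(tab),
                 n = as.integer(tab), total = length(v),
                 percent = 100 * as.integer(tab) / length(v))
    }))
  }
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H statistic with tie correction and the chi-square
#' approximation on `k - 1` degrees of freedom. All-tied input returns
#' `p = 1` with a degenerate flag.
#'
#' @param values numeric vector.
#' @param labels group label per element.
#' @return list with `H`, `p`, `df`, `degenerate`.
#' @export
kruskal_wallis <- function(values, labels) {
  ok <- !is.na(values) & !is.na(labels)
  v <- values[ok]; g <- factor(labels[ok])
  stopifnot(nlevels(g) >= 2)
  if (length(unique(v)) < 2)
    return(list(H = 0, p = 1, df = nlevels(g) - 1L, degenerate = TRUE))
  kt <- stats::kruskal.test(v, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), degenerate = FALSE)
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise z statistics on the pooled ranks with tie correction,
#'
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12 (N - 1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}
#'
#' with two-sided p-values from the standard normal, multiplied by the
#' number of pairs `C(k, 2)` and capped at 1.
#'
#' @param values numeric vector.
#' @param labels group label per element.
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return data.frame: group1, group2, z, p (raw), p_adj.
#' @export
dunn_posthoc <- function(values, labels, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  ok <- !is.na(values) & !is.na(labels)
  v <- values[ok]; g <- factor(labels[ok])
  stopifnot(nlevels(g) >= 2)
  N <- length(v)
  r <- rank(v)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  varfac <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(levels(g), 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(varfac * (1 / n[[a]] + 1 / n[[b]]))
    z[j] <- (rbar[[a]] - rbar[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  p_adj <- if (adjust == "bonferroni") pmin(1, p * ncol(pairs)) else p
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = z, p = p, p_adj = p_adj, stringsAsFactors = FALSE)
}

#' Contingency test with chi-square/Fisher switching
#'
#' Chi-square without continuity correction when all expected counts are at
#' least 5, otherwise Fisher's exact test. Pairwise 2x2 column comparisons
#' are Bonferroni-adjusted by the number of pairs and capped at 1.
#' Zero-margin rows/columns are dropped with a warning.
#'
#' @param counts integer matrix (r x k contingency table; columns = clusters).
#' @param pairwise also compute pairwise column tests (default TRUE when
#'   `k > 2`).
#' @return list with `p`, `method`, and (if requested) `pairwise`
#'   data.frame (group1, group2, p, p_adj, method).
#' @export
categorical_test <- function(counts, pairwise = ncol(counts) > 2) {
  counts <- as.matrix(counts)
  drop_r <- rowSums(counts) == 0
  drop_c <- colSums(counts) == 0
  if (any(drop_r) || any(drop_c)) {
    warning("dropping zero-margin rows/columns")
    counts <- counts[!drop_r, !drop_c, drop = FALSE]
  }
  stopifnot(nrow(counts) >= 2, ncol(counts) >= 2)
  one_test <- function(tab) {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(expected >= 5))
      list(p = stats::chisq.test(tab, correct = FALSE)$p.value,
           method = "chi-squared")
    else
      list(p = stats::fisher.test(tab,
                                  workspace = 2e6,
                                  simulate.p.value = prod(dim(tab)) > 12,
                                  B = 1e5)$p.value,
           method = "fisher")
  }
  omni <- one_test(counts)
  out <- list(p = omni$p, method = omni$method)
  if (pairwise) {
    cols <- colnames(counts) %||% as.character(seq_len(ncol(counts)))
    prs <- utils::combn(seq_len(ncol(counts)), 2)
    m <- ncol(prs)
    pw <- do.call(rbind, lapply(seq_len(m), function(j) {
      tab <- counts[, prs[, j], drop = FALSE]
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      tt <- one_test(tab)
      data.frame(group1 = cols[prs[1, j]], group2 = cols[prs[2, j]],
                 p = tt$p, p_adj = min(1, tt$p * m), method = tt$method,
                 stringsAsFactors = FALSE)
    }))
    out$pairwise <- pw
  }
  out
}

#' Kaplan-Meier curves per cluster and survival-time summary
#'
#' Product-limit survival estimate per cluster with administrative censoring
#' at 30 days, via the standard survival machinery; separately, the
#' publication-table statistic: median (IQR) of the death day among deceased
#' patients only.
#'
#' @param times follow-up time in days (death day for deceased, 30 for
#'   survivors).
#' @param events logical/0-1 death indicator.
#' @param labels cluster label per patient.
#' @return list with `curves` (data.frame: cluster, time, n_risk, n_event,
#'   surv) and `death_day_summary` (cluster, n_deceased, q25, median, q75).
#' @export
km_curve <- function(times, events, labels) {
  stopifnot(all(times >= 0 & times <= 30, na.rm = TRUE))
  g <- if (is.factor(labels)) labels else factor(labels)
  curves <- do.call(rbind, lapply(levels(g), function(l) {
    sel <- g == l & !is.na(times)
    if (!any(sel)) {
      warning("empty cluster skipped: ", l)
      return(NULL)
    }
    sf <- survival::survfit(survival::Surv(times[sel], events[sel]) ~ 1)
    data.frame(cluster = l, time = sf$time, n_risk = sf$n.risk,
               n_event = sf$n.event, surv = sf$surv)
  }))
  dd <- do.call(rbind, lapply(levels(g), function(l) {
    sel <- g == l & as.logical(events) & !is.na(times)
    q <- if (any(sel)) stats::quantile(times[sel], c(0.25, 0.5, 0.75), type = 7)
         else rep(NA_real_, 3)
    data.frame(cluster = l, n_deceased = sum(sel),
               q25 = q[[1]], median = q[[2]], q75 = q[[3]])
  }))
  list(curves = curves, death_day_summary = dd)
}

#' Publication-style clinical summary table
#'
#' For every registered variable: per-cluster summaries
#' ([summarize_by_cluster()]), the omnibus test (Kruskal-Wallis for numeric,
#' chi-square/Fisher for categorical) and Bonferroni-adjusted pairwise
#' post-hoc p-values (Dunn for numeric, 2x2 contingency tests for
#' categorical). Omnibus p-values are reported raw, as in the source table.
#'
#' @param wide one-row-per-patient data.frame from [aggregate_daily()].
#' @param registry variable registry.
#' @param labels named integer vector of subtype labels (names = patient id).
#' @return data.frame, one row per variable x cluster pair summary with
#'   omnibus and post-hoc p columns in long form.
#' @export
clinical_summary_table <- function(wide, registry, labels) {
  lab <- labels[wide$patient_id]
  rows <- lapply(registry$variable, function(v) {
    vals <- wide[[v]]
    if (registry$type[registry$variable == v] == "numeric") {
      omni <- kruskal_wallis(vals, lab)
      ph <- dunn_posthoc(vals, lab)
      data.frame(variable = v, type = "numeric",
                 omnibus_p = omni$p,
                 pair = paste(ph$group1, ph$group2, sep = "-"),
                 pair_p_adj = ph$p_adj, stringsAsFactors = FALSE)
    } else {
      tab <- table(vals, lab)
      ct <- categorical_test(as.matrix(tab))
      pair <- if (!is.null(ct$pairwise))
        data.frame(pair = paste(ct$pairwise$group1, ct$pairwise$group2,
                                sep = "-"),
                   pair_p_adj = ct$pairwise$p_adj)
      else data.frame(pair = NA_character_, pair_p_adj = NA_real_)
      data.frame(variable = v, type = "categorical",
                 omnibus_p = ct$p, pair, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
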