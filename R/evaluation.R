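# Evaluation: the smoothed Dice similarity coefficient and the statistical
# comparison suite over DSC tables (Kruskal-Wallis across models with
# Holm-Bonferroni adjustment and Dunn post hoc; Mann-Kendall age trends
# with Benjamini-Hochberg FDR control; Mann-Whitney age-group and
# cohort comparisons). All table-level functions take a tibble of DSC
# records (patient, organ, model, cohort, age, dsc) and return tibbles.

#' Statistical analysis configuration
#'
#' @param alpha_holm family-wise alpha for the Kruskal-Wallis stage.
#' @param alpha_fdr FDR level for trend and cohort batches.
#' @param alpha_pairwise alpha for Dunn and Mann-Whitney tests.
#' @param age_split years; records with `age >= age_split` form the older
#'   group (an age of exactly 10 goes to the older group).
#' @param epsilon DSC smoothing term.
#' @return a `stats_config` list.
#' @export
stats_config <- function(alpha_holm = 0.05, alpha_fdr = 0.05,
                         alpha_pairwise = 0.05, age_split = 10,
                         epsilon = 1e-7) {
  for (a in c(alpha_holm, alpha_fdr, alpha_pairwise)) {
    if (a <= 0 || a >= 1) abort("alpha levels must be in (0,1).")
  }
  structure(list(alpha_holm = alpha_holm, alpha_fdr = alpha_fdr,
                 alpha_pairwise = alpha_pairwise, age_split = age_split,
                 epsilon = epsilon),
            class = "stats_config")
}

#' Dice similarity coefficient with smoothing
#'
#' `(2|A intersect B| + eps) / (|A| + |B| + eps)`; the smoothing term keeps
#' the coefficient defined (and equal to 1) when both masks are empty.
#'
#' @param A,B binary arrays of identical shape.
#' @param epsilon smoothing term, default `1e-7`.
#' @return the 3D DSC in `[0, 1]`.
#' @export
dsc <- function(A, B, epsilon = 1e-7) {
  if (!identical(dim(A), dim(B))) abort("mask shapes differ.")
  a <- A != 0; b <- B != 0
  (2 * sum(a & b) + epsilon) / (sum(a) + sum(b) + epsilon)
}

#' Assemble a DSC record row
#'
#' @param patient,organ,model,cohort identifiers.
#' @param age patient age in years.
#' @param dsc_value DSC in `[0, 1]`.
#' @return one-row tibble.
#' @export
dsc_record <- function(patient, organ, model, dsc_value, age = NA_real_,
                       cohort = NA_character_) {
  if (dsc_value < 0 || dsc_value > 1) abort("dsc must be in [0,1].")
  tibble::tibble(patient = patient, organ = organ, model = model,
                 cohort = cohort, age = age, dsc = dsc_value)
}

check_records <- function(records, cols = c("organ", "model", "dsc")) {
  miss <- setdiff(cols, names(records))
  if (length(miss)) abort(paste("records lack columns:", paste(miss, collapse = ", ")))
  invisible(records)
}

stat_row <- function(test, organ, grouping, statistic, p_raw,
                     p_adjusted = NA_real_, adjust_method = "none",
                     significant = NA) {
  tibble::tibble(test = test, organ = organ, grouping = grouping,
                 statistic = statistic, p_raw = p_raw,
                 p_adjusted = p_adjusted, adjust_method = adjust_method,
                 significant = significant)
}

# --- Mann-Kendall ----------------------------------------------------------

#' Mann-Kendall trend test
#'
#' The original (unmodified) test: `S` is the signed count of concordant
#' minus discordant pairs of the sequence in time order, its variance uses
#' the tie correction, and the z statistic carries the +/-1 continuity
#' correction. `tau = S / (n(n-1)/2)`.
#'
#' @param x numeric sequence already sorted by the time covariate.
#' @return list with `S`, `var_s`, `tau`, `z`, `p` (two-sided).
#' @export
mann_kendall <- function(x) {
  n <- length(x)
  if (n < 4) abort("Mann-Kendall needs at least 4 observations.")
  S <- 0
  for (i in seq_len(n - 1)) {
    S <- S + sum(sign(x[(i + 1):n] - x[i]))
  }
  ties <- table(x)
  t_j <- as.numeric(ties[ties > 1])
  var_s <- (n * (n - 1) * (2 * n + 5) - sum(t_j * (t_j - 1) * (2 * t_j + 5))) / 18
  z <- if (S > 0) (S - 1) / sqrt(var_s) else if (S < 0) (S + 1) / sqrt(var_s) else 0
  p <- 2 * stats::pnorm(-abs(z))
  list(S = S, var_s = var_s, tau = S / (n * (n - 1) / 2), z = z, p = min(1, p))
}

# --- Dunn post hoc ---------------------------------------------------------

# Dunn's multiple-comparison z statistics on the joint ranks, with the
# standard tie correction; two-sided normal p-values.
dunn_pairs <- function(values, groups) {
  groups <- as.character(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  t_j <- as.numeric(ties[ties > 1])
  tie_term <- sum(t_j^3 - t_j) / (12 * (N - 1))
  lev <- unique(groups)
  mean_r <- vapply(lev, function(g) mean(r[groups == g]), numeric(1))
  n_g <- vapply(lev, function(g) sum(groups == g), numeric(1))
  out <- list()
  for (i in seq_along(lev)[-length(lev)]) {
    for (j in (i + 1):length(lev)) {
      se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[i] + 1 / n_g[j]))
      z <- unname((mean_r[i] - mean_r[j]) / se)
      out[[length(out) + 1L]] <- tibble::tibble(
        group1 = lev[i], group2 = lev[j], z = z,
        p = min(1, 2 * stats::pnorm(-abs(z)))
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Compare models per organ: Kruskal-Wallis with Holm adjustment, Dunn post
#' hoc
#'
#' One Kruskal-Wallis H test per organ across models, Holm-Bonferroni
#' adjusted over the family of organs; organs surviving adjustment get
#' Dunn's pairwise post-hoc comparisons (reported unadjusted within the
#' organ's family by default).
#'
#' @param records DSC record tibble.
#' @param cfg a [stats_config()].
#' @param adjust_pairwise adjust Dunn p-values within each organ's family
#'   ("none" or a [stats::p.adjust()] method).
#' @return tibble of test results (`test`, `organ`, `grouping`,
#'   `statistic`, `p_raw`, `p_adjusted`, `adjust_method`, `significant`).
#' @export
compare_models <- function(records, cfg = stats_config(), adjust_pairwise = "none") {
  check_records(records)
  if (dplyr::n_distinct(records$model) < 2) abort("need at least two models.")
  kw <- records |>
    dplyr::group_by(.data$organ) |>
    dplyr::group_modify(function(df, key) {
      if (dplyr::n_distinct(df$model) < 2) abort("need >= 2 models per organ.")
      ht <- stats::kruskal.test(df$dsc, factor(df$model))
      tibble::tibble(statistic = unname(ht$statistic), p_raw = ht$p.value)
    }) |>
    dplyr::ungroup()
  kw$p_adjusted <- stats::p.adjust(kw$p_raw, method = "holm")
  kw_rows <- stat_row("kruskal_wallis", kw$organ, "model", kw$statistic,
                      kw$p_raw, kw$p_adjusted, "holm_bonferroni",
                      kw$p_adjusted <= cfg$alpha_holm)
  dunn_rows <- list()
  for (org in kw$organ[kw$p_adjusted <= cfg$alpha_holm]) {
    df <- records[records$organ == org, ]
    dp <- dunn_pairs(df$dsc, df$model)
    p_adj <- if (adjust_pairwise == "none") dp$p else stats::p.adjust(dp$p, adjust_pairwise)
    dunn_rows[[org]] <- stat_row(
      "dunn", org, paste(dp$group1, "vs", dp$group2), dp$z, dp$p,
      p_adj, if (adjust_pairwise == "none") "none" else adjust_pairwise,
      p_adj <= cfg$alpha_pairwise
    )
  }
  dplyr::bind_rows(kw_rows, dplyr::bind_rows(dunn_rows))
}

#' DSC trend with patient age, per model and organ
#'
#' Mann-Kendall on the DSC sequence sorted by age, for every model-organ
#' cell; Benjamini-Hochberg FDR applied across the whole batch.
#'
#' @param records DSC record tibble with an `age` column.
#' @param cfg a [stats_config()].
#' @return tibble of trend results (`statistic` is Kendall's tau; `model`
#'   column added).
#' @export
trend_with_age <- function(records, cfg = stats_config()) {
  check_records(records, c("organ", "model", "dsc", "age"))
  res <- records |>
    dplyr::group_by(.data$model, .data$organ) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 4) abort("need >= 4 records for a trend test.")
      df <- df[order(df$age), ]
      mk <- mann_kendall(df$dsc)
      tibble::tibble(statistic = mk$tau, p_raw = mk$p)
    }) |>
    dplyr::ungroup()
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = "BH")
  dplyr::bind_cols(
    tibble::tibble(model = res$model),
    stat_row("mann_kendall", res$organ, "age", res$statistic, res$p_raw,
             res$p_adjusted, "fdr_bh", res$p_adjusted <= cfg$alpha_fdr)
  )
}

#' Compare DSC between young and old patients
#'
#' Two-sided Mann-Whitney U between the `age < age_split` and
#' `age >= age_split` groups (exactly 10 years goes to the older group);
#' unadjusted, following up on an observed trend.
#'
#' @param records DSC record tibble for one model and organ.
#' @param model,organ cell selectors.
#' @param cfg a [stats_config()].
#' @return one-row result tibble.
#' @export
age_group_compare <- function(records, model, organ, cfg = stats_config()) {
  check_records(records, c("organ", "model", "dsc", "age"))
  df <- records[records$model == model & records$organ == organ, ]
  young <- df$dsc[df$age < cfg$age_split]
  old <- df$dsc[df$age >= cfg$age_split]
  if (!length(young) || !length(old)) abort("both age groups must be nonempty.")
  ht <- suppressWarnings(stats::wilcox.test(young, old, exact = length(df$dsc) <= 20))
  dplyr::bind_cols(
    tibble::tibble(model = model),
    stat_row("mann_whitney", organ, sprintf("age<%s vs age>=%s", cfg$age_split, cfg$age_split),
             unname(ht$statistic), ht$p.value, ht$p.value, "none",
             ht$p.value <= cfg$alpha_pairwise)
  )
}

#' Compare DSC between cohorts, per model and organ
#'
#' Two-sided Mann-Whitney U between the validation and test cohorts for
#' every model-organ cell, with Benjamini-Hochberg FDR across the batch.
#'
#' @param records DSC record tibble with a `cohort` column holding both
#'   cohorts.
#' @param cohorts the two cohort labels to compare.
#' @param cfg a [stats_config()].
#' @return tibble of results.
#' @export
dataset_compare <- function(records, cohorts = c("validation", "test"),
                            cfg = stats_config()) {
  check_records(records, c("organ", "model", "dsc", "cohort"))
  res <- records |>
    dplyr::group_by(.data$model, .data$organ) |>
    dplyr::group_modify(function(df, key) {
      a <- df$dsc[df$cohort == cohorts[1]]
      b <- df$dsc[df$cohort == cohorts[2]]
      if (!length(a) || !length(b)) abort("both cohorts must be present.")
      ht <- suppressWarnings(stats::wilcox.test(a, b, exact = (length(a) + length(b)) <= 20))
      tibble::tibble(statistic = unname(ht$statistic), p_raw = ht$p.value)
    }) |>
    dplyr::ungroup()
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = "BH")
  dplyr::bind_cols(
    tibble::tibble(model = res$model),
    stat_row("mann_whitney", res$organ, paste(cohorts, collapse = " vs "),
             res$statistic, res$p_raw, res$p_adjusted, "fdr_bh",
             res$p_adjusted <= cfg$alpha_fdr)
  )
}

#' Summarize a DSC table as mean +/- standard deviation
#'
#' @param records DSC record tibble.
#' @return tibble with one row per organ x model x cohort: `n`, `mean`,
#'   `sd` (0 for a single record) and a formatted `mean_sd` string.
#' @export
summarize_dsc <- function(records) {
  check_records(records)
  records |>
    dplyr::group_by(.data$organ, .data$model,
                    cohort = if ("cohort" %in% names(records)) .data$cohort else NA) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$dsc),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$dsc), 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean_sd = sprintf("%.2f ± %.2f", .data$mean, .data$sd))
}

#' Write DSC summary and statistics tables as delimited text
#'
#' @param records DSC record tibble.
#' @param stats optional tibble of statistical results.
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
write_report <- function(records, stats = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, "dsc_summary.tsv")
  utils::write.table(summarize_dsc(records), paths[1], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(stats)) {
    p2 <- file.path(dir, "statistics.tsv")
    utils::write.table(stats, p2, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}

#' Box plot of DSC by organ and model
#'
#' @param records DSC record tibble.
#' @return a ggplot object.
#' @export
plot_dsc <- function(records) {
  check_records(records)
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$organ, y = .data$dsc, fill = .data$model)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "DSC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
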