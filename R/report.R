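#' Full group-level analysis
#'
#' Reproduces the study's statistical layer on a simulated (or imported)
#' cohort: questionnaire group contrasts, behavioural contrasts and
#' mixed-logistic error models, ERP group contrasts per condition and
#' channel pool, the Spearman correlation matrix between the
#' centroparietal Go-condition P3 measures and the questionnaire indices,
#' and both biomarker regression pairs (P3 amplitude + latency, and P3
#' amplitude + N2-P3 interpeak latency, each predicting the BBI-15 score
#' and the BRIEF-A metacognition index). Only ERP-eligible subjects enter
#' the ERP contrasts, correlations, and regressions. All p-values are
#' nominal (uncorrected), matching the study's reporting.
#'
#' If a group is absent the report is marked partial and the affected
#' sections are listed in `gaps`.
#'
#' @param cohort A `cohort_data` from [simulate_cohort()], or a list with
#'   `profiles`, `outcomes`, `measures`, `exclusions`.
#' @return A list of class `erp_report`.
#' @export
run_full_analysis <- function(cohort) {
  profiles <- cohort$profiles
  measures <- cohort$measures
  outcomes <- cohort$outcomes
  gaps <- character()
  groups_present <- intersect(c("burnout", "non_burnout"),
                              unique(profiles$group))
  two_groups <- length(groups_present) == 2

  split2 <- function(values, group) {
    list(a = values[group == "burnout"], b = values[group == "non_burnout"])
  }

  ## -- questionnaire contrasts ------------------------------------------
  scales <- c("age_years", "bbi15", "bdi21", "brief_bri", "brief_mi",
              "brief_gec")
  questionnaires <- NULL
  if (two_groups) {
    questionnaires <- do.call(rbind, lapply(scales, function(sc) {
      g <- split2(profiles[[sc]], profiles$group)
      kw <- kruskal_wallis(g$a, g$b, c("burnout", "non_burnout"))
      data.frame(scale = sc,
                 burnout_mean = mean(g$a), burnout_sd = sd(g$a),
                 non_burnout_mean = mean(g$b), non_burnout_sd = sd(g$b),
                 chisq = kw$statistic, p = kw$p_value,
                 stringsAsFactors = FALSE)
    }))
  } else gaps <- c(gaps, "questionnaire contrasts (one group absent)")

  ## -- behaviour ---------------------------------------------------------
  behavior <- list()
  if (!is.null(outcomes) && nrow(outcomes)) {
    test <- outcomes[!outcomes$is_practice, , drop = FALSE]
    per_group <- lapply(setNames(groups_present, groups_present), function(g)
      summarize_behavior(test[test$group == g, , drop = FALSE],
                         practice_excluded = FALSE))
    behavior$summary <- per_group
    if (two_groups) {
      rt <- lapply(per_group, function(s) s$per_subject$median_rt_ms)
      behavior$rt_contrast <- kruskal_wallis(rt$burnout, rt$non_burnout,
                                             c("burnout", "non_burnout"))
      behavior$error_contrasts <- lapply(
        setNames(nm = c("pct_total", "pct_incorrect", "pct_miss",
                        "pct_commission")),
        function(m) kruskal_wallis(per_group$burnout$per_subject[[m]],
                                   per_group$non_burnout$per_subject[[m]],
                                   c("burnout", "non_burnout")))
      behavior$or_tables <- lapply(
        setNames(nm = c("total", "incorrect", "miss", "commission")),
        function(ty) tryCatch(fit_error_model(test, ty),
                              error = function(e) conditionMessage(e)))
    } else gaps <- c(gaps, "behavioural contrasts (one group absent)")
  } else gaps <- c(gaps, "behaviour (no trial outcomes supplied)")

  ## -- ERP contrasts -----------------------------------------------------
  erp_contrasts <- NULL
  eligible <- measures[measures$eligible, , drop = FALSE]
  metrics <- c("n2_amplitude_uv", "n2_latency_ms", "p3_amplitude_uv",
               "p3_latency_ms", "n2_p3_ipl_ms")
  if (two_groups && nrow(eligible) &&
      all(table(eligible$group[!duplicated(eligible$subject)]) >= 2)) {
    grid <- expand.grid(condition = unique(eligible$condition),
                        pool = unique(eligible$pool), metric = metrics,
                        stringsAsFactors = FALSE)
    erp_contrasts <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      sel <- eligible[eligible$condition == grid$condition[i] &
                        eligible$pool == grid$pool[i], , drop = FALSE]
      g <- split2(sel[[grid$metric[i]]], sel$group)
      if (length(g$a) < 2 || length(g$b) < 2) return(NULL)
      kw <- kruskal_wallis(g$a, g$b, c("burnout", "non_burnout"))
      data.frame(condition = grid$condition[i], pool = grid$pool[i],
                 metric = grid$metric[i],
                 burnout_median = kw$medians["burnout"],
                 burnout_iqr = kw$iqrs["burnout"],
                 non_burnout_median = kw$medians["non_burnout"],
                 non_burnout_iqr = kw$iqrs["non_burnout"],
                 chisq = kw$statistic, p = kw$p_value,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  } else gaps <- c(gaps, "ERP contrasts (insufficient eligible subjects)")

  ## -- correlations and biomarker regressions (CP, Go) -------------------
  correlations <- NULL
  regressions <- NULL
  cp_go <- eligible[eligible$condition == "Go" &
                      eligible$pool == "centroparietal", , drop = FALSE]
  if (nrow(cp_go) >= 4) {
    d <- merge(cp_go, profiles, by = "subject")
    erp_vars <- c(p3_amplitude_uv = "CP P3 Go amplitude",
                  p3_latency_ms = "CP P3 Go latency",
                  n2_p3_ipl_ms = "CP N2-P3 Go IPL")
    q_vars <- c(bbi15 = "BBI-15", bdi21 = "BDI-21", brief_gec = "GEC",
                brief_mi = "MI", brief_bri = "BRI")
    correlations <- do.call(rbind, lapply(names(q_vars), function(qv)
      do.call(rbind, lapply(names(erp_vars), function(ev) {
        sp <- spearman(d[[ev]], d[[qv]])
        data.frame(questionnaire = q_vars[[qv]], erp_measure = erp_vars[[ev]],
                   rho = sp$rho, p = sp$p_value, n = sp$n,
                   stringsAsFactors = FALSE)
      }))))
    models <- list(
      amp_lat = c("p3_amplitude_uv", "p3_latency_ms"),
      amp_ipl = c("p3_amplitude_uv", "n2_p3_ipl_ms"))
    regressions <- lapply(models, function(preds)
      lapply(setNames(nm = c("bbi15", "brief_mi")), function(resp)
        tryCatch(fit_biomarker_model(d, resp, preds),
                 error = function(e) conditionMessage(e))))
  } else gaps <- c(gaps, "correlations/regressions (too few eligible subjects)")

  n_eligible <- table(eligible$group[!duplicated(eligible$subject)])
  structure(list(
    questionnaires = questionnaires,
    behavior = behavior,
    erp_contrasts = erp_contrasts,
    correlations = correlations,
    regressions = regressions,
    n_per_group = table(profiles$group),
    n_erp_eligible = n_eligible,
    exclusions = cohort$exclusions,
    partial = length(gaps) > 0,
    gaps = gaps
  ), class = "erp_report")
}

#' @export
print.erp_report <- function(x, ...) {
  cat("==== ERP biomarker analysis report ====\n")
  cat("Cohort:", paste(sprintf("%s n=%d", names(x$n_per_group),
                               x$n_per_group), collapse = ", "),
      "| ERP-eligible:", paste(sprintf("%s n=%d", names(x$n_erp_eligible),
                                       x$n_erp_eligible), collapse = ", "),
      "\n")
  if (x$partial)
    cat("PARTIAL report; missing sections:\n ",
        paste(x$gaps, collapse = "\n  "), "\n")
  if (!is.null(x$questionnaires)) {
    cat("\n-- Questionnaire group contrasts (Kruskal-Wallis) --\n")
    print(x$questionnaires, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$behavior$rt_contrast)) {
    cat("\n-- Reaction time (correct Go trials) --\n")
    print(x$behavior$rt_contrast)
  }
  if (!is.null(x$erp_contrasts)) {
    cat("\n-- ERP group contrasts --\n")
    print(x$erp_contrasts, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$correlations)) {
    cat("\n-- Spearman correlations (CP Go measures x questionnaires) --\n")
    print(x$correlations, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$regressions)) {
    cat("\n-- Biomarker regressions --\n")
    for (m in names(x$regressions))
      for (r in names(x$regressions[[m]])) {
        obj <- x$regressions[[m]][[r]]
        if (is.character(obj)) cat(m, r, ": ", obj, "\n") else print(obj)
      }
  }
  invisible(x)
}

## ---- serialization ------------------------------------------------------

provenance_header <- function(config) {
  cfg <- config[!vapply(config, is.null, TRUE)]
  cfg$out_dir <- NULL  # paths do not define the run

  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  tmp <- tempfile(); writeLines(json, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  c(sprintf("# burnoutERP %s", as.character(utils::packageVersion("burnoutERP"))),
    sprintf("# seed: %s", config$seed),
    sprintf("# config_md5: %s", hash))
}

#' Write a tab-separated table with a provenance header
#'
#' @param x Data frame.
#' @param path Output file.
#' @param config Optional [run_config()] whose seed/hash are recorded in
#'   `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) writeLines(provenance_header(config), con)
  write.table(format(x, digits = 10, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_tsv()]
#' @param path File path.
#' @return Data frame (provenance header lines are skipped).
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

report_summary_list <- function(cohort, report) {
  num <- function(x) if (is.null(x)) NULL else x
  list(
    n_per_group = as.list(report$n_per_group),
    n_erp_eligible = as.list(report$n_erp_eligible),
    exclusions = report$exclusions,
    questionnaires = num(report$questionnaires),
    erp_contrasts = num(report$erp_contrasts),
    correlations = num(report$correlations),
    regressions = lapply(report$regressions, function(m)
      lapply(m, function(r) if (is.character(r)) list(error = r) else
        list(f = r$f_statistic, df1 = r$df1, df2 = r$df2, p = r$p_value,
             r2 = r$r2, adj_r2 = r$adj_r2, n = r$n))),
    gaps = report$gaps
  )
}

write_report_bundle <- function(cohort, report, dir) {
  cfg <- cohort$config
  paths <- c(
    trials = write_tsv(cohort$outcomes, file.path(dir, "trials.tsv"), cfg),
    profiles = write_tsv(cohort$profiles, file.path(dir, "profiles.tsv"), cfg),
    measures = write_tsv(cohort$measures, file.path(dir, "measures.tsv"), cfg),
    summary = {
      p <- file.path(dir, "summary.json")
      jsonlite::write_json(report_summary_list(cohort, report), p,
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows")
      p
    })
  paths
}
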