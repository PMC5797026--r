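# End-to-end pipeline ---------------------------------------------------------

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

fmt1 <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f", x))
fmt3 <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))

#' Run the full NK-AML analysis pipeline
#'
#' Orchestrates filter, classify, subgroup statistics and survival analysis
#' into one reproducible run: reads the mutation and clinical tables,
#' applies the somatic retention filter, classifies every patient into the
#' eight genomic subgroups, computes CR and transplant subgroup-vs-rest
#' statistics, derives endpoints and estimates per-subgroup 5-year OS, EFS
#' (Kaplan-Meier) and relapse incidence (Aalen-Johansen), with log-rank and
#' Gray tests across subgroups and a Cox model with transplant as a
#' time-dependent covariate. Output is a pure function of the input files
#' and options; the run log records versions and thresholds.
#'
#' @param mutation_file mutation table path (`.vcf` selects the VCF-like
#'   dialect, anything else the MAF-like TSV).
#' @param clinical_file clinical table path (CSV/TSV).
#' @param out_dir output directory (created if needed); when `NULL`
#'   nothing is written and only the result bundle is returned.
#' @param panel a [gene_panel()].
#' @param vaf_min,p_max somatic-filter thresholds (see
#'   [apply_somatic_filter()]).
#' @param noncr_efs_time EFS event time for CR non-achievers (months).
#' @param report_format `"csv"` or `"markdown"` for the Table-1-style
#'   report.
#' @param seed recorded in the run log (the pipeline itself draws no random
#'   numbers).
#' @return object of class `nkaml_run`: list with `filter_decisions`,
#'   `classification`, `cr_stats`, `sct_stats`, `survival_summary`,
#'   `tests`, `cox_sct`, `table1`, `files`.
#' @export
run_pipeline <- function(mutation_file, clinical_file, out_dir = NULL,
                         panel = default_gene_panel(),
                         vaf_min = 0.03, p_max = 0.001,
                         noncr_efs_time = 1,
                         report_format = c("csv", "markdown"),
                         seed = NULL) {
  report_format <- match.arg(report_format)
  mut_format <- if (grepl("\\.vcf$", mutation_file)) "vcf_like" else "maf_tsv"
  variants <- stage("read_mutations",
                    read_mutation_table(mutation_file, mut_format))
  clinical <- stage("read_clinical", read_clinical_table(clinical_file))

  decisions <- stage("filter",
                     apply_somatic_filter(variants, panel, vaf_min, p_max))
  profiles <- stage("profiles",
                    build_profiles(decisions, panel,
                                   patient_ids = clinical$patient_id))
  classification <- stage("classify", classify_cohort(profiles, panel))
  labels <- classification$assignments$label

  stopifnot(identical(classification$assignments$patient_id,
                      clinical$patient_id))
  cr_stats <- stage("stats", suppressWarnings(
    subgroup_vs_rest(labels, clinical$cr_achieved)))
  sct_stats <- stage("stats", suppressWarnings(
    subgroup_vs_rest(labels, !is.na(clinical$sct_time))))

  ep <- stage("endpoints", derive_endpoints(clinical, noncr_efs_time))
  surv_rows <- stage("survival", lapply(GENOMIC_CLASSES, function(cl) {
    sel <- labels == cl
    row <- data.frame(label = cl, n = sum(sel),
                      os5 = NA_real_, os5_low = NA_real_, os5_high = NA_real_,
                      efs5 = NA_real_, efs5_low = NA_real_,
                      efs5_high = NA_real_,
                      relapse5 = NA_real_, relapse5_low = NA_real_,
                      relapse5_high = NA_real_, stringsAsFactors = FALSE)
    if (!any(sel)) return(row)
    os <- survival_at(kaplan_meier(ep$os_time[sel], ep$os_event[sel]))
    efs <- survival_at(kaplan_meier(ep$efs_time[sel], ep$efs_event[sel]))
    row$os5 <- 100 * os$estimate
    row$os5_low <- 100 * os$ci_low; row$os5_high <- 100 * os$ci_high
    row$efs5 <- 100 * efs$estimate
    row$efs5_low <- 100 * efs$ci_low; row$efs5_high <- 100 * efs$ci_high
    crsel <- sel & !is.na(ep$relapse_code)
    if (any(crsel)) {
      aj <- aalen_johansen(ep$relapse_time[crsel], ep$relapse_code[crsel])
      if (1 %in% attr(aj, "causes")) {
        rl <- cif_at(aj, 60, cause = 1)
        row$relapse5 <- 100 * rl$estimate
        row$relapse5_low <- 100 * rl$ci_low
        row$relapse5_high <- 100 * rl$ci_high
      } else {
        row$relapse5 <- 0
      }
    }
    row
  }))
  survival_summary <- do.call(rbind, surv_rows)

  present <- GENOMIC_CLASSES[GENOMIC_CLASSES %in% labels]
  tests <- stage("survival", {
    multi <- length(present) >= 2
    lr_os <- if (multi) logrank(ep$os_time, ep$os_event,
                                droplevels(factor(labels))) else NULL
    lr_efs <- if (multi) logrank(ep$efs_time, ep$efs_event,
                                 droplevels(factor(labels))) else NULL
    crsel <- !is.na(ep$relapse_code)
    gr <- if (multi && sum(crsel) > 0 &&
              length(unique(labels[crsel])) >= 2) {
      grays_test(ep$relapse_time[crsel], ep$relapse_code[crsel],
                 droplevels(factor(labels[crsel])))
    } else {
      NULL
    }
    data.frame(
      test = c("logrank_os", "logrank_efs", "gray_relapse"),
      statistic = c(if (is.null(lr_os)) NA else lr_os$statistic,
                    if (is.null(lr_efs)) NA else lr_efs$statistic,
                    if (is.null(gr)) NA else gr$statistic),
      df = c(if (is.null(lr_os)) NA else lr_os$df,
             if (is.null(lr_efs)) NA else lr_efs$df,
             if (is.null(gr)) NA else gr$df),
      p_value = c(if (is.null(lr_os)) NA else lr_os$p_value,
                  if (is.null(lr_efs)) NA else lr_efs$p_value,
                  if (is.null(gr)) NA else gr$p_value),
      stringsAsFactors = FALSE
    )
  })

  cox_sct <- stage("survival", {
    iv <- make_sct_intervals(clinical, ep, "os")
    if (sum(iv$event) > 0 && length(unique(iv$sct)) > 1) {
      cox_time_dependent(iv, "sct")
    } else {
      NULL
    }
  })

  table1 <- stage("report", {
    cs <- classification$summary
    df <- data.frame(metric = c("n", "pct", "cr_pct", "sct_pct",
                                "relapse5_pct", "efs5_pct", "os5_pct"),
                     stringsAsFactors = FALSE)
    for (i in seq_along(GENOMIC_CLASSES)) {
      cl <- GENOMIC_CLASSES[i]
      df[[cl]] <- c(cs$n[i], cs$pct[i],
                    round(cr_stats$rate_pct[i], 1),
                    round(sct_stats$rate_pct[i], 1),
                    round(survival_summary$relapse5[i], 1),
                    round(survival_summary$efs5[i], 1),
                    round(survival_summary$os5[i], 1))
    }
    df
  })

  files <- character()
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wr <- function(x, name, ...) {
      path <- file.path(out_dir, name)
      utils::write.table(x, path, row.names = FALSE, quote = FALSE, na = ".",
                         ...)
      path
    }
    files <- c(
      wr(decisions, "filter_decisions.tsv", sep = "\t"),
      wr(classification$assignments, "labels.tsv", sep = "\t"),
      wr(classification$summary, "class_summary.csv", sep = ","),
      wr(cbind(outcome = "cr", cr_stats), "stats_cr.csv", sep = ","),
      wr(cbind(outcome = "sct", sct_stats), "stats_sct.csv", sep = ","),
      wr(survival_summary, "survival_summary.csv", sep = ","),
      wr(tests, "tests.csv", sep = ",")
    )
    rep_path <- file.path(out_dir,
                          if (report_format == "csv") "table1_replica.csv" else {
                            "table1_replica.md"
                          })
    if (report_format == "csv") {
      utils::write.table(table1, rep_path, sep = ",", row.names = FALSE,
                         quote = FALSE, na = ".")
    } else {
      hdr <- paste0("| metric | ", paste(GENOMIC_CLASSES, collapse = " | "),
                    " |")
      sepl <- paste0("|", paste(rep("---", 9), collapse = "|"), "|")
      body <- apply(table1, 1, function(r) {
        paste0("| ", paste(r, collapse = " | "), " |")
      })
      writeLines(c(hdr, sepl, body), rep_path)
    }
    files <- c(files, rep_path)
    log_path <- file.path(out_dir, "run_log.txt")
    writeLines(c(
      paste("nkaml version:", as.character(utils::packageVersion("nkaml"))),
      paste("R version:", R.version.string),
      paste("mutation_file:", mutation_file),
      paste("clinical_file:", clinical_file),
      paste("vaf_min:", vaf_min),
      paste("p_max:", p_max),
      paste("noncr_efs_time:", noncr_efs_time),
      paste("seed:", if (is.null(seed)) "NA" else seed),
      paste("n_patients:", nrow(clinical)),
      paste("n_variants:", nrow(variants)),
      paste("n_retained:", sum(decisions$retained))
    ), log_path)
    files <- c(files, log_path)
  }

  structure(
    list(filter_decisions = decisions, classification = classification,
         cr_stats = cr_stats, sct_stats = sct_stats,
         survival_summary = survival_summary, tests = tests,
         cox_sct = cox_sct, table1 = table1, files = files),
    class = "nkaml_run"
  )
}

#' @export
print.nkaml_run <- function(x, ...) {
  cat("NK-AML pipeline run:", x$classification$n, "patients\n\n")
  print(x$classification)
  cat("\n5-year outcome summary (%):\n")
  s <- x$survival_summary
  print(data.frame(label = s$label, n = s$n, os5 = fmt1(s$os5),
                   efs5 = fmt1(s$efs5), relapse5 = fmt1(s$relapse5)),
        row.names = FALSE)
  invisible(x)
}
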