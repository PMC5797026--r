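# Synthetic cohort generation ------------------------------------------------
#
# Mutation side: each patient gets the class-defining lesion(s) planted for
# the drawn label, independent Bernoulli co-mutations in FLT3/DNMT3A/NRAS/
# TET2 at the configured marginal frequencies (excluded for NO_DRIVER, the
# only label they would change), plus filter-fodder decoys (a germline-
# flagged polymorphism and a sub-threshold noise call) that the somatic
# filter must remove. Depths emulate deep targeted sequencing (400-800x)
# with planted VAFs uniform on [0.05, 0.5] and clean controls, so every
# planted lesion survives the retention rule by construction.
#
# Outcome side: the all-cause death hazard per class is exponential with
# rate -log(five_year_os)/60; for CR patients the death clock restarts at
# the CR date (memoryless residual), which shifts the class 5-year OS up by
# well under one point (CR dates fall within two months) while making the
# post-CR competing-risks calibration exact: relapse (solved hazard) and
# death without relapse (the OS hazard) compete so that the exponential
# CIF of relapse at 60 months from CR equals the configured 5-year relapse
# target. Relapse does not accelerate death - a deliberate simplification
# that keeps both calibration points essentially exact. Administrative
# censoring is uniform on (followup_min, followup_horizon).

rexp_rate <- function(n, rate) {
  if (rate <= 0) rep(Inf, n) else stats::rexp(n, rate)
}

new_variant <- function(patient_id, gene, variant_class, protein_change,
                        cfg, vaf = stats::runif(1, 0.05, 0.5),
                        has_control = TRUE,
                        germline = FALSE, known = TRUE, biallelic = FALSE) {
  t_tot <- round(stats::runif(1, 400, 800))
  t_alt <- round(vaf * t_tot)
  if (has_control) {
    # somatic variants get a clean control (zero alt reads), so every
    # planted lesion passes the Fisher rule by construction; germline
    # decoys carry the same allele fraction in the control
    n_tot <- round(stats::runif(1, 400, 800))
    n_alt <- if (germline) round(vaf * n_tot) else 0
  } else {
    n_tot <- NA_integer_
    n_alt <- NA_integer_
  }
  list(patient_id = patient_id, gene = gene, variant_class = variant_class,
       protein_change = protein_change,
       tumor_ref_depth = as.integer(t_tot - t_alt),
       tumor_alt_depth = as.integer(t_alt),
       normal_ref_depth = if (is.na(n_tot)) NA_integer_ else {
         as.integer(n_tot - n_alt)
       },
       normal_alt_depth = as.integer(n_alt),
       known_somatic_flag = known,
       germline_suspect_flag = germline,
       control_free_somatic_flag = !has_control && !germline,
       biallelic_annotation = biallelic)
}

plant_lesion <- function(lesion, patient_id, cfg, has_control) {
  switch(lesion,
    NPM1 = list(new_variant(patient_id, "NPM1", "frameshift", "p.W288fs",
                            cfg, has_control = has_control)),
    CHROMATIN_SPLICE = {
      g <- sample(CHROMATIN_SPLICEOSOME_GENES, 1)
      list(new_variant(patient_id, g, sample(c("missense", "frameshift"), 1),
                       "p.X1X", cfg, has_control = has_control))
    },
    TP53 = list(new_variant(patient_id, "TP53", "missense", "p.R175H",
                            cfg, has_control = has_control)),
    BIALLELIC_CEBPA = list(
      new_variant(patient_id, "CEBPA", "frameshift", "p.P23fs", cfg,
                  has_control = has_control),
      new_variant(patient_id, "CEBPA", "inframe_indel", "p.K313dup", cfg,
                  has_control = has_control)
    ),
    IDH2_R172 = list(new_variant(patient_id, "IDH2", "missense", "p.R172K",
                                 cfg, has_control = has_control)),
    stop("no planted lesion for ", lesion, call. = FALSE)
  )
}

co_mutation_variant <- function(gene, patient_id, cfg, has_control) {
  spec <- switch(gene,
    FLT3 = if (stats::runif(1) < 0.75) c("ITD", "p.ITD") else {
      c("missense", "p.D835Y")
    },
    DNMT3A = c("missense", "p.R882H"),
    NRAS = c("missense", "p.G12D"),
    TET2 = c("nonsense", "p.Q1084*"),
    c("missense", "p.X1X")
  )
  new_variant(patient_id, gene, spec[1], spec[2], cfg,
              has_control = has_control)
}

#' Sample one patient's mutation profile for a planted class
#'
#' Plants the class-defining lesion(s) for `label`, adds independent
#' Bernoulli co-mutations at the configured frequencies (never a gene that
#' would change the class), and appends decoy variants (a germline-flagged
#' polymorphism and a sub-threshold noise call) that exercise the somatic
#' filter. Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param label one of [GENOMIC_CLASSES].
#' @param cfg a [sim_config()].
#' @param patient_id identifier stamped on the rows.
#' @return mutation-table data.frame (possibly zero rows for `NO_DRIVER`
#'   once decoys are filtered).
#' @export
sample_mutation_profile <- function(label, cfg = sim_config(),
                                    patient_id = "P1") {
  stopifnot(inherits(cfg, "sim_config"), label %in% GENOMIC_CLASSES)
  has_control <- stats::runif(1) < cfg$prob_control
  vars <- list()
  lesions <- switch(label,
    MULTI_CLASS = sample(c("NPM1", "CHROMATIN_SPLICE", "TP53",
                           "BIALLELIC_CEBPA"), 2),
    DRIVER_NO_CLASS = character(),
    NO_DRIVER = character(),
    label
  )
  for (lesion in lesions) {
    vars <- c(vars, plant_lesion(lesion, patient_id, cfg, has_control))
  }
  if (label != "NO_DRIVER") {
    fired <- names(cfg$co_mutation_freqs)[
      stats::runif(length(cfg$co_mutation_freqs)) < cfg$co_mutation_freqs]
    for (g in fired) {
      vars <- c(vars, list(co_mutation_variant(g, patient_id, cfg,
                                               has_control)))
    }
    if (label == "DRIVER_NO_CLASS" && length(vars) == 0) {
      # needs >= 1 driver; fall back to a non-class-defining hotspot so the
      # configured co-mutation marginals stay untouched
      vars <- list(new_variant(patient_id, "IDH1", "missense", "p.R132H",
                               cfg, has_control = has_control))
    }
  }
  # decoys the filter must remove
  if (stats::runif(1) < 0.6) {
    vars <- c(vars, list(new_variant(
      patient_id, sample(DEFAULT_DRIVER_GENES, 1), "missense", "p.P100L",
      cfg, vaf = stats::runif(1, 0.35, 0.65), has_control = has_control,
      germline = TRUE, known = FALSE)))
  }
  if (stats::runif(1) < 0.6) {
    vars <- c(vars, list(new_variant(
      patient_id, sample(DEFAULT_DRIVER_GENES, 1), "missense", "p.A5V",
      cfg, vaf = stats::runif(1, 0.005, 0.025), has_control = has_control,
      known = FALSE)))
  }
  if (length(vars) == 0) return(empty_mutation_table())
  do.call(rbind, lapply(vars, function(v) {
    as.data.frame(v, stringsAsFactors = FALSE)
  }))
}

#' Sample clinical outcomes for planted class labels
#'
#' Vectorised over patients. CR is Bernoulli at the class CR rate; death is
#' exponential at the class rate `-log(five_year_os)/60` (restarted at the
#' CR date for CR patients); relapse competes with death without relapse
#' after CR at the solved relapse hazard (see [sim_config()]); transplant
#' in first CR is Bernoulli
#' at the class-level transplant fraction rescaled among CR patients, with
#' the transplant date uniform within six months of CR. Administrative
#' censoring is uniform on (`followup_min`, `followup_horizon`). Uses the
#' current RNG state.
#'
#' @param labels character vector of class labels, one per patient.
#' @param cfg a [sim_config()].
#' @param patient_ids identifiers (default P0001...).
#' @return clinical data.frame in the [read_clinical_table()] dialect.
#' @export
sample_outcomes <- function(labels, cfg = sim_config(),
                            patient_ids = sprintf("P%04d", seq_along(labels))) {
  stopifnot(inherits(cfg, "sim_config"), all(labels %in% GENOMIC_CLASSES))
  n <- length(labels)
  if (n == 0) return(empty_clinical_table())
  cp <- cfg$class_params
  rates <- class_rates(cfg)
  li <- match(labels, cp$label)

  age <- pmin(pmax(stats::rnorm(n, cp$age_median[li],
                                (cp$age_hi[li] - cp$age_lo[li]) / 4),
                   cp$age_lo[li]), cp$age_hi[li])
  wbc <- pmin(pmax(stats::rlnorm(n, log(cp$wbc_median[li]),
                                 (log(cp$wbc_hi[li]) - log(cp$wbc_lo[li])) / 4),
                   cp$wbc_lo[li]), cp$wbc_hi[li])
  blast <- pmin(pmax(stats::rnorm(n, cp$blast_median[li],
                                  (cp$blast_hi[li] - cp$blast_lo[li]) / 4),
                     cp$blast_lo[li]), cp$blast_hi[li])
  sex <- ifelse(stats::runif(n) < cp$male_frac[li], "M", "F")

  cr <- stats::runif(n) < cp$cr_prob[li]
  t_death <- vapply(seq_len(n), function(i) {
    rexp_rate(1, rates$lam_os[li[i]])
  }, numeric(1))
  censor <- stats::runif(n, cfg$followup_min, cfg$followup_horizon)

  cr_time <- rep(NA_real_, n)
  relapse_time <- rep(NA_real_, n)
  sct_time <- rep(NA_real_, n)
  cr_raw <- stats::runif(n, 0.75, 2)
  t_rel <- vapply(seq_len(n), function(i) {
    rexp_rate(1, rates$lam_rel[li[i]])
  }, numeric(1))
  sct_draw <- stats::runif(n)
  sct_gap <- stats::runif(n, 0, 6)
  for (i in which(cr)) {
    # the death clock of a CR patient restarts at the CR date with the
    # memoryless exponential residual, so the competing-risks calibration
    # (relapse vs death without relapse) is exact from CR
    cr_time[i] <- cr_raw[i]
    t_death[i] <- cr_time[i] + rexp_rate(1, rates$lam_os[li[i]])
    rel_abs <- cr_time[i] + t_rel[i]
    if (rel_abs < t_death[i] && rel_abs <= censor[i]) {
      relapse_time[i] <- rel_abs
    }
    p_sct <- min(1, cp$sct_prob[li[i]] / cp$cr_prob[li[i]])
    if (sct_draw[i] < p_sct) {
      cand <- cr_time[i] + sct_gap[i]
      horizon_i <- min(rel_abs, t_death[i], censor[i])
      if (cand < horizon_i) sct_time[i] <- cand
    }
  }
  death_time <- ifelse(t_death <= censor, t_death, NA_real_)
  last_fu <- pmin(t_death, censor)
  data.frame(
    patient_id = patient_ids,
    age = round(age), sex = sex, wbc = round(wbc, 1),
    bm_blast_pct = round(blast),
    cr_achieved = cr,
    cr_time = cr_time, sct_time = sct_time, relapse_time = relapse_time,
    death_time = death_time, last_followup_time = last_fu,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic NK-AML cohort
#'
#' Draws class labels from the configured subgroup probabilities, then the
#' mutation table ([sample_mutation_profile()]) and clinical table
#' ([sample_outcomes()]) per patient. The planted label is recorded in the
#' truth table and is recoverable exactly by
#' [apply_somatic_filter()] + [build_profiles()] + [classify_cohort()].
#' Fully deterministic given `cfg$seed` (Mersenne-Twister via `set.seed`).
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory; when given, writes
#'   `mutations.tsv`, `clinical.csv`, `truth.tsv` and `panel.txt` in the
#'   package's file dialects.
#' @return (invisibly when `dir` is given) list with `mutations`,
#'   `clinical`, `truth` data.frames and the `config`.
#' @export
generate_cohort <- function(cfg = sim_config(), dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  labels <- if (n > 0) {
    sample(GENOMIC_CLASSES, n, replace = TRUE, prob = cfg$class_probs)
  } else {
    character()
  }
  ids <- if (n > 0) sprintf("P%04d", seq_len(n)) else character()
  mut_list <- lapply(seq_len(n), function(i) {
    sample_mutation_profile(labels[i], cfg, ids[i])
  })
  mutations <- if (n > 0) do.call(rbind, mut_list) else empty_mutation_table()
  rownames(mutations) <- NULL
  clinical <- sample_outcomes(labels, cfg, ids)
  truth <- data.frame(patient_id = ids, true_label = labels,
                      stringsAsFactors = FALSE)
  out <- list(mutations = mutations, clinical = clinical, truth = truth,
              config = cfg)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_mutation_table(mutations, file.path(dir, "mutations.tsv"))
    write_clinical_table(clinical, file.path(dir, "clinical.csv"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_gene_panel(default_gene_panel(), file.path(dir, "panel.txt"))
    return(invisible(out))
  }
  out
}
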