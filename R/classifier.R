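# Eight-way genomic classification -------------------------------------------
#
# Class-defining lesions: NPM1 mutation; any mutation in the nine
# chromatin/spliceosome genes; TP53 mutation; biallelic CEBPA; IDH2-R172
# (subordinate: it fires only when no other lesion does, so it can never
# contribute to the multi-class bin). Patients matching one lesion get that
# class; two or more -> MULTI_CLASS; none with at least one driver ->
# DRIVER_NO_CLASS; none and no drivers -> NO_DRIVER.

#' Genomic class labels
#' @format Character vector of the eight labels in reporting order.
#' @export
GENOMIC_CLASSES <- c("NPM1", "CHROMATIN_SPLICE", "TP53", "BIALLELIC_CEBPA",
                     "IDH2_R172", "DRIVER_NO_CLASS", "NO_DRIVER",
                     "MULTI_CLASS")

#' Human-readable names of the genomic classes
#' @format Named character vector keyed by [GENOMIC_CLASSES].
#' @export
GENOMIC_CLASS_NAMES <- c(
  NPM1 = "NPM1 mutation",
  CHROMATIN_SPLICE = "Chromatin and/or RNA-splicing genes mutation",
  TP53 = "TP53 mutation",
  BIALLELIC_CEBPA = "Biallelic CEBPA mutations",
  IDH2_R172 = "IDH2-R172 mutation, no other class-defining lesion",
  DRIVER_NO_CLASS = "Driver mutations, no class-defining lesion",
  NO_DRIVER = "No detected driver mutation",
  MULTI_CLASS = "More than one subgroup"
)

profile_fields <- function(p) {
  genes <- p$mutated_genes
  if (is.list(genes)) genes <- genes[[1]]
  list(genes = normalize_gene(genes),
       biallelic_cebpa = isTRUE(p$biallelic_cebpa[[1]]),
       idh2_r172 = isTRUE(p$idh2_r172[[1]]),
       n_driver = as.integer(p$n_driver_mutations[[1]]))
}

#' Class-defining lesions of a patient profile
#'
#' Returns the subset of `{NPM1, CHROMATIN_SPLICE, TP53, BIALLELIC_CEBPA,
#' IDH2_R172}` the profile matches. IDH2-R172 is subordinate: it fires only
#' if no other lesion fires, so it never appears in a set of size two or
#' more.
#'
#' @param profile one-row profile (see [build_profiles()]) or a list with
#'   elements `mutated_genes`, `biallelic_cebpa`, `idh2_r172`,
#'   `n_driver_mutations`.
#' @param panel a [gene_panel()] supplying the chromatin/spliceosome list.
#' @return character vector of matched lesions (possibly empty).
#' @export
class_defining_lesions <- function(profile, panel = default_gene_panel()) {
  stopifnot(inherits(panel, "gene_panel"))
  f <- profile_fields(profile)
  lesions <- character()
  if ("NPM1" %in% f$genes) lesions <- c(lesions, "NPM1")
  if (length(intersect(f$genes, panel$chromatin_spliceosome_genes)) > 0) {
    lesions <- c(lesions, "CHROMATIN_SPLICE")
  }
  if ("TP53" %in% f$genes) lesions <- c(lesions, "TP53")
  if (f$biallelic_cebpa) lesions <- c(lesions, "BIALLELIC_CEBPA")
  if (length(lesions) == 0 && f$idh2_r172) lesions <- "IDH2_R172"
  lesions
}

#' Classify one patient profile
#'
#' @inheritParams class_defining_lesions
#' @return list with `label` (one of [GENOMIC_CLASSES]) and
#'   `matched_lesions` (character vector of the lesions that fired).
#' @export
classify_patient <- function(profile, panel = default_gene_panel()) {
  lesions <- class_defining_lesions(profile, panel)
  f <- profile_fields(profile)
  label <- if (length(lesions) >= 2) {
    "MULTI_CLASS"
  } else if (length(lesions) == 1) {
    lesions
  } else if (f$n_driver >= 1) {
    "DRIVER_NO_CLASS"
  } else {
    "NO_DRIVER"
  }
  list(label = label, matched_lesions = lesions)
}

#' Classify a cohort of patient profiles
#'
#' Applies [classify_patient()] to every profile and tabulates the eight
#' subgroups with percentages to one decimal. The summary is independent of
#' patient order; per-patient assignments keep input order.
#'
#' @param profiles profile data.frame from [build_profiles()], one row per
#'   patient.
#' @param panel a [gene_panel()].
#' @return object of class `genomic_classification`: list with
#'   `assignments` (patient_id, label, matched_lesions), `summary`
#'   (label, n, pct) and `n`.
#' @export
classify_cohort <- function(profiles, panel = default_gene_panel()) {
  if (anyDuplicated(profiles$patient_id)) {
    stop("duplicate patient_id in profiles: ",
         paste(unique(profiles$patient_id[duplicated(profiles$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  n <- nrow(profiles)
  res <- lapply(seq_len(n), function(i) {
    classify_patient(profiles[i, , drop = FALSE], panel)
  })
  labels <- factor(vapply(res, `[[`, character(1), "label"),
                   levels = GENOMIC_CLASSES)
  assignments <- data.frame(
    patient_id = profiles$patient_id,
    label = labels,
    matched_lesions = vapply(res, function(r) {
      paste(r$matched_lesions, collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  counts <- as.integer(table(labels))
  summary <- data.frame(
    label = GENOMIC_CLASSES,
    n = counts,
    pct = if (n > 0) round(100 * counts / n, 1) else rep(NA_real_, 8),
    stringsAsFactors = FALSE
  )
  structure(list(assignments = assignments, summary = summary, n = n),
            class = "genomic_classification")
}

#' @export
print.genomic_classification <- function(x, ...) {
  cat("Genomic classification of", x$n, "patients\n")
  s <- x$summary
  s$label <- GENOMIC_CLASS_NAMES[s$label]
  print(s, row.names = FALSE)
  invisible(x)
}
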