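# Somatic variant retention -------------------------------------------------
#
# Retention rule for a candidate variant, evaluated in a fixed order so the
# recorded reason is deterministic:
#   1. gene must be on the driver panel                (not_in_panel)
#   2. tumour VAF >= vaf_min, boundary inclusive       (below_vaf)
#   3. no germline-database suspicion                  (germline_suspect)
#   4. somatic evidence:
#        control present -> Fisher exact p < p_max     (fisher_ns)
#        control absent  -> control-free caller flag   (control_free_fail)

FILTER_REASONS <- c("pass", "below_vaf", "fisher_ns", "germline_suspect",
                    "not_in_panel", "control_free_fail")

#' Two-sided Fisher exact test for a tumour/control allele table
#'
#' Exact two-sided p-value for the 2x2 table of reference and alternative
#' allele counts in tumour and control, computed by hypergeometric
#' enumeration: the sum of the probabilities of all tables (with the same
#' margins) whose probability does not exceed that of the observed table.
#' Tables whose probability is within a relative 1e-7 of the observed one
#' count as ties, the conventional guard against floating-point noise.
#'
#' @param t_ref,t_alt tumour reference / alternative allele counts.
#' @param n_ref,n_alt control reference / alternative allele counts.
#' @return p-value in \[0, 1\].
#' @examples
#' fisher_two_sided(10, 10, 10, 10)  # identical proportions -> 1
#' @export
fisher_two_sided <- function(t_ref, t_alt, n_ref, n_alt) {
  counts <- c(t_ref, t_alt, n_ref, n_alt)
  if (length(counts) != 4 || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be four non-negative integers", call. = FALSE)
  }
  if (all(counts == 0)) {
    stop("undefined input: all four counts are zero", call. = FALSE)
  }
  m <- t_ref + t_alt         # tumour row total
  nn <- n_ref + n_alt        # control row total
  k <- t_alt + n_alt         # alternative-allele column total
  lo <- max(0L, k - nn)
  hi <- min(m, k)
  support <- lo:hi
  d <- stats::dhyper(support, m, nn, k)
  p_obs <- d[support == t_alt]
  min(1, sum(d[d <= p_obs * (1 + 1e-7)]))
}

#' Apply the somatic retention filter to a mutation table
#'
#' Vectorised over the rows of a mutation table. A variant is retained iff
#' its gene is on the panel, its tumour VAF is at least `vaf_min`
#' (boundary inclusive), it carries no germline-database flag, and its
#' somatic evidence holds: with a control sample present the two-sided
#' Fisher exact p-value must be strictly below `p_max`; without a control
#' the control-free caller flag must be set. The `reason` column records
#' the first failing rule in the order panel, VAF, germline, evidence.
#'
#' @param variants mutation-table data.frame (see [MUTATION_COLUMNS]).
#' @param panel a [gene_panel()].
#' @param vaf_min minimum tumour variant allele fraction (default 0.03).
#' @param p_max Fisher exact significance threshold (default 0.001,
#'   strict inequality).
#' @return the input with columns `vaf`, `fisher_p` (NA when no control),
#'   `retained` and `reason` appended.
#' @export
apply_somatic_filter <- function(variants, panel = default_gene_panel(),
                                 vaf_min = 0.03, p_max = 0.001) {
  stopifnot(inherits(panel, "gene_panel"))
  if (!(is.numeric(vaf_min) && vaf_min >= 0 && vaf_min <= 1)) {
    stop("vaf_min must be a fraction in [0, 1]", call. = FALSE)
  }
  if (!(is.numeric(p_max) && p_max > 0 && p_max <= 1)) {
    stop("p_max must be a probability in (0, 1]", call. = FALSE)
  }
  variants <- validate_mutation_table(variants)
  n <- nrow(variants)
  if (n == 0) {
    out <- variants
    out$vaf <- numeric(); out$fisher_p <- numeric()
    out$retained <- logical(); out$reason <- character()
    return(out)
  }
  tot <- variants$tumor_ref_depth + variants$tumor_alt_depth
  if (any(is.na(tot) | tot <= 0)) {
    stop("tumour depth must be positive and parseable for every variant ",
         "entering the filter (row(s) ",
         paste(which(is.na(tot) | tot <= 0), collapse = ", "), ")",
         call. = FALSE)
  }
  vaf <- variants$tumor_alt_depth / tot
  ctrl_tot <- variants$normal_ref_depth + variants$normal_alt_depth
  has_control <- !is.na(ctrl_tot) & ctrl_tot > 0
  fisher_p <- rep(NA_real_, n)
  idx <- which(has_control)
  if (length(idx) > 0) {
    fisher_p[idx] <- mapply(fisher_two_sided,
                            variants$tumor_ref_depth[idx],
                            variants$tumor_alt_depth[idx],
                            variants$normal_ref_depth[idx],
                            variants$normal_alt_depth[idx])
  }
  in_panel <- variants$gene %in% panel$driver_genes
  germline <- isTRUE_vec(variants$germline_suspect_flag)
  cf_ok <- isTRUE_vec(variants$control_free_somatic_flag)

  reason <- rep("pass", n)
  undecided <- rep(TRUE, n)
  set_reason <- function(fail, code) {
    hit <- undecided & fail
    reason[hit] <<- code
    undecided[hit] <<- FALSE
  }
  set_reason(!in_panel, "not_in_panel")
  set_reason(vaf < vaf_min, "below_vaf")
  set_reason(germline, "germline_suspect")
  set_reason(has_control & !(fisher_p < p_max), "fisher_ns")
  set_reason(!has_control & !cf_ok, "control_free_fail")

  out <- variants
  out$vaf <- vaf
  out$fisher_p <- fisher_p
  out$retained <- reason == "pass"
  out$reason <- reason
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Build per-patient driver-mutation profiles
#'
#' Collapses filter-retained variants into one profile per patient, with the
#' derived lesion flags used by the genomic classifier: biallelic CEBPA (two
#' or more distinct retained CEBPA variants, or an explicit biallelic
#' annotation), IDH2-R172 (an IDH2 variant whose protein change hits codon
#' 172), and FLT3-ITD. Exact duplicate variant rows for a patient are
#' deduplicated with a warning. Patients listed in `patient_ids` with no
#' retained variant get an empty profile, so no-driver patients stay in the
#' cohort.
#'
#' @param variants retained variants; if a `retained` column is present
#'   (output of [apply_somatic_filter()]) only retained rows are used.
#' @param panel a [gene_panel()] (membership is not re-checked here; the
#'   filter owns the panel rule).
#' @param patient_ids optional character vector fixing the cohort and its
#'   order; defaults to the patients present in `variants`.
#' @return data.frame with one row per patient: `patient_id`,
#'   `n_driver_mutations`, `biallelic_cebpa`, `idh2_r172`, `flt3_itd`, and
#'   the list column `mutated_genes`.
#' @export
build_profiles <- function(variants, panel = default_gene_panel(),
                           patient_ids = NULL) {
  if ("retained" %in% names(variants)) {
    variants <- variants[isTRUE_vec(variants$retained), , drop = FALSE]
  }
  key <- paste(variants$patient_id, variants$gene, variants$variant_class,
               ifelse(is.na(variants$protein_change), ".",
                      variants$protein_change), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate variant row(s) deduplicated", call. = FALSE)
    variants <- variants[!dup, , drop = FALSE]
  }
  ids <- patient_ids
  if (is.null(ids)) {
    ids <- unique(variants$patient_id)
  } else {
    ids <- as.character(ids)
    extra <- setdiff(unique(variants$patient_id), ids)
    if (length(extra) > 0) {
      warning("variants for patient(s) absent from patient_ids kept: ",
              paste(extra, collapse = ", "), call. = FALSE)
      ids <- c(ids, extra)
    }
  }
  rows <- lapply(ids, function(id) {
    v <- variants[variants$patient_id == id, , drop = FALSE]
    pc <- ifelse(is.na(v$protein_change), "", v$protein_change)
    cebpa <- v$gene == "CEBPA"
    list(
      patient_id = id,
      n_driver_mutations = nrow(v),
      biallelic_cebpa = sum(cebpa) >= 2 ||
        any(cebpa & isTRUE_vec(v$biallelic_annotation)),
      idh2_r172 = any(v$gene == "IDH2" & grepl("R172", pc)),
      flt3_itd = any(v$gene == "FLT3" & v$variant_class == "ITD"),
      genes = list(unique(v$gene))
    )
  })
  out <- data.frame(
    patient_id = vapply(rows, `[[`, character(1), "patient_id"),
    n_driver_mutations = vapply(rows, `[[`, integer(1), "n_driver_mutations"),
    biallelic_cebpa = vapply(rows, `[[`, logical(1), "biallelic_cebpa"),
    idh2_r172 = vapply(rows, `[[`, logical(1), "idh2_r172"),
    flt3_itd = vapply(rows, `[[`, logical(1), "flt3_itd"),
    stringsAsFactors = FALSE
  )
  out$mutated_genes <- I(lapply(rows, function(r) r$genes[[1]]))
  out
}
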