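# Table dialects ------------------------------------------------------------
#
# Mutation tables are plain data.frames with one row per candidate somatic
# variant. The 12-column MAF-like TSV dialect is tab-separated, UTF-8, header
# row mandatory, '.' for missing. The VCF-like dialect is a minimal VCF 4.2
# whose analysis-relevant fields travel in INFO (PID, GENE, VC, PC, KS, GS,
# CF, BA) and whose TUMOR/NORMAL sample columns carry AD (ref,alt) depths.

#' Column names of the mutation-table dialect
#' @format Character vector of the 12 required columns.
#' @export
MUTATION_COLUMNS <- c(
  "patient_id", "gene", "variant_class", "protein_change",
  "tumor_ref_depth", "tumor_alt_depth",
  "normal_ref_depth", "normal_alt_depth",
  "known_somatic_flag", "germline_suspect_flag", "control_free_somatic_flag",
  "biallelic_annotation"
)

#' Recognised variant classes
#' @format Character vector.
#' @export
VARIANT_CLASSES <- c("missense", "nonsense", "frameshift", "inframe_indel",
                     "splice", "ITD", "other")

empty_mutation_table <- function() {
  data.frame(
    patient_id = character(), gene = character(), variant_class = character(),
    protein_change = character(),
    tumor_ref_depth = integer(), tumor_alt_depth = integer(),
    normal_ref_depth = integer(), normal_alt_depth = integer(),
    known_somatic_flag = logical(), germline_suspect_flag = logical(),
    control_free_somatic_flag = logical(), biallelic_annotation = logical(),
    stringsAsFactors = FALSE
  )
}

parse_flag <- function(x) {
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "True", "true", "T", "1")] <- TRUE
  out[x %in% c("FALSE", "False", "false", "F", "0")] <- FALSE
  as.logical(out)
}

parse_depth <- function(x, col, rows_bad) {
  suppressWarnings(v <- as.integer(x))
  bad <- !is.na(x) & is.na(v)
  if (any(bad)) {
    warning(sprintf("unparseable %s in row(s) %s; kept as NA", col,
                    paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  v
}

validate_mutation_table <- function(x) {
  if (nrow(x) == 0) return(x)
  if (any(!nzchar(x$patient_id) | is.na(x$patient_id))) {
    stop("mutation table has empty patient_id values", call. = FALSE)
  }
  if (any(!nzchar(x$gene) | is.na(x$gene))) {
    stop("mutation table has empty gene symbols", call. = FALSE)
  }
  bad_class <- !x$variant_class %in% VARIANT_CLASSES
  if (any(bad_class)) {
    stop("unknown variant_class value(s): ",
         paste(unique(x$variant_class[bad_class]), collapse = ", "),
         call. = FALSE)
  }
  neg <- c("tumor_ref_depth", "tumor_alt_depth",
           "normal_ref_depth", "normal_alt_depth")
  for (col in neg) {
    if (any(x[[col]] < 0, na.rm = TRUE)) {
      stop("negative depths in column ", col, call. = FALSE)
    }
  }
  x
}

#' Read a mutation table
#'
#' Reads candidate somatic variants either from the package's 12-column
#' MAF-like TSV dialect or from a minimal VCF ("vcf_like") whose INFO field
#' carries `PID`, `GENE`, `VC`, `PC`, `KS`, `GS`, `CF`, `BA` and whose
#' TUMOR/NORMAL sample columns carry `AD` ref,alt depths. Rows with
#' unparseable depths are reported by warning and kept (with `NA` depths),
#' never silently dropped. Input order is preserved.
#'
#' @param path input file.
#' @param format `"maf_tsv"` (default) or `"vcf_like"`.
#' @return data.frame with the columns in [MUTATION_COLUMNS].
#' @export
read_mutation_table <- function(path, format = c("maf_tsv", "vcf_like")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "maf_tsv") read_mutation_maf(path) else read_mutation_vcf(path)
}

read_mutation_maf <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           na.strings = ".", colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(MUTATION_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("mutation table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, MUTATION_COLUMNS, drop = FALSE]
  if (nrow(raw) == 0) {
    warning("empty mutation table: ", path, call. = FALSE)
    return(empty_mutation_table())
  }
  out <- data.frame(
    patient_id = raw$patient_id,
    gene = normalize_gene(raw$gene),
    variant_class = raw$variant_class,
    protein_change = raw$protein_change,
    tumor_ref_depth = parse_depth(raw$tumor_ref_depth, "tumor_ref_depth"),
    tumor_alt_depth = parse_depth(raw$tumor_alt_depth, "tumor_alt_depth"),
    normal_ref_depth = parse_depth(raw$normal_ref_depth, "normal_ref_depth"),
    normal_alt_depth = parse_depth(raw$normal_alt_depth, "normal_alt_depth"),
    known_somatic_flag = parse_flag(raw$known_somatic_flag),
    germline_suspect_flag = parse_flag(raw$germline_suspect_flag),
    control_free_somatic_flag = parse_flag(raw$control_free_somatic_flag),
    biallelic_annotation = parse_flag(raw$biallelic_annotation),
    stringsAsFactors = FALSE
  )
  validate_mutation_table(out)
}

read_mutation_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  n <- nrow(vcf@fix)
  if (is.null(n) || n == 0) {
    warning("empty mutation table: ", path, call. = FALSE)
    return(empty_mutation_table())
  }
  info1 <- function(key) as.character(vcfR::extract.info(vcf, element = key))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  split_ad <- function(col) {
    if (!col %in% colnames(ad)) {
      return(matrix(NA_integer_, nrow = n, ncol = 2))
    }
    parts <- strsplit(ifelse(is.na(ad[, col]), ",", ad[, col]), ",", fixed = TRUE)
    t(vapply(parts, function(p) {
      p <- suppressWarnings(as.integer(p))
      c(p[1], if (length(p) >= 2) p[2] else NA_integer_)
    }, integer(2)))
  }
  tad <- split_ad("TUMOR")
  nad <- split_ad("NORMAL")
  flag <- function(key) {
    v <- info1(key)
    out <- rep(NA, n)
    out[v %in% "1"] <- TRUE
    out[v %in% "0"] <- FALSE
    as.logical(out)
  }
  pc <- info1("PC")
  pc[pc %in% "."] <- NA_character_
  out <- data.frame(
    patient_id = info1("PID"),
    gene = normalize_gene(info1("GENE")),
    variant_class = info1("VC"),
    protein_change = pc,
    tumor_ref_depth = tad[, 1], tumor_alt_depth = tad[, 2],
    normal_ref_depth = nad[, 1], normal_alt_depth = nad[, 2],
    known_somatic_flag = flag("KS"),
    germline_suspect_flag = flag("GS"),
    control_free_somatic_flag = flag("CF"),
    biallelic_annotation = flag("BA"),
    stringsAsFactors = FALSE
  )
  validate_mutation_table(out)
}

#' Write a mutation table
#'
#' Inverse of [read_mutation_table()]; `write` then `read` recovers the
#' table field-for-field.
#'
#' @param x mutation-table data.frame (columns of [MUTATION_COLUMNS]).
#' @param path output file.
#' @param format `"maf_tsv"` or `"vcf_like"`.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(x, path, format = c("maf_tsv", "vcf_like")) {
  format <- match.arg(format)
  missing <- setdiff(MUTATION_COLUMNS, names(x))
  if (length(missing) > 0) {
    stop("cannot write mutation table; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- x[, MUTATION_COLUMNS, drop = FALSE]
  if (format == "maf_tsv") {
    utils::write.table(x, path, sep = "\t", quote = FALSE, na = ".",
                       row.names = FALSE)
  } else {
    write_mutation_vcf(x, path)
  }
  invisible(path)
}

write_mutation_vcf <- function(x, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=nkaml",
    '##INFO=<ID=PID,Number=1,Type=String,Description="Patient identifier">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="HGNC gene symbol">',
    '##INFO=<ID=VC,Number=1,Type=String,Description="Variant class">',
    '##INFO=<ID=PC,Number=1,Type=String,Description="Protein change">',
    '##INFO=<ID=KS,Number=1,Type=Integer,Description="Known somatic flag">',
    '##INFO=<ID=GS,Number=1,Type=Integer,Description="Germline suspect flag">',
    '##INFO=<ID=CF,Number=1,Type=Integer,Description="Control-free somatic call flag">',
    '##INFO=<ID=BA,Number=1,Type=Integer,Description="Explicit biallelic annotation">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths ref,alt">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL"
  )
  fmt_flag <- function(v) ifelse(is.na(v), ".", ifelse(v, "1", "0"))
  fmt_ad <- function(ref, alt) {
    ifelse(is.na(ref) & is.na(alt), ".",
           paste(ifelse(is.na(ref), ".", ref), ifelse(is.na(alt), ".", alt),
                 sep = ","))
  }
  n <- nrow(x)
  if (n == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  info <- sprintf("PID=%s;GENE=%s;VC=%s;PC=%s;KS=%s;GS=%s;CF=%s;BA=%s",
                  x$patient_id, x$gene, x$variant_class,
                  ifelse(is.na(x$protein_change), ".", x$protein_change),
                  fmt_flag(x$known_somatic_flag),
                  fmt_flag(x$germline_suspect_flag),
                  fmt_flag(x$control_free_somatic_flag),
                  fmt_flag(x$biallelic_annotation))
  # positional fields are placeholders: this dialect carries its payload in
  # INFO and the AD depths
  rows <- sprintf("1\t%d\t.\tA\tT\t.\t.\t%s\tAD\t%s\t%s",
                  seq_len(n), info,
                  fmt_ad(x$tumor_ref_depth, x$tumor_alt_depth),
                  fmt_ad(x$normal_ref_depth, x$normal_alt_depth))
  writeLines(c(header, rows), path)
  invisible(path)
}

# Clinical tables ------------------------------------------------------------

#' Column names of the clinical-table dialect
#' @format Character vector of the 11 required columns.
#' @export
CLINICAL_COLUMNS <- c(
  "patient_id", "age", "sex", "wbc", "bm_blast_pct",
  "cr_achieved", "cr_time", "sct_time", "relapse_time", "death_time",
  "last_followup_time"
)

empty_clinical_table <- function() {
  data.frame(
    patient_id = character(), age = numeric(), sex = character(),
    wbc = numeric(), bm_blast_pct = numeric(), cr_achieved = logical(),
    cr_time = numeric(), sct_time = numeric(), relapse_time = numeric(),
    death_time = numeric(), last_followup_time = numeric(),
    stringsAsFactors = FALSE
  )
}

#' Validate a clinical table
#'
#' Checks the record-level invariants: all times non-negative; relapse
#' requires prior CR and `cr_time <= relapse_time`; CR patients carry a CR
#' date; `last_followup_time` is at least every recorded event time. All
#' violations are collected and reported per patient id.
#'
#' @param x clinical data.frame (columns of [CLINICAL_COLUMNS]).
#' @return `x`, invisibly, if valid; otherwise an error listing violations.
#' @export
validate_clinical <- function(x) {
  missing <- setdiff(CLINICAL_COLUMNS, names(x))
  if (length(missing) > 0) {
    stop("clinical table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  problems <- character()
  note <- function(id, msg) sprintf("%s: %s", id, msg)
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    id <- r$patient_id
    if (is.na(id) || !nzchar(id)) {
      problems <- c(problems, note(paste0("row ", i), "empty patient_id"))
      next
    }
    tms <- c(r$cr_time, r$sct_time, r$relapse_time, r$death_time,
             r$last_followup_time)
    if (any(tms < 0, na.rm = TRUE)) {
      problems <- c(problems, note(id, "negative time"))
    }
    if (is.na(r$last_followup_time)) {
      problems <- c(problems, note(id, "missing last_followup_time"))
    }
    if (!is.na(r$relapse_time) && (is.na(r$cr_achieved) || !r$cr_achieved)) {
      problems <- c(problems, note(id, "relapse recorded without CR"))
    }
    if (isTRUE(r$cr_achieved) && is.na(r$cr_time)) {
      problems <- c(problems, note(id, "CR achieved but cr_time missing"))
    }
    if (!is.na(r$cr_time) && !is.na(r$relapse_time) &&
        r$cr_time > r$relapse_time) {
      problems <- c(problems, note(id, "cr_time after relapse_time"))
    }
    if (!is.na(r$sct_time) && (is.na(r$cr_achieved) || !r$cr_achieved)) {
      problems <- c(problems, note(id, "SCT recorded without CR"))
    }
    ev_max <- suppressWarnings(
      max(c(r$cr_time, r$sct_time, r$relapse_time, r$death_time), na.rm = TRUE))
    if (is.finite(ev_max) && !is.na(r$last_followup_time) &&
        r$last_followup_time < ev_max - 1e-9) {
      problems <- c(problems, note(id, "last_followup_time before an event time"))
    }
    if (!is.na(r$sex) && !r$sex %in% c("M", "F")) {
      problems <- c(problems, note(id, "sex must be 'M' or 'F'"))
    }
  }
  if (length(problems) > 0) {
    stop("clinical table validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  if (anyDuplicated(x$patient_id)) {
    stop("duplicate patient_id in clinical table: ",
         paste(unique(x$patient_id[duplicated(x$patient_id)]), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Read a clinical table
#'
#' CSV or TSV (sniffed from the header line) with the columns of
#' [CLINICAL_COLUMNS]; times are months from the start of induction
#' chemotherapy, `.` or empty marks a missing value. Records are
#' invariant-checked via [validate_clinical()] and returned in input order.
#'
#' @param path input file.
#' @return validated clinical data.frame.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           na.strings = c(".", "", "NA"),
                           colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(CLINICAL_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("clinical table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, CLINICAL_COLUMNS, drop = FALSE]
  if (nrow(raw) == 0) {
    warning("empty clinical table: ", path, call. = FALSE)
    return(empty_clinical_table())
  }
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  out <- data.frame(
    patient_id = raw$patient_id,
    age = num("age"), sex = raw$sex, wbc = num("wbc"),
    bm_blast_pct = num("bm_blast_pct"),
    cr_achieved = parse_flag(raw$cr_achieved),
    cr_time = num("cr_time"), sct_time = num("sct_time"),
    relapse_time = num("relapse_time"), death_time = num("death_time"),
    last_followup_time = num("last_followup_time"),
    stringsAsFactors = FALSE
  )
  validate_clinical(out)
  out
}

#' Write a clinical table
#'
#' @param x clinical data.frame.
#' @param path output file; a `.tsv` extension selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(x, path) {
  missing <- setdiff(CLINICAL_COLUMNS, names(x))
  if (length(missing) > 0) {
    stop("cannot write clinical table; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(x[, CLINICAL_COLUMNS, drop = FALSE], path, sep = sep,
                     quote = FALSE, na = ".", row.names = FALSE)
  invisible(path)
}
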