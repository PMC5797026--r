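#' Chromatin / spliceosome gene list
#'
#' The nine genes whose mutation defines the chromatin and/or RNA-splicing
#' subgroup: RUNX1, ASXL1, BCOR, STAG2, EZH2, SRSF2, SF3B1, U2AF1, ZRSR2.
#'
#' @format Character vector of HGNC symbols.
#' @export
CHROMATIN_SPLICEOSOME_GENES <- c(
  "RUNX1", "ASXL1", "BCOR", "STAG2", "EZH2",
  "SRSF2", "SF3B1", "U2AF1", "ZRSR2"
)

# Driver genes named in the source cohort's text; user-replaceable via
# gene_panel()/read_gene_panel().
DEFAULT_DRIVER_GENES <- c(
  "NPM1", "FLT3", "DNMT3A", "IDH1", "IDH2", "NRAS", "TET2", "CEBPA", "TP53",
  CHROMATIN_SPLICEOSOME_GENES
)

normalize_gene <- function(x) toupper(trimws(as.character(x)))

#' Construct a driver gene panel
#'
#' A gene panel holds the set of genes whose mutations count as drivers,
#' plus the subset whose mutation is class-defining for the
#' chromatin/spliceosome subgroup. Gene symbols are matched
#' case-insensitively after whitespace trimming.
#'
#' @param driver_genes character vector of HGNC symbols counted as drivers.
#' @param chromatin_spliceosome_genes character vector, must be a subset of
#'   `driver_genes`.
#' @return An object of class `gene_panel`: a list with elements
#'   `driver_genes` and `chromatin_spliceosome_genes`.
#' @examples
#' p <- gene_panel(c("NPM1", "RUNX1"), "RUNX1")
#' @export
gene_panel <- function(driver_genes = DEFAULT_DRIVER_GENES,
                       chromatin_spliceosome_genes = CHROMATIN_SPLICEOSOME_GENES) {
  driver_genes <- unique(normalize_gene(driver_genes))
  chromatin_spliceosome_genes <- unique(normalize_gene(chromatin_spliceosome_genes))
  if (any(!nzchar(driver_genes))) {
    stop("gene panel contains empty gene symbols", call. = FALSE)
  }
  missing <- setdiff(chromatin_spliceosome_genes, driver_genes)
  if (length(missing) > 0) {
    stop("chromatin/spliceosome genes not in driver set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(
    list(driver_genes = driver_genes,
         chromatin_spliceosome_genes = chromatin_spliceosome_genes),
    class = "gene_panel"
  )
}

#' Default gene panel
#'
#' Panel containing the driver genes named in the source cohort (the nine
#' chromatin/spliceosome genes plus NPM1, FLT3, DNMT3A, IDH1, IDH2, NRAS,
#' TET2, CEBPA and TP53). Replace with [read_gene_panel()] for a custom
#' targeted panel.
#'
#' @return A `gene_panel` object.
#' @export
default_gene_panel <- function() {
  gene_panel(DEFAULT_DRIVER_GENES, CHROMATIN_SPLICEOSOME_GENES)
}

#' Read a gene panel from a plain-text config
#'
#' Format: one gene symbol per line, `#` comments allowed, with section
#' headers `[drivers]` and `[chromatin_spliceosome]`. Genes in the
#' chromatin/spliceosome section are automatically included among the
#' drivers.
#'
#' @param path path to the panel file.
#' @return A `gene_panel` object.
#' @export
read_gene_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- "drivers"
  drv <- character()
  chs <- character()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- tolower(gsub("^\\[|\\]$", "", ln))
      if (!section %in% c("drivers", "chromatin_spliceosome")) {
        stop("unknown panel section: [", section, "]", call. = FALSE)
      }
    } else if (section == "drivers") {
      drv <- c(drv, ln)
    } else {
      chs <- c(chs, ln)
    }
  }
  gene_panel(c(drv, chs), chs)
}

#' Write a gene panel to a plain-text config
#'
#' @param panel a `gene_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_panel <- function(panel, path) {
  stopifnot(inherits(panel, "gene_panel"))
  only_drv <- setdiff(panel$driver_genes, panel$chromatin_spliceosome_genes)
  writeLines(c("[drivers]", only_drv,
               "[chromatin_spliceosome]", panel$chromatin_spliceosome_genes),
             path)
  invisible(path)
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("Gene panel:", length(x$driver_genes), "driver genes,",
      length(x$chromatin_spliceosome_genes), "chromatin/spliceosome genes\n")
  invisible(x)
}
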