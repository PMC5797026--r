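test_that("fisher_two_sided handles degenerate and symmetric tables", {
  expect_equal(fisher_two_sided(10, 10, 10, 10), 1.0)
  expect_equal(fisher_two_sided(100, 0, 100, 0), 1.0)
  expect_equal(fisher_two_sided(0, 0, 5, 5), 1.0)
  expect_error(fisher_two_sided(0, 0, 0, 0), "all four counts")
  expect_error(fisher_two_sided(-1, 2, 3, 4), "non-negative")
})

test_that("fisher_two_sided is symmetric under swapping tumour and control", {
  set.seed(31)
  for (i in 1:50) {
    cnt <- rpois(4, 12)
    if (all(cnt == 0)) next
    expect_equal(fisher_two_sided(cnt[1], cnt[2], cnt[3], cnt[4]),
                 fisher_two_sided(cnt[3], cnt[4], cnt[1], cnt[2]),
                 tolerance = 1e-12)
  }
})

test_that("fisher_two_sided matches the reference exact test", {
  # stats::fisher.test is the independent route to the same two-sided
  # probability-mass definition
  set.seed(77)
  for (i in 1:200) {
    cnt <- rpois(4, sample(c(3, 10, 40), 1))
    if (sum(cnt) == 0) next
    mine <- fisher_two_sided(cnt[1], cnt[2], cnt[3], cnt[4])
    ref <- stats::fisher.test(matrix(c(cnt[2], cnt[4], cnt[1], cnt[3]),
                                     nrow = 2))$p.value
    expect_equal(mine, min(ref, 1), tolerance = 1e-10)
  }
  expect_equal(fisher_two_sided(90, 10, 100, 0),
               stats::fisher.test(matrix(c(10, 0, 90, 100), 2))$p.value,
               tolerance = 1e-12)
})

test_that("filter reasons follow the fixed rule order", {
  panel <- default_gene_panel()
  # VAF 0.029 with overwhelming Fisher evidence still fails on VAF
  v1 <- make_variant_row(tumor_ref_depth = 971L, tumor_alt_depth = 29L,
                         normal_ref_depth = 1000L, normal_alt_depth = 0L)
  d1 <- apply_somatic_filter(v1, panel)
  expect_false(d1$retained)
  expect_equal(d1$reason, "below_vaf")
  expect_lt(d1$fisher_p, 1e-4)

  # VAF 0.30 but a p-value at/above the threshold fails the evidence rule
  v2 <- make_variant_row(tumor_ref_depth = 70L, tumor_alt_depth = 30L,
                         normal_ref_depth = 93L, normal_alt_depth = 12L)
  p2 <- fisher_two_sided(70, 30, 93, 12)
  d2 <- apply_somatic_filter(v2, panel, p_max = p2)
  expect_equal(d2$fisher_p, p2)
  expect_equal(d2$reason, "fisher_ns")

  # control-free path with the caller flag set passes all rules
  v3 <- make_variant_row(gene = "NPM1", tumor_ref_depth = 55L,
                         tumor_alt_depth = 45L,
                         normal_ref_depth = NA_integer_,
                         normal_alt_depth = NA_integer_,
                         control_free_somatic_flag = TRUE)
  d3 <- apply_somatic_filter(v3, panel)
  expect_true(d3$retained)
  expect_equal(d3$reason, "pass")
  expect_true(is.na(d3$fisher_p))

  # control-free without the flag fails on evidence
  v4 <- v3
  v4$control_free_somatic_flag <- FALSE
  expect_equal(apply_somatic_filter(v4, panel)$reason, "control_free_fail")

  # off-panel gene short-circuits everything else
  v5 <- make_variant_row(gene = "ZZGENE1", germline_suspect_flag = TRUE,
                         tumor_alt_depth = 1L)
  expect_equal(apply_somatic_filter(v5, panel)$reason, "not_in_panel")

  # germline flag beats the evidence rule
  v6 <- make_variant_row(germline_suspect_flag = TRUE)
  expect_equal(apply_somatic_filter(v6, panel)$reason, "germline_suspect")
})

test_that("VAF boundary is inclusive and p boundary strict", {
  panel <- default_gene_panel()
  v <- make_variant_row(tumor_ref_depth = 97L, tumor_alt_depth = 3L,
                        normal_ref_depth = 1000L, normal_alt_depth = 0L)
  d <- apply_somatic_filter(v, panel)
  expect_equal(d$vaf, 0.03)
  expect_false(d$reason == "below_vaf")  # vaf == vaf_min passes the floor
  # a fisher_p exactly at p_max must fail (strict <)
  v2 <- make_variant_row(tumor_ref_depth = 60L, tumor_alt_depth = 40L,
                         normal_ref_depth = 60L, normal_alt_depth = 40L)
  p_eq <- fisher_two_sided(60, 40, 60, 40)
  d2 <- apply_somatic_filter(v2, panel, p_max = p_eq)
  expect_equal(d2$reason, "fisher_ns")
})

test_that("raising the VAF floor never enlarges the retained set", {
  tab <- random_mutation_table(120, seed = 404)
  panel <- default_gene_panel()
  prev <- rep(TRUE, nrow(tab))
  for (v in c(0, 0.03, 0.1, 0.2, 0.5)) {
    ret <- apply_somatic_filter(tab, panel, vaf_min = v)$retained
    expect_true(all(ret <= prev))
    prev <- ret
  }
})

test_that("retention equals the brute-force rule conjunction on random data", {
  tab <- random_mutation_table(150, seed = 505)
  panel <- default_gene_panel()
  dec <- apply_somatic_filter(tab, panel)
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    vaf <- r$tumor_alt_depth / (r$tumor_ref_depth + r$tumor_alt_depth)
    has_ctrl <- !is.na(r$normal_ref_depth) &&
      (r$normal_ref_depth + r$normal_alt_depth) > 0
    evidence <- if (has_ctrl) {
      fisher_two_sided(r$tumor_ref_depth, r$tumor_alt_depth,
                       r$normal_ref_depth, r$normal_alt_depth) < 0.001
    } else {
      r$control_free_somatic_flag
    }
    keep <- r$gene %in% panel$driver_genes && vaf >= 0.03 &&
      !r$germline_suspect_flag && evidence
    expect_identical(dec$retained[i], keep)
  }
  expect_identical(dec$retained, dec$reason == "pass")
})

test_that("profiles derive biallelic CEBPA, IDH2-R172 and FLT3-ITD flags", {
  tab <- rbind(
    make_variant_row("A", "CEBPA", "frameshift", "p.P23fs"),
    make_variant_row("A", "CEBPA", "inframe_indel", "p.K313dup"),
    make_variant_row("B", "CEBPA", "frameshift", "p.P23fs"),
    make_variant_row("C", "IDH2", "missense", "p.R172K"),
    make_variant_row("D", "IDH2", "missense", "p.R140Q"),
    make_variant_row("E", "FLT3", "ITD", "p.ITD"),
    make_variant_row("F", "CEBPA", "missense", "p.Q10L",
                     biallelic_annotation = TRUE)
  )
  prof <- build_profiles(tab, default_gene_panel())
  rownames(prof) <- prof$patient_id
  expect_true(prof["A", "biallelic_cebpa"])
  expect_false(prof["B", "biallelic_cebpa"])
  expect_true(prof["F", "biallelic_cebpa"])  # explicit annotation
  expect_true(prof["C", "idh2_r172"])
  expect_false(prof["D", "idh2_r172"])
  expect_true(prof["E", "flt3_itd"])
  expect_equal(prof["A", "n_driver_mutations"], 2L)
})

test_that("duplicate variant rows are deduplicated with a warning and empty
           profiles are kept for listed patients", {
  tab <- rbind(make_variant_row("A", "NPM1"), make_variant_row("A", "NPM1"))
  expect_warning(prof <- build_profiles(tab, default_gene_panel(),
                                        patient_ids = c("A", "B")),
                 "duplicate")
  expect_equal(prof$n_driver_mutations, c(1L, 0L))
  expect_equal(prof$patient_id, c("A", "B"))
  expect_equal(prof$mutated_genes[[2]], character(0))
})
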