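# Shared fixture builders (all fixtures are generated in code).

make_variant_row <- function(patient_id = "P1", gene = "NPM1",
                             variant_class = "missense",
                             protein_change = "p.X1X",
                             tumor_ref_depth = 80L, tumor_alt_depth = 20L,
                             normal_ref_depth = 100L, normal_alt_depth = 0L,
                             known_somatic_flag = TRUE,
                             germline_suspect_flag = FALSE,
                             control_free_somatic_flag = FALSE,
                             biallelic_annotation = FALSE) {
  data.frame(patient_id, gene, variant_class, protein_change,
             tumor_ref_depth, tumor_alt_depth,
             normal_ref_depth, normal_alt_depth,
             known_somatic_flag, germline_suspect_flag,
             control_free_somatic_flag, biallelic_annotation,
             stringsAsFactors = FALSE)
}

make_clinical_row <- function(patient_id = "P1", age = 50, sex = "F",
                              wbc = 20, bm_blast_pct = 70,
                              cr_achieved = TRUE, cr_time = 1.5,
                              sct_time = NA_real_, relapse_time = NA_real_,
                              death_time = NA_real_,
                              last_followup_time = 60) {
  data.frame(patient_id, age, sex, wbc, bm_blast_pct, cr_achieved,
             cr_time, sct_time, relapse_time, death_time,
             last_followup_time, stringsAsFactors = FALSE)
}

random_mutation_table <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sample(c(DEFAULT_DRIVER_GENES, "ZZGENE1", "ZZGENE2"), n,
                  replace = TRUE)
  has_ctrl <- runif(n) < 0.7
  tab <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_variant_row(
      patient_id = sprintf("P%03d", sample(1:20, 1)),
      gene = genes[i],
      variant_class = sample(VARIANT_CLASSES, 1),
      protein_change = if (runif(1) < 0.8) {
        sprintf("p.R%dK", sample(1:500, 1))
      } else {
        NA_character_
      },
      tumor_ref_depth = sample(50:500, 1),
      tumor_alt_depth = sample(0:200, 1),
      normal_ref_depth = if (has_ctrl[i]) sample(50:500, 1) else NA_integer_,
      normal_alt_depth = if (has_ctrl[i]) sample(0:20, 1) else NA_integer_,
      known_somatic_flag = runif(1) < 0.5,
      germline_suspect_flag = runif(1) < 0.2,
      control_free_somatic_flag = runif(1) < 0.5,
      biallelic_annotation = runif(1) < 0.05
    )
  }))
  rownames(tab) <- NULL
  tab
}

# one-row profile usable by classify_patient()
make_profile <- function(genes = character(), biallelic_cebpa = FALSE,
                         idh2_r172 = FALSE, flt3_itd = FALSE,
                         n_driver = length(genes), patient_id = "P1") {
  out <- data.frame(patient_id = patient_id,
                    n_driver_mutations = as.integer(n_driver),
                    biallelic_cebpa = biallelic_cebpa,
                    idh2_r172 = idh2_r172, flt3_itd = flt3_itd,
                    stringsAsFactors = FALSE)
  out$mutated_genes <- I(list(genes))
  out
}
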