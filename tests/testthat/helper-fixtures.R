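# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# small structured panel: 4 groups x 2 populations x 15 samples, 2,000 SNPs,
# 80 planted AIMs, fully observed
small_sim <- function() memo("small_sim", {
  simulate_ancestry_panel(sim_config(
    n_groups = 4, populations_per_group = 2, samples_per_population = 15,
    n_snps = 2000, n_planted_aims = 80, fst_between_group = 0.05,
    fst_within_group = 0.01, seed = 42))
})

# same panel, imputed view (identity here: no missing cells)
small_m <- function() small_sim()$matrix
small_labels <- function() small_m()$samples$group_label

# tiny deterministic matrix from explicit dosages (one chromosome)
toy_matrix <- function(dosage, populations = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); p <- ncol(dosage)
  genotype_matrix(
    dosage,
    variants = data.frame(id = sprintf("v%03d", seq_len(p)), chrom = "1",
                          pos = seq_len(p) * 100L, ref = "A", alt = "C"),
    samples = data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                         population = populations %||% rep("pop1", n),
                         latitude = 50, longitude = 40))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
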