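# small shared builders for the test suite

tiny_library <- function(n_genes = 3, guides_per_gene = 2, n_nt = 1,
                         seed = 42) {
  simulate_guide_library(n_genes, guides_per_gene, n_nt, seed = seed)
}

# a balanced CGA table with explicit proportions
cga_table <- function(drug, vehicle, n_assays = 1, n_reps = NULL) {
  if (is.null(n_reps)) n_reps <- length(drug) / n_assays
  grid <- expand.grid(replicate = seq_len(n_reps), assay = seq_len(n_assays))
  rbind(data.frame(sgrna = "sg1", assay = grid$assay,
                   replicate = grid$replicate, condition = "drug",
                   proportion = drug),
        data.frame(sgrna = "sg1", assay = grid$assay,
                   replicate = grid$replicate, condition = "vehicle",
                   proportion = vehicle))
}

# exact Bliss-null checkerboard builder used by synergy tests
null_board <- function(doses_x = equipotency_doses(1),
                       doses_y = equipotency_doses(1, c(0.03125, 0.0625,
                                                        0.125, 0.25, 0.5, 1,
                                                        2, 4, 8)),
                       noise_sd = 0, replicates = 3, seed = 1) {
  simulate_checkerboard(doses_x, doses_y, noise_sd = noise_sd,
                        replicates = replicates, seed = seed)
}
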