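# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small except where a check is explicitly about
# calibration at depth.

# An editing_matrix built directly from edited/unedited count matrices
# (columns: WT_1, WT_2, mut_1, mut_2, ... following `genotypes`).
toy_matrix <- function(edited, unedited, genotypes, roles = NULL,
                       n_rep = 2L, backgrounds = NULL) {
  if (is.null(roles)) {
    roles <- setNames(c("wildtype", rep("mutant", length(genotypes) - 1)),
                      genotypes)
  }
  if (is.null(names(n_rep))) {
    n_rep <- setNames(rep(n_rep[1], length(genotypes)), genotypes)
  }
  design <- make_design(genotypes, n_rep, roles, backgrounds)
  sites <- data.frame(
    site_id = paste0("tx1_C", seq_len(nrow(edited)) * 10L),
    transcript = "tx1", organelle = "mito", complex_group = "complex I",
    strand = "+", tx_position = seq_len(nrow(edited)) * 10L,
    genome_position = seq_len(nrow(edited)) * 10L,
    stringsAsFactors = FALSE
  )
  editing_matrix(edited, unedited, sites = sites, design = design)
}

# Site annotation with guaranteed spacing (farther apart than a read
# length), so every site-covering read informs exactly one site. Two
# transcripts, one per strand, to exercise both orientations.
spaced_sites <- function(n, spacing = 400L) {
  pos <- 200L + (seq_len(n) - 1L) * spacing
  tx <- rep(c("txp", "txm"), length.out = n)
  strand <- ifelse(tx == "txp", "+", "-")
  data.frame(
    site_id = paste0(tx, "_C", pos), transcript = tx,
    organelle = "mito", complex_group = "complex I", strand = strand,
    tx_position = pos, genome_position = pos, stringsAsFactors = FALSE
  )
}

# A small complete synthetic study: WT + two mutants sharing truth +
# two transgenic lines per mutant, counts at the given depth.
toy_study <- function(n_mito = 60, n_plastid = 6, depth = 2000, seed = 42,
                      frac_increased = 0.14, frac_decreased = 0.03,
                      delta_range = c(0.15, 0.4), restore = 1,
                      invariant_shift = 0, n_invariant_shifted = NULL) {
  sites <- gen_sites(n_mito, n_plastid, n_transcripts = 6, seed = seed)
  truth <- gen_truth(sites, frac_increased = frac_increased,
                     frac_decreased = frac_decreased,
                     delta_range = delta_range, seed = seed + 1,
                     mutants = c("mutA", "mutB"))
  for (m in c("mutA", "mutB")) {
    for (k in 1:2) {
      truth <- add_transgenic_truth(
        truth, paste0("T_", m, "_", k), m, restore = restore,
        invariant_shift = invariant_shift,
        n_invariant_shifted = n_invariant_shifted, seed = seed + 2)
    }
  }
  design <- design_from_truth(truth)
  list(sites = sites, truth = truth, design = design,
       matrix = gen_counts(truth, design, depth = depth, seed = seed + 3))
}
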