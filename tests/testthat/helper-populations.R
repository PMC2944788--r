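# Small shared populations, simulated once per test run.

tiny_cfg <- sim_config(n_ind = 200, n_snp = 300, n_chrom = 3,
                       chrom_length_morgans = 0.6, ne = 50,
                       n_generations = 150, n_sires = 10,
                       n_discovery = 120, n_validation = 60, seed = 42)
tiny_pop_raw <- sim_population(tiny_cfg)
tiny_pop <- qc_filter(tiny_pop_raw)

# a hand-checkable population wrapper around an explicit dosage matrix
manual_population <- function(g, chrom = rep(1L, ncol(g))) {
  if (is.null(rownames(g))) rownames(g) <- sprintf("id%04d", seq_len(nrow(g)))
  if (is.null(colnames(g))) colnames(g) <- sprintf("snp%05d", seq_len(ncol(g)))
  structure(list(
    genotypes = g,
    snp_map = data.frame(snp_id = colnames(g), chrom = chrom,
                         pos_bp = seq_len(ncol(g)), pos_cm = seq_len(ncol(g)),
                         stringsAsFactors = FALSE),
    pedigree = data.frame(id = rownames(g),
                          sire = rep("sire001", nrow(g)),
                          stringsAsFactors = FALSE),
    allele_freq = colMeans(g, na.rm = TRUE) / 2,
    config = NULL), class = "population")
}
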