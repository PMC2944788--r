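test_that("simulation is reproducible and seed-sensitive", {
  cfg <- sim_config(n_ind = 60, n_snp = 80, n_chrom = 2, ne = 20,
                    n_generations = 40, n_sires = 6, n_discovery = 30,
                    n_validation = 20, seed = 9)
  p1 <- sim_population(cfg)
  p2 <- sim_population(cfg)
  expect_identical(p1$genotypes, p2$genotypes)
  cfg2 <- cfg; cfg2$seed <- 10L
  p3 <- sim_population(cfg2)
  expect_false(identical(p1$genotypes, p3$genotypes))
})

test_that("population structure matches the configuration", {
  g <- tiny_pop_raw$genotypes
  expect_equal(dim(g), c(200, 300))
  expect_true(all(g %in% 0:2))
  expect_equal(rownames(g), tiny_pop_raw$pedigree$id)
  expect_equal(length(unique(tiny_pop_raw$pedigree$sire)), 10)
  expect_equal(tiny_pop_raw$allele_freq, colMeans(g) / 2)
  map <- tiny_pop_raw$snp_map
  expect_equal(nrow(map), 300)
  expect_equal(sort(unique(map$chrom)), 1:3)
  for (c in 1:3)
    expect_false(is.unsorted(map$pos_cm[map$chrom == c]))
})

test_that("QC applies the three panel rules exactly on a hand-built fixture", {
  n <- 50
  g <- cbind(
    s1 = rep(c(0, 1, 2), times = c(12, 26, 12)),        # clean, kept
    s2 = c(rep(NA, 10), rep(c(0, 1), each = 20)),       # call rate 0.80
    s3 = c(1, 1, rep(0, 48)),                           # MAF exactly 0.02
    s4 = c(rep(1, 5), rep(0, 45)),                      # MAF 0.05, kept
    s5 = rep(1, n),                                     # all hets: HWE fail
    s6 = c(NA, NA, rep(c(0, 2, 1, 1), 12)),             # kept, 2 imputed
    s7 = rep(0, n),                                     # monomorphic
    s8 = rep(c(0, 2), each = 25))                       # no hets: HWE fail
  pop <- manual_population(g)
  out <- qc_filter(pop)
  rep_ <- attr(out, "qc_report")
  expect_equal(colnames(out$genotypes), c("s1", "s4", "s6"))
  expect_equal(rep_$n_input, 8)
  expect_equal(rep_$n_kept, 3)
  expect_equal(rep_$fail_call_rate, 1)
  expect_equal(rep_$fail_maf, 2)
  expect_equal(rep_$fail_hwe, 2)
  expect_equal(rep_$n_imputed, 2)
  # mean imputation: the two missing s6 calls get the observed mean (1)
  expect_equal(out$genotypes[1:2, "s6"], c(id0001 = 1, id0002 = 1))
  expect_false(anyNA(out$genotypes))
  # the MAF boundary is strict: exactly min_maf is removed, just above is kept
  pop_b <- manual_population(cbind(b1 = c(1, 1, rep(0, 48)),
                                   b2 = c(1, 1, 1, rep(0, 47)),
                                   filler = rep(c(0, 1, 2), times = c(12, 26, 12))))
  kept <- colnames(qc_filter(pop_b)$genotypes)
  expect_false("b1" %in% kept)   # MAF = 0.02
  expect_true("b2" %in% kept)    # MAF = 0.03
})

test_that("injected missingness is caught by the call-rate rule", {
  # at rate 0.005 a minority of SNPs get >2 missing calls out of 200 and
  # fail a 0.99 call-rate threshold, while most of the panel survives
  popm <- add_missing(tiny_pop_raw, rate = 0.005, seed = 3)
  expect_gt(sum(is.na(popm$genotypes)), 0)
  out <- qc_filter(popm, min_call_rate = 0.99)
  expect_false(anyNA(out$genotypes))
  expect_gt(attr(out, "qc_report")$fail_call_rate, 0)
})

test_that("trait architectures have the documented shapes", {
  a_type <- trait_architecture(tiny_pop, "type_like", seed = 1)
  a_fat <- trait_architecture(tiny_pop, "fat_like", seed = 1)
  a_blk <- trait_architecture(tiny_pop, "black_like", seed = 1)
  expect_length(a_type$qtl_idx, 0)
  expect_equal(a_type$tail_dist, "normal")
  expect_equal(a_fat$qtl_frac, 0.30)
  expect_equal(a_blk$qtl_frac, c(0.094, 0.060, 0.088))
  expect_equal(a_blk$tail_dist, "t")
  # moderate loci on distinct chromosomes, decently polymorphic
  chr <- tiny_pop$snp_map$chrom[a_blk$qtl_idx]
  expect_equal(length(unique(chr)), 3)
  maf <- pmin(tiny_pop$allele_freq, 1 - tiny_pop$allele_freq)
  expect_true(all(maf[a_blk$qtl_idx] >= 0.1))
  # the tail avoids the windows around moderate loci
  excl <- unlist(lapply(a_blk$qtl_idx, function(i) (i - 25):(i + 25)))
  expect_length(intersect(a_blk$tail_idx, excl), 0)
})

test_that("h2 = 1 makes the phenotype equal the breeding value", {
  arch <- trait_architecture(tiny_pop, "fat_like", seed = 2)
  tr <- sim_trait(tiny_pop, arch, h2 = 1, seed = 3)
  expect_equal(tr$phenotype, tr$tbv)
})

test_that("the realised heritability matches the target over replicates", {
  arch <- trait_architecture(tiny_pop, "black_like", seed = 4)
  h2s <- betas <- numeric(30)
  for (r in 1:30) {
    tr <- sim_trait(tiny_pop, arch, h2 = 0.74, seed = 100 + r)
    h2s[r] <- var(tr$tbv) / var(tr$phenotype)
    betas[r] <- coef(lm(tr$phenotype ~ tr$tbv))[2]
  }
  expect_equal(mean(h2s), 0.74, tolerance = 0.05)
  expect_equal(mean(betas), 1, tolerance = 0.05)
})

test_that("moderate loci carry their nominal phenotypic variance fractions", {
  # needs a panel large enough that the tail is non-degenerate: on the tiny
  # panel the three black_like exclusion windows leave no tail candidates,
  # in which case the moderate loci absorb the whole genetic variance
  cfg <- sim_config(n_ind = 300, n_snp = 600, n_chrom = 3, ne = 50,
                    n_generations = 150, n_sires = 15, n_discovery = 180,
                    n_validation = 80, seed = 43)
  pop <- qc_filter(sim_population(cfg))
  g <- pop$genotypes
  for (nm in c("fat_like", "black_like")) {
    arch <- trait_architecture(pop, nm, seed = 5)
    expect_gt(length(arch$tail_idx), 50)
    h2 <- if (nm == "fat_like") 0.83 else 0.74
    fr <- matrix(0, 30, length(arch$qtl_idx))
    for (r in 1:30) {
      tr <- sim_trait(pop, arch, h2 = h2, seed = 200 + r)
      for (k in seq_along(arch$qtl_idx))
        fr[r, k] <- var(g[, arch$qtl_idx[k]] * tr$true_effects[arch$qtl_idx[k]]) /
          var(tr$phenotype)
    }
    expect_equal(colMeans(fr), arch$qtl_frac, tolerance = 0.031,
                 ignore_attr = TRUE)
  }
})

test_that("moderate loci cannot exceed the genetic variance", {
  arch <- trait_architecture(tiny_pop, "fat_like", seed = 5)
  expect_error(sim_trait(tiny_pop, arch, h2 = 0.25, seed = 1), "exceed")
})

test_that("a trait without genetic variance errors or degrades to noise", {
  arch <- trait_architecture(tiny_pop, "type_like", n_tail = 3, seed = 6)
  arch$tail_idx <- integer(0)   # strip every causal locus
  expect_error(sim_trait(tiny_pop, arch, h2 = 0.5, seed = 1), "variance")
  tr <- sim_trait(tiny_pop, arch, h2 = 0.5, seed = 1, on_zero_variance = "noise")
  expect_true(all(tr$tbv == 0))
  expect_gt(var(tr$phenotype), 0)
})

test_that("the family split keeps discovery and validation sires disjoint", {
  arch <- trait_architecture(tiny_pop, "type_like", seed = 7)
  tr <- sim_trait(tiny_pop, arch, h2 = 0.63, seed = 8)
  sires <- setNames(tiny_pop$pedigree$sire, tiny_pop$pedigree$id)
  ids_d <- names(tr$phenotype)[tr$split == "discovery"]
  ids_v <- names(tr$phenotype)[tr$split == "validation"]
  expect_length(intersect(sires[ids_d], sires[ids_v]), 0)
  expect_equal(length(ids_v), tiny_cfg$n_validation)
  expect_lte(length(ids_d), tiny_cfg$n_discovery)
})

test_that("the random split assigns exactly the configured sizes", {
  arch <- trait_architecture(tiny_pop, "type_like", seed = 7)
  tr <- sim_trait(tiny_pop, arch, h2 = 0.63, seed = 8, split_by = "random")
  expect_equal(sum(tr$split == "discovery"), tiny_cfg$n_discovery)
  expect_equal(sum(tr$split == "validation"), tiny_cfg$n_validation)
  expect_equal(sum(tr$split == "unused"),
               200 - tiny_cfg$n_discovery - tiny_cfg$n_validation)
})

test_that("the default map sits in the intended LD regime", {
  # adjacent-SNP r2 on the QC-passed panel of the default-scale generator
  cfg <- sim_config(seed = 2026)
  pop <- qc_filter(sim_population(cfg))
  r2 <- adjacent_r2(pop)
  expect_gt(r2, 0.15)
  expect_lt(r2, 0.35)
  # at this scale the near-infinitesimal archetype respects its defining
  # bound: no locus carries more than 0.5% of the genetic variance
  arch <- trait_architecture(pop, "type_like", seed = 3)
  expect_equal(arch$max_locus_frac, 0.005)
  tr <- sim_trait(pop, arch, h2 = 0.63, seed = 3)
  vj <- apply(pop$genotypes, 2, var)
  fr <- vj * tr$true_effects^2 / var(tr$tbv)
  expect_lt(max(fr), 0.0075)
})

test_that("zero recombination leaves segregating SNPs in complete LD", {
  # with no recombination and no mutation a chromosome is inherited whole;
  # the seed is chosen so that exactly two founder haplotype classes survive
  # the drift phase, in which case every pair of segregating SNPs has r2 = 1
  cfg <- sim_config(n_ind = 60, n_snp = 30, n_chrom = 1,
                    chrom_length_morgans = 0, mu = 0, ne = 10,
                    n_generations = 12, n_sires = 5, n_discovery = 30,
                    n_validation = 20, seed = 1)
  pop <- sim_population(cfg)
  v <- apply(pop$genotypes, 2, var)
  seg <- which(v > 0)
  expect_gt(length(seg), 1)
  cc <- cor(pop$genotypes[, seg])^2
  expect_equal(unname(cc[upper.tri(cc)]), rep(1, sum(upper.tri(cc))),
               tolerance = 1e-12)
})
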