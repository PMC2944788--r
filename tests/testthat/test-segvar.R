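test_that("segment partition arithmetic is exact and never spans chromosomes", {
  map1 <- data.frame(chrom = rep(1L, 120))
  seg <- partition_segments(map1, 50)
  expect_equal(seg$n_snp, c(50, 50, 20))
  expect_equal(seg$short, c(FALSE, FALSE, TRUE))
  expect_equal(seg$snp_start, c(1, 51, 101))
  expect_equal(seg$snp_end, c(50, 100, 120))
  # property: random maps conserve every SNP exactly once per segment table
  set.seed(41)
  for (i in 1:10) {
    nc <- sample(1:4, 1)
    per <- sample(5:90, nc, replace = TRUE)
    mp <- data.frame(chrom = rep(seq_len(nc), per))
    sz <- sample(2:60, 1)
    sg <- partition_segments(mp, sz)
    covered <- unlist(Map(seq, sg$snp_start, sg$snp_end))
    expect_equal(sort(covered), seq_len(nrow(mp)))
    expect_equal(sum(sg$n_snp), nrow(mp))
    for (r in seq_len(nrow(sg)))
      expect_length(unique(mp$chrom[sg$snp_start[r]:sg$snp_end[r]]), 1)
    expect_true(all(sg$n_snp <= sz))
  }
  expect_error(partition_segments(map1, 1), "at least 2")
})

test_that("the permutation sigma estimator recovers known noise levels", {
  set.seed(42)
  for (s in c(0.05, 0.1, 0.2)) {
    p_null <- pmax(rnorm(20000, 0, s), 0)^2
    expect_equal(sigma_from_null(p_null), s, tolerance = 0.1)
  }
  expect_error(sigma_from_null(numeric(0)), "no finite")
})

test_that("EM deconvolves a known two-component mixture within 0.03", {
  set.seed(43)
  n <- 3000
  truth0 <- 0.7; mu1 <- 0.30; sg <- 0.05
  t_true <- ifelse(runif(n) < truth0, 0, mu1)
  y <- pmax(t_true + rnorm(n, 0, sg), 0)
  dist <- em_effect_distribution(y, sg)
  expect_true(all(diff(dist$trace) > -1e-9))
  mass0 <- sum(dist$freq[dist$grid < 0.15])
  mass1 <- sum(dist$freq[dist$grid >= 0.15 & dist$grid <= 0.45])
  expect_equal(mass0, truth0, tolerance = 0.03)
  expect_equal(mass1, 1 - truth0, tolerance = 0.03)
  # the recovered nonzero component is centred near its true location
  nz <- dist$grid >= 0.15
  expect_equal(sum(dist$grid[nz] * dist$freq[nz]) / sum(dist$freq[nz]),
               mu1, tolerance = 0.02)
})

test_that("EM output is a distribution and invariant to input order", {
  set.seed(44)
  y <- pmax(rnorm(500, 0.05, 0.08), 0)
  d1 <- em_effect_distribution(y, 0.08)
  d2 <- em_effect_distribution(sample(y), 0.08)
  expect_equal(sum(d1$freq), 1, tolerance = 1e-10)
  expect_true(all(d1$freq >= 0))
  expect_equal(d1$freq, d2$freq, tolerance = 1e-12)
  expect_error(em_effect_distribution(c(-0.1, 0.2), 0.05), ">= 0")
  expect_error(em_effect_distribution(y, -1), "sigma")
})

test_that("sigma = 0 snaps the empirical distribution onto the grid", {
  y <- c(0, 0, 0.1, 0.1, 0.304, 1)
  d <- em_effect_distribution(y, 0)
  expect_equal(d$freq[d$grid == 0], 2 / 6)
  expect_equal(d$freq[abs(d$grid - 0.1) < 1e-9], 2 / 6)
  expect_equal(d$freq[abs(d$grid - 0.30) < 1e-9], 1 / 6)
  expect_equal(d$freq[d$grid == 1], 1 / 6)
})

test_that("binning on the variance scale conserves mass", {
  set.seed(45)
  y <- pmax(rnorm(400, 0.1, 0.1), 0)
  d <- em_effect_distribution(y, 0.1)
  b <- bin_t_squared(d, c(0, 1e-4, 1e-3, 1e-2, 1e-1, 1))
  expect_equal(sum(b$mass), 1, tolerance = 1e-10)
  expect_true(all(b$mass >= 0))
  # the bin (l, u] collects exactly the classes with l < t^2 <= u
  expect_equal(b$mass[b$lower == 1e-2 & b$upper == 1e-1],
               sum(d$freq[d$grid^2 > 1e-2 & d$grid^2 <= 1e-1]))
  expect_error(bin_t_squared(d, c(0.5, 0.2)), "ascending")
})

test_that("the cumulative curve is monotone and masks linked neighbours", {
  sc <- data.frame(segment = 1:8, chrom = c(1, 1, 1, 1, 2, 2, 2, 2),
                   p_hat = c(0.05, 0.40, 0.30, 0.01, 0.20, 0.02, 0, 0.03))
  cv <- cumulative_variance_curve(sc, exclusion_radius = 1)
  expect_equal(cv$segment[1], 2)
  # segment 3 is adjacent to the selected 2: its contribution is zeroed
  expect_equal(cv$p_hat[cv$segment == 3], 0)
  expect_true(all(diff(cv$cumulative) >= 0))
  expect_equal(cv$cumulative_prop[nrow(cv)], 1)
  # radius 0 keeps every contribution
  cv0 <- cumulative_variance_curve(sc, exclusion_radius = 0)
  expect_equal(max(cv0$cumulative), sum(sc$p_hat))
  # chromosome boundaries stop the masking: segment 5 keeps its value
  expect_equal(cv$p_hat[cv$segment == 5], 0.20)
})

test_that("the segment scan finds the segment carrying a planted QTL", {
  # a single planted locus with no polygenic tail: on this small panel most
  # SNPs are tail loci, so a full archetype spreads real variance into every
  # segment and localization is not the property being tested
  arch <- trait_architecture(tiny_pop, "fat_like", seed = 46)
  arch$tail_idx <- integer(0)
  tr <- sim_trait(tiny_pop, arch, h2 = 0.83, seed = 46)
  segs <- partition_segments(tiny_pop$snp_map, 30)
  sc <- segment_variance_scan(tr$phenotype, tiny_pop, segs, max_iter = 100)
  expect_true(all(sc$p_hat >= 0 & sc$p_hat <= 1, na.rm = TRUE))
  expect_equal(sc$y_i, sqrt(sc$p_hat))
  qseg <- which(segs$snp_start <= arch$qtl_idx[1] &
                  segs$snp_end >= arch$qtl_idx[1])
  expect_equal(which.max(sc$p_hat), qseg)
  expect_gt(sc$p_hat[qseg], 2 * median(sc$p_hat, na.rm = TRUE))
})

test_that("permutation of phenotypes yields small estimates and a usable sigma", {
  set.seed(47)
  arch <- trait_architecture(tiny_pop, "fat_like", seed = 46)
  tr <- sim_trait(tiny_pop, arch, h2 = 0.83, seed = 46)
  segs <- partition_segments(tiny_pop$snp_map, 30)[1:4, ]
  ns <- permutation_sigma(tr$phenotype, tiny_pop, segs, n_perm = 2,
                          max_iter = 60)
  expect_gt(ns$sigma, 0)
  expect_lt(ns$mean_null_proportion, 0.5)
  expect_length(ns$pooled, 8)
})
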