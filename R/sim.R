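#' Simulation configuration for a half-sib SNP population
#'
#' Defines the demographic and genomic parameters of the synthetic population:
#' a Wright-Fisher ancestral population of effective size `ne` evolved for
#' `n_generations` discrete generations with recombination (Haldane map, no
#' interference) and recurrent mutation, then expanded into `n_ind` offspring
#' distributed over `n_sires` paternal half-sib families.
#'
#' The defaults emulate a dairy-cattle progeny-test design: 1156 genotyped
#' bulls (756 discovery + 400 validation), 2000 SNPs on 5 chromosomes, and an
#' effective population size of 100.  The marker spacing (2.7 Morgans per
#' chromosome) is chosen so that the expected adjacent-marker linkage
#' disequilibrium under drift-recombination equilibrium, E(r2) = 1/(1 + 4 Ne c)
#' (Sved), is close to 0.27 at Ne = 100.
#'
#' @param n_ind number of offspring individuals.
#' @param n_snp total number of SNPs (split evenly across chromosomes).
#' @param n_chrom number of autosomes.
#' @param chrom_length_morgans genetic length of each chromosome, Morgans.
#' @param ne effective population size of the ancestral population (>= 2).
#' @param n_generations Wright-Fisher generations; at least `4 * ne` is
#'   recommended so linkage disequilibrium reaches drift equilibrium.
#' @param n_sires number of sires; offspring are allocated to sires as evenly
#'   as possible.
#' @param mu per-site, per-gamete recurrent mutation rate.  The default keeps
#'   the marker frequency spectrum close to that of a common-variant
#'   genotyping array through the burn-in.
#' @param n_discovery,n_validation sizes of the discovery and validation
#'   subsets used when traits are simulated (`n_discovery + n_validation`
#'   must not exceed `n_ind`).
#' @param seed integer seed; every stochastic operation downstream is
#'   deterministic given the configuration seed.
#' @return an object of class `sim_config`.
#' @seealso [sim_population()], [sim_trait()]
#' @export
sim_config <- function(n_ind = 1156, n_snp = 2000, n_chrom = 5,
                       chrom_length_morgans = 0.6, ne = 100,
                       n_generations = 4 * ne, n_sires = 50, mu = 2.5e-4,
                       n_discovery = 756, n_validation = 400, seed = 1) {
  if (n_snp < n_chrom || n_snp <= 0) stop("n_snp must be >= n_chrom and positive")
  if (ne < 2) stop("ne must be >= 2")
  if (n_ind < 1 || n_sires < 1 || n_sires > ne) stop("need 1 <= n_sires <= ne")
  if (chrom_length_morgans < 0) stop("chrom_length_morgans must be >= 0")
  if (n_discovery + n_validation > n_ind)
    stop("n_discovery + n_validation exceeds n_ind")
  structure(list(n_ind = as.integer(n_ind), n_snp = as.integer(n_snp),
                 n_chrom = as.integer(n_chrom),
                 chrom_length_morgans = chrom_length_morgans,
                 ne = as.integer(ne), n_generations = as.integer(n_generations),
                 n_sires = as.integer(n_sires), mu = mu,
                 n_discovery = as.integer(n_discovery),
                 n_validation = as.integer(n_validation),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d individuals (%d sires), %d SNPs on %d chromosomes of %.2f M\n",
              x$n_ind, x$n_sires, x$n_snp, x$n_chrom, x$chrom_length_morgans))
  cat(sprintf("  Ne = %d, %d generations, mu = %.2g, seed = %d\n",
              x$ne, x$n_generations, x$mu, x$seed))
  invisible(x)
}

# evenly spaced cM map; bp positions at 1 Mb per cM, 1-based
.make_map <- function(cfg) {
  per <- diff(round(seq(0, cfg$n_snp, length.out = cfg$n_chrom + 1)))
  chrom <- rep(seq_len(cfg$n_chrom), per)
  cm <- unlist(lapply(per, function(k)
    seq(0, cfg$chrom_length_morgans * 100, length.out = k)))
  data.frame(snp_id = sprintf("snp%05d", seq_len(cfg$n_snp)),
             chrom = chrom, pos_bp = as.integer(round(cm * 1e6)) + 1L,
             pos_cm = cm, stringsAsFactors = FALSE)
}

#' Simulate a genotyped half-sib population
#'
#' Forward-in-time Wright-Fisher simulation at effective size `cfg$ne` with
#' per-chromosome recombination and recurrent mutation, followed by expansion
#' into paternal half-sib families: `cfg$n_sires` sires and random dams are
#' drawn from the final ancestral generation and each offspring receives one
#' recombinant gamete from its sire and one from its dam.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `population` with elements
#'   \describe{
#'     \item{genotypes}{`n_ind` x `n_snp` integer matrix of allele-2 dosages
#'       (0/1/2); `NA` marks a missing call.}
#'     \item{snp_map}{data frame with `snp_id`, `chrom`, `pos_bp`, `pos_cm`.}
#'     \item{pedigree}{data frame with `id` and `sire` for every individual.}
#'     \item{allele_freq}{per-SNP frequency of the counted ("2") allele.}
#'   }
#' @export
sim_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  map <- .make_map(cfg)
  chr_start <- vapply(unique(map$chrom), function(c) min(which(map$chrom == c)), 1L) - 1L
  chr_end <- vapply(unique(map$chrom), function(c) max(which(map$chrom == c)), 1L) - 1L
  hap0 <- matrix(rbinom(2L * cfg$ne * cfg$n_snp, 1L, 0.5),
                 nrow = 2L * cfg$ne, ncol = cfg$n_snp)
  hap <- cpp_wf_evolve(hap0, map$pos_cm, chr_start, chr_end,
                       cfg$n_generations, cfg$mu)
  sires <- sample.int(cfg$ne, cfg$n_sires)
  fam <- rep(seq_len(cfg$n_sires), length.out = cfg$n_ind)
  fam <- fam[order(fam)]
  dams <- sample.int(cfg$ne, cfg$n_ind, replace = TRUE)
  gam_s <- cpp_gametes(hap, sires[fam], map$pos_cm, chr_start, chr_end, cfg$mu)
  gam_d <- cpp_gametes(hap, dams, map$pos_cm, chr_start, chr_end, cfg$mu)
  geno <- gam_s + gam_d
  storage.mode(geno) <- "integer"
  rownames(geno) <- sprintf("id%04d", seq_len(cfg$n_ind))
  colnames(geno) <- map$snp_id
  ped <- data.frame(id = rownames(geno),
                    sire = sprintf("sire%03d", fam), stringsAsFactors = FALSE)
  structure(list(genotypes = geno, snp_map = map, pedigree = ped,
                 allele_freq = colMeans(geno) / 2, config = cfg),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("Population: %d individuals x %d SNPs on %d chromosomes, %d sire families\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$snp_map$chrom)), length(unique(x$pedigree$sire))))
  maf <- pmin(x$allele_freq, 1 - x$allele_freq)
  cat(sprintf("  mean MAF %.3f, %d monomorphic\n", mean(maf, na.rm = TRUE),
              sum(maf == 0, na.rm = TRUE)))
  invisible(x)
}

#' Mean squared correlation between adjacent SNPs
#'
#' Linkage-disequilibrium summary: r2 between each pair of physically adjacent
#' SNPs on the same chromosome, averaged over pairs where both SNPs segregate.
#'
#' @param pop a [sim_population()] result.
#' @return mean adjacent-SNP r2.
#' @export
adjacent_r2 <- function(pop) {
  g <- pop$genotypes
  r2 <- numeric(0)
  for (c in unique(pop$snp_map$chrom)) {
    idx <- which(pop$snp_map$chrom == c)
    gs <- g[, idx, drop = FALSE]
    v <- apply(gs, 2, var)
    for (j in seq_len(length(idx) - 1)) {
      if (v[j] > 0 && v[j + 1] > 0)
        r2 <- c(r2, cor(gs[, j], gs[, j + 1])^2)
    }
  }
  mean(r2)
}

#' Define a trait architecture
#'
#' Three archetypes of genetic architecture:
#' \describe{
#'   \item{`type_like`}{no moderate loci; many small effects drawn from a
#'     normal distribution (a near-infinitesimal conformation-type trait).
#'     By definition no single locus may explain more than 0.5\% of the
#'     genetic variance (`max_locus_frac = 0.005`, enforced by
#'     [sim_trait()]).}
#'   \item{`fat_like`}{one locus explaining 30\% of the phenotypic variance
#'     (a DGAT1-like major gene) plus a heavy-tailed polygenic tail.}
#'   \item{`black_like`}{three loci explaining 9.4\%, 6.0\% and 8.8\% of the
#'     phenotypic variance (KIT/MITF-like spotting loci) plus a heavy-tailed
#'     tail.}
#' }
#' Moderate loci are placed on distinct chromosomes at minor allele frequency
#' of at least `min_qtl_maf`; tail loci are drawn from the remaining
#' polymorphic SNPs, excluding a window around each moderate locus so that the
#' nominal variance fractions are not inflated by linkage.
#'
#' @param pop a [sim_population()] result.
#' @param name archetype name.
#' @param n_tail number of small-effect tail loci.  The default (500 for
#'   `type_like`, 300 otherwise) is capped at the number of eligible SNPs so
#'   small panels still work; an explicit `n_tail` larger than the panel
#'   allows errors.
#' @param tail_df degrees of freedom of the t-distributed tail (heavy-tailed
#'   archetypes).
#' @param min_qtl_maf minimum minor allele frequency for a moderate locus.
#' @param seed integer seed for locus placement.
#' @return an object of class `trait_architecture` with fields `qtl_idx`,
#'   `qtl_frac` (fractions of phenotypic variance; [sim_trait()] converts
#'   them to genetic-variance fractions through its `h2`), `tail_idx`,
#'   `tail_dist`, `tail_df`.
#' @export
trait_architecture <- function(pop,
                               name = c("type_like", "fat_like", "black_like"),
                               n_tail = NULL,
                               tail_df = 4.012, min_qtl_maf = 0.1, seed = 1) {
  name <- match.arg(name)
  stopifnot(inherits(pop, "population"))
  set.seed(seed)
  frac <- switch(name, type_like = numeric(0), fat_like = 0.30,
                 black_like = c(0.094, 0.060, 0.088))
  tail_dist <- if (name == "type_like") "normal" else "t"
  maf <- pmin(pop$allele_freq, 1 - pop$allele_freq)
  qtl_idx <- integer(0)
  if (length(frac)) {
    chroms <- unique(pop$snp_map$chrom)
    if (length(chroms) < length(frac))
      stop("not enough chromosomes to separate the moderate loci")
    for (k in seq_along(frac)) {
      cand <- which(pop$snp_map$chrom == chroms[k] & maf >= min_qtl_maf)
      if (!length(cand))
        stop("no SNP with sufficient allele frequency for a moderate locus on chromosome ",
             chroms[k])
      qtl_idx[k] <- cand[which.min(abs(cand - stats::median(cand)))]
    }
  }
  excl <- unlist(lapply(qtl_idx, function(i) (i - 25):(i + 25)))
  tail_cand <- setdiff(which(maf > 0.01), excl)
  if (is.null(n_tail))
    n_tail <- min(if (name == "type_like") 500L else 300L, length(tail_cand))
  if (length(tail_cand) < n_tail)
    stop("not enough polymorphic SNPs for ", n_tail, " tail loci")
  tail_idx <- sort(sample(tail_cand, n_tail))
  structure(list(name = name, qtl_idx = qtl_idx, qtl_frac = frac,
                 tail_idx = tail_idx, tail_dist = tail_dist,
                 tail_df = tail_df, n_tail = n_tail,
                 max_locus_frac = if (name == "type_like") 0.005 else Inf),
            class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf("Trait architecture '%s': %d moderate locus/loci (%s of phenotypic variance), %d %s-tail loci\n",
              x$name, length(x$qtl_idx),
              if (length(x$qtl_frac)) paste0(round(100 * x$qtl_frac, 1), "%", collapse = ", ") else "0%",
              x$n_tail, x$tail_dist))
  invisible(x)
}

#' Simulate a quantitative trait on a population
#'
#' True breeding values are built as `tbv = genotypes \%*\% effects`.  The
#' architecture's moderate-locus fractions are of phenotypic variance and are
#' first converted to genetic-variance fractions (`qtl_frac / h2`); each
#' moderate locus effect is then sized from that fraction
#' against the empirical dosage variance of that locus; tail effects are drawn
#' from the architecture's tail distribution and rescaled so the tail
#' contributes the remaining genetic variance.  The phenotype adds normal
#' environmental noise with variance `var(tbv) * (1 - h2) / h2`, so the
#' heritability of a record is `h2`; with `h2 = 1` the phenotype equals the
#' true breeding value exactly.
#'
#' @param pop a [sim_population()] result.
#' @param arch a [trait_architecture()].
#' @param h2 heritability of a record, in (0, 1].
#' @param seed integer seed.
#' @param n_discovery,n_validation discovery/validation split sizes (defaults
#'   from the population's configuration).
#' @param split_by `"family"` (default) assigns whole sire families to the
#'   validation set so that no validation animal has a paternal half-sib among
#'   the discovery records, emulating forward validation on a later cohort;
#'   `"random"` assigns individuals at random, in which case validation
#'   animals typically have close relatives in the reference and realised
#'   accuracies are dominated by family covariance rather than marker effects.
#' @param on_zero_variance what to do when the architecture carries no
#'   genetic variance: `"error"` (default) or `"noise"` (return a pure-noise
#'   trait with `tbv = 0`).
#' @return an object of class `trait_data` with `phenotype`, `tbv`,
#'   `true_effects`, `h2_record` and a `split` factor
#'   (`"discovery"`/`"validation"`).
#' @export
sim_trait <- function(pop, arch, h2, seed = 1,
                      n_discovery = pop$config$n_discovery,
                      n_validation = pop$config$n_validation,
                      split_by = c("family", "random"),
                      on_zero_variance = c("error", "noise")) {
  stopifnot(inherits(pop, "population"), inherits(arch, "trait_architecture"))
  on_zero_variance <- match.arg(on_zero_variance)
  split_by <- match.arg(split_by)
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  set.seed(seed)
  g <- pop$genotypes
  n <- nrow(g); m <- ncol(g)
  eff <- numeric(m)
  # architecture fractions are of phenotypic variance; on the genetic scale
  # a locus explaining f of the phenotype explains f / h2 of the tbv variance
  gfrac <- arch$qtl_frac / h2
  if (sum(gfrac) >= 1)
    stop("moderate loci would exceed the genetic variance at h2 = ", h2)
  frac_tail <- 1 - sum(gfrac)
  if (length(arch$tail_idx) && frac_tail > 0) {
    nt <- length(arch$tail_idx)
    raw <- if (arch$tail_dist == "t") rt(nt, df = arch$tail_df) else rnorm(nt)
    gt <- g[, arch$tail_idx, drop = FALSE]
    vtail <- var(as.vector(gt %*% raw))
    if (vtail > 0) raw <- raw * sqrt(frac_tail / vtail)
    # the near-infinitesimal archetype bounds every single locus: no tail
    # locus may carry more than max_locus_frac of the genetic variance
    # (relaxed to slightly above the equal-share fraction when the panel is
    # too small for the nominal bound to be feasible)
    cap <- arch$max_locus_frac
    if (is.finite(cap) && vtail > 0) {
      cap <- max(cap, 1.05 * frac_tail / nt)
      vj <- apply(gt, 2, var)
      for (it in 1:50) {
        over <- vj * raw^2 > cap
        if (!any(over)) break
        raw[over] <- sign(raw[over]) * sqrt(cap / vj[over])
        vtail <- var(as.vector(gt %*% raw))
        if (vtail > 0) raw <- raw * sqrt(frac_tail / vtail)
      }
    }
    eff[arch$tail_idx] <- raw
  }
  for (k in seq_along(arch$qtl_idx)) {
    vq <- var(g[, arch$qtl_idx[k]])
    if (vq <= 0) stop("moderate locus is monomorphic; requested variance unreachable")
    eff[arch$qtl_idx[k]] <- sample(c(-1, 1), 1) * sqrt(gfrac[k] / vq)
  }
  tbv <- as.vector(g %*% eff)
  vg <- var(tbv)
  if (vg == 0) {
    if (on_zero_variance == "error")
      stop("architecture carries no genetic variance (all effects zero)")
    phe <- rnorm(n)
  } else {
    phe <- tbv + rnorm(n, 0, sqrt(vg * (1 - h2) / h2))
  }
  if (split_by == "family") {
    fam <- pop$pedigree$sire
    split <- rep("discovery", n)
    in_val <- rep(FALSE, n)
    for (f in sample(unique(fam))) {
      if (sum(in_val) >= n_validation) break
      in_val <- in_val | fam == f
    }
    split[in_val] <- "validation"
    if (sum(in_val) > n_validation)
      split[sample(which(in_val), sum(in_val) - n_validation)] <- "unused"
    dpool <- which(split == "discovery")
    if (length(dpool) > n_discovery)
      split[sample(dpool, length(dpool) - n_discovery)] <- "unused"
  } else {
    split <- rep("validation", n)
    disc <- sample.int(n, n_discovery)
    split[disc] <- "discovery"
    if (n_discovery + n_validation < n) {
      extra <- setdiff(seq_len(n), disc)
      split[sample(extra, length(extra) - n_validation)] <- "unused"
    }
  }
  structure(list(phenotype = setNames(phe, rownames(g)),
                 tbv = setNames(tbv, rownames(g)),
                 true_effects = eff, h2_record = h2,
                 split = factor(split, levels = c("discovery", "validation", "unused")),
                 arch = arch$name),
            class = "trait_data")
}

#' @export
print.trait_data <- function(x, ...) {
  cat(sprintf("Trait ('%s'): %d records, h2 = %.2f, realised var(tbv)/var(y) = %.3f\n",
              x$arch, length(x$phenotype), x$h2_record,
              var(x$tbv) / var(x$phenotype)))
  cat(sprintf("  split: %s\n",
              paste(names(table(x$split)), table(x$split), collapse = ", ")))
  invisible(x)
}

#' Inject missing genotype calls
#'
#' Sets a random fraction of genotype entries to `NA`, emulating failed calls.
#'
#' @param pop a population.
#' @param rate per-entry missing probability.
#' @param seed integer seed.
#' @return the population with missing entries.
#' @export
add_missing <- function(pop, rate, seed = 1) {
  set.seed(seed)
  g <- pop$genotypes
  miss <- which(runif(length(g)) < rate)
  g[miss] <- NA_integer_
  pop$genotypes <- g
  pop$allele_freq <- colMeans(g, na.rm = TRUE) / 2
  pop
}

#' Genotype quality control
#'
#' Removes SNPs failing any of three panel rules -- call rate below
#' `min_call_rate`, minor allele frequency not strictly greater than
#' `min_maf`, or a Hardy-Weinberg chi-square (1 df) goodness-of-fit P value
#' below `hwe_p_min` -- then mean-imputes any remaining missing calls in the
#' surviving SNPs.  The MAF boundary is strict: a SNP with MAF exactly equal
#' to `min_maf` is removed.
#'
#' @param pop a population whose genotypes may contain `NA`.
#' @param min_call_rate minimum fraction of non-missing calls.
#' @param min_maf minor-allele-frequency threshold (strict).
#' @param hwe_p_min minimum Hardy-Weinberg P value.
#' @return the filtered population; imputed dosages are real-valued.  The QC
#'   report (counts of SNPs failing each rule) is attached as attribute
#'   `"qc_report"`.
#' @export
qc_filter <- function(pop, min_call_rate = 0.90, min_maf = 0.02,
                      hwe_p_min = 1e-5) {
  stopifnot(min_call_rate > 0, min_call_rate <= 1, min_maf >= 0, min_maf < 0.5,
            hwe_p_min > 0, hwe_p_min < 1)
  g <- pop$genotypes
  n <- nrow(g)
  call_rate <- colMeans(!is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]; x <- x[!is.na(x)]
    if (!length(x)) return(1)
    nn <- length(x)
    obs <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    pj <- (2 * obs[3] + obs[2]) / (2 * nn)
    if (pj <= 0 || pj >= 1) return(1)
    expct <- nn * c((1 - pj)^2, 2 * pj * (1 - pj), pj^2)
    stat <- sum((obs - expct)^2 / expct)
    pchisq(stat, df = 1, lower.tail = FALSE)
  }, numeric(1))
  fail_call <- call_rate < min_call_rate
  fail_maf <- !(maf > min_maf) | is.na(maf)
  fail_hwe <- hwe_p < hwe_p_min
  keep <- !(fail_call | fail_maf | fail_hwe)
  if (!any(keep)) stop("QC removed every SNP")
  g2 <- g[, keep, drop = FALSE]
  storage.mode(g2) <- "double"
  if (anyNA(g2)) {
    for (j in which(colSums(is.na(g2)) > 0)) {
      mj <- mean(g2[, j], na.rm = TRUE)
      g2[is.na(g2[, j]), j] <- mj
    }
  }
  pop$genotypes <- g2
  pop$snp_map <- pop$snp_map[keep, , drop = FALSE]
  pop$allele_freq <- colMeans(g2) / 2
  attr(pop, "qc_report") <- list(
    n_input = length(keep), n_kept = sum(keep),
    fail_call_rate = sum(fail_call), fail_maf = sum(fail_maf),
    fail_hwe = sum(fail_hwe), n_imputed = sum(is.na(g[, keep])))
  pop
}

# A-inverse of the half-sib pedigree (sires founders, dams unknown), as
# triplets over levels = c(individuals, sires); Henderson's rules with
# one known parent (mendelian sampling variance 3/4).
sire_ainverse <- function(pedigree) {
  ids <- pedigree$id
  sires <- unique(pedigree$sire)
  levels <- c(ids, sires)
  n <- length(ids); q <- length(levels)
  si <- n + match(pedigree$sire, sires)
  ii <- c(seq_len(n), seq_len(n), si, si, (n + 1):q)
  jj <- c(seq_len(n), si, seq_len(n), si, (n + 1):q)
  xx <- c(rep(4 / 3, n), rep(-2 / 3, 2 * n), rep(1 / 3, n), rep(1, q - n))
  list(i = ii, j = jj, x = xx, levels = levels, n_ind = n)
}
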