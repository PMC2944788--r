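#' Single-SNP association scan with a random sire effect
#'
#' For each SNP fits `y = mu + x b + Z s + e` with sire effects
#' `s ~ N(0, I s2_S)`, which absorbs spurious associations caused by the
#' half-sib family structure.  The sire-to-residual variance ratio is
#' estimated once under the no-SNP null model (REML via \pkg{lme4}) and held
#' fixed across SNPs by default; the residual scale is re-estimated per SNP
#' from the generalised residual sum of squares, so that with a zero sire
#' variance the statistic reduces exactly to the ordinary least-squares F.
#' P values use an F(1, n - n_sires - 2) reference distribution.
#'
#' @param y named phenotypes (e.g. the discovery subset).
#' @param pop the genotyped population (QC-filtered).
#' @param sires optional named vector/factor of sire ids; defaults to the
#'   population pedigree.  Individuals with unknown sire form singleton
#'   families.
#' @param snps SNP column indices to test (default all).
#' @param lambda optional fixed sire/residual variance ratio, overriding the
#'   null-model estimate (use 0 to force ordinary least squares).
#' @param re_estimate if `TRUE`, the sire variance ratio is re-estimated for
#'   every SNP (slow; the default keeps the null-model estimate).
#' @return an object of class `snp_scan`: a data frame with `snp_id`,
#'   `chrom`, `pos_bp`, `b`, `F`, `p` (monomorphic SNPs give `NA` rows),
#'   with the sire and residual variances of the null model as attributes.
#' @export
snp_scan <- function(y, pop, sires = NULL, snps = NULL, lambda = NULL,
                     re_estimate = FALSE) {
  stopifnot(inherits(pop, "population"))
  g <- pop$genotypes
  ids <- names(y)
  if (is.null(ids)) stop("y must be named by individual id")
  ri <- match(ids, rownames(g))
  if (anyNA(ri)) stop("phenotyped ids missing from the genotype matrix")
  X <- g[ri, , drop = FALSE]
  if (is.null(sires)) sires <- setNames(pop$pedigree$sire, pop$pedigree$id)[ids]
  sires <- as.character(sires)
  sires[is.na(sires)] <- paste0(".solo", seq_len(sum(is.na(sires))))
  fam <- factor(sires)
  n <- length(y); nfam <- nlevels(fam)
  if (is.null(snps)) snps <- seq_len(ncol(X))

  null_fit <- NULL
  if (is.null(lambda)) {
    null_fit <- lme4::lmer(y ~ 1 + (1 | fam),
                           control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                                       check.nobs.vs.nRE = "ignore"))
    vcs <- as.data.frame(lme4::VarCorr(null_fit))
    s2s <- vcs$vcov[vcs$grp == "fam"]
    s2e <- vcs$vcov[vcs$grp == "Residual"]
    lambda <- s2s / s2e
  } else {
    s2s <- lambda; s2e <- 1
  }
  # with a zero sire variance the sire term drops from the model entirely
  dfden <- if (lambda == 0) n - 2 else n - nfam - 2
  if (dfden < 1) stop("not enough residual degrees of freedom")

  one_lambda <- function(lam, cols) {
    nf <- tabulate(fam, nfam)
    kf <- lam / (1 + nf * lam)
    vi <- function(M) {
      M <- as.matrix(M)
      M - (kf[as.integer(fam)] * rowsum(M, fam)[as.integer(fam), , drop = FALSE])
    }
    ones <- rep(1, n)
    vi1 <- drop(vi(ones)); viy <- drop(vi(y))
    a11 <- sum(vi1); a1y <- sum(viy); yy <- sum(y * viy)
    Xs <- X[, cols, drop = FALSE]
    ViX <- vi(Xs)
    xx <- colSums(Xs * ViX)
    x1 <- colSums(ViX)
    xy <- colSums(ViX * y)
    det <- a11 * xx - x1^2
    mono <- apply(Xs, 2, var) == 0 | det <= 1e-10 * a11
    b <- (a11 * xy - x1 * a1y) / det
    b0 <- (xx * a1y - x1 * xy) / det
    rss <- yy - b0 * a1y - b * xy
    s2hat <- rss / dfden
    varb <- (a11 / det) * s2hat
    Fv <- b^2 / varb
    b[mono] <- Fv[mono] <- NA
    list(b = b, F = Fv)
  }

  if (!re_estimate) {
    res <- one_lambda(lambda, snps)
  } else {
    bs <- Fs <- rep(NA_real_, length(snps))
    for (i in seq_along(snps)) {
      j <- snps[i]
      if (var(X[, j]) == 0) next
      fit <- lme4::lmer(y ~ X[, j] + (1 | fam),
                        control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                                    check.nobs.vs.nRE = "ignore"))
      vcs <- as.data.frame(lme4::VarCorr(fit))
      lam_j <- vcs$vcov[vcs$grp == "fam"] / vcs$vcov[vcs$grp == "Residual"]
      r <- one_lambda(lam_j, j)
      bs[i] <- r$b; Fs[i] <- r$F
    }
    res <- list(b = bs, F = Fs)
  }
  out <- data.frame(snp_id = pop$snp_map$snp_id[snps],
                    chrom = pop$snp_map$chrom[snps],
                    pos_bp = pop$snp_map$pos_bp[snps],
                    b = res$b, F = res$F,
                    p = pf(res$F, 1, dfden, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  structure(out, class = c("snp_scan", "data.frame"),
            sigma2_sire = s2s, sigma2_e = s2e, lambda = lambda,
            df_den = dfden, n = n)
}

#' @export
print.snp_scan <- function(x, ...) {
  cat(sprintf("Single-SNP scan: %d SNPs, %d records, sire/residual ratio %.4f, df = (1, %d)\n",
              nrow(x), attr(x, "n"), attr(x, "lambda"), attr(x, "df_den")))
  top <- x[order(x$p), ][1:min(5, nrow(x)), ]
  print(as.data.frame(top), row.names = FALSE)
  invisible(x)
}

#' @export
plot.snp_scan <- function(x, p_line = 1e-4, ...) {
  lp <- -log10(x$p)
  plot(seq_along(lp), lp, col = 1 + x$chrom %% 2, pch = 20,
       xlab = "SNP index", ylab = "-log10 P", ...)
  abline(h = -log10(p_line), lty = 2)
  invisible(x)
}

#' Confirm discovery hits in an independent validation set
#'
#' SNPs below `p_disc` in the discovery scan are refitted on the validation
#' individuals with the same sire-adjusted model; a SNP is confirmed when its
#' validation P value falls below `p_val`.  The variance explained by each
#' confirmed SNP is reported as `2 p (1 - p) b^2 / var(y_val)` using
#' validation allele frequencies.
#'
#' @param scan_disc a discovery [snp_scan()].
#' @param y_val named validation phenotypes (disjoint from discovery).
#' @param pop the population (provides validation genotypes).
#' @param p_disc discovery significance threshold.
#' @param p_val validation (confirmation) threshold.
#' @return data frame of the tested SNPs with discovery and validation
#'   statistics, `var_explained`, and a logical `confirmed`; empty when no
#'   SNP passes `p_disc`.
#' @export
validate_hits <- function(scan_disc, y_val, pop, p_disc = 1e-4, p_val = 0.001) {
  hit <- which(!is.na(scan_disc$p) & scan_disc$p < p_disc)
  empty <- data.frame(snp_id = character(0), chrom = integer(0),
                      pos_bp = integer(0), b_disc = numeric(0),
                      p_disc = numeric(0), b_val = numeric(0),
                      F_val = numeric(0), p_val = numeric(0),
                      var_explained = numeric(0), confirmed = logical(0))
  if (!length(hit)) return(empty)
  idx <- match(scan_disc$snp_id[hit], pop$snp_map$snp_id)
  vscan <- snp_scan(y_val, pop, snps = idx)
  gv <- pop$genotypes[names(y_val), idx, drop = FALSE]
  pv <- colMeans(gv) / 2
  ve <- 2 * pv * (1 - pv) * vscan$b^2 / var(y_val)
  data.frame(snp_id = scan_disc$snp_id[hit], chrom = scan_disc$chrom[hit],
             pos_bp = scan_disc$pos_bp[hit], b_disc = scan_disc$b[hit],
             p_disc = scan_disc$p[hit], b_val = vscan$b, F_val = vscan$F,
             p_val = vscan$p, var_explained = ve,
             confirmed = !is.na(vscan$p) & vscan$p < p_val,
             stringsAsFactors = FALSE)
}
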