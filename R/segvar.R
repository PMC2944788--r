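#' Partition a SNP map into chromosome segments
#'
#' Consecutive non-overlapping windows of `size` adjacent SNPs within each
#' chromosome; a trailing remainder shorter than `size` is kept as a short
#' segment and flagged.  Segments never span a chromosome boundary.
#'
#' @param snp_map data frame with a `chrom` column, sorted by chromosome and
#'   position (as produced by [sim_population()]).
#' @param size segment size in SNPs (default 50).
#' @return data frame with `segment`, `chrom`, `snp_start`, `snp_end`
#'   (column indices), `n_snp` and `short`.
#' @export
partition_segments <- function(snp_map, size = 50) {
  if (size < 2) stop("segment size must be at least 2")
  out <- do.call(rbind, lapply(unique(snp_map$chrom), function(c) {
    idx <- which(snp_map$chrom == c)
    starts <- seq(idx[1], idx[length(idx)], by = size)
    ends <- pmin(starts + size - 1, idx[length(idx)])
    data.frame(chrom = c, snp_start = starts, snp_end = ends)
  }))
  out$n_snp <- out$snp_end - out$snp_start + 1
  out$short <- out$n_snp < size
  out <- cbind(segment = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Variance explained by each chromosome segment
#'
#' For every segment, builds the segment GRM `G1` and the rest-of-genome GRM
#' `G2` (which absorbs variance from the rest of the genome and population
#' structure), fits the three-component model
#' `y = mu + g1 + g2 + e` by REML, and records the estimated proportion of
#' variance attributed to the segment.  By default the proportion is of the
#' genetic variance, `s2_g1 / (s2_g1 + s2_g2)`; set
#' `denominator = "phenotypic"` for `s2_g1 / (s2_g1 + s2_g2 + s2_e)`.
#' Because REML restricts estimates to the parameter space, null segments
#' are reported as exactly zero about half the time, and the proportions
#' summed over segments can exceed 1 through linkage double counting.
#'
#' @param y named phenotypes.
#' @param pop the population (QC-filtered).
#' @param segments a [partition_segments()] table (or subset of its rows).
#' @param denominator `"genetic"` (default) or `"phenotypic"`.
#' @param max_iter REML iteration cap per segment; non-convergence flags the
#'   segment and records `NA`.
#' @return an object of class `segment_scan`: the segments table plus
#'   `s2_g1`, `s2_g2`, `s2_e`, `p_hat`, `y_i` (its square root) and
#'   `converged`.
#' @export
segment_variance_scan <- function(y, pop, segments,
                                  denominator = c("genetic", "phenotypic"),
                                  max_iter = 200L) {
  denominator <- match.arg(denominator)
  if (nrow(segments) < 2) stop("need at least 2 segments so G2 is non-empty")
  g <- pop$genotypes
  ids <- names(y)
  ri <- match(ids, rownames(g))
  if (anyNA(ri)) stop("phenotyped ids missing from the genotype matrix")
  freqs <- colMeans(g[ri, , drop = FALSE]) / 2
  res <- segments
  res$s2_g1 <- res$s2_g2 <- res$s2_e <- res$p_hat <- NA_real_
  res$converged <- FALSE
  sub <- pop
  sub$genotypes <- g[ri, , drop = FALSE]
  for (i in seq_len(nrow(segments))) {
    seg <- segments$snp_start[i]:segments$snp_end[i]
    gp <- grm_pair(sub, seg, freqs)
    fit <- try(greml(y, list(gp$G1, gp$G2), max_iter = max_iter), silent = TRUE)
    if (inherits(fit, "try-error")) next
    vc <- fit$varcomp
    res$s2_g1[i] <- vc[1]; res$s2_g2[i] <- vc[2]; res$s2_e[i] <- vc[3]
    tot <- if (denominator == "genetic") vc[1] + vc[2] else sum(vc)
    res$p_hat[i] <- if (tot > 0) vc[1] / tot else 0
    res$converged[i] <- fit$converged
  }
  res$y_i <- sqrt(res$p_hat)
  structure(res, class = c("segment_scan", "data.frame"),
            denominator = denominator, n = length(y))
}

#' @export
print.segment_scan <- function(x, ...) {
  ok <- !is.na(x$p_hat)
  cat(sprintf("Segment variance scan: %d segments (%d converged), %d records\n",
              nrow(x), sum(x$converged), attr(x, "n")))
  cat(sprintf("  proportions (of %s variance): sum %.3f, max %.3f, %.0f%% at the zero boundary\n",
              attr(x, "denominator"), sum(x$p_hat[ok]), max(x$p_hat[ok]),
              100 * mean(x$p_hat[ok] == 0)))
  invisible(x)
}

#' Sampling standard deviation of segment estimates from permutations
#'
#' Destroys the genotype-phenotype link by permuting phenotypes, re-runs the
#' segment scan, and pools the permuted estimates across segments and
#' permutations.  Under the null the reported proportions are a 50:50 mixture
#' of exact zeros and the positive half of a normal squared, so the sampling
#' standard deviation of the square-root-scale error is
#' `sigma = sqrt(2 * mean(permuted proportions))`.
#'
#' @param y named phenotypes.
#' @param pop the population.
#' @param segments a [partition_segments()] table.
#' @param n_perm number of permutations (the published protocol used 1000; a
#'   much smaller number already pins the pooled mean well).
#' @param seed integer seed.
#' @param ... passed to [segment_variance_scan()].
#' @return list of class `null_sigma` with `sigma`, `n_perm`,
#'   `mean_null_proportion` and the pooled permuted estimates.
#' @export
permutation_sigma <- function(y, pop, segments, n_perm = 100, seed = 1, ...) {
  if (n_perm < 1) stop("n_perm must be positive")
  set.seed(seed)
  pooled <- numeric(0)
  for (b in seq_len(n_perm)) {
    yp <- setNames(sample(y), names(y))
    sc <- segment_variance_scan(yp, pop, segments, ...)
    pooled <- c(pooled, sc$p_hat[!is.na(sc$p_hat)])
  }
  if (!length(pooled)) stop("no finite permuted estimates")
  structure(list(sigma = sigma_from_null(pooled), n_perm = n_perm,
                 mean_null_proportion = mean(pooled), pooled = pooled),
            class = "null_sigma")
}

#' @export
print.null_sigma <- function(x, ...) {
  cat(sprintf("Permutation null: sigma = %.4f from %d permutations (mean null proportion %.5f, %d estimates)\n",
              x$sigma, x$n_perm, x$mean_null_proportion, length(x$pooled)))
  invisible(x)
}

#' @describeIn permutation_sigma the estimator itself:
#'   `sqrt(2 * mean(p_hat_null))`, the factor 2 accounting for negative
#'   estimates being reported as zero.
#' @param p_hat_null pooled null estimates of the variance proportion.
#' @export
sigma_from_null <- function(p_hat_null) {
  p_hat_null <- p_hat_null[!is.na(p_hat_null)]
  if (!length(p_hat_null)) stop("no finite null estimates")
  sqrt(2 * mean(p_hat_null))
}

#' EM deconvolution of the true segment-effect distribution
#'
#' Models each observed square-root proportion as `y_i = t_i + e_i`, with
#' `t_i` the true correlation between segment and phenotype and
#' `e_i ~ N(0, sigma)` sampling error; a segment whose `t + e` falls below
#' zero is reported as exactly zero.  The distribution of `t` is
#' approximated on a discrete grid (step `grid_step`, including 0) and the
#' class frequencies `f_j` are estimated by EM:
#' the probability of observing `y_i > 0` under class `t_j` is
#' `dnorm(y_i - t_j, 0, sigma)` and of observing `y_i = 0` is
#' `pnorm(0, t_j, sigma)`; responsibilities are normalised per segment and
#' frequencies updated to their mean until `max |delta f| < tol`.
#' The frequencies sum to 1 after every iteration and the incomplete-data
#' log-likelihood is non-decreasing.
#'
#' @param y_values observed `y_i = sqrt(p_hat_i)`, all `>= 0`.
#' @param sigma sampling standard deviation (from [permutation_sigma()]).
#'   `sigma = 0` degenerates to snapping the empirical distribution to the
#'   grid.
#' @param grid_step grid resolution on the `t` scale.
#' @param tol convergence tolerance on `max |delta f|`.
#' @param max_iter iteration cap.
#' @return an object of class `effect_distribution` with `grid`, `freq`,
#'   `sigma`, `n_iter` and the log-likelihood `trace`.
#' @export
em_effect_distribution <- function(y_values, sigma, grid_step = 0.01,
                                   tol = 1e-8, max_iter = 10000L) {
  if (any(y_values < 0) || anyNA(y_values)) stop("y_values must be >= 0")
  grid <- seq(0, 1, by = grid_step)
  K <- length(grid)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) {
    snapped <- grid[pmin(K, pmax(1, round(y_values / grid_step) + 1))]
    f <- as.numeric(table(factor(snapped, levels = grid))) / length(y_values)
    return(structure(list(grid = grid, freq = f, sigma = 0, n_iter = 0L,
                          trace = numeric(0)), class = "effect_distribution"))
  }
  L <- matrix(0, length(y_values), K)
  zero <- y_values == 0
  for (j in seq_len(K)) {
    L[!zero, j] <- dnorm(y_values[!zero] - grid[j], 0, sigma)
    L[zero, j] <- pnorm(0, grid[j], sigma)
  }
  f <- rep(1 / K, K)
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mix <- drop(L %*% f)
    trace <- c(trace, sum(log(pmax(mix, 1e-300))))
    resp <- t(t(L) * f) / pmax(mix, 1e-300)
    fnew <- colMeans(resp)
    fnew <- fnew / sum(fnew)
    if (max(abs(fnew - f)) < tol || iter >= max_iter) { f <- fnew; break }
    f <- fnew
  }
  structure(list(grid = grid, freq = f, sigma = sigma, n_iter = iter,
                 trace = trace), class = "effect_distribution")
}

#' @export
print.effect_distribution <- function(x, ...) {
  cat(sprintf("Deconvolved segment-effect distribution: %d grid classes, sigma = %.4f, %d EM iterations\n",
              length(x$grid), x$sigma, x$n_iter))
  cat(sprintf("  mass at t = 0: %.3f; mean t^2: %.5f\n", x$freq[1],
              sum(x$freq * x$grid^2)))
  invisible(x)
}

#' @export
plot.effect_distribution <- function(x, ...) {
  plot(x$grid^2, x$freq, type = "h", log = "", xlab = "proportion of variance (t^2)",
       ylab = "frequency of segments", ...)
  invisible(x)
}

#' Bin a deconvolved distribution on the variance (t squared) scale
#'
#' Frequencies of all grid values of `t` falling inside each
#' square-root-transformed bin are summed: the bin `(l, u]` on the `t^2`
#' scale collects classes with `sqrt(l) < t <= sqrt(u)` (the first bin is
#' closed on the left so the point mass at 0 is kept).  Total mass is
#' conserved.
#'
#' @param dist an [em_effect_distribution()] result.
#' @param edges ascending bin edges on the `t^2` scale, spanning \[0, 1\].
#' @return data frame with `lower`, `upper` (t^2 scale) and `mass`.
#' @export
bin_t_squared <- function(dist, edges) {
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be strictly ascending")
  if (edges[1] > 0) edges <- c(0, edges)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  t2 <- dist$grid^2
  bin <- cut(t2, breaks = edges, include.lowest = TRUE, right = TRUE)
  mass <- as.numeric(tapply(dist$freq, bin, sum, default = 0))
  data.frame(lower = edges[-length(edges)], upper = edges[-1], mass = mass)
}

#' Cumulative variance explained by ranked segments
#'
#' Ranks segments from the largest estimated variance proportion to the
#' smallest and accumulates the total.  To avoid double counting a mutation
#' whose variance leaks into flanking windows through linkage, the
#' proportions of segments within `exclusion_radius` segments of a selected
#' segment (same chromosome) are set to zero before they can be selected.
#'
#' @param scan a [segment_variance_scan()] result, or any data frame with
#'   `segment`, `chrom` and `p_hat`.
#' @param exclusion_radius neighbour radius in segments (0 disables masking;
#'   default 1 masks immediately adjacent segments).
#' @return data frame with `rank`, `segment`, `p_hat`, `cumulative` and
#'   `cumulative_prop` (of the summed unmasked total); the curve is
#'   non-decreasing.
#' @export
cumulative_variance_curve <- function(scan, exclusion_radius = 1) {
  p <- scan$p_hat
  keep <- !is.na(p)
  p <- p[keep]
  seg <- scan$segment[keep]
  chrom <- scan$chrom[keep]
  if (!length(p))
    return(data.frame(rank = integer(0), segment = integer(0),
                      p_hat = numeric(0), cumulative = numeric(0),
                      cumulative_prop = numeric(0)))
  avail <- rep(TRUE, length(p))
  work <- p
  ranks <- segments <- integer(0)
  vals <- numeric(0)
  while (any(avail)) {
    i <- which(avail)[which.max(work[avail])]
    ranks <- c(ranks, length(ranks) + 1L)
    segments <- c(segments, seg[i])
    vals <- c(vals, work[i])
    avail[i] <- FALSE
    if (exclusion_radius > 0) {
      nb <- which(chrom == chrom[i] & abs(seg - seg[i]) <= exclusion_radius)
      work[nb[nb != i & avail[nb]]] <- 0
    }
  }
  cum <- cumsum(vals)
  data.frame(rank = ranks, segment = segments, p_hat = vals,
             cumulative = cum,
             cumulative_prop = if (cum[length(cum)] > 0) cum / cum[length(cum)] else cum)
}
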