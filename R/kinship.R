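#' Allele frequencies from dosages
#'
#' Frequency of the counted ("2") allele: `p_j = sum(dosage_j) / (2 n)`.
#' Frequencies are typically computed on the discovery individuals only and
#' reused when centring validation genotypes, so that no validation
#' information leaks into the predictor.
#'
#' @param pop a population, or a dosage matrix.
#' @param individuals optional subset (indices or row names).
#' @return numeric vector of per-SNP frequencies in \[0, 1\].
#' @export
allele_frequencies <- function(pop, individuals = NULL) {
  g <- if (inherits(pop, "population")) pop$genotypes else pop
  if (!is.null(individuals)) g <- g[individuals, , drop = FALSE]
  if (nrow(g) == 0) stop("empty individual subset")
  colMeans(g, na.rm = TRUE) / 2
}

#' Centred marker matrix W
#'
#' `w_ij = dosage_ij - 2 p_j`, i.e. 0/1/2 become `-2p`, `1-2p`, `2-2p`.
#' The scaling constant `sum_j 2 p_j (1 - p_j)` -- the expected sum of column
#' variances under Hardy-Weinberg -- is attached for use by [build_grm()].
#' Monomorphic SNPs (p of 0 or 1) contribute zero columns and a warning.
#'
#' @param pop a population or dosage matrix.
#' @param freqs per-SNP frequencies of the counted allele; defaults to
#'   frequencies computed from `pop` itself.
#' @return an object of class `w_matrix`: list with `values` (n x m), `freqs`
#'   and `scale`.
#' @export
build_w <- function(pop, freqs = allele_frequencies(pop)) {
  g <- if (inherits(pop, "population")) pop$genotypes else pop
  if (length(freqs) != ncol(g)) stop("freqs not aligned to the SNP panel")
  mono <- freqs <= 0 | freqs >= 1
  if (all(mono)) stop("all SNPs monomorphic: W has no information")
  if (any(mono)) warning(sum(mono), " monomorphic SNP(s) contribute nothing to the scale")
  w <- sweep(g, 2L, 2 * freqs, "-")
  structure(list(values = w, freqs = freqs,
                 scale = sum(2 * freqs * (1 - freqs))),
            class = "w_matrix")
}

#' Genomic relationship matrix
#'
#' `G = W W' / sum_j 2 p_j (1 - p_j)`.  With frequencies estimated in the
#' same (unrelated, Hardy-Weinberg) individuals the mean diagonal is close
#' to 1.
#'
#' @param w a [build_w()] result, or a population (then W is built first).
#' @param freqs frequencies forwarded to [build_w()] when `w` is a population.
#' @return an object of class `grm`: the symmetric n x n matrix with the SNP
#'   ids used stored in attribute `"snp_ids"`.
#' @export
build_grm <- function(w, freqs = NULL) {
  if (!inherits(w, "w_matrix"))
    w <- if (is.null(freqs)) build_w(w) else build_w(w, freqs)
  if (w$scale <= 0) stop("zero scale: no polymorphic SNPs")
  G <- tcrossprod(w$values) / w$scale
  attr(G, "snp_ids") <- colnames(w$values)
  class(G) <- c("grm", class(G))
  G
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("GRM: %d x %d, mean diagonal %.3f (built from %d SNPs)\n",
              nrow(x), ncol(x), mean(diag(x)),
              length(attr(x, "snp_ids"))))
  invisible(x)
}

#' Segment and rest-of-genome GRM pair
#'
#' For a window of SNPs, builds `G1` from the window SNPs only and `G2` from
#' every other SNP.  The two SNP sets are disjoint and their union is the full
#' panel; both matrices use frequencies estimated on the same individuals.
#'
#' @param pop a population (ideally QC-filtered).
#' @param segment integer vector of SNP column indices forming the segment.
#' @param freqs optional frequencies for centring (defaults to all
#'   individuals in `pop`).
#' @return list with elements `G1`, `G2` and `segment`.
#' @export
grm_pair <- function(pop, segment, freqs = allele_frequencies(pop)) {
  m <- ncol(pop$genotypes)
  segment <- as.integer(segment)
  if (any(segment < 1 | segment > m)) stop("segment outside the SNP map")
  if (anyDuplicated(segment)) stop("duplicated SNP indices in segment")
  rest <- setdiff(seq_len(m), segment)
  if (length(rest) < 2) stop("fewer than 2 SNPs outside the segment")
  g <- pop$genotypes
  G1 <- build_grm(g[, segment, drop = FALSE], freqs[segment])
  G2 <- build_grm(g[, rest, drop = FALSE], freqs[rest])
  list(G1 = G1, G2 = G2, segment = segment)
}

#' Write / read a GRM as GCTA-style lower-triangle text
#'
#' `write_grm` writes `<prefix>.grm.txt` (columns: row index, column index,
#' number of SNPs, relationship) and `<prefix>.grm.id`; `read_grm` reads the
#' pair back into a symmetric matrix.
#'
#' @param G a GRM with row names as individual ids.
#' @param prefix file path prefix.
#' @return `write_grm` the prefix, invisibly; `read_grm` a `grm` matrix.
#' @export
write_grm <- function(G, prefix) {
  n <- nrow(G)
  idx <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  nsnp <- length(attr(G, "snp_ids"))
  df <- data.frame(i = idx[, 1], j = idx[, 2], n = nsnp, g = G[idx])
  write.table(df, paste0(prefix, ".grm.txt"), row.names = FALSE,
              col.names = FALSE, quote = FALSE, sep = "\t")
  ids <- rownames(G)
  if (is.null(ids)) ids <- sprintf("id%04d", seq_len(n))
  write.table(data.frame(fid = ids, iid = ids), paste0(prefix, ".grm.id"),
              row.names = FALSE, col.names = FALSE, quote = FALSE, sep = "\t")
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  df <- read.table(paste0(prefix, ".grm.txt"))
  ids <- read.table(paste0(prefix, ".grm.id"))[[2]]
  n <- max(df[[1]])
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  G[cbind(df[[1]], df[[2]])] <- df[[4]]
  G[cbind(df[[2]], df[[1]])] <- df[[4]]
  class(G) <- c("grm", class(G))
  G
}
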