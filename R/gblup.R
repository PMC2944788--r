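#' Genomic BLUP
#'
#' Best linear unbiased prediction of breeding values with a genomic
#' relationship matrix in place of the pedigree relationship matrix.  The
#' variance components are estimated by [greml()] on the training records
#' (or supplied), the overall mean by generalised least squares, and the
#' breeding values of every individual in `G` -- phenotyped or not -- by
#' `g_hat = s2_g G[, train] V^-1 (y - mu)` with
#' `V = s2_g G[train, train] + s2_e I`.  Validation individuals are thus
#' predicted through their genomic relationships without their phenotypes.
#'
#' @param y named numeric vector of training phenotypes; names must appear in
#'   `rownames(G)`.
#' @param G genomic relationship matrix over all individuals to predict.
#' @param vc optional [greml()] fit (one kernel); estimated if missing.
#' @return an object of class `gblup` with `gebv` (all individuals), `mu`,
#'   `vc` and `train` ids.
#' @seealso [realized_accuracy()], [bayesa()]
#' @export
gblup <- function(y, G, vc = NULL) {
  if (is.null(names(y)) || is.null(rownames(G)))
    stop("y and G must carry individual ids")
  ti <- match(names(y), rownames(G))
  if (anyNA(ti)) stop("training ids missing from G")
  Gtt <- unclass(G)[ti, ti]
  if (is.null(vc)) vc <- greml(y, Gtt)
  s2g <- vc$varcomp[1]; s2e <- vc$varcomp["residual"]
  n <- length(y)
  V <- s2g * Gtt + diag(s2e + 1e-10, n)
  cV <- chol(V)
  solveV <- function(b) backsolve(cV, forwardsolve(t(cV), b))
  one <- rep(1, n)
  Vi1 <- solveV(one)
  mu <- sum(Vi1 * y) / sum(Vi1 * one)
  r <- solveV(y - mu)
  gebv <- drop(s2g * unclass(G)[, ti] %*% r)
  names(gebv) <- rownames(G)
  structure(list(gebv = gebv, mu = mu, vc = vc, train = names(y),
                 method = "blup"), class = "gblup")
}

#' @export
print.gblup <- function(x, ...) {
  cat(sprintf("GBLUP fit: %d training records, %d individuals predicted\n",
              length(x$train), length(x$gebv)))
  cat(sprintf("  variance proportions: genetic %.3f, residual %.3f; mu = %.4f\n",
              x$vc$proportions[1], x$vc$proportions["residual"], x$mu))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$gebv

#' @export
predict.gblup <- function(object, ids = NULL, ...) {
  if (is.null(ids)) object$gebv else object$gebv[ids]
}

#' SNP-BLUP (ridge regression) genomic prediction
#'
#' The marker-effect formulation equivalent to GBLUP: solves the mixed-model
#' equations for an intercept plus all SNP effects with common shrinkage
#' `lambda = s2_e / s2_u`, where the per-SNP variance is
#' `s2_u = s2_g / sum_j 2 p_j (1 - p_j)`.  GEBV are `W u_hat`.
#'
#' @param y named training phenotypes.
#' @param w a [build_w()] result covering all individuals to predict.
#' @param vc a [greml()] fit providing `s2_g` and `s2_e` on the GRM scale.
#' @return an object of class `gblup` (method `"snp_blup"`) with an extra
#'   element `u_hat` of per-SNP effects.
#' @export
snp_blup <- function(y, w, vc) {
  W <- w$values
  ti <- match(names(y), rownames(W))
  if (anyNA(ti)) stop("training ids missing from W")
  Wt <- W[ti, , drop = FALSE]
  m <- ncol(Wt)
  s2u <- vc$varcomp[1] / w$scale
  lambda <- vc$varcomp["residual"] / s2u
  C <- rbind(cbind(length(y), t(colSums(Wt))),
             cbind(colSums(Wt), crossprod(Wt) + diag(lambda, m)))
  rhs <- c(sum(y), crossprod(Wt, y))
  sol <- solve(C, rhs)
  u <- sol[-1]
  gebv <- drop(W %*% u)
  names(gebv) <- rownames(W)
  structure(list(gebv = gebv, mu = sol[1], u_hat = u, vc = vc,
                 train = names(y), method = "snp_blup"), class = "gblup")
}

#' Realised accuracy of genomic breeding values
#'
#' `r(GEBV, y_val) / h`: the Pearson correlation between predictions and
#' validation phenotypes, divided by the correlation `h` between a phenotype
#' and the true breeding value (the square root of the record heritability).
#' In small samples the ratio can exceed 1.
#'
#' @param gebv predictions: a named vector or a fitted `gblup`/`bayesa`
#'   object.
#' @param y_val named validation phenotypes (not used in training).
#' @param h correlation between record and true breeding value, in (0, 1].
#' @return the realised accuracy (a scalar).
#' @export
realized_accuracy <- function(gebv, y_val, h) {
  if (!is.numeric(gebv)) gebv <- coef(gebv)
  if (h <= 0 || h > 1) stop("h must be in (0, 1]")
  if (length(y_val) < 3) stop("need at least 3 validation individuals")
  g <- gebv[names(y_val)]
  if (anyNA(g)) stop("validation ids missing from predictions")
  if (sd(g) == 0 || sd(y_val) == 0) stop("zero variance in predictions or phenotypes")
  unname(cor(g, y_val) / h)
}
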