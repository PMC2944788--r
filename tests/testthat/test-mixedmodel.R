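# independent dense REML log-likelihood used as an oracle
.reml_ll <- function(y, G, s2g, s2e) {
  n <- length(y)
  V <- s2g * G + diag(s2e, n)
  cV <- chol(V)
  Vi <- chol2inv(cV)
  X <- matrix(1, n, 1)
  XtViX <- crossprod(X, Vi %*% X)
  Py <- Vi %*% y - Vi %*% X %*% solve(XtViX, crossprod(X, Vi %*% y))
  drop(-0.5 * (2 * sum(log(diag(cV))) + log(XtViX) + crossprod(y, Py)))
}

test_that("greml matches a two-dimensional likelihood grid search at n = 20", {
  set.seed(11)
  n <- 20
  W <- matrix(rnorm(n * 40), n)
  G <- tcrossprod(W) / 40
  y <- drop(chol(G + diag(1e-8, n)) %*% rnorm(n)) * 0.8 + rnorm(n)
  fit <- greml(y, G)
  # the reported log-likelihood agrees with an independent implementation
  expect_equal(fit$loglik,
               .reml_ll(y, G, fit$varcomp[1], fit$varcomp[2]),
               tolerance = 1e-6)
  # no point of a fine grid beats the REML optimum
  grid <- expand.grid(s2g = seq(0.01, 3, length.out = 40),
                      s2e = seq(0.01, 3, length.out = 40))
  ll <- mapply(function(a, b) .reml_ll(y, G, a, b), grid$s2g, grid$s2e)
  expect_gte(fit$loglik, max(ll) - 1e-6)
})

test_that("pure-noise data drives the genetic variance to the zero boundary", {
  set.seed(12)
  G <- unclass(build_grm(tiny_pop))
  y <- rnorm(80)
  fit <- greml(y, G[1:80, 1:80])
  expect_lt(fit$proportions[1], 0.1)
  expect_true(fit$converged)
})

test_that("greml recovers known variance components", {
  set.seed(13)
  G <- unclass(build_grm(tiny_pop))
  n <- nrow(G)
  L <- chol(G + diag(1e-8, n))
  props <- numeric(10)
  for (r in 1:10) {
    y <- drop(crossprod(L, rnorm(n))) + rnorm(n)  # h2 = 0.5 on average
    props[r] <- greml(y, G)$proportions[1]
  }
  expect_equal(mean(props), 0.5, tolerance = 0.1)
})

test_that("the EM trace is monotone and scaling y rescales the components", {
  set.seed(14)
  G <- unclass(build_grm(tiny_pop))[1:100, 1:100]
  y <- drop(chol(G + diag(1e-8, 100)) %*% rnorm(100)) + rnorm(100)
  fit <- greml(y, G)
  expect_true(all(diff(fit$trace) > -1e-6))
  fit10 <- greml(10 * y, G)
  expect_equal(fit10$varcomp, 100 * fit$varcomp, tolerance = 1e-3)
  expect_equal(fit10$proportions, fit$proportions, tolerance = 1e-5)
})

test_that("the dense multi-kernel path recovers both components", {
  set.seed(15)
  n <- 150
  W1 <- matrix(rnorm(n * 60), n); W2 <- matrix(rnorm(n * 60), n)
  G1 <- tcrossprod(W1) / 60; G2 <- tcrossprod(W2) / 60
  y <- drop(crossprod(chol(G1 + diag(1e-8, n)), rnorm(n))) * sqrt(2) +
    drop(crossprod(chol(G2 + diag(1e-8, n)), rnorm(n))) + rnorm(n)
  fit <- greml(y, list(G1, G2))
  expect_true(all(diff(fit$trace) > -1e-6))
  expect_named(fit$varcomp, c("g1", "g2", "residual"))
  expect_equal(unname(fit$varcomp), c(2, 1, 1), tolerance = 0.9)
  expect_gt(fit$varcomp[1], fit$varcomp[2])
})

test_that("greml validates its inputs", {
  expect_error(greml(rnorm(10), diag(5)), "dimension")
  expect_error(greml(rep(1, 10), diag(10)), "zero variance")
  expect_error(greml(rnorm(10), diag(10), init = c(1, 1, 1)), "init")
})

test_that("GBLUP equals SNP-ridge on a 200 x 500 panel to 1e-6", {
  set.seed(16)
  n <- 200; m <- 500
  g <- matrix(rbinom(n * m, 2, rep(runif(m, 0.1, 0.9), each = n)), n, m)
  rownames(g) <- sprintf("i%03d", seq_len(n))
  colnames(g) <- sprintf("s%03d", seq_len(m))
  train <- rownames(g)[1:150]
  freqs <- allele_frequencies(g, train)
  w <- build_w(g, freqs)
  G <- build_grm(w)
  beta <- rnorm(m, 0, 0.05)
  y <- setNames(drop(g %*% beta) + rnorm(n), rownames(g))[train]
  fit_g <- gblup(y, G)
  fit_s <- snp_blup(y, w, fit_g$vc)
  expect_lt(max(abs(fit_g$gebv - fit_s$gebv[names(fit_g$gebv)])), 1e-6)
  expect_equal(unname(fit_g$mu), unname(fit_s$mu), tolerance = 1e-6)
})

test_that("GBLUP predicts every individual and shrinks toward the mean", {
  set.seed(17)
  arch <- trait_architecture(tiny_pop, "fat_like", seed = 18)
  tr <- sim_trait(tiny_pop, arch, h2 = 0.83, seed = 18)
  y <- tr$phenotype[tr$split == "discovery"]
  G <- build_grm(build_w(tiny_pop, allele_frequencies(tiny_pop, names(y))))
  fit <- gblup(y, G)
  expect_named(fit$gebv, rownames(tiny_pop$genotypes), ignore.order = TRUE)
  expect_lt(var(fit$gebv[names(y)]), var(y))
  expect_gt(cor(fit$gebv[names(y)], y), 0.3)
  expect_equal(coef(fit), fit$gebv)
  expect_equal(predict(fit, names(y)[1:5]), fit$gebv[names(y)[1:5]])
})

test_that("realised accuracy is the validation correlation over h", {
  set.seed(19)
  gebv <- setNames(rnorm(50), sprintf("v%02d", 1:50))
  yv <- setNames(gebv + rnorm(50), names(gebv))
  expect_equal(realized_accuracy(gebv, yv, 1), cor(gebv, yv))
  expect_equal(realized_accuracy(gebv, yv, 0.5), cor(gebv, yv) / 0.5)
  expect_error(realized_accuracy(gebv, yv, 0), "h must")
  expect_error(realized_accuracy(gebv[1:10], yv, 1), "missing")
  # a predictor independent of the validation set scores near zero
  accs <- replicate(30, {
    yv2 <- setNames(rnorm(400), sprintf("n%03d", 1:400))
    gb2 <- setNames(rnorm(400), names(yv2))
    realized_accuracy(gb2, yv2, 1)
  })
  expect_gt(mean(abs(accs) < 0.15), 0.9)
})
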