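test_that("autoscaling centres, scales and round-trips", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 10, 10), c = c(0, 4, 5))
  sc <- autoscale(X)
  expect_equal(sc$dropped, "b")
  expect_true(all(abs(colMeans(sc$scaled)) < 1e-10))
  expect_equal(unname(apply(sc$scaled, 2, sd)), c(1, 1))
  set.seed(21)
  Y <- matrix(rnorm(40, 5, 3), 10, 4, dimnames = list(NULL, letters[1:4]))
  scy <- autoscale(Y)
  back <- sweep(sweep(scy$scaled, 2, scy$sds, "*"), 2, scy$means, "+")
  expect_equal(back, Y, tolerance = 1e-12)
  expect_error(autoscale(matrix(1, 3, 2)), "constant")
  expect_error(autoscale(X[1, , drop = FALSE]), "two rows")
})

test_that("PCA matches the singular value decomposition", {
  set.seed(22)
  X <- matrix(rnorm(24), 8, 3)
  sc <- autoscale(X)
  p <- pca_profiles(sc$scaled, 3)
  sv <- svd(sc$scaled)
  expect_equal(abs(p$loadings), abs(sv$v), tolerance = 1e-10)
  expect_equal(abs(p$scores), abs(sv$u %*% diag(sv$d)), tolerance = 1e-10)
  expect_equal(p$explained, sv$d^2 / sum(sv$d^2), tolerance = 1e-12)
  expect_true(all(diff(p$explained) <= 1e-12))
  # perfectly collinear data: first component carries all variance
  Z <- cbind(1:6, 2 * (1:6))
  pz <- suppressMessages(pca_profiles(autoscale(Z)$scaled, 2))
  expect_equal(pz$explained[1], 1.0, tolerance = 1e-12)
  expect_error(pca_profiles(sc$scaled, 5), "exceeds")
})

test_that("PLS1 agrees with closed-form regression oracles", {
  set.seed(23)
  # single predictor, one component == univariate least squares
  x <- matrix(rnorm(12), 12, 1); y <- rnorm(12)
  sc <- autoscale(x)
  f1 <- fit_pls1(sc$scaled, y - mean(y), 1)
  uni <- lm(y ~ x)
  expect_equal(mean(y) + drop(sc$scaled %*% f1$coefficients),
               unname(fitted(uni)), tolerance = 1e-10)
  # full rank == multiple regression
  X <- matrix(rnorm(50), 10, 5); y2 <- rnorm(10)
  sc2 <- autoscale(X)
  f5 <- fit_pls1(sc2$scaled, y2 - mean(y2), 5)
  expect_equal(mean(y2) + drop(sc2$scaled %*% f5$coefficients),
               unname(fitted(lm(y2 ~ X))), tolerance = 1e-8)
  # scores orthogonal, deflation shrinks X monotonically
  G <- crossprod(f5$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  Xd <- sc2$scaled; nrm <- norm(Xd, "F")
  for (a in 1:5) {
    t_ <- f5$scores[, a]
    Xd <- Xd - tcrossprod(t_, f5$x_loadings[, a])
    expect_lte(norm(Xd, "F"), nrm + 1e-12)
    nrm <- norm(Xd, "F")
  }
  # response (almost) orthogonal to all columns gives near-zero coefficients
  Xo_s <- scale(matrix(rnorm(40), 10, 4))
  yo <- residuals(lm(rnorm(10) ~ Xo_s)) + 1e-9 * rnorm(10)
  fo <- fit_pls1(Xo_s, yo - mean(yo), 1)
  expect_lt(max(abs(fo$coefficients)), 1e-6)
  expect_error(fit_pls1(sc2$scaled, rep(0, 10), 2), "zero variance")
})

test_that("predictions are invariant under affine rescaling of inputs", {
  set.seed(24)
  X <- matrix(rexp(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * X[, 1] - X[, 2] + rnorm(20, 0, 0.1)
  sc <- autoscale(X)
  f <- fit_pls1(sc$scaled, y - mean(y), 2)
  pred <- mean(y) + drop(sc$scaled %*% f$coefficients)
  X2 <- sweep(sweep(X, 2, c(3, 0.5, 10), "*"), 2, c(1, -2, 5), "+")
  sc2 <- autoscale(X2)
  f2 <- fit_pls1(sc2$scaled, y - mean(y), 2)
  pred2 <- mean(y) + drop(sc2$scaled %*% f2$coefficients)
  expect_equal(pred, pred2, tolerance = 1e-8)
})

test_that("leave-one-out cross-validation matches an independent oracle", {
  set.seed(25)
  n <- 20
  X <- matrix(rnorm(n * 5), n, 5)
  y <- X[, 1] + 0.5 * X[, 2] - X[, 3] + rnorm(n, 0, 0.3)
  cv <- cross_validate(X, y, 3)
  # oracle: explicit LOO loop around the standalone NIPALS in the helpers
  for (a in 1:3) {
    press <- vapply(seq_len(n), function(i)
      (y[i] - oracle_pls1_predict(X[-i, ], y[-i], X[i, , drop = FALSE], a))^2,
      numeric(1))
    expect_equal(cv$rmsecv[a], sqrt(mean(press)), tolerance = 1e-10)
  }
  # noiseless full-rank response cross-validates to ~zero error
  yn <- drop(X %*% c(1, -2, 0.5, 0, 1))
  cvn <- cross_validate(X, yn, 5)
  expect_lt(min(cvn$rmsecv), 1e-8)
  # pure noise: parsimony rule falls back to one component
  yr <- rnorm(n)
  expect_equal(cross_validate(X, yr, 4)$suggested, 1L)
})

test_that("jackknife uncertainty separates stable from unstable coefficients", {
  b <- c(x = 1.5, y = 0, z = -2)
  Bsame <- matrix(rep(b, each = 10), 10, 3, dimnames = list(NULL, names(b)))
  u <- martens_uncertainty(b, Bsame)
  expect_equal(u$jackknife_sd, rep(0, 3))
  expect_equal(u$significant, c(TRUE, FALSE, TRUE))
  # jackknife variance grows monotonically with injected perturbation
  set.seed(26)
  noise <- matrix(rnorm(30), 10, 3)
  vars <- vapply(c(0.01, 0.1, 0.5, 2), function(s)
    martens_uncertainty(b, Bsame + s * noise)$jackknife_sd[1], numeric(1))
  expect_true(all(diff(vars) > 0))
  expect_error(martens_uncertainty(b, Bsame[1:2, ]), "three submodels")
})

test_that("variable reduction keeps informative markers, drops noise", {
  set.seed(27)
  n <- 60
  informative <- matrix(rnorm(n * 3), n, 3,
                        dimnames = list(NULL, c("m1", "m2", "m3")))
  y <- drop(informative %*% c(3, -2, 1.5)) + rnorm(n, 0, 0.2)
  noise <- matrix(rnorm(n * 4), n, 4,
                  dimnames = list(NULL, paste0("n", 1:4)))
  rv <- reduce_variables(cbind(informative, noise), y)
  expect_setequal(rv$survivors$variable, c("m1", "m2", "m3"))
  # a single perfectly predictive variable survives with the right sign
  x1 <- rnorm(n)
  rv2 <- reduce_variables(cbind(good = x1, junk = rnorm(n)), -4 * x1)
  expect_true("good" %in% rv2$survivors$variable)
  expect_lt(rv2$survivors$coefficient[rv2$survivors$variable == "good"], 0)
  # all-noise candidates leave no survivors
  expect_error(reduce_variables(matrix(rnorm(n * 3), n, 3), rnorm(n)),
               "no variable passed")
})

test_that("species fixture singles out the published marker methoxyflavones", {
  # pure-juice PLS-DA layout: 65 orange + 40 mandarin samples over the
  # seven prescreened methoxyflavones, heterogeneous cultivar dispersion
  tmpl <- fx_templates()
  mfs <- c("isosinensetin", "sinensetin", "tetramethyl-O-isoscutellarein",
           "nobiletin", "tetramethyl-O-scutellarein", "tangeretin",
           "5-demethylnobiletin")
  o <- sample_profiles(tmpl$orange,
                       sim_config(seed = 301, n_cultivars = 65, cv = 0.25))
  m <- sample_profiles(tmpl$mandarin,
                       sim_config(seed = 302, n_cultivars = 40, cv = 0.25))
  X <- rbind(o$values[, mfs], m$values[, mfs])
  y <- c(rep(100, 65), rep(0, 40))
  rv <- reduce_variables(X, y)
  top3 <- rv$survivors$variable[1:3]
  expect_setequal(top3, c("isosinensetin", "sinensetin", "tangeretin"))
  # marker directions: mandarin markers negative, orange marker positive
  cf <- stats::setNames(rv$uncertainty$coefficient, rv$uncertainty$variable)
  expect_lt(cf[["isosinensetin"]], 0)
  expect_lt(cf[["tangeretin"]], 0)
  expect_gt(cf[["sinensetin"]], 0)
  # a pure-noise variable appended to the block is rejected
  set.seed(303)
  rvn <- reduce_variables(cbind(X, noise = rnorm(nrow(X))), y)
  expect_false("noise" %in% rvn$survivors$variable)
})
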