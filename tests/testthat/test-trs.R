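mk_classes <- function(n = 25, d = 4, sep = 3, seed = 1) {
  set.seed(seed)
  x1 <- matrix(rnorm(n * d), n, d)
  x2 <- matrix(rnorm(n * d, sep), n, d)
  x <- rbind(x1, x2)
  colnames(x) <- paste0("p", seq_len(d))
  list(x = x, group = rep(c("control", "dyslexic"), each = n))
}

test_that("normalisation standardises the training set and applies to held-out vectors", {
  d <- mk_classes()
  nr <- normalize_params(d$x)
  expect_equal(unname(colMeans(nr$x)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(nr$x, 2, sd)), rep(1, 4), tolerance = 1e-9)
  v <- matrix(colMeans(d$x), 1)
  expect_equal(unname(normalize_params(v, nr)$x), matrix(0, 1, 4),
               tolerance = 1e-9)
  held <- matrix(c(1, 2, 3, 4), 1)
  expect_equal(unname(normalize_params(held, nr)$x[1, ]),
               (c(1, 2, 3, 4) - nr$center) / nr$scale, tolerance = 1e-12,
               ignore_attr = TRUE)
  bad <- cbind(d$x, const = 1)
  expect_error(normalize_params(bad), "SD")
})

test_that("fitting recovers separated class means; shrinkage 1 gives diagonal covariance", {
  d <- mk_classes(n = 200, sep = 3, seed = 2)
  fit <- trs(d$x, d$group)
  cm <- coef(fit)
  # class means on the raw scale reconstruct the empirical group means
  expect_equal(cm["control", ], colMeans(d$x[1:200, ]), tolerance = 1e-9)
  expect_equal(cm["dyslexic", ], colMeans(d$x[201:400, ]), tolerance = 1e-9)
  # and sit near the generating truth within sampling error
  expect_lt(max(abs(cm["control", ] - 0)), 4 / sqrt(200))
  expect_lt(max(abs(cm["dyslexic", ] - 3)), 4 / sqrt(200))

  fit_diag <- trs(d$x, d$group, shrinkage = 1)
  off <- fit_diag$control$cov - diag(diag(fit_diag$control$cov))
  expect_lt(max(abs(off)), 1e-9)

  expect_identical(trs(d$x, d$group)$control$mean,
                   trs(d$x, d$group)$control$mean)
})

test_that("scores are posterior probabilities: symmetric at the midpoint, complementary under label swap", {
  set.seed(3)
  x1 <- matrix(rnorm(40 * 3), 40, 3)
  shift <- c(4, -2, 1)
  x2 <- sweep(x1, 2, shift, "+")  # identical sample covariance by construction
  x <- rbind(x1, x2); colnames(x) <- c("a", "b", "c")
  g <- rep(c("control", "dyslexic"), each = 40)
  fit <- trs(x, g)
  mid <- matrix((colMeans(x1) + colMeans(x2)) / 2, 1,
                dimnames = list(NULL, colnames(x)))
  expect_equal(trs_score(fit, mid), 0.5, tolerance = 1e-9)
  expect_gt(trs_score(fit, matrix(colMeans(x1), 1,
                                  dimnames = list(NULL, colnames(x)))), 0.5)

  swapped <- trs(x, ifelse(g == "control", "dyslexic", "control"))
  pts <- x[c(1, 20, 45, 80), ]
  expect_equal(trs_score(swapped, pts), 1 - trs_score(fit, pts),
               tolerance = 1e-9)
  s <- trs_score(fit, x)
  expect_true(all(s > 0 & s < 1))
})

test_that("scores match an independent log-density oracle and never produce NaN", {
  d <- mk_classes(seed = 4)
  fit <- trs(d$x, d$group)
  z <- sweep(sweep(d$x, 2, fit$center), 2, fit$scale, "/")
  ld <- function(zrow, cls) {
    S <- cls$cov
    -0.5 * (length(zrow) * log(2 * pi) + determinant(S)$modulus[1] +
              drop(t(zrow - cls$mean) %*% solve(S) %*% (zrow - cls$mean)))
  }
  for (i in c(1, 13, 30, 50)) {
    lc <- ld(z[i, ], fit$control) + log(0.5)
    l2 <- ld(z[i, ], fit$dyslexic) + log(0.5)
    oracle <- exp(lc) / (exp(lc) + exp(l2))
    expect_equal(unname(trs_score(fit, d$x[i, , drop = FALSE])), oracle,
                 tolerance = 1e-9)
  }
  # an extreme vector underflows both densities but still scores cleanly
  far <- matrix(1e4, 1, 4, dimnames = list(NULL, colnames(d$x)))
  s <- trs_score(fit, far)
  expect_false(is.nan(s))
  expect_true(s >= 0 && s <= 1)
})

test_that("priors shift the posterior as Bayes dictates", {
  d <- mk_classes(seed = 5)
  even <- trs(d$x, d$group)
  skew <- trs(d$x, d$group, priors = c(control = 0.9, dyslexic = 0.1))
  pts <- d$x[c(2, 48), ]
  expect_true(all(trs_score(skew, pts) >= trs_score(even, pts) - 1e-12))
})

test_that("leave-one-out validation equals a brute-force refit and is chance-level on null data", {
  d <- mk_classes(n = 12, d = 3, sep = 2.5, seed = 6)
  cv <- trs_loocv(d$x, d$group)
  for (i in c(1, 7, 20)) {
    fit_i <- trs(d$x[-i, ], d$group[-i])
    expect_equal(cv$scores$score[i],
                 unname(trs_score(fit_i, d$x[i, , drop = FALSE])),
                 tolerance = 1e-12)
  }
  expect_equal(cv$accuracy,
               mean(cv$scores$predicted == cv$scores$group))

  acc <- vapply(1:4, function(s) {
    dd <- mk_classes(n = 15, d = 3, sep = 0, seed = 100 + s)
    trs_loocv(dd$x, dd$group)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(acc) - 0.5), 0.25)
})

test_that("widening the class separation never hurts validated accuracy", {
  set.seed(7)
  base <- matrix(rnorm(30 * 3), 30, 3)
  noise <- matrix(rnorm(30 * 3), 30, 3)
  acc <- vapply(c(0.5, 2, 4), function(sep) {
    x <- rbind(base, noise + sep)
    colnames(x) <- c("a", "b", "c")
    trs_loocv(x, rep(c("control", "dyslexic"), each = 30))$accuracy
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
})

test_that("simulating from the fitted model and refitting recovers the class means", {
  d <- mk_classes(n = 40, d = 4, sep = 2, seed = 8)
  fit <- trs(d$x, d$group)
  sim <- simulate(fit, seed = 9,
                  n_per_class = c(control = 300, dyslexic = 300))
  refit <- trs(sim$x, sim$group)
  for (cls in c("control", "dyslexic")) {
    se <- apply(sim$x[sim$group == cls, ], 2, sd) / sqrt(300)
    expect_true(all(abs(coef(refit)[cls, ] - coef(fit)[cls, ]) < 2.5 * se))
  }
})

test_that("PCA projections order variance and match an SVD oracle up to sign", {
  # points on a line: all variance on the first component
  t <- seq(-2, 2, length.out = 30)
  line <- cbind(a = 3 * t + 0.5, b = -2 * t + 1) +
    matrix(rnorm(60, 0, 1e-8), 30)
  p <- pca_projection(line)
  expect_lt(p$sdev[2] / p$sdev[1], 1e-4)

  d <- mk_classes(seed = 10)
  pr <- pca_projection(d$x)
  expect_true(all(diff(pr$sdev) <= 1e-12))
  z <- scale(scale(d$x, scale = apply(d$x, 2, sd)), scale = FALSE)
  sv <- svd(scale(z, scale = FALSE))
  first <- sv$u[, 1] * sv$d[1]
  expect_true(max(abs(pr$pc_first - first)) < 1e-8 ||
                max(abs(pr$pc_first + first)) < 1e-8)
})
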