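test_that("independent columns give an identity-like inverse correlation", {
  set.seed(2)
  x <- matrix(rnorm(10000 * 5), ncol = 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  cs <- correlation_summary(x)
  off <- cs$K - diag(diag(cs$K))
  expect_true(all(abs(off) < 0.05))
  expect_true(all(abs(cs$K %*% cs$C - diag(5)) < 1e-8))
  expect_true(all(cs$R >= 0 & cs$R < 1))
  expect_equal(diag(cs$P), rep(1, 5), ignore_attr = TRUE)
  expect_equal(cs$P, t(cs$P))
})

test_that("degenerate ensembles are reported as singular", {
  set.seed(3)
  x <- matrix(rnorm(200 * 3), ncol = 3)
  expect_error(correlation_summary(cbind(x, x[, 3])), "singular")
  expect_error(correlation_summary(cbind(x, 1)), "singular")
  expect_error(correlation_summary(x[1:3, ]), "n > p")
})

test_that("one tight linear constraint creates one dominant stiff direction", {
  set.seed(7)
  n <- 8000
  x <- matrix(rnorm(n * 4), ncol = 4)
  x5 <- (x[, 1] + x[, 2] + x[, 3] + x[, 4]) / 2 + rnorm(n, 0, 0.05)
  ens <- cbind(x, x5)
  cs <- correlation_summary(ens)
  sp <- stiffness_spectrum(cs)
  expect_gt(sp$values[1] / sp$values[2], 20)
  # eigenvector aligned with the standardized constraint normal
  normal <- c(1, 1, 1, 1, -2)
  normal <- normal / sqrt(sum(normal^2))
  cosang <- abs(sum(sp$vectors[, 1] * normal))
  expect_gt(cosang, 0.95)
  # orthonormality
  expect_true(all(abs(crossprod(sp$vectors) - diag(5)) < 1e-8))
})

test_that("multiple correlation matches the regression oracle", {
  for (seed in c(11, 12, 13)) {
    x <- random_gaussian_ensemble(10000, 5, seed)
    cs <- correlation_summary(x)
    for (j in 1:5) {
      fit <- stats::lm(x[, j] ~ x[, -j])
      expect_equal(unname(cs$R[j]), sqrt(summary(fit)$r.squared),
                   tolerance = 0.01)
    }
  }
})

test_that("partial correlations match the residual-regression oracle", {
  for (seed in c(21, 22)) {
    x <- random_gaussian_ensemble(10000, 4, seed)
    cs <- correlation_summary(x)
    for (i in 1:3) for (j in (i + 1):4) {
      rest <- x[, -c(i, j), drop = FALSE]
      ri <- stats::resid(stats::lm(x[, i] ~ rest))
      rj <- stats::resid(stats::lm(x[, j] ~ rest))
      expect_equal(cs$P[i, j], stats::cor(ri, rj), tolerance = 0.01)
    }
  }
})

test_that("a mediated chain has zero partial but nonzero marginal correlation", {
  set.seed(5)
  n <- 10000
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n, 0, 0.6)
  z <- 0.8 * y + rnorm(n, 0, 0.6)
  cs <- correlation_summary(cbind(x = x, y = y, z = z))
  expect_gt(stats::cor(x, z), 0.3)
  expect_lt(abs(cs$P["x", "z"]), 0.05)
})

test_that("row permutation leaves the analysis invariant, column permutation is consistent", {
  x <- random_gaussian_ensemble(2000, 4, 31)
  cs <- correlation_summary(x)
  cs_perm <- correlation_summary(x[sample.int(nrow(x)), ])
  expect_identical(cs$eigenvalues, cs_perm$eigenvalues)
  expect_identical(cs$P, cs_perm$P)
  perm <- c(3, 1, 4, 2)
  cs_col <- correlation_summary(x[, perm])
  expect_equal(cs_col$P, cs$P[perm, perm], tolerance = 1e-12)
  expect_equal(unname(cs_col$R), unname(cs$R[perm]), tolerance = 1e-12)
  expect_equal(cs_col$eigenvalues, cs$eigenvalues, tolerance = 1e-9)
})

test_that("subsampling two halves of one ensemble keeps the stiff direction", {
  x <- random_gaussian_ensemble(20000, 5, 41)
  a <- correlation_summary(x[1:10000, ])
  b <- correlation_summary(x[10001:20000, ])
  cosang <- abs(sum(a$eigenvectors[, 1] * b$eigenvectors[, 1]))
  expect_gt(cosang, 0.9)
})

# two ensembles with a prescribed correlation on the (1,2) pair and
# independent remaining columns
pair_ensemble <- function(n, rho, seed) {
  set.seed(seed)
  z <- matrix(rnorm(n * 4), ncol = 4)
  x1 <- z[, 1]
  x2 <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  cbind(a = x1, b = x2, c = z[, 3], d = z[, 4])
}

test_that("pair-change classification finds flips and losses, not phantoms", {
  A <- correlation_summary(pair_ensemble(10000, 0.4, 1))
  B_flip <- correlation_summary(pair_ensemble(10000, -0.4, 2))
  B_lose <- correlation_summary(pair_ensemble(10000, 0.0, 3))
  B_gain <- correlation_summary(pair_ensemble(10000, 0.8, 4))

  expect_equal(nrow(classify_pair_changes(A, A)), 0)   # identical ensembles

  res_flip <- classify_pair_changes(A, B_flip)
  expect_equal(nrow(res_flip), 1)
  expect_equal(res_flip$class, "flip")
  expect_equal(sort(c(res_flip$name1, res_flip$name2)), c("a", "b"))
  expect_equal(res_flip$difference, res_flip$r_A - res_flip$r_B)

  res_lose <- classify_pair_changes(A, B_lose)
  expect_equal(nrow(res_lose), 1)
  expect_equal(res_lose$class, "lose")

  res_gain <- classify_pair_changes(A, B_gain)
  expect_equal(nrow(res_gain), 1)
  expect_equal(res_gain$class, "gain")

  expect_error(classify_pair_changes(A, correlation_summary(
    random_gaussian_ensemble(1000, 5, 9))), "dimensions")
})

test_that("analysis artifacts are written as CSV", {
  x <- random_gaussian_ensemble(2000, 4, 51)
  cs <- correlation_summary(x)
  dir <- tempfile()
  paths <- write_analysis_artifacts(cs, dir, prefix = "toy",
                                    pair_changes = classify_pair_changes(cs, cs))
  expect_true(all(file.exists(paths)))
  spec <- utils::read.csv(file.path(dir, "toy_spectrum.csv"))
  expect_equal(spec$eigenvalue, cs$eigenvalues)
})

test_that("ensemble subsampling is seeded and size-correct", {
  x <- random_gaussian_ensemble(500, 3, 61)
  s1 <- subsample_ensemble(x, 100, seed = 2)
  s2 <- subsample_ensemble(x, 100, seed = 2)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 100)
  expect_equal(nrow(subsample_ensemble(x, 800, seed = 2)), 800)
})
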