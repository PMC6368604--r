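## small standardized design helper
makeDesign <- function(n, p, rho = 0.4, seed = 1, betas = NULL,
                       noise = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n)
  S <- rho ^ abs(outer(seq_len(p), seq_len(p), "-"))
  X <- Z %*% chol(S)
  colnames(X) <- paste0("x", seq_len(p))
  if (is.null(betas)) betas <- seq_len(p) / p
  y <- as.numeric(X %*% betas + rnorm(n, 0, noise))
  gr <- setNames(rep("g", p), colnames(X))
  dm <- buildDriverMatrix(y, as.data.frame(X), groups = gr)
  dm
}

test_that("orthogonal predictors split the explained variance in
           proportion to their marginal R2", {
  n <- 4000
  set.seed(42)
  x1 <- rnorm(n); x2 <- rnorm(n)
  x2 <- as.numeric(residuals(lm(x2 ~ x1)))  # exactly orthogonal in-sample
  y <- sqrt(0.3) * x1 / sd(x1) + sqrt(0.2) * x2 / sd(x2) +
    rnorm(n, 0, sqrt(0.5))
  dm <- buildDriverMatrix(y, data.frame(x1 = x1, x2 = x2),
                          groups = c(x1 = "a", x2 = "b"))
  res <- lmg(dm)
  sh <- res$table$lmg_share
  expect_equal(sh[1] / sh[2],
               summary(lm(dm$y ~ dm$X[, 1]))$r.squared /
                 summary(lm(dm$y ~ dm$X[, 2]))$r.squared,
               tolerance = 1e-9)
})

test_that("the covariance-recursion LMG equals factorial brute force on
           correlated designs", {
  for (seed in 1:6) {
    p <- sample(3:5, 1)
    dm <- makeDesign(50, p, rho = 0.6, seed = seed)
    res <- suppressWarnings(lmg(dm))
    oracle <- bruteLmg(dm$X, dm$y)
    expect_equal(res$table$lmg_share, oracle, tolerance = 1e-10)
  }
})

test_that("LMG shares are permutation-equivariant, scale-invariant, sum to
           100 and are non-negative", {
  dm <- makeDesign(200, 4, seed = 3)
  res <- lmg(dm)
  expect_equal(sum(res$table$lmg_share), 100, tolerance = 1e-9)
  expect_true(all(res$table$lmg_share >= -1e-12))
  ## permute the columns
  perm <- c(3, 1, 4, 2)
  dm2 <- dm; dm2$X <- dm$X[, perm]; dm2$groups <- dm$groups[perm]
  res2 <- lmg(dm2)
  expect_equal(res2$table$lmg_share,
               res$table$lmg_share[perm], tolerance = 1e-10)
  ## affine rescaling of a raw predictor changes nothing (standardized)
  raw <- as.data.frame(dm$X %*% diag(c(1, 100, 1, 1)))
  names(raw) <- colnames(dm$X)
  raw$x2 <- raw$x2 + 5000
  dm3 <- buildDriverMatrix(dm$y, raw,
                           groups = setNames(dm$groups, colnames(dm$X)))
  expect_equal(lmg(dm3)$table$lmg_share, res$table$lmg_share,
               tolerance = 1e-9)
})

test_that("a response orthogonal to all predictors is flagged degenerate", {
  set.seed(4)
  X <- matrix(rnorm(300), 100)
  y <- rnorm(100)
  y <- as.numeric(residuals(lm(y ~ X)))
  dm <- buildDriverMatrix(y, as.data.frame(X))
  expect_error(lmg(dm), "degenerate|zero")
})

test_that("the collinearity screen drops near-duplicates, keeping the
           member closer to the response", {
  set.seed(5)
  n <- 300
  a <- rnorm(n)
  b <- 0.95 * a + sqrt(1 - 0.95^2) * rnorm(n)  # ~0.95-correlated copy
  c3 <- rnorm(n)
  y <- a + c3 + rnorm(n, 0, 0.5)
  dm <- buildDriverMatrix(y, data.frame(d_annual_rainfall = a,
                                        d_intensity = b, other = c3))
  expect_message(sc <- collinearityScreen(dm), "d_intensity")
  expect_false("d_intensity" %in% colnames(sc$X))
  ## uncorrelated design passes unchanged
  dm2 <- buildDriverMatrix(y, data.frame(a = a, c3 = c3))
  sc2 <- collinearityScreen(dm2)
  expect_identical(colnames(sc2$X), colnames(dm2$X))
  ## an exact duplicate (|r| = 1): exactly one of the pair is dropped
  dm3 <- buildDriverMatrix(y, data.frame(a = a, a2 = a * 2 + 1, c3 = c3))
  sc3 <- suppressMessages(collinearityScreen(dm3))
  expect_equal(sum(c("a", "a2") %in% colnames(sc3$X)), 1L)
})

test_that("zero-variance predictors are excluded with a warning before
           modelling", {
  set.seed(6)
  expect_warning(
    dm <- buildDriverMatrix(rnorm(50),
                            data.frame(a = rnorm(50), b = rep(3, 50))),
    "zero-variance")
  expect_false("b" %in% colnames(dm$X))
})

test_that("bootstrap CIs are deterministic given the seed and bracket the
           point estimates", {
  dm <- makeDesign(150, 4, seed = 7)
  b1 <- lmgBootstrap(dm, reps = 200, seed = 11)
  b2 <- lmgBootstrap(dm, reps = 200, seed = 11)
  expect_identical(b1$table, b2$table)
  expect_true(all(b1$table$ci_lo <= b1$table$ci_hi))
  expect_true(all(b1$groupTable$ci_lo - 1e-9 <= b1$groupTable$share &
                    b1$groupTable$share <= b1$groupTable$ci_hi + 1e-9))
})

test_that("bootstrap CI width shrinks monotonically as the response noise
           vanishes", {
  widths <- vapply(c(2, 0.5, 0.05), function(ns) {
    dm <- makeDesign(120, 3, seed = 13, betas = c(1, 0.5, 0.25),
                     noise = ns)
    b <- lmgBootstrap(dm, reps = 200, seed = 5)
    mean(b$table$ci_hi - b$table$ci_lo)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("partial slopes equal the multiple-regression coefficients and
           collapse to univariate slopes for orthogonal designs", {
  set.seed(9)
  n <- 500
  x1 <- rnorm(n)
  x2 <- as.numeric(residuals(lm(rnorm(n) ~ x1)))
  y <- 1.5 * scale(x1) + rnorm(n, 0, 0.1)
  dm <- buildDriverMatrix(as.numeric(y), data.frame(x1 = x1, x2 = x2))
  ps <- partialSlopes(dm, vars = c("x1", "x2"))
  expect_equal(ps$partial_slope, ps$uni_slope, tolerance = 1e-9)
  ## correlated pair, y depending only on x1: in standardized units the
  ## partial slopes are (1, 0) while the univariate slope on x2 absorbs
  ## the cross-correlation (slope = cor(x2, y))
  rho <- 0.8
  x1 <- rnorm(n)
  x2 <- rho * x1 + sqrt(1 - rho^2) * rnorm(n)
  y2 <- 2 * x1
  dm2 <- buildDriverMatrix(y2, data.frame(x1 = x1, x2 = x2))
  ## the perfect fit is deliberate here
  ps2 <- suppressWarnings(partialSlopes(dm2, vars = c("x1", "x2")))
  expect_equal(ps2$partial_slope, c(1, 0), tolerance = 1e-9)
  expect_equal(ps2$uni_slope[2], cor(x2, y2), tolerance = 1e-9)
  expect_true(all(ps2$partial_lo <= ps2$partial_slope &
                    ps2$partial_slope <= ps2$partial_hi))
})

test_that("slopes on a signal-free response vanish within sampling error", {
  dm <- makeDesign(2000, 3, seed = 17, betas = c(0, 0, 0), noise = 1)
  ps <- partialSlopes(dm, vars = colnames(dm$X))
  se <- (ps$partial_hi - ps$partial_slope) / qt(0.95, nrow(dm$X) - 4)
  expect_true(all(abs(ps$partial_slope) < 3 * se))
})
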