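# Beta regression: response preparation, log-posterior, sampler, summaries.

test_that("prepareResponse clamps into the open interval and counts clamps", {
  expect_silent(y0 <- prepareResponse(0.22))
  expect_equal(as.numeric(y0), 0.22)
  expect_equal(attr(y0, "nClamped"), 0)
  expect_message(y1 <- prepareResponse(c(-0.046, 0.3), epsilon = 0.005),
                 "clamped 1")
  expect_equal(as.numeric(y1), c(0.005, 0.3))
  expect_equal(attr(y1, "nClamped"), 1)
  expect_equal(as.numeric(suppressMessages(prepareResponse(1, 0.005))), 0.995)
  expect_error(prepareResponse(0.5, epsilon = 0.05),
               class = "nkassay_input_error")
})

test_that("regressionData validates its invariants", {
  expect_error(regressionData(c(0.2, 0), group = c("a", "b")),
               regexp = "strictly inside")
  rd <- regressionData(c(0.2, 0.4), group = c("a", "b"), pair = c("p", "p"),
                       contrast = c("b", "a"))
  expect_s4_class(rd, "RegressionData")
  expect_error(regressionData(c(0.2, 0.4), group = c("a", "b"),
                              contrast = c("a", "zzz")),
               regexp = "contrast")
})

test_that("logPosterior matches an independent hand computation", {
  y <- c(0.22, 0.30, 0.26)
  rd <- regressionData(y, group = rep("g", 3))
  # mu = 0.5, phi = 2 makes the likelihood Beta(1,1): zero for any y
  th0 <- c(0, log(2))
  expect_equal(logPosterior(th0, rd) - logPosterior(th0, rd, includeLikelihood = FALSE),
               0, tolerance = 1e-12)
  # hand computation via the Beta log-density written out with lgamma
  handLp <- function(alpha, logphi) {
    mu <- 1 / (1 + exp(-alpha))
    phi <- exp(logphi)
    a <- mu * phi; b <- (1 - mu) * phi
    ll <- sum(lgamma(a + b) - lgamma(a) - lgamma(b) +
              (a - 1) * log(y) + (b - 1) * log(1 - y))
    pr <- -0.5 * (alpha / 2.5)^2 - log(2.5 * sqrt(2 * pi)) -
      0.5 * ((logphi - 3) / 1.5)^2 - log(1.5 * sqrt(2 * pi))
    ll + pr
  }
  th1 <- c(-1.2, 2.5); th2 <- c(-0.8, 4.0)
  expect_equal(logPosterior(th1, rd) - logPosterior(th2, rd),
               handLp(-1.2, 2.5) - handLp(-0.8, 4.0), tolerance = 1e-10)
  expect_error(logPosterior(c(0, 0, 0), rd), class = "nkassay_input_error")
})

test_that("MCMC agrees with dense-grid quadrature on a tiny dataset", {
  y <- c(0.22, 0.30, 0.26)
  rd <- regressionData(y, group = rep("g", 3))
  a <- seq(-4, 2, length.out = 301); l <- seq(-2, 9, length.out = 301)
  lp <- outer(a, l, Vectorize(function(ai, li) logPosterior(c(ai, li), rd)))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  fit <- samplePosterior(rd, nChains = 2, nWarmup = 500, nKept = 2000, seed = 71)
  dm <- drawsMatrix(fit)
  expect_equal(mean(plogis(dm[, "alpha"])), sum(plogis(a) * rowSums(w)),
               tolerance = 0.02)
  expect_equal(mean(dm[, "alpha"]), sum(a * rowSums(w)), tolerance = 0.02)
  expect_equal(mean(dm[, "logphi"]), sum(l * colSums(w)), tolerance = 0.02)
})

test_that("prior-only sampling reproduces the prior", {
  rd <- regressionData(c(0.3, 0.5), group = c("a", "a"))
  fit <- samplePosterior(rd, nChains = 2, nWarmup = 500, nKept = 4000,
                         seed = 72, includeLikelihood = FALSE)
  dm <- drawsMatrix(fit)
  qs <- c(0.1, 0.5, 0.9)
  expect_equal(unname(quantile(dm[, "alpha"], qs)), qnorm(qs, 0, 2.5),
               tolerance = 0.15)
  expect_equal(unname(quantile(dm[, "logphi"], qs)), qnorm(qs, 3, 1.5),
               tolerance = 0.1)
})

test_that("the posterior recovers a known group mean", {
  set.seed(73)
  y <- rbeta(50, 0.3 * 60, 0.7 * 60)
  rd <- regressionData(y, group = rep("g", 50))
  fit <- samplePosterior(rd, nChains = 2, nWarmup = 500, nKept = 2000, seed = 74)
  expect_lt(abs(median(plogis(drawsMatrix(fit)[, "alpha"])) - 0.3), 0.03)
})

test_that("sampler defaults and determinism match the reporting convention", {
  set.seed(75)
  y <- rbeta(12, 10, 30)
  rd <- regressionData(y, group = rep(c("a", "b"), 6),
                       pair = rep(1:6, each = 2), contrast = c("b", "a"))
  fit <- samplePosterior(rd, seed = 76)
  expect_equal(nrow(drawsMatrix(fit)), 4 * 2500)
  expect_identical(fit@nWarmup, 2500L)
  fit2 <- samplePosterior(rd, seed = 76)
  expect_identical(drawsMatrix(fit), drawsMatrix(fit2))
})

test_that("groupMeanDraws marginalizes pairs with equal weight", {
  rd <- regressionData(c(0.2, 0.3, 0.25, 0.35),
                       group = c("a", "b", "a", "b"),
                       pair = c("p1", "p1", "p2", "p2"),
                       contrast = c("b", "a"))
  mat <- matrix(c(0.5, 0.2, 0.8, 4), nrow = 1,
                dimnames = list(NULL, c("alpha", "beta_b", "gamma_p2", "logphi")))
  fd <- fakeDraws(mat, rd)
  expect_equal(groupMeanDraws(fd, "a"),
               (plogis(0.5) + plogis(0.5 + 0.8)) / 2)
  expect_equal(groupMeanDraws(fd, "b"),
               (plogis(0.7) + plogis(0.7 + 0.8)) / 2)
  # Jensen: equal-weight average of inverse-logits is below the inverse-logit
  # at the midpoint on the concave side
  expect_lt(groupMeanDraws(fd, "a"), plogis(0.5 + 0.4))
  # identical group coefficients give identical group means
  mat0 <- matrix(c(0.5, 0, 0.8, 4), nrow = 1,
                 dimnames = list(NULL, c("alpha", "beta_b", "gamma_p2", "logphi")))
  fd0 <- fakeDraws(mat0, rd)
  expect_identical(groupMeanDraws(fd0, "a"), groupMeanDraws(fd0, "b"))
  expect_error(groupMeanDraws(fd, "zzz"), class = "nkassay_input_error")
})

test_that("falseSignRate counts draws opposing the median sign", {
  expect_equal(falseSignRate(c(0.1, 0.4, 2)), 0)
  expect_equal(falseSignRate(c(-2, -1, 1, 2)), 0.5)  # median exactly 0
  expect_equal(falseSignRate(c(-0.1, -0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)),
               0.2)
  expect_error(falseSignRate(0.3), class = "nkassay_input_error")
})

test_that("summarizeDraws uses linear-interpolation quantiles", {
  s <- summarizeDraws(rep(3.2, 10))
  expect_equal(postMedian(s), 3.2)
  expect_equal(unname(credInt(s)), c(3.2, 3.2))
  s2 <- summarizeDraws(as.numeric(1:100))
  expect_equal(postMedian(s2), 50.5)
  expect_equal(unname(credInt(s2)), c(3.475, 97.525))
  # affine equivariance for a > 0
  x <- rnorm(500)
  s3 <- summarizeDraws(x); s4 <- summarizeDraws(2 * x + 1)
  expect_equal(postMedian(s4), 2 * postMedian(s3) + 1)
  expect_equal(unname(credInt(s4)), 2 * unname(credInt(s3)) + 1)
})

test_that("foldChange is the per-draw ratio of group means", {
  rd <- regressionData(c(0.17, 0.25),
                       group = factor(c("lo", "hi"), levels = c("lo", "hi")),
                       contrast = c("hi", "lo"))
  mat <- matrix(c(qlogis(0.17), qlogis(0.25) - qlogis(0.17), 5,
                  qlogis(0.18), qlogis(0.27) - qlogis(0.18), 5),
                nrow = 2, byrow = TRUE,
                dimnames = list(NULL, c("alpha", "beta_hi", "logphi")))
  fd <- fakeDraws(mat, rd)
  fc <- foldChange(fd)
  expect_equal(sort(effectDraws(fc)), c(0.25 / 0.17, 0.27 / 0.18),
               tolerance = 1e-12)
  expect_equal(postMedian(fc), (0.25 / 0.17 + 0.27 / 0.18) / 2,
               tolerance = 1e-12)
  # reversing the contrast gives reciprocal draws, draw by draw
  fcRev <- foldChange(fd, contrast = c("lo", "hi"))
  expect_equal(effectDraws(fcRev), 1 / effectDraws(fc), tolerance = 1e-12)
  # identical groups: median fold exactly 1
  mat1 <- matrix(c(qlogis(0.2), 0, 5), nrow = 1,
                 dimnames = list(NULL, c("alpha", "beta_hi", "logphi")))
  expect_equal(postMedian(foldChange(fakeDraws(mat1[c(1, 1), ], rd))), 1)
})

test_that("FSR shrinks as the true effect grows", {
  set.seed(77)
  fsrs <- vapply(c(0, 0.06, 0.12), function(delta) {
    y <- c(rbeta(8, (0.2 + delta) * 300, (0.8 - delta) * 300),
           rbeta(8, 0.2 * 300, 0.8 * 300))
    rd <- regressionData(y, group = rep(c("b", "a"), each = 8),
                         contrast = c("b", "a"))
    fit <- samplePosterior(rd, nChains = 2, nWarmup = 400, nKept = 800,
                           seed = 78)
    fsr(foldChange(fit))
  }, numeric(1))
  expect_true(all(diff(fsrs) <= 0))
  expect_gt(fsrs[1], 0.2)   # null effect: high sign uncertainty
  expect_lt(fsrs[3], 0.05)  # strong effect: sign nearly certain
})
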