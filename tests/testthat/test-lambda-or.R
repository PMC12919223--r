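test_that("misclassification matrix is row-stochastic in (p, q)", {
  expect_identical(unname(misclassificationMatrix(misclassSpec(1, 1))), diag(2))
  K <- misclassificationMatrix(misclassSpec(0.9, 0.95))
  expect_equal(unname(K), rbind(c(0.9, 0.1), c(0.05, 0.95)))
  expect_warning(misclassificationMatrix(misclassSpec(0.6, 0.4)),
                 "singular")
  expect_error(misclassSpec(0, 0.9))
  expect_error(misclassSpec(0.9, 1.2))
})

test_that("table correction inverts the noise process exactly", {
  tab <- noisyTable(13, 7, 2, 19)
  # perfect labels: identity
  expect_equal(correctTable(tab, misclassSpec(1, 1), 0), tableCounts(tab))
  # hand-inverted fixture: symmetric 10% noise on a diagonal table
  fix <- noisyTable(90, 10, 10, 90)
  Tc <- correctTable(fix, misclassSpec(0.9, 0.9), 0)
  expect_equal(unname(Tc), rbind(c(100, 0), c(0, 100)), tolerance = 1e-12)
  # worked-matrix convention: observed = true %*% K, so correcting the
  # noiseless expectation recovers the true table even when p != q
  p <- 0.85; q <- 0.95
  K <- misclassificationMatrix(misclassSpec(p, q))
  trueT <- rbind(c(40, 10), c(20, 30))
  observed <- trueT %*% K
  rec <- correctTable(noisyTable(observed[1, 1], observed[1, 2],
                                 observed[2, 1], observed[2, 2]),
                      misclassSpec(p, q), 0)
  expect_equal(unname(rec), trueT, tolerance = 1e-10)
  # ridge shrinks everything to zero in the limit
  far <- correctTable(tab, misclassSpec(0.9, 0.9), 1e9)
  expect_true(all(abs(far) < 1e-6))
  expect_error(correctTable(tab, misclassSpec(0.55, 0.4501), 0), "degeneracy")
})

test_that("minimal feasible lambda matches the dense-grid oracle", {
  expect_identical(findMinLambda(noisyTable(50, 50, 50, 50),
                                 misclassSpec(0.9, 0.9))$lambda, 0)
  set.seed(21)
  checked <- 0
  while (checked < 60) {
    tab <- noisyTable(sample(0:30, 1), sample(0:30, 1),
                      sample(0:30, 1), sample(0:30, 1) + 1)
    spec <- misclassSpec(runif(1, 0.7, 0.98), runif(1, 0.7, 0.98))
    if (min(correctTable(tab, spec, 0)) >= 0.5) next
    oracle <- gridMinLambdaOracle(tab, spec)
    got <- findMinLambda(tab, spec)
    if (is.na(oracle)) {
      expect_false(got$feasible)
    } else {
      expect_true(got$feasible)
      expect_lt(abs(got$lambda - oracle), 1e-6 * max(1e-3, oracle))
    }
    checked <- checked + 1
  }
  # an all-unexposed-case table can never be made feasible
  inf <- findMinLambda(noisyTable(0, 50, 0, 50), misclassSpec(0.9, 0.9))
  expect_false(inf$feasible)
  expect_true(is.na(inf$lambda))
})

test_that("classical log odds ratio and variance follow the 2x2 formulas", {
  r <- naiveLogOR(noisyTable(10, 10, 10, 10))
  expect_identical(r$logOR, 0)
  expect_equal(r$varNaive, 0.4)
  r2 <- naiveLogOR(noisyTable(20, 10, 5, 10))
  expect_equal(r2$logOR, log(4))
  expect_equal(r2$varNaive, 0.45)
  expect_error(naiveLogOR(noisyTable(0, 10, 5, 10)), "zero")
  # a large diabetes-exposure table assembled from published cohort margins
  big <- noisyTable(177240, 2543094, 307481, 9841665)
  expect_equal(exp(naiveLogOR(big)$logOR), 2.23, tolerance = 0.005)
})

test_that("extra variance from estimated (p, q) behaves at its limits", {
  expect_identical(extraVariance(misclassSpec(1, 1, nVal = 100)), 0)
  expect_identical(extraVariance(misclassSpec(0.9, 0.9)), 0)  # known exactly
  v <- extraVariance(misclassSpec(0.9, 0.9, nVal = 1000))
  # independent term-by-term evaluation
  p <- 0.9; q <- 0.9
  t1 <- ((1 - q) / (p + q - 1)^2)^2 * 2 * p * (1 - p) / 1000
  t2 <- ((1 - p) / (p + q - 1)^2)^2 * 2 * q * (1 - q) / 1000
  expect_equal(v, t1 + t2, tolerance = 1e-14)
  expect_lt(extraVariance(misclassSpec(0.9, 0.9, nVal = 1e7)), 1e-8)
  expect_error(extraVariance(misclassSpec(0.9, 0.9, nVal = 1)), "exceed 1")
})

test_that("the corrected estimator reduces to the naive one for perfect labels", {
  r <- lambdaOR(noisyTable(10, 10, 10, 10), misclassSpec(1, 1))
  expect_identical(r@lambda, 0)
  expect_identical(r@logOR, 0)
  expect_identical(r@z, 0)
  expect_identical(r@pTwoSided, 1)
  expect_equal(r@varNaive, 0.4, tolerance = 1e-12)
  expect_identical(r@varExtra, 0)
})

test_that("total variance dominates the sampling variance, with equality iff nVal absent", {
  set.seed(31)
  for (i in 1:20) {
    tab <- noisyTable(sample(5:80, 1), sample(5:80, 1),
                      sample(5:80, 1), sample(5:80, 1))
    known <- lambdaOR(tab, misclassSpec(0.9, 0.85))
    est <- lambdaOR(tab, misclassSpec(0.9, 0.85, nVal = 500))
    expect_identical(known@varTotal, known@varNaive)
    expect_gt(est@varTotal, est@varNaive)
    expect_equal(est@varTotal, est@varNaive + est@varExtra)
  }
})

test_that("exposure-swapped tables negate the estimate and keep the p-value", {
  set.seed(32)
  for (i in 1:20) {
    a <- sample(5:80, 1); b <- sample(5:80, 1)
    cc <- sample(5:80, 1); d <- sample(5:80, 1)
    spec <- misclassSpec(0.9, 0.95, nVal = 800)
    r1 <- lambdaOR(noisyTable(a, b, cc, d), spec)
    r2 <- lambdaOR(noisyTable(cc, d, a, b), spec)
    expect_equal(r1@logOR, -r2@logOR, tolerance = 1e-9)
    expect_equal(r1@pTwoSided, r2@pTwoSided, tolerance = 1e-9)
  }
})

test_that("corrected estimates recover a planted effect within three standard errors", {
  set.seed(33)
  tab <- simulateNoisyTable(log(3), p = 0.9, q = 0.95, n = 50000L)
  r <- lambdaOR(tab, misclassSpec(0.9, 0.95))
  expect_true(abs(r@logOR - log(3)) < 3 * sqrt(r@varTotal))
})

test_that("stratified tables cross-tabulate exposure against risk stratum", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.3, 0.2, 0.15, 0.1)
  exposed <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  tab <- buildStratifiedTable(scores, exposed, threshold = 0.5)
  expect_equal(unname(tableCounts(tab)), rbind(c(3, 1), c(1, 3)))
  expect_warning(buildStratifiedTable(scores, exposed, threshold = max(scores)),
                 "degenerate")
  expect_error(buildStratifiedTable(scores, exposed, threshold = 2),
               "outside")
})

test_that("volcano tables rank, sign and BH-adjust per-code results", {
  mk <- function(lo, p) new("LambdaORResult",
    correctedTable = matrix(1, 2, 2), lambda = 0, epsilon = 0.5, logOR = lo,
    varNaive = 1, varExtra = 0, varTotal = 1, z = lo,
    pTwoSided = p, ciLow = lo - 2, ciHigh = lo + 2, alpha = 0.05,
    feasible = TRUE)
  single <- volcanoTable(list(E11 = mk(0.5, 0.01)))
  expect_identical(nrow(single), 1L)
  res <- list(A = mk(0.4, 0.01), B = mk(-1.2, 0.02), C = mk(0.1, 0.9))
  v <- volcanoTable(res, fdrQ = 0.05)
  expect_identical(v$code, c("B", "A", "C"))  # sorted by |log OR|
  expect_identical(v$direction[v$code == "B"], "protective")
  expect_identical(v$direction[v$code == "A"], "risk")
  # hand-computed Benjamini-Hochberg on the three p-values
  expect_equal(v$qValue[match(c("A", "B", "C"), v$code)], c(0.03, 0.03, 0.9))
})
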