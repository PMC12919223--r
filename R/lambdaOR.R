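#' Misclassification matrix of a noisy labelling process
#'
#' Rows index the true label (case, control), columns the observed
#' label: \code{rbind(c(p, 1-p), c(1-q, q))} for sensitivity \code{p}
#' and specificity \code{q}. Near \code{p + q = 1} the matrix is
#' singular and correction is impossible; a warning is raised here and
#' the correction functions refuse such specifications outright.
#'
#' @param spec a \linkS4class{MisclassSpec}.
#' @return 2x2 row-stochastic matrix.
#' @examples
#' misclassificationMatrix(misclassSpec(0.9, 0.95))
#' @export
misclassificationMatrix <- function(spec) {
  stopifnot(is(spec, "MisclassSpec"))
  if (abs(spec@p + spec@q - 1) < 1e-3)
    warning("p + q is (nearly) 1: misclassification matrix is (nearly) singular")
  matrix(c(spec@p, 1 - spec@p, 1 - spec@q, spec@q), 2, 2, byrow = TRUE,
         dimnames = list(true = c("case", "control"),
                         observed = c("case", "control")))
}

degeneracyGuard <- function(spec) {
  if (abs(spec@p + spec@q - 1) < 1e-3)
    stop("p + q - 1 is below the degeneracy guard (1e-3): ",
         "labels carry no recoverable signal")
}

# (K + lambda I)^-1 for the 2x2 misclassification matrix, closed form
ridgeInverse <- function(spec, lambda) {
  p <- spec@p; q <- spec@q
  det <- (p + lambda) * (q + lambda) - (1 - p) * (1 - q)
  if (abs(det) < .Machine$double.eps * 16)
    stop("K + lambda*I is singular; increase lambda")
  matrix(c(q + lambda, -(1 - p), -(1 - q), p + lambda), 2, 2, byrow = TRUE) / det
}

#' Ridge-corrected 2x2 table under label misclassification
#'
#' In expectation the observed exposure-by-status table satisfies
#' \eqn{\tilde T = T K}, with rows of the misclassification matrix K
#' indexed by true status (observed case counts mix true cases kept with
#' probability p and true controls leaking in with probability 1-q).
#' The corrected table is the ridge-regularized inversion
#' \eqn{T(\lambda) = \tilde T (K + \lambda I)^{-1}}: exact matrix
#' algebra, no clipping. At \eqn{p = q = 1, \lambda = 0} the observed
#' table is returned unchanged.
#'
#' @param tab a \linkS4class{NoisyTable}.
#' @param spec a \linkS4class{MisclassSpec}.
#' @param lambda nonnegative ridge strength.
#' @return Corrected 2x2 numeric matrix.
#' @examples
#' correctTable(noisyTable(90, 10, 10, 90), misclassSpec(0.9, 0.9), 0)
#' @export
correctTable <- function(tab, spec, lambda = 0) {
  stopifnot(is(tab, "NoisyTable"), is(spec, "MisclassSpec"), lambda >= 0)
  degeneracyGuard(spec)
  out <- tab@counts %*% ridgeInverse(spec, lambda)
  dimnames(out) <- dimnames(tab@counts)
  out
}

#' Smallest feasible ridge strength
#'
#' The minimal \eqn{\lambda \ge 0} such that every entry of
#' \eqn{T(\lambda)} is at least \code{epsilon}. Each corrected entry is
#' a ratio of a linear to a quadratic polynomial in \eqn{\lambda}, so
#' the feasible set is an interval; the left edge is located by a
#' golden-section maximization of the minimum entry followed by
#' bisection, to relative tolerance \code{tol}. Returns 0 when the
#' unregularized inverse is already feasible, and an infeasible flag
#' (not an error) when no \eqn{\lambda \le} \code{lambdaMax} works.
#'
#' @param tab a \linkS4class{NoisyTable}.
#' @param spec a \linkS4class{MisclassSpec}.
#' @param epsilon positive feasibility floor on corrected counts
#'   (default 0.5, the midpoint of the conventional [0.1, 1] range).
#' @param lambdaMax upper end of the search bracket (default
#'   \code{10 * max(counts)}).
#' @param tol relative tolerance of the bisection.
#' @return list(lambda, feasible).
#' @export
findMinLambda <- function(tab, spec, epsilon = 0.5,
                          lambdaMax = 10 * max(tableCounts(tab)), tol = 1e-9) {
  stopifnot(is(tab, "NoisyTable"), epsilon > 0)
  degeneracyGuard(spec)
  f <- function(l) min(tab@counts %*% ridgeInverse(spec, l)) - epsilon
  if (f(0) >= 0) return(list(lambda = 0, feasible = TRUE))
  # golden-section search for the maximizer of the quasiconcave f
  gr <- (sqrt(5) - 1) / 2
  lo <- 0; hi <- lambdaMax
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  for (it in seq_len(200)) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    }
    if ((hi - lo) < tol * max(1, hi)) break
  }
  peak <- (lo + hi) / 2
  if (f(peak) < 0) return(list(lambda = NA_real_, feasible = FALSE))
  # left feasibility edge: bisect between infeasible 0 and feasible peak
  lo <- 0; hi <- peak
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  list(lambda = hi, feasible = TRUE)
}

#' Classical log odds ratio of a 2x2 table
#'
#' \eqn{\log(ad/bc)} with the classical variance
#' \eqn{1/a + 1/b + 1/c + 1/d}. Zero cells are an error; apply
#' smoothing or the ridge correction upstream.
#'
#' @param tab a \linkS4class{NoisyTable} or a 2x2 matrix of positive
#'   counts.
#' @return list(logOR, varNaive).
#' @examples
#' naiveLogOR(noisyTable(20, 10, 5, 10))   # log 4, var 0.45
#' @export
naiveLogOR <- function(tab) {
  m <- if (is(tab, "NoisyTable")) tab@counts else tab
  stopifnot(all(dim(m) == c(2, 2)))
  if (any(m <= 0)) stop("zero or negative cell: classical log OR undefined")
  list(logOR = log(m[1, 1] * m[2, 2] / (m[1, 2] * m[2, 1])),
       varNaive = sum(1 / m))
}

#' Extra variance from estimated sensitivity and specificity
#'
#' Delta-method variance contribution of plugging in sensitivity and
#' specificity estimated from an independent validation cohort of size
#' \code{nVal}:
#' \deqn{\left(\frac{1-q}{(p+q-1)^2}\right)^2 \frac{2p(1-p)}{n_{val}}
#'     + \left(\frac{1-p}{(p+q-1)^2}\right)^2 \frac{2q(1-q)}{n_{val}}.}
#' Zero when \code{nVal} is absent (p and q known exactly); vanishes as
#' \code{nVal} grows and at \code{p = q = 1}.
#'
#' @param spec a \linkS4class{MisclassSpec}.
#' @return Nonnegative scalar variance.
#' @export
extraVariance <- function(spec) {
  stopifnot(is(spec, "MisclassSpec"))
  if (is.na(spec@nVal)) return(0)
  if (spec@nVal <= 1) stop("nVal must exceed 1")
  p <- spec@p; q <- spec@q
  denom <- (p + q - 1)^2
  ((1 - q) / denom)^2 * 2 * p * (1 - p) / spec@nVal +
    ((1 - p) / denom)^2 * 2 * q * (1 - q) / spec@nVal
}

# Sampling variance of the corrected log OR: within each exposure row
# the observed (case, control) split is binomial given the row margin;
# propagating it through the ridge inverse W = (K + lambda I)^-1 gives,
# per row i,
#   [ (W11 - W21)/a_i - (W12 - W22)/b_i ]^2 * atilde_i * btilde_i / n_i
# summed over the two rows (a_i, b_i the corrected row entries). For
# W = I this reduces algebraically to the classical 1/a + 1/b + 1/c + 1/d.
correctedSamplingVariance <- function(tabCounts, corrected, W) {
  v <- 0
  for (i in 1:2) {
    ni <- sum(tabCounts[i, ])
    if (ni <= 0) next
    g <- (W[1, 1] - W[2, 1]) / corrected[i, 1] - (W[1, 2] - W[2, 2]) / corrected[i, 2]
    v <- v + g^2 * tabCounts[i, 1] * tabCounts[i, 2] / ni
  }
  v
}

#' Misclassification-corrected, ridge-regularized odds ratio
#'
#' The full correction pipeline: find the smallest feasible ridge
#' strength, invert the misclassification, form the corrected log odds
#' ratio, and attach delta-method inference. The total variance is the
#' sampling variance of the corrected estimator (which reduces to the
#' classical \eqn{1/a+1/b+1/c+1/d} for noiseless labels) plus the
#' extra-variance term for estimated sensitivity/specificity; the Wald
#' statistic, two-sided normal p-value and (1 - alpha) confidence
#' interval follow.
#'
#' @param tab a \linkS4class{NoisyTable} of observed counts.
#' @param spec a \linkS4class{MisclassSpec}.
#' @param epsilon feasibility floor for corrected counts (default 0.5).
#' @param alpha nominal two-sided test level (default 0.05).
#' @param lambdaMax search bracket for the ridge strength.
#' @return A \linkS4class{LambdaORResult}; when no feasible ridge
#'   strength exists the result is flagged infeasible and carries no
#'   estimate.
#' @examples
#' lambdaOR(noisyTable(90, 10, 10, 90), misclassSpec(0.9, 0.9))
#' @export
lambdaOR <- function(tab, spec, epsilon = 0.5, alpha = 0.05,
                     lambdaMax = 10 * max(tableCounts(tab))) {
  stopifnot(is(tab, "NoisyTable"), is(spec, "MisclassSpec"),
            alpha > 0, alpha < 1)
  degeneracyGuard(spec)
  fm <- findMinLambda(tab, spec, epsilon = epsilon, lambdaMax = lambdaMax)
  if (!fm$feasible) {
    return(new("LambdaORResult",
               correctedTable = matrix(NA_real_, 2, 2), lambda = NA_real_,
               epsilon = epsilon, logOR = NA_real_, varNaive = NA_real_,
               varExtra = NA_real_, varTotal = NA_real_, z = NA_real_,
               pTwoSided = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
               alpha = alpha, feasible = FALSE))
  }
  W <- ridgeInverse(spec, fm$lambda)
  corrected <- tab@counts %*% W
  dimnames(corrected) <- dimnames(tab@counts)
  lo <- log(corrected[1, 1] * corrected[2, 2] /
              (corrected[1, 2] * corrected[2, 1]))
  varNaive <- correctedSamplingVariance(tab@counts, corrected, W)
  varExtra <- extraVariance(spec)
  varTotal <- varNaive + varExtra
  z <- lo / sqrt(varTotal)
  crit <- qnorm(1 - alpha / 2)
  new("LambdaORResult",
      correctedTable = corrected, lambda = fm$lambda, epsilon = epsilon,
      logOR = lo, varNaive = varNaive, varExtra = varExtra,
      varTotal = varTotal, z = z, pTwoSided = 2 * pnorm(-abs(z)),
      ciLow = lo - crit * sqrt(varTotal), ciHigh = lo + crit * sqrt(varTotal),
      alpha = alpha, feasible = TRUE)
}

#' Exposure-by-risk-stratum table from model scores
#'
#' Cross-tabulates a binary exposure indicator against the
#' model-predicted risk stratum at a threshold: patients scoring
#' strictly above the threshold form the empirical high-risk stratum.
#' The resulting table feeds \code{\link{lambdaOR}} in place of an
#' unstratified marginal table.
#'
#' @param scores numeric risk scores.
#' @param exposed logical exposure indicators, aligned with scores.
#' @param threshold risk threshold; must lie within the observed score
#'   range.
#' @return A \linkS4class{NoisyTable} with a = exposed & high-risk,
#'   b = exposed & low-risk, c = unexposed & high-risk,
#'   d = unexposed & low-risk.
#' @export
buildStratifiedTable <- function(scores, exposed, threshold) {
  stopifnot(length(scores) == length(exposed))
  if (threshold < min(scores) || threshold > max(scores))
    stop("threshold outside the observed score range")
  high <- scores > threshold
  a <- sum(exposed & high); b <- sum(exposed & !high)
  c <- sum(!exposed & high); d <- sum(!exposed & !high)
  if (a + c == 0L || b + d == 0L)
    warning("degenerate stratification: an entire risk stratum is empty")
  tab <- noisyTable(a, b, c, d)
  dimnames(tab@counts) <- list(exposure = c("exposed", "unexposed"),
                               stratum = c("high", "low"))
  tab
}

#' Ranked volcano table of per-code corrected odds ratios
#'
#' Assembles per-code \code{\link{lambdaOR}} results into a
#' plotting-ready table: corrected log odds ratio, -log10 p,
#' Benjamini--Hochberg adjusted q-value, risk/protective direction,
#' sorted by effect magnitude.
#'
#' @param results named list of \linkS4class{LambdaORResult} (names =
#'   codes).
#' @param fdrQ FDR level used for the \code{significant} flag.
#' @return data.frame(code, logOR, negLog10P, qValue, direction,
#'   significant), infeasible results dropped with a message.
#' @export
volcanoTable <- function(results, fdrQ = 0.05) {
  stopifnot(length(results) >= 1L, !is.null(names(results)))
  feas <- vapply(results, function(r) r@feasible, logical(1))
  if (any(!feas))
    message(sum(!feas), " infeasible result(s) dropped from the volcano table")
  results <- results[feas]
  lo <- vapply(results, function(r) r@logOR, numeric(1))
  p <- vapply(results, function(r) r@pTwoSided, numeric(1))
  q <- p.adjust(p, method = "BH")
  out <- data.frame(code = names(results), logOR = lo,
                    negLog10P = -log10(p), qValue = q,
                    direction = ifelse(lo < 0, "protective", "risk"),
                    significant = q <= fdrQ,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-abs(out$logOR)), , drop = FALSE]
}
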