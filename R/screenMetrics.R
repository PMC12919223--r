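#' Area under the ROC curve (Mann--Whitney form)
#'
#' Computed as the pairwise concordance statistic: the fraction of
#' case/control score pairs in which the case scores higher, ties
#' counted one half. Implemented through average ranks, so it is exact
#' (no trapezoid approximation) and invariant under strictly monotone
#' transforms of the scores.
#'
#' @param scores numeric scores.
#' @param labels 0/1 or logical labels (1 = case), aligned with scores.
#' @return AUC in [0, 1].
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))  # 1
#' @export
rocAuc <- function(scores, labels) {
  y <- as.logical(labels)
  stopifnot(length(scores) == length(y), !anyNA(scores), !anyNA(y))
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score threshold achieving a target specificity
#'
#' The smallest threshold whose empirical control specificity reaches
#' the target, under the convention that scores strictly greater than
#' the threshold are flagged positive (ties are pushed toward fewer
#' false positives). The returned threshold is the
#' \code{ceiling(target * n)}-th control order statistic; for
#' \code{target = 1} this is the maximum control score, so only scores
#' above every control are flagged.
#'
#' @param controlScores numeric scores of control patients.
#' @param target required specificity in (0, 1].
#' @return The threshold.
#' @export
thresholdAtSpecificity <- function(controlScores, target = 0.95) {
  stopifnot(length(controlScores) >= 1L, target > 0, target <= 1)
  n <- length(controlScores)
  if (n < 20L)
    warning("fewer than 20 controls: specificity threshold is unstable")
  s <- sort(controlScores)
  if (s[1] == s[n])
    warning("constant control scores: threshold is degenerate")
  s[ceiling(target * n)]
}

#' Prevalence-standardized predictive values and likelihood ratios
#'
#' PPV and NPV at an assumed target prevalence \eqn{\pi} via Bayes'
#' rule, plus the prevalence-invariant likelihood ratios:
#' \deqn{PPV = \frac{se\,\pi}{se\,\pi + (1-sp)(1-\pi)}, \quad
#'       NPV = \frac{sp\,(1-\pi)}{(1-se)\,\pi + sp\,(1-\pi)},}
#' \eqn{LR^+ = se/(1-sp)} (infinite at sp = 1) and
#' \eqn{LR^- = (1-se)/sp}.
#'
#' @param sensitivity,specificity operating point in [0, 1].
#' @param prevalence assumed prevalence in (0, 1); the package default
#'   0.109 harmonizes reporting at a 10.9\% ADRD prevalence (1 in 9).
#' @return list(ppv, npv, lrPos, lrNeg).
#' @examples
#' standardizedPredictiveValues(0.68, 0.95, 0.109)
#' @export
standardizedPredictiveValues <- function(sensitivity, specificity,
                                         prevalence = 0.109) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            prevalence > 0, prevalence < 1)
  se <- sensitivity; sp <- specificity; pi <- prevalence
  ppv <- se * pi / (se * pi + (1 - sp) * (1 - pi))
  npv <- sp * (1 - pi) / ((1 - se) * pi + sp * (1 - pi))
  lrPos <- if (sp < 1) se / (1 - sp) else Inf
  lrNeg <- (1 - se) / sp
  list(ppv = ppv, npv = npv, lrPos = lrPos, lrNeg = lrNeg)
}

#' Positive predictive value implied by a positive likelihood ratio
#'
#' \eqn{PPV = LR^+\pi / (LR^+\pi + 1 - \pi)}: the posterior probability
#' of disease after a positive screen at prevalence \eqn{\pi}.
#'
#' @param lrPos positive likelihood ratio.
#' @param prevalence assumed prevalence in (0, 1).
#' @return PPV in [0, 1].
#' @examples
#' ppvFromLR(8.22, 0.109)
#' @export
ppvFromLR <- function(lrPos, prevalence = 0.109) {
  stopifnot(lrPos >= 0, prevalence > 0, prevalence < 1)
  lrPos * prevalence / (lrPos * prevalence + 1 - prevalence)
}

#' Screening metrics at a specificity-anchored threshold
#'
#' Thresholds the scores at the target specificity (on the controls),
#' then reports AUC, the empirical operating point, and
#' prevalence-standardized PPV, NPV, accuracy and likelihood ratios.
#' Accuracy is computed at the standardized prevalence:
#' \code{se * pi + sp * (1 - pi)}.
#'
#' @param scores,labels scores and 0/1 labels.
#' @param prevalence assumed prevalence.
#' @param targetSpecificity specificity anchor (default 0.95).
#' @param threshold optional externally fixed threshold; overrides the
#'   specificity anchor.
#' @return list with auc, threshold, sensitivity, specificity, ppv,
#'   npv, accuracy, lrPos, lrNeg, nCase, nControl.
#' @export
metricReport <- function(scores, labels, prevalence = 0.109,
                         targetSpecificity = 0.95, threshold = NULL) {
  y <- as.logical(labels)
  if (is.null(threshold))
    threshold <- thresholdAtSpecificity(scores[!y], targetSpecificity)
  se <- mean(scores[y] > threshold)
  sp <- mean(scores[!y] <= threshold)
  spv <- standardizedPredictiveValues(se, sp, prevalence)
  list(auc = rocAuc(scores, labels), threshold = threshold,
       sensitivity = se, specificity = sp,
       ppv = spv$ppv, npv = spv$npv,
       accuracy = se * prevalence + sp * (1 - prevalence),
       lrPos = spv$lrPos, lrNeg = spv$lrNeg,
       nCase = sum(y), nControl = sum(!y))
}

#' Per-year decline of AUC across prediction horizons
#'
#' Two summaries of temporal degradation, both in percent AUC per year:
#' the endpoint decline \code{(AUC at min horizon - AUC at max horizon)
#' / span} and the (negated) ordinary least-squares slope of AUC on
#' horizon.
#'
#' @param aucByHorizon named numeric vector, names = horizon years.
#' @return list(endpointDecline, olsDecline), percent per year.
#' @examples
#' horizonDecay(c(`0` = 0.957, `10` = 0.83))  # endpoint 1.27 %/yr
#' @export
horizonDecay <- function(aucByHorizon) {
  stopifnot(length(aucByHorizon) >= 2L, !is.null(names(aucByHorizon)))
  h <- as.numeric(names(aucByHorizon))
  if (anyNA(h)) stop("horizon names must be numeric years")
  if (anyDuplicated(h)) stop("duplicate horizons")
  o <- order(h)
  h <- h[o]; a <- as.numeric(aucByHorizon)[o]
  span <- h[length(h)] - h[1]
  list(endpointDecline = 100 * (a[1] - a[length(a)]) / span,
       olsDecline = -100 * unname(coef(lm(a ~ h))[2]))
}

#' Per-stratum screening reports
#'
#' One \code{\link{metricReport}} per stratum of the supplied grouping
#' fields; strata with fewer than the minimum cases or controls are
#' suppressed with a reason rather than reported unstably.
#'
#' @param scores,labels scores and 0/1 labels.
#' @param strata data.frame of per-patient stratification fields (age
#'   band, sex, race, ethnicity, risk stratum, ...).
#' @param prevalence assumed prevalence.
#' @param targetSpecificity specificity anchor.
#' @param minCases,minControls suppression thresholds.
#' @return data.frame: one row per stratum with the metric columns, or
#'   NA metrics and a \code{suppressed} reason.
#' @export
subgroupReport <- function(scores, labels, strata, prevalence = 0.109,
                           targetSpecificity = 0.95,
                           minCases = 10L, minControls = 20L) {
  stopifnot(is.data.frame(strata), nrow(strata) == length(scores))
  y <- as.logical(labels)
  key <- interaction(strata, drop = TRUE, sep = "|")
  out <- lapply(levels(key), function(k) {
    sel <- key == k
    info <- strata[which(sel)[1], , drop = FALSE]
    nCase <- sum(y[sel]); nCtl <- sum(!y[sel])
    base <- cbind(info, nCase = nCase, nControl = nCtl, row.names = NULL)
    if (nCase < minCases || nCtl < minControls) {
      return(cbind(base, auc = NA_real_, sensitivity = NA_real_,
                   specificity = NA_real_, ppv = NA_real_, npv = NA_real_,
                   accuracy = NA_real_, lrPos = NA_real_, lrNeg = NA_real_,
                   suppressed = sprintf("n too small (%d cases, %d controls)",
                                        nCase, nCtl)))
    }
    m <- metricReport(scores[sel], y[sel], prevalence, targetSpecificity)
    cbind(base, auc = m$auc, sensitivity = m$sensitivity,
          specificity = m$specificity, ppv = m$ppv, npv = m$npv,
          accuracy = m$accuracy, lrPos = m$lrPos, lrNeg = m$lrNeg,
          suppressed = NA_character_)
  })
  do.call(rbind, out)
}

#' Percentile bootstrap half-widths for a screening metric
#'
#' Patient-level resampling stratified by label, seeded for
#' reproducibility. \code{B = 0} disables the bootstrap and returns NA.
#'
#' @param metricFun function(scores, labels) -> scalar.
#' @param scores,labels scores and 0/1 labels.
#' @param B number of bootstrap replicates (default 200).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return list(estimate, halfWidth, ciLow, ciHigh, B).
#' @export
bootstrapCI <- function(metricFun, scores, labels, B = 200L, seed = 1L,
                        conf = 0.95) {
  y <- as.logical(labels)
  est <- metricFun(scores, y)
  if (B <= 0)
    return(list(estimate = est, halfWidth = NA_real_, ciLow = NA_real_,
                ciHigh = NA_real_, B = 0L))
  stopifnot(B >= 100L)
  idxCase <- which(y); idxCtl <- which(!y)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  stats <- vapply(seq_len(B), function(b) {
    i <- c(sample(idxCase, replace = TRUE), sample(idxCtl, replace = TRUE))
    metricFun(scores[i], y[i])
  }, numeric(1))
  qs <- quantile(stats, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(estimate = est, halfWidth = (qs[2] - qs[1]) / 2,
       ciLow = qs[1], ciHigh = qs[2], B = as.integer(B))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}
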