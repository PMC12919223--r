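#' @import methods
#' @importFrom stats median quantile sd rbinom rnorm runif rpois setNames qnorm
#'   pnorm p.adjust lm coef glm binomial predict plogis
#' @importFrom utils head read.delim write.table
NULL

VALID_CHANNELS <- c("DX", "RX", "PROC")

CHANNEL_PREFIX_LENGTHS <- list(
  DX   = c(1L, 2L, 3L, 5L, 6L),
  RX   = c(3L, 4L, 5L, 8L),
  PROC = c(1L, 2L, 3L, 4L, 5L)
)

#' EHR code channel
#'
#' A channel is one of the three EHR code streams: diagnoses (\code{DX},
#' ICD-10), prescriptions (\code{RX}, custom therapeutic codes) and
#' procedures (\code{PROC}). Each channel carries the set of hierarchical
#' prefix lengths tracked when code vocabularies and presence embeddings
#' are built: 1, 2, 3, 5, 6 for DX; 3, 4, 5, 8 for RX; 1--5 for PROC.
#'
#' @slot name channel identifier, one of \code{"DX"}, \code{"RX"}, \code{"PROC"}.
#' @slot prefixLengths integer vector of tracked prefix lengths.
#' @export
setClass("CodeChannel",
  representation(name = "character", prefixLengths = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!(object@name %in% VALID_CHANNELS))
      msg <- c(msg, "channel name must be one of DX, RX, PROC")
    else if (!identical(object@prefixLengths, CHANNEL_PREFIX_LENGTHS[[object@name]]))
      msg <- c(msg, sprintf("prefix lengths for %s must be {%s}", object@name,
                            paste(CHANNEL_PREFIX_LENGTHS[[object@name]], collapse = ",")))
    if (is.null(msg)) TRUE else msg
  })

#' Construct a code channel
#'
#' @param name one of \code{"DX"}, \code{"RX"}, \code{"PROC"}.
#' @return A \linkS4class{CodeChannel} object.
#' @examples
#' codeChannel("DX")
#' @export
codeChannel <- function(name) {
  name <- match.arg(toupper(name), VALID_CHANNELS)
  new("CodeChannel", name = name, prefixLengths = CHANNEL_PREFIX_LENGTHS[[name]])
}

#' @describeIn codeChannel channel name accessor.
#' @param x a \code{CodeChannel}.
#' @export
channelName <- function(x) x@name

#' @describeIn codeChannel tracked prefix length accessor.
#' @export
prefixLengths <- function(x) x@prefixLengths

setMethod("show", "CodeChannel", function(object) {
  cat(sprintf("CodeChannel %s (prefix lengths %s)\n", object@name,
              paste(object@prefixLengths, collapse = ", ")))
})

#' Code vocabulary
#'
#' The deterministic, lexicographically ordered set of full codes and
#' tracked-length prefixes observed in a code-inference (training) split.
#' Presence embeddings are indexed by these entries.
#'
#' @slot channel a \linkS4class{CodeChannel}.
#' @slot entries sorted character vector of codes and prefixes.
#' @slot sourceCount number of patient records used to build the vocabulary.
#' @slot fingerprint hash of the patient identifiers the vocabulary was
#'   fitted on (leakage guard); empty when untracked.
#' @export
setClass("CodeVocabulary",
  representation(channel = "CodeChannel", entries = "character",
                 sourceCount = "integer", fingerprint = "character"),
  prototype(fingerprint = ""),
  validity = function(object) {
    msg <- NULL
    if (any(!nzchar(object@entries))) msg <- c(msg, "vocabulary entries must be non-empty")
    if (is.unsorted(object@entries, strictly = TRUE) && length(object@entries) > 1)
      msg <- c(msg, "entries must be strictly sorted (deterministic ordering)")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "CodeVocabulary", function(object) {
  cat(sprintf("CodeVocabulary <%s>: %d entries from %d records\n",
              object@channel@name, length(object@entries), object@sourceCount))
  if (length(object@entries))
    cat("  head:", paste(head(object@entries, 6), collapse = " "), "\n")
})

#' @describeIn buildVocabulary vocabulary entry accessor.
#' @export
vocabEntries <- function(x) x@entries

setMethod("length", "CodeVocabulary", function(x) length(x@entries))

#' Odds-ratio dictionary
#'
#' Per-code cubed odds ratios estimated on the code-inference split:
#' for each full code, the ratio of the fraction of case patients whose
#' observation window contains the code to the corresponding control
#' fraction, raised to the third power. Membership semantics: a patient
#' contributes once per code regardless of within-window repetition.
#'
#' @slot channel a \linkS4class{CodeChannel}.
#' @slot ratios named nonnegative numeric vector, code -> cubed odds ratio.
#' @slot caseN,controlN numbers of case/control patients used.
#' @slot smoothing additive (Haldane--Anscombe) smoothing constant used.
#' @slot fingerprint hash of the patient identifiers fitted on.
#' @export
setClass("ORDictionary",
  representation(channel = "CodeChannel", ratios = "numeric",
                 caseN = "integer", controlN = "integer",
                 smoothing = "numeric", fingerprint = "character"),
  prototype(fingerprint = ""),
  validity = function(object) {
    msg <- NULL
    if (any(object@ratios < 0)) msg <- c(msg, "odds ratios must be nonnegative")
    if (length(object@ratios) && is.null(names(object@ratios)))
      msg <- c(msg, "ratios must be named by code")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "ORDictionary", function(object) {
  cat(sprintf("ORDictionary <%s>: %d codes (cases=%d, controls=%d, smoothing=%g)\n",
              object@channel@name, length(object@ratios),
              object@caseN, object@controlN, object@smoothing))
})

#' @describeIn fitORDictionary cubed odds-ratio accessor.
#' @export
orRatios <- function(x) x@ratios

#' Aggregation set for odds-ratio embeddings
#'
#' An ordered collection of exactly 12 summary functions that map the
#' multiset of within-window odds ratios to a fixed-length embedding.
#' Each function must accept a non-empty numeric vector; the embedding
#' of an empty window is \code{emptyValue} in every coordinate.
#'
#' @slot fns named list of 12 functions.
#' @slot emptyValue value emitted for all coordinates on an empty window.
#' @export
setClass("AggregationSet",
  representation(fns = "list", emptyValue = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@fns) != 12L) msg <- c(msg, "exactly 12 aggregation functions required")
    if (!all(vapply(object@fns, is.function, logical(1))))
      msg <- c(msg, "all aggregations must be functions")
    if (is.null(names(object@fns)) || any(!nzchar(names(object@fns))))
      msg <- c(msg, "aggregations must be named")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "AggregationSet", function(object) {
  cat("AggregationSet:", paste(names(object@fns), collapse = ", "), "\n")
})

setMethod("names", "AggregationSet", function(x) names(x@fns))

#' Observed 2x2 exposure-by-status table
#'
#' Counts of an exposure cross-tabulated against a (possibly noisy)
#' binary case/control status. Rows index exposure (exposed, unexposed);
#' columns index status (case, control): \code{a} exposed cases, \code{b}
#' exposed controls, \code{c} unexposed cases, \code{d} unexposed controls.
#'
#' @slot counts 2x2 nonnegative numeric matrix.
#' @export
setClass("NoisyTable",
  representation(counts = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (!all(dim(object@counts) == c(2L, 2L))) msg <- c(msg, "counts must be 2x2")
    else {
      if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
      if (sum(object@counts) <= 0) msg <- c(msg, "table total must be positive")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct an observed 2x2 table
#'
#' @param a,b,c,d exposed-case, exposed-control, unexposed-case and
#'   unexposed-control counts.
#' @return A \linkS4class{NoisyTable}.
#' @examples
#' noisyTable(20, 10, 5, 10)
#' @export
noisyTable <- function(a, b, c, d) {
  m <- matrix(as.numeric(c(a, b, c, d)), 2, 2, byrow = TRUE,
              dimnames = list(exposure = c("exposed", "unexposed"),
                              status = c("case", "control")))
  new("NoisyTable", counts = m)
}

#' @describeIn noisyTable raw count matrix accessor.
#' @param x a \code{NoisyTable}.
#' @export
tableCounts <- function(x) x@counts

#' @describeIn noisyTable exposure prevalence among cases, a / (a + c).
#' @export
casePrevalence <- function(x) {
  m <- x@counts
  m[1, 1] / (m[1, 1] + m[2, 1])
}

#' @describeIn noisyTable exposure prevalence among controls, b / (b + d).
#' @export
controlPrevalence <- function(x) {
  m <- x@counts
  m[1, 2] / (m[1, 2] + m[2, 2])
}

#' @describeIn noisyTable case fraction of the table, (a + c) / total.
#' @export
caseFraction <- function(x) {
  m <- x@counts
  (m[1, 1] + m[2, 1]) / sum(m)
}

setMethod("show", "NoisyTable", function(object) {
  cat("NoisyTable (exposure x status):\n")
  print(object@counts)
})

#' Label misclassification specification
#'
#' Sensitivity \code{p} = P(observed case | true case) and specificity
#' \code{q} = P(observed control | true control) of the noisy labelling
#' process, optionally with the size \code{nVal} of the validation cohort
#' from which \code{p} and \code{q} were estimated (drives the
#' extra-variance term; leave \code{NA} when p and q are known exactly).
#'
#' @slot p sensitivity in (0, 1].
#' @slot q specificity in (0, 1].
#' @slot nVal validation-cohort size (> 1) or \code{NA_real_}.
#' @export
setClass("MisclassSpec",
  representation(p = "numeric", q = "numeric", nVal = "numeric"),
  prototype(nVal = NA_real_),
  validity = function(object) {
    msg <- NULL
    if (!(object@p > 0 && object@p <= 1)) msg <- c(msg, "p must be in (0, 1]")
    if (!(object@q > 0 && object@q <= 1)) msg <- c(msg, "q must be in (0, 1]")
    if (!is.na(object@nVal) && object@nVal <= 1) msg <- c(msg, "nVal must exceed 1 when given")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a misclassification specification
#'
#' @param p label sensitivity in (0, 1].
#' @param q label specificity in (0, 1].
#' @param nVal optional validation-cohort size used to estimate p and q.
#' @return A \linkS4class{MisclassSpec}.
#' @examples
#' misclassSpec(0.9, 0.95)
#' misclassSpec(0.9, 0.95, nVal = 1000)
#' @export
misclassSpec <- function(p, q, nVal = NA_real_) {
  new("MisclassSpec", p = as.numeric(p), q = as.numeric(q), nVal = as.numeric(nVal))
}

setMethod("show", "MisclassSpec", function(object) {
  cat(sprintf("MisclassSpec: p = %g, q = %g, nVal = %s\n", object@p, object@q,
              if (is.na(object@nVal)) "known exactly" else format(object@nVal)))
})

#' Misclassification-corrected odds-ratio result
#'
#' Output of \code{\link{lambdaOR}}: the ridge-corrected 2x2 table, the
#' regularization strength used, the corrected log odds ratio, its
#' variance decomposition (sampling + misclassification-estimation), the
#' Wald statistic, two-sided p-value and confidence interval.
#'
#' @slot correctedTable corrected 2x2 count matrix T(lambda).
#' @slot lambda ridge strength used (0 when the plain inverse is feasible).
#' @slot epsilon feasibility floor applied to corrected counts.
#' @slot logOR corrected log odds ratio.
#' @slot varNaive sampling variance of the corrected log odds ratio;
#'   reduces to 1/a + 1/b + 1/c + 1/d for noiseless labels.
#' @slot varExtra extra variance from estimated sensitivity/specificity.
#' @slot varTotal \code{varNaive + varExtra}.
#' @slot z,pTwoSided Wald statistic and two-sided normal p-value.
#' @slot ciLow,ciHigh (1 - alpha) confidence limits for the log odds ratio.
#' @slot alpha nominal test level.
#' @slot feasible whether a feasible lambda was found; when \code{FALSE}
#'   all estimate slots are \code{NA}.
#' @export
setClass("LambdaORResult",
  representation(correctedTable = "matrix", lambda = "numeric", epsilon = "numeric",
                 logOR = "numeric", varNaive = "numeric", varExtra = "numeric",
                 varTotal = "numeric", z = "numeric", pTwoSided = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", alpha = "numeric",
                 feasible = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@feasible) {
      if (!isTRUE(all.equal(object@varTotal, object@varNaive + object@varExtra)))
        msg <- c(msg, "varTotal must equal varNaive + varExtra")
      if (!is.na(object@logOR) &&
          !(object@ciLow <= object@logOR && object@logOR <= object@ciHigh))
        msg <- c(msg, "confidence interval must bracket the estimate")
    }
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "LambdaORResult", function(object) {
  if (!object@feasible) {
    cat("LambdaORResult: infeasible (no lambda keeps all corrected counts above epsilon)\n")
    return(invisible(NULL))
  }
  cat(sprintf("LambdaORResult: log OR = %.4f (lambda = %.4g, eps = %g)\n",
              object@logOR, object@lambda, object@epsilon))
  cat(sprintf("  var = %.4g (naive %.4g + extra %.4g); Z = %.3f, p = %.3g\n",
              object@varTotal, object@varNaive, object@varExtra,
              object@z, object@pTwoSided))
  cat(sprintf("  %g%% CI [%.4f, %.4f]\n", 100 * (1 - object@alpha),
              object@ciLow, object@ciHigh))
})

#' @describeIn lambdaOR corrected log odds-ratio accessor.
#' @export
logOR <- function(x) x@logOR

#' Stacked risk-score ensemble
#'
#' Six gradient-boosted base learners (presence and odds-ratio blocks for
#' DX, RX, PROC) whose out-of-fold scores, together with sex and age, feed
#' a final meta classifier producing a risk score in [0, 1].
#'
#' @slot baseModels named list of six fitted base boosters.
#' @slot metaModel fitted meta classifier.
#' @slot metaMethod \code{"xgboost"} or \code{"logistic"}.
#' @slot manifest training manifest: per-block feature names, training
#'   fingerprint, seed, package version.
#' @export
setClass("RiskEnsemble",
  representation(baseModels = "list", metaModel = "ANY",
                 metaMethod = "character", manifest = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@baseModels) != 6L)
      msg <- c(msg, "an ensemble carries exactly six base models")
    if (!object@metaMethod %in% c("xgboost", "logistic"))
      msg <- c(msg, "metaMethod must be 'xgboost' or 'logistic'")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "RiskEnsemble", function(object) {
  cat("RiskEnsemble: 6 base models ->", object@metaMethod, "meta classifier\n")
  cat("  blocks:", paste(names(object@baseModels), collapse = ", "), "\n")
  cat("  seed:", object@manifest$seed, "\n")
})

#' Synthetic cohort configuration
#'
#' Generative parameters for the synthetic EHR cohort: design counts,
#' per-channel vocabulary sizes and mean background code loads, planted
#' per-code class-conditional window rates, demographics, window/horizon
#' geometry and optional label-noise rates. The defaults describe the
#' study conditions exercised throughout the package: 2,000 cases and
#' 20,000 controls with 30 planted codes at case/control rate ratios
#' between 2 and 4.
#'
#' @slot nCase,nControl design numbers of true cases and controls.
#' @slot vocabSize named integer vector of background vocabulary sizes.
#' @slot meanCodes named numeric vector of mean background codes per
#'   patient window, per channel.
#' @slot plantedEffects data.frame(channel, code, rateCase, rateControl).
#' @slot labelNoise numeric c(p, q) or NA for noiseless labels.
#' @slot ageMeanCase,ageMeanControl,ageSD age-at-index distribution (years).
#' @slot femaleProb probability of female sex.
#' @slot horizonYears prediction horizon used for case geometry.
#' @slot windowWeeks observation-window length in weeks.
#' @slot excludeRate fraction of controls given an exclusion-list code.
#' @slot rxOnlyCaseRate fraction of cases whose only ADRD evidence is an
#'   anti-dementia prescription.
#' @slot seed mandatory RNG seed.
#' @export
setClass("SimConfig",
  representation(nCase = "integer", nControl = "integer",
                 vocabSize = "integer", meanCodes = "numeric",
                 plantedEffects = "data.frame", labelNoise = "numeric",
                 ageMeanCase = "numeric", ageMeanControl = "numeric",
                 ageSD = "numeric", femaleProb = "numeric",
                 horizonYears = "numeric", windowWeeks = "numeric",
                 excludeRate = "numeric", rxOnlyCaseRate = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    pe <- object@plantedEffects
    if (!all(c("channel", "code", "rateCase", "rateControl") %in% names(pe)))
      msg <- c(msg, "plantedEffects needs columns channel, code, rateCase, rateControl")
    else if (nrow(pe) && (any(pe$rateCase < 0 | pe$rateCase > 1) ||
                          any(pe$rateControl < 0 | pe$rateControl > 1)))
      msg <- c(msg, "planted rates must lie in [0, 1]")
    if (!all(names(object@vocabSize) %in% VALID_CHANNELS))
      msg <- c(msg, "vocabSize must be named by channel")
    if (length(object@seed) != 1L || is.na(object@seed))
      msg <- c(msg, "seed is mandatory")
    if (!all(is.na(object@labelNoise)) &&
        (length(object@labelNoise) != 2L || any(object@labelNoise <= 0 | object@labelNoise > 1)))
      msg <- c(msg, "labelNoise must be c(p, q) with both in (0, 1]")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d cases / %d controls, %d planted codes, seed %d\n",
              object@nCase, object@nControl, nrow(object@plantedEffects),
              object@seed))
})
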