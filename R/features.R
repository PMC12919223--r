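#' Default aggregation set for odds-ratio embeddings
#'
#' Twelve multiset summaries spanning location, scale and extremes:
#' min, max, mean, median, standard deviation (0 for singletons), sum,
#' count, the 10th/25th/75th/90th percentiles and the geometric mean.
#' Every coordinate of the embedding of an empty window is
#' \code{emptyValue} (default 0, neutral under tree models).
#'
#' @param emptyValue value emitted for empty windows.
#' @return An \linkS4class{AggregationSet}.
#' @export
defaultAggregations <- function(emptyValue = 0) {
  fns <- list(
    min    = min,
    max    = max,
    mean   = mean,
    median = median,
    sd     = function(x) if (length(x) < 2L) 0 else sd(x),
    sum    = sum,
    count  = length,
    p10    = function(x) unname(quantile(x, 0.10)),
    p25    = function(x) unname(quantile(x, 0.25)),
    p75    = function(x) unname(quantile(x, 0.75)),
    p90    = function(x) unname(quantile(x, 0.90)),
    gmean  = function(x) exp(mean(log(pmax(x, .Machine$double.xmin))))
  )
  new("AggregationSet", fns = fns, emptyValue = emptyValue)
}

#' Binary presence vector of an observation window
#'
#' Bit i is 1 iff vocabulary entry i is a window code or a
#' tracked-length prefix of a window code. Codes absent from the
#' vocabulary contribute only through their in-vocabulary prefixes, so a
#' fully unseen code yields an all-zero vector. Hierarchy consistency
#' follows by construction: if a full code's bit is set, so are the bits
#' of its tracked prefixes present in the vocabulary.
#'
#' @param window character vector of window codes for the channel.
#' @param vocab a \linkS4class{CodeVocabulary}.
#' @return Named integer 0/1 vector over vocabulary entries.
#' @export
computePresence <- function(window, vocab) {
  stopifnot(is(vocab, "CodeVocabulary"))
  v <- integer(length(vocab@entries))
  names(v) <- vocab@entries
  if (length(window)) {
    present <- expandPrefixSet(window, vocab@channel)
    v[names(v) %in% present] <- 1L
  }
  v
}

# sparse patients x entries presence matrix over a list of windows
presenceMatrix <- function(windows, vocab) {
  entries <- vocab@entries
  np <- length(windows)
  ii <- vector("list", np)
  for (k in seq_len(np)) {
    w <- windows[[k]]
    if (!length(w)) next
    hit <- match(expandPrefixSet(w, vocab@channel), entries)
    ii[[k]] <- hit[!is.na(hit)]
  }
  lens <- lengths(ii)
  Matrix::sparseMatrix(i = rep.int(seq_len(np), lens),
                       j = unlist(ii, use.names = FALSE),
                       x = 1,
                       dims = c(np, length(entries)),
                       dimnames = list(names(windows), entries))
}

#' Fit a per-code cubed odds-ratio dictionary
#'
#' For each full code observed in the labeled inference split (prefixes
#' are not scored), the fraction of case patients whose window contains
#' the code is divided by the corresponding control fraction, and the
#' ratio is cubed. Fractions use additive (Haldane--Anscombe) smoothing:
#' \code{(k + s) / (n + 2s)} with smoothing constant \code{s}.
#'
#' @param windows list of per-patient code vectors for one channel.
#' @param labels logical or 0/1 vector, TRUE/1 = case, aligned with
#'   \code{windows}.
#' @param channel a \linkS4class{CodeChannel}.
#' @param smoothing additive smoothing constant (default 0.5).
#' @param fingerprint optional split fingerprint for leakage checks.
#' @return An \linkS4class{ORDictionary}.
#' @examples
#' fitORDictionary(list(c("E11"), c("E11"), c("I10"), character(0)),
#'                 c(1, 1, 0, 0), codeChannel("DX"))
#' @export
fitORDictionary <- function(windows, labels, channel, smoothing = 0.5,
                            fingerprint = "") {
  stopifnot(is(channel, "CodeChannel"), length(windows) == length(labels))
  y <- as.logical(labels)
  nCase <- sum(y); nCtl <- sum(!y)
  if (nCase == 0L || nCtl == 0L)
    stop("odds-ratio dictionary needs at least one case and one control")
  # membership semantics: one count per patient per code
  codeOf <- function(w) unique(w)
  caseCodes <- unlist(lapply(windows[y], codeOf), use.names = FALSE)
  ctlCodes <- unlist(lapply(windows[!y], codeOf), use.names = FALSE)
  codes <- sortC(c(caseCodes, ctlCodes))
  kCase <- table(factor(caseCodes, levels = codes))
  kCtl <- table(factor(ctlCodes, levels = codes))
  fCase <- (as.numeric(kCase) + smoothing) / (nCase + 2 * smoothing)
  fCtl <- (as.numeric(kCtl) + smoothing) / (nCtl + 2 * smoothing)
  ratios <- setNames((fCase / fCtl)^3, codes)
  new("ORDictionary", channel = channel, ratios = ratios,
      caseN = as.integer(nCase), controlN = as.integer(nCtl),
      smoothing = smoothing, fingerprint = fingerprint)
}

#' Odds-ratio embedding of an observation window
#'
#' Collects the dictionary odds ratios of the distinct window codes
#' found in the dictionary (within-window repetition is ignored) and
#' applies each of the 12 aggregation functions. An empty collection
#' yields the aggregation set's declared empty value in every
#' coordinate.
#'
#' @param window character vector of window codes.
#' @param orDict an \linkS4class{ORDictionary}.
#' @param aggs an \linkS4class{AggregationSet}.
#' @return Named numeric vector of length 12.
#' @export
computeOREmbedding <- function(window, orDict, aggs = defaultAggregations()) {
  stopifnot(is(orDict, "ORDictionary"), is(aggs, "AggregationSet"))
  vals <- orDict@ratios[unique(window)]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    return(setNames(rep(aggs@emptyValue, length(aggs@fns)), names(aggs@fns)))
  vapply(aggs@fns, function(f) as.numeric(f(vals)), numeric(1))
}

orEmbeddingMatrix <- function(windows, orDict, aggs = defaultAggregations()) {
  m <- t(vapply(windows, computeOREmbedding, numeric(length(aggs@fns)),
                orDict = orDict, aggs = aggs))
  rownames(m) <- names(windows)
  m
}

#' Assemble the per-patient feature bundle
#'
#' Builds the six feature blocks (presence and odds-ratio embedding for
#' DX, RX, PROC) for a set of patients and returns them as a
#' \code{SummarizedExperiment} with features as rows and patients as
#' columns. \code{rowData} carries the block assignment; \code{colData}
#' carries sex, age at index and (optionally) labels. Block order is
#' fixed: DX, RX, PROC presence, then DX, RX, PROC odds-ratio
#' embeddings.
#'
#' Leakage guard: when \code{evalIds} is supplied (the evaluation-split
#' patient identifiers), assembly refuses vocabularies or dictionaries
#' whose fingerprint matches a split containing any of those patients.
#'
#' @param windows named list (by patient id) of per-channel code sets,
#'   as produced by \code{\link{buildCohort}}.
#' @param sex character vector ("male"/"female") aligned with windows.
#' @param age numeric ages at index, aligned with windows.
#' @param vocabs named list of \linkS4class{CodeVocabulary} (DX, RX, PROC).
#' @param orDicts named list of \linkS4class{ORDictionary} (DX, RX, PROC).
#' @param aggs an \linkS4class{AggregationSet}.
#' @param labels optional 0/1 or logical labels for colData.
#' @param evalIds optional evaluation-split patient ids for the leakage
#'   guard.
#' @return A \code{SummarizedExperiment} (features x patients, sparse
#'   assay \code{"X"}).
#' @export
assembleFeatures <- function(windows, sex, age, vocabs, orDicts,
                             aggs = defaultAggregations(), labels = NULL,
                             evalIds = NULL) {
  stopifnot(all(VALID_CHANNELS %in% names(vocabs)),
            all(VALID_CHANNELS %in% names(orDicts)),
            length(sex) == length(windows), length(age) == length(windows))
  for (ch in VALID_CHANNELS) {
    if (vocabs[[ch]]@channel@name != ch || orDicts[[ch]]@channel@name != ch)
      stop("channel mismatch in vocabularies or dictionaries for ", ch)
  }
  if (!is.null(evalIds)) {
    evalFp <- splitFingerprint(evalIds)
    fps <- c(vapply(vocabs, function(v) v@fingerprint, character(1)),
             vapply(orDicts, function(d) d@fingerprint, character(1)))
    fps <- fps[nzchar(fps)]
    if (any(fps == evalFp))
      stop("leakage guard: vocabularies/dictionaries were fitted on the evaluation split")
  }
  blocks <- list()
  blockOf <- character(0)
  for (ch in VALID_CHANNELS) {
    wch <- lapply(windows, `[[`, ch)
    m <- presenceMatrix(wch, vocabs[[ch]])
    colnames(m) <- paste0(ch, "_presence:", colnames(m))
    blocks[[paste0(ch, "_presence")]] <- m
    blockOf <- c(blockOf, rep(paste0(ch, "_presence"), ncol(m)))
  }
  for (ch in VALID_CHANNELS) {
    wch <- lapply(windows, `[[`, ch)
    m <- orEmbeddingMatrix(wch, orDicts[[ch]], aggs)
    colnames(m) <- paste0(ch, "_or:", colnames(m))
    blocks[[paste0(ch, "_or")]] <- Matrix::Matrix(m, sparse = TRUE)
    blockOf <- c(blockOf, rep(paste0(ch, "_or"), ncol(m)))
  }
  X <- Matrix::t(Reduce(Matrix::cbind2, lapply(unname(blocks), function(m)
    methods::as(m, "CsparseMatrix"))))  # features x patients
  if (any(!is.finite(X@x))) stop("non-finite feature values")
  cd <- S4Vectors::DataFrame(patient_id = names(windows),
                             sex = sex, age_at_index = age)
  if (!is.null(labels)) cd$label <- as.integer(as.logical(labels))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(X = X),
    rowData = S4Vectors::DataFrame(block = blockOf),
    colData = cd)
  S4Vectors::metadata(se)$manifest <- featureManifest(se)
  se
}

# per-block feature-name fingerprints; the ensemble refuses bundles whose
# manifest differs from its training manifest
featureManifest <- function(se) {
  blocks <- SummarizedExperiment::rowData(se)$block
  rn <- rownames(se)
  lapply(split(rn, blocks), splitFingerprint)
}
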