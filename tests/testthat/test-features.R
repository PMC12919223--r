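dxVocab <- new("CodeVocabulary", channel = codeChannel("DX"),
               entries = c("E", "E11", "E119", "I10"), sourceCount = 2L,
               fingerprint = "")

test_that("presence bits mark window codes and their tracked prefixes", {
  expect_identical(unname(computePresence("E119", dxVocab)), c(1L, 1L, 1L, 0L))
  expect_identical(unname(computePresence(character(0), dxVocab)),
                   rep(0L, 4L))
  # fully unseen code (no prefix in vocabulary) contributes nothing
  expect_identical(unname(computePresence("K21", dxVocab)), rep(0L, 4L))
  # partially seen code contributes through its in-vocabulary prefixes
  expect_identical(unname(computePresence("E66", dxVocab)), c(1L, 0L, 0L, 0L))
})

test_that("presence vectors satisfy hierarchy-bit implication", {
  set.seed(8)
  fx <- smallCohort()
  wins <- lapply(fx$cohort$windows[1:80], `[[`, "DX")
  vocab <- buildVocabulary(wins, codeChannel("DX"))
  M <- adscreen:::presenceMatrix(wins, vocab)
  ent <- vocabEntries(vocab)
  for (j in seq_along(ent)) {
    lens <- prefixLengths(codeChannel("DX"))
    lens <- lens[lens < nchar(ent[j])]
    if (!length(lens)) next
    pre <- substring(ent[j], 1, lens)
    pre <- pre[pre %in% ent]
    if (!length(pre)) next
    on <- M[, j] == 1
    for (p in pre) expect_true(all(M[on, ent == p] == 1))
  }
})

test_that("odds-ratio dictionaries cube smoothed patient-fraction ratios", {
  ch <- codeChannel("DX")
  # 50% of cases vs 25% of controls, no smoothing: 2^3 = 8
  wins <- list(c("E11"), character(0), c("E11"), character(0),
               character(0), character(0))
  d <- fitORDictionary(wins, c(1, 1, 0, 0, 0, 0), ch, smoothing = 0)
  expect_equal(unname(orRatios(d)["E11"]), 8)
  # equal prevalence: identity
  d2 <- fitORDictionary(list("I10", "I10"), c(1, 0), ch, smoothing = 0)
  expect_equal(unname(orRatios(d2)["I10"]), 1)
  # 3/10 cases vs 1/20 controls with smoothing 0.5 (hand arithmetic)
  wins3 <- c(replicate(3, "K21", simplify = FALSE), replicate(7, character(0), simplify = FALSE),
             replicate(1, "K21", simplify = FALSE), replicate(19, character(0), simplify = FALSE))
  y3 <- c(rep(1, 10), rep(0, 20))
  d3 <- fitORDictionary(wins3, y3, ch, smoothing = 0.5)
  expect_equal(unname(orRatios(d3)["K21"]), ((3.5 / 11) / (1.5 / 21))^3,
               tolerance = 1e-12)
  expect_equal(unname(orRatios(d3)["K21"]), 88.39, tolerance = 1e-4)
  expect_error(fitORDictionary(wins3, rep(1, 30), ch), "at least one case")
})

test_that("cubing preserves the ranking of uncubed ratios", {
  set.seed(12)
  ch <- codeChannel("DX")
  for (r in 1:20) {
    nCase <- sample(5:30, 1); nCtl <- sample(5:30, 1)
    mk <- function(k, n, code) c(replicate(k, code, simplify = FALSE),
                                 replicate(n - k, character(0), simplify = FALSE))
    k1 <- sample(0:nCase, 1); k2 <- sample(0:nCtl, 1)
    k3 <- sample(0:nCase, 1); k4 <- sample(0:nCtl, 1)
    wins <- c(mapply(function(a, b) unique(c(a, b)),
                     mk(k1, nCase, "A01"), mk(k3, nCase, "B01"), SIMPLIFY = FALSE),
              mapply(function(a, b) unique(c(a, b)),
                     mk(k2, nCtl, "A01"), mk(k4, nCtl, "B01"), SIMPLIFY = FALSE))
    y <- c(rep(1, nCase), rep(0, nCtl))
    d <- fitORDictionary(wins, y, ch, smoothing = 0.5)
    raw1 <- ((k1 + 0.5) / (nCase + 1)) / ((k2 + 0.5) / (nCtl + 1))
    raw2 <- ((k3 + 0.5) / (nCase + 1)) / ((k4 + 0.5) / (nCtl + 1))
    expect_identical(orRatios(d)[["A01"]] > orRatios(d)[["B01"]], raw1 > raw2)
  }
})

test_that("odds-ratio embeddings aggregate the window's dictionary values", {
  ch <- codeChannel("DX")
  d <- new("ORDictionary", channel = ch,
           ratios = c(A01 = 1, B01 = 8, C01 = 27), caseN = 10L,
           controlN = 10L, smoothing = 0.5, fingerprint = "")
  aggs <- defaultAggregations()
  single <- computeOREmbedding("B01", d, aggs)
  expect_equal(unname(single[c("min", "max", "mean", "median")]),
               rep(8, 4))
  expect_equal(unname(computeOREmbedding(character(0), d, aggs)),
               rep(0, 12))
  e <- computeOREmbedding(c("A01", "B01", "C01"), d, aggs)
  expect_equal(unname(e[c("mean", "max", "min", "sum", "count")]),
               c(12, 27, 1, 36, 3))
  # duplicates within a window contribute once (membership semantics)
  expect_equal(computeOREmbedding(c("B01", "B01", "A01"), d, aggs),
               computeOREmbedding(c("A01", "B01"), d, aggs))
  # unknown codes contribute only through nothing (skipped)
  expect_equal(computeOREmbedding(c("ZZZ"), d, aggs),
               computeOREmbedding(character(0), d, aggs))
})

test_that("aggregation sets must have exactly 12 named functions", {
  expect_error(new("AggregationSet", fns = list(min = min), emptyValue = 0),
               "12")
  expect_identical(length(names(defaultAggregations())), 12L)
})

test_that("assembled feature bundles are deterministic, shaped and guarded", {
  fx <- smallCohort()
  co <- fx$cohort
  tab <- co$table
  y <- as.integer(tab$label == "case")
  n <- nrow(tab)
  trIdx <- seq_len(n) <= floor(0.7 * n)
  trIds <- tab$patient_id[trIdx]; teIds <- tab$patient_id[!trIdx]
  fp <- splitFingerprint(trIds)
  wtr <- co$windows[trIdx]
  vocabs <- lapply(CHS, function(ch)
    buildVocabulary(lapply(wtr, `[[`, ch), codeChannel(ch), fingerprint = fp))
  dicts <- lapply(CHS, function(ch)
    fitORDictionary(lapply(wtr, `[[`, ch), y[trIdx], codeChannel(ch),
                    fingerprint = fp))
  se <- assembleFeatures(wtr, tab$sex[trIdx], tab$age_at_index[trIdx],
                         vocabs, dicts, labels = y[trIdx], evalIds = teIds)
  expect_identical(ncol(se), sum(trIdx))
  expect_identical(nrow(se), sum(vapply(vocabs, length, 1L)) + 3L * 12L)
  blocks <- SummarizedExperiment::rowData(se)$block
  expect_identical(unique(blocks),
                   c("DX_presence", "RX_presence", "PROC_presence",
                     "DX_or", "RX_or", "PROC_or"))
  # determinism and invariance to within-window code order
  wtr2 <- lapply(wtr, function(w) lapply(w, rev))
  se2 <- assembleFeatures(wtr2, tab$sex[trIdx], tab$age_at_index[trIdx],
                          vocabs, dicts, labels = y[trIdx])
  expect_equal(as.matrix(SummarizedExperiment::assay(se, "X")),
               as.matrix(SummarizedExperiment::assay(se2, "X")))
  # leakage guard: dictionaries fitted on the evaluation split are refused
  badDicts <- dicts
  badDicts$DX@fingerprint <- splitFingerprint(teIds)
  expect_error(assembleFeatures(wtr, tab$sex[trIdx], tab$age_at_index[trIdx],
                                vocabs, badDicts, evalIds = teIds),
               "leakage")
  # channel mismatch is refused
  swapped <- vocabs; swapped$DX <- vocabs$RX
  expect_error(assembleFeatures(wtr, tab$sex[trIdx], tab$age_at_index[trIdx],
                                swapped, dicts), "channel mismatch")
})

test_that("vocabulary and dictionary serialization round-trips", {
  fx <- smallCohort()
  wins <- lapply(fx$cohort$windows[1:50], `[[`, "DX")
  v <- buildVocabulary(wins, codeChannel("DX"))
  d <- tempfile(); dir.create(d)
  path <- writeVocabulary(v, d)
  expect_match(basename(path), "DX")
  v2 <- readVocabulary(path)
  expect_identical(vocabEntries(v2), vocabEntries(v))
  expect_identical(channelName(v2@channel), "DX")
})
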