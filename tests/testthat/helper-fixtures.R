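# shared fixtures and independent oracles

CHS <- setNames(c("DX", "RX", "PROC"), c("DX", "RX", "PROC"))

makePatient <- function(id = "p1", sex = "female", birth_week = -3000L,
                        end_week = 600L, channel = character(0),
                        code = character(0), week = integer(0)) {
  ev <- data.frame(channel = channel, code = code, week = as.integer(week),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$week), , drop = FALSE]
  list(patient_id = id, sex = sex, birth_week = as.integer(birth_week),
       record_end_week = as.integer(end_week), events = ev)
}

# small end-to-end synthetic cohort reused across tests
smallCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generateCohort(simConfig(nCase = 150L, nControl = 700L, seed = 11L))
      cache <<- list(gen = g,
                     cohort = buildCohort(g$patients, defaultCaseDefinition()))
    }
    cache
  }
})

# compact feature bundle for ensemble tests, built once
ensembleFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    fx <- smallCohort()
    co <- fx$cohort
    tab <- co$table
    y <- as.integer(tab$label == "case")
    n <- nrow(tab)
    set.seed(61)
    trIdx <- sample(c(rep(TRUE, round(0.7 * n)), rep(FALSE, n - round(0.7 * n))))
    fp <- splitFingerprint(tab$patient_id[trIdx])
    wtr <- co$windows[trIdx]
    vocabs <- lapply(CHS, function(ch)
      buildVocabulary(lapply(wtr, `[[`, ch), codeChannel(ch), fingerprint = fp))
    dicts <- lapply(CHS, function(ch)
      fitORDictionary(lapply(wtr, `[[`, ch), y[trIdx], codeChannel(ch),
                      fingerprint = fp))
    seTr <- assembleFeatures(wtr, tab$sex[trIdx], tab$age_at_index[trIdx],
                             vocabs, dicts, labels = y[trIdx])
    seTe <- assembleFeatures(co$windows[!trIdx], tab$sex[!trIdx],
                             tab$age_at_index[!trIdx], vocabs, dicts,
                             labels = y[!trIdx])
    cache <<- list(seTr = seTr, seTe = seTe, yTr = y[trIdx], yTe = y[!trIdx],
                   tab = tab, trIdx = trIdx)
    cache
  }
})

# O(n^2) pairwise-concordance oracle for the AUC
aucPairOracle <- function(scores, labels) {
  y <- as.logical(labels)
  cs <- scores[y]; ct <- scores[!y]
  tot <- 0
  for (s in cs) tot <- tot + sum(s > ct) + 0.5 * sum(s == ct)
  tot / (length(cs) * length(ct))
}

# corrected-table entries over a vector of lambdas, closed form
tableEntriesAt <- function(tab, spec, lambdas) {
  m <- tableCounts(tab)
  p <- spec@p; q <- spec@q
  det <- (p + lambdas) * (q + lambdas) - (1 - p) * (1 - q)
  e11 <- (m[1, 1] * (q + lambdas) - m[1, 2] * (1 - q)) / det
  e12 <- (-m[1, 1] * (1 - p) + m[1, 2] * (p + lambdas)) / det
  e21 <- (m[2, 1] * (q + lambdas) - m[2, 2] * (1 - q)) / det
  e22 <- (-m[2, 1] * (1 - p) + m[2, 2] * (p + lambdas)) / det
  pmin(pmin(e11, e12), pmin(e21, e22))
}

# staged dense-grid oracle for the minimal feasible ridge strength
gridMinLambdaOracle <- function(tab, spec, epsilon = 0.5,
                                lambdaMax = 10 * max(tableCounts(tab)),
                                points = 2000L, stages = 4L) {
  lo <- 0; hi <- lambdaMax
  for (s in seq_len(stages)) {
    grid <- seq(lo, hi, length.out = points)
    feas <- tableEntriesAt(tab, spec, grid) >= epsilon
    if (!any(feas)) return(NA_real_)
    k <- which(feas)[1]
    if (k == 1L) return(grid[1])
    lo <- grid[k - 1L]; hi <- grid[k]
  }
  hi
}

# simulate one noisy 2x2 table with known true log OR and label noise
simulateNoisyTable <- function(theta, p, q, n = 50000L,
                               controlExposure = 0.3) {
  odds0 <- controlExposure / (1 - controlExposure)
  pe1 <- odds0 * exp(theta) / (1 + odds0 * exp(theta))
  nCase <- n %/% 2L; nCtl <- n - nCase
  a <- rbinom(1L, nCase, pe1); cc <- nCase - a
  b <- rbinom(1L, nCtl, controlExposure); d <- nCtl - b
  aObs <- rbinom(1L, a, p) + rbinom(1L, b, 1 - q)
  cObs <- rbinom(1L, cc, p) + rbinom(1L, d, 1 - q)
  noisyTable(aObs, a + b - aObs, cObs, cc + d - cObs)
}
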