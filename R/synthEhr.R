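#' Default case/exclusion code lists for the synthetic cohort
#'
#' Stand-in phenotype lists used by the generator and the worked
#' examples: ADRD diagnosis prefixes (dementia ICD-10 families),
#' an anti-dementia prescription stem, a control exclusion family and a
#' comorbidity list drawn from the planted risk codes. Real analyses
#' supply their own lists via \code{\link{caseDefinition}}.
#'
#' @return A \code{\link{caseDefinition}}.
#' @export
defaultCaseDefinition <- function() {
  caseDefinition(
    adrdDx = c("F01", "F02", "F03", "G30"),
    antiDementiaRx = "rxNCH",
    exclusion = c("G31", "F04"),
    comorbidity = c("I10", "E11", "I25", "I50", "I63", "F32"))
}

defaultPlantedEffects <- function() {
  dxCodes <- c("I10", "E11", "F32", "I25", "I50", "I63", "J44", "M80",
               "G47", "E66", "E78", "H90", "K21", "N18")
  rxCodes <- c("rxCHD1", "rxAAA2", "rxBXA1", "rxNSA3", "rxCVB1", "rxDER2",
               "rxGIA1", "rxHOR4")
  procCodes <- c("9920", "8501", "7301", "4512", "9341", "0051", "3127", "8872")
  codes <- c(dxCodes, rxCodes, procCodes)
  nn <- length(codes)
  # deterministic spread of control rates 0.05-0.16 and ratios 2-4
  rateControl <- 0.05 + 0.11 * (seq_len(nn) - 1) / (nn - 1)
  ratio <- 2 + 2 * ((seq_len(nn) * 7) %% 11) / 10
  data.frame(channel = c(rep("DX", length(dxCodes)),
                         rep("RX", length(rxCodes)),
                         rep("PROC", length(procCodes))),
             code = codes,
             rateCase = pmin(rateControl * ratio, 0.95),
             rateControl = rateControl,
             stringsAsFactors = FALSE)
}

backgroundVocab <- function(channel, n) {
  switch(channel,
         DX   = sprintf("B%03d", seq_len(n)),
         RX   = paste0("rxB", LETTERS[(seq_len(n) - 1) %% 26 + 1],
                       LETTERS[(seq_len(n) - 1) %/% 26 + 1],
                       (seq_len(n) - 1) %% 4 + 1),
         PROC = sprintf("%04d", 1000 + seq_len(n)))
}

#' Synthetic cohort configuration constructor
#'
#' See \linkS4class{SimConfig} for slot semantics. Defaults define the
#' package's reference study conditions: 2,000 cases and 20,000
#' controls, 30 planted codes with case/control rate ratios of 2--4,
#' per-channel background vocabularies, a 1-year horizon with a 2-year
#' (104-week) observation window, and noiseless labels.
#'
#' @param nCase,nControl true case/control design counts.
#' @param vocabSize named background vocabulary sizes per channel.
#' @param meanCodes named mean background codes per window per channel.
#' @param plantedEffects data.frame(channel, code, rateCase, rateControl).
#' @param labelNoise c(p, q) or NA (noiseless).
#' @param ageMeanCase,ageMeanControl,ageSD age-at-index model (years).
#' @param femaleProb probability of female sex.
#' @param horizonYears,windowWeeks cohort geometry.
#' @param excludeRate fraction of controls carrying an exclusion code.
#' @param rxOnlyCaseRate fraction of cases with prescription-only ADRD
#'   evidence.
#' @param seed mandatory RNG seed.
#' @return A \linkS4class{SimConfig}.
#' @export
simConfig <- function(nCase = 2000L, nControl = 20000L,
                      vocabSize = c(DX = 150L, RX = 80L, PROC = 100L),
                      meanCodes = c(DX = 8, RX = 4, PROC = 5),
                      plantedEffects = defaultPlantedEffects(),
                      labelNoise = NA_real_,
                      ageMeanCase = 74, ageMeanControl = 71, ageSD = 8,
                      femaleProb = 0.55,
                      horizonYears = 1, windowWeeks = 104,
                      excludeRate = 0.02, rxOnlyCaseRate = 0.15,
                      seed = 1L) {
  new("SimConfig", nCase = as.integer(nCase), nControl = as.integer(nControl),
      vocabSize = vapply(vocabSize, as.integer, integer(1)),
      meanCodes = meanCodes, plantedEffects = plantedEffects,
      labelNoise = as.numeric(labelNoise),
      ageMeanCase = ageMeanCase, ageMeanControl = ageMeanControl,
      ageSD = ageSD, femaleProb = femaleProb,
      horizonYears = horizonYears, windowWeeks = windowWeeks,
      excludeRate = excludeRate, rxOnlyCaseRate = rxOnlyCaseRate,
      seed = as.integer(seed))
}

#' Generate a synthetic EHR cohort with known ground truth
#'
#' Simulates per-patient timed code streams in the three channels.
#' Every patient gets an anchor DX code at week 0 (the record clock's
#' origin). Planted codes enter the observation window independently
#' with their class-conditional rates; background codes arrive at
#' channel-specific Poisson loads, mostly inside the window with a
#' pre-window remainder exercising window extraction. True cases
#' receive ADRD-defining evidence (a dementia diagnosis code or, for a
#' configurable fraction, an anti-dementia prescription only) placed
#' \code{max(1, horizon)} years after the index date, so cohort
#' labeling recovers the generative truth; a small fraction of controls
#' carry an exclusion-list code. Output is deterministic given the
#' seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list(patients, truth): patients as used by
#'   \code{\link{buildCohort}}; truth with per-patient true labels, the
#'   planted per-code odds ratios implied by the rates, and the
#'   configured label-noise rates.
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed)
  pe <- config@plantedEffects
  if (nrow(pe) && (any(pe$rateCase < 0 | pe$rateCase > 1) ||
                   any(pe$rateControl < 0 | pe$rateControl > 1)))
    stop("planted rates must lie in [0, 1]")
  bg <- lapply(setNames(VALID_CHANNELS, VALID_CHANNELS), function(ch)
    backgroundVocab(ch, config@vocabSize[[ch]]))
  n <- config@nCase + config@nControl
  isCase <- c(rep(TRUE, config@nCase), rep(FALSE, config@nControl))
  adrdDxPool <- c("G300", "G309", "F03", "F019")
  patients <- vector("list", n)
  ww <- config@windowWeeks
  hzw <- max(1, config@horizonYears) * WEEKS_PER_YEAR
  for (i in seq_len(n)) {
    case <- isCase[i]
    if (case) {
      indexWeek <- sample(156:364, 1L)
      adrdWeek <- indexWeek + hzw
      endWeek <- adrdWeek + sample(0:52, 1L)
    } else {
      endWeek <- sample(364:520, 1L)
      indexWeek <- endWeek - max(2, config@horizonYears + 1) * WEEKS_PER_YEAR
    }
    winStart <- indexWeek - ww
    chans <- "DX"; codes <- "Z00"; weeks <- 0L
    for (ch in VALID_CHANNELS) {
      rates <- if (case) pe$rateCase else pe$rateControl
      sel <- pe$channel == ch & runif(nrow(pe)) < rates
      planted <- pe$code[sel]
      nbgIn <- rpois(1L, config@meanCodes[[ch]])
      bgIn <- sample(bg[[ch]], min(nbgIn, length(bg[[ch]])))
      inWin <- c(planted, bgIn)
      if (length(inWin)) {
        chans <- c(chans, rep(ch, length(inWin)))
        codes <- c(codes, inWin)
        weeks <- c(weeks, sample(winStart:(indexWeek - 1L), length(inWin),
                                 replace = TRUE))
      }
      nbgOut <- rpois(1L, config@meanCodes[[ch]] * 0.5)
      if (nbgOut > 0L && winStart > 1L) {
        bgOut <- sample(bg[[ch]], min(nbgOut, length(bg[[ch]])))
        chans <- c(chans, rep(ch, length(bgOut)))
        codes <- c(codes, bgOut)
        weeks <- c(weeks, sample(1:(winStart - 1L), length(bgOut),
                                 replace = TRUE))
      }
    }
    if (case) {
      rxOnly <- runif(1) < config@rxOnlyCaseRate
      chans <- c(chans, if (rxOnly) "RX" else "DX")
      codes <- c(codes, if (rxOnly) "rxNCH1" else sample(adrdDxPool, 1L))
      weeks <- c(weeks, adrdWeek)
    } else if (runif(1) < config@excludeRate) {
      chans <- c(chans, "DX")
      codes <- c(codes, "G319")
      weeks <- c(weeks, sample(winStart:(indexWeek - 1L), 1L))
    }
    o <- order(weeks, chans, codes)
    events <- data.frame(channel = chans[o], code = codes[o],
                         week = as.integer(weeks[o]),
                         stringsAsFactors = FALSE)
    ageMean <- if (case) config@ageMeanCase else config@ageMeanControl
    age <- min(95, max(52, rnorm(1, ageMean, config@ageSD)))
    patients[[i]] <- list(
      patient_id = sprintf("P%06d", i),
      sex = if (runif(1) < config@femaleProb) "female" else "male",
      birth_week = as.integer(round(indexWeek - age * WEEKS_PER_YEAR_EXACT)),
      record_end_week = as.integer(endWeek),
      events = events)
  }
  truth <- list(
    labels = data.frame(
      patient_id = vapply(patients, `[[`, character(1), "patient_id"),
      trueLabel = as.integer(isCase), stringsAsFactors = FALSE),
    plantedOR = cbind(pe, trueOR = (pe$rateCase / (1 - pe$rateCase)) /
                        (pe$rateControl / (1 - pe$rateControl))),
    labelNoise = config@labelNoise)
  list(patients = patients, truth = truth)
}

#' Corrupt true labels with known sensitivity and specificity
#'
#' Independent per-patient flips: a true case keeps its case label with
#' probability \code{p} (sensitivity), a true control keeps its control
#' label with probability \code{q} (specificity). \code{p = q = 1} is
#' the identity.
#'
#' @param trueLabels 0/1 or logical true labels.
#' @param p,q sensitivity and specificity in (0, 1].
#' @param seed RNG seed.
#' @return Integer 0/1 noisy labels.
#' @export
corruptLabels <- function(trueLabels, p, q, seed = 1L) {
  stopifnot(p > 0, p <= 1, q > 0, q <= 1)
  y <- as.logical(trueLabels)
  set.seed(seed)
  u <- runif(length(y))
  as.integer(ifelse(y, u < p, u >= q))
}

#' Cross-tabulate code exposure against noisy labels
#'
#' Exposure is prefix-matched presence of \code{code} in the patient's
#' observation window for the given channel.
#'
#' @param windows named list of per-channel window code sets
#'   (\code{\link{buildCohort}} output).
#' @param noisyLabels 0/1 labels aligned with \code{windows}.
#' @param code code or code prefix defining the exposure.
#' @param channel channel name (default \code{"DX"}).
#' @return A \linkS4class{NoisyTable}.
#' @export
make2x2 <- function(windows, noisyLabels, code, channel = "DX") {
  stopifnot(length(windows) == length(noisyLabels))
  y <- as.logical(noisyLabels)
  exposed <- vapply(windows, function(w) any(startsWith(w[[channel]], code)),
                    logical(1))
  noisyTable(sum(exposed & y), sum(exposed & !y),
             sum(!exposed & y), sum(!exposed & !y))
}
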