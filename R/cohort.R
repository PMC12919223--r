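WEEKS_PER_YEAR_EXACT <- 52.1775  # age arithmetic
WEEKS_PER_YEAR <- 52             # window/index arithmetic (integer weeks)

#' Case/exclusion code definition
#'
#' The four externally supplied code-prefix lists that define the
#' phenotype: ADRD diagnosis prefixes, anti-dementia prescription
#' prefixes, control exclusion prefixes (conditions associated with or
#' causally related to dementia) and known ADRD comorbidity prefixes
#' used for high/low-risk stratification. Matching is by prefix, so a
#' three-character entry catches all of its child codes.
#'
#' @param adrdDx,antiDementiaRx,exclusion,comorbidity character vectors
#'   of code prefixes (normalized internally).
#' @return A list of class \code{CaseDefinition}.
#' @export
caseDefinition <- function(adrdDx, antiDementiaRx = character(0),
                           exclusion = character(0), comorbidity = character(0)) {
  structure(list(adrdDx = normalizeCode(adrdDx),
                 antiDementiaRx = antiDementiaRx,  # rx codes keep case
                 exclusion = normalizeCode(exclusion),
                 comorbidity = normalizeCode(comorbidity)),
            class = "CaseDefinition")
}

#' Cohort construction configuration
#'
#' @param minAgeYears minimum age at index (years).
#' @param minHistoryYears minimum record history before index (years).
#' @param observationWindowYears observation-window length (years).
#' @param horizonYears prediction horizon in years (0--10).
#' @param controlBufferYears ADRD-free confirmation buffer required after
#'   a control's index date (years).
#' @return A list of class \code{CohortConfig}.
#' @export
cohortConfig <- function(minAgeYears = 50, minHistoryYears = 3,
                         observationWindowYears = 2, horizonYears = 1,
                         controlBufferYears = 2) {
  stopifnot(horizonYears >= 0, horizonYears <= 10,
            minAgeYears >= 0, minHistoryYears >= 0,
            observationWindowYears > 0, controlBufferYears >= 0)
  structure(list(minAgeYears = minAgeYears, minHistoryYears = minHistoryYears,
                 observationWindowYears = observationWindowYears,
                 horizonYears = horizonYears,
                 controlBufferYears = controlBufferYears),
            class = "CohortConfig")
}

# does any code start with any of the prefixes?
prefixMatchAny <- function(codes, prefixes) {
  if (!length(codes) || !length(prefixes)) return(FALSE)
  for (p in prefixes) if (any(startsWith(codes, p))) return(TRUE)
  FALSE
}

patientEvents <- function(patient, channel = NULL) {
  ev <- patient$events
  if (is.null(ev) || !length(ev$code)) {
    return(data.frame(channel = character(0), code = character(0),
                      week = integer(0)))
  }
  ev <- as.data.frame(ev, stringsAsFactors = FALSE)
  if (!is.null(channel)) ev <- ev[ev$channel == channel, , drop = FALSE]
  ev
}

#' Label a patient as case, control or excluded
#'
#' A patient is a case if any DX event prefix-matches the ADRD code list
#' or any RX event prefix-matches the anti-dementia prescription list;
#' otherwise a control, unless any DX event prefix-matches the exclusion
#' list, in which case the patient is excluded from the control pool.
#'
#' @param patient a patient record (see \code{\link{readPatients}} for
#'   the structure).
#' @param defn a \code{\link{caseDefinition}}.
#' @return list(label = "case" | "control" | "excluded",
#'   reason = NA or the exclusion reason).
#' @export
labelPatient <- function(patient, defn) {
  stopifnot(inherits(defn, "CaseDefinition"))
  dx <- patientEvents(patient, "DX")$code
  rx <- patientEvents(patient, "RX")$code
  if (prefixMatchAny(dx, defn$adrdDx) || prefixMatchAny(rx, defn$antiDementiaRx))
    return(list(label = "case", reason = NA_character_))
  if (prefixMatchAny(dx, defn$exclusion))
    return(list(label = "excluded", reason = "dementia-associated condition"))
  list(label = "control", reason = NA_character_)
}

# earliest week of ADRD-qualifying evidence (DX diagnosis or anti-dementia RX)
firstQualifyingWeek <- function(patient, defn) {
  ev <- patientEvents(patient)
  hit <- (ev$channel == "DX" &
            vapply(ev$code, function(cd) prefixMatchAny(cd, defn$adrdDx), logical(1))) |
         (ev$channel == "RX" &
            vapply(ev$code, function(cd) prefixMatchAny(cd, defn$antiDementiaRx), logical(1)))
  if (!any(hit)) return(NA_integer_)
  min(ev$week[hit])
}

#' Assign the index date (in weeks) for a labeled patient
#'
#' Cases are anchored \code{max(1, horizon)} years before the first
#' ADRD-qualifying event (earliest of a matching diagnosis or
#' anti-dementia prescription); controls \code{max(controlBuffer,
#' horizon + 1)} years before end-of-record. Cases with under three
#' years of record before the first ADRD evidence and controls with
#' under four years of history are excluded.
#'
#' @param patient a patient record.
#' @param label \code{"case"} or \code{"control"}.
#' @param defn a \code{\link{caseDefinition}}.
#' @param config a \code{\link{cohortConfig}}.
#' @return list(indexWeek, reason); \code{indexWeek} is NA when excluded.
#' @export
assignIndex <- function(patient, label, defn, config) {
  stopifnot(label %in% c("case", "control"))
  ev <- patientEvents(patient)
  firstWeek <- if (nrow(ev)) min(ev$week) else 0L
  if (label == "case") {
    w0 <- firstQualifyingWeek(patient, defn)
    if (is.na(w0)) stop("case patient has no ADRD-qualifying event")
    if (w0 - firstWeek < 3 * WEEKS_PER_YEAR)
      return(list(indexWeek = NA_integer_, reason = "<3 years before first ADRD code"))
    idx <- w0 - max(1, config$horizonYears) * WEEKS_PER_YEAR
  } else {
    endw <- patient$record_end_week
    if (endw - firstWeek < 4 * WEEKS_PER_YEAR)
      return(list(indexWeek = NA_integer_, reason = "control history<4y"))
    idx <- endw - max(config$controlBufferYears, config$horizonYears + 1) * WEEKS_PER_YEAR
  }
  list(indexWeek = as.integer(idx), reason = NA_character_)
}

#' Age and history eligibility at the index date
#'
#' @param patient a patient record.
#' @param indexWeek index week from \code{\link{assignIndex}}.
#' @param config a \code{\link{cohortConfig}}.
#' @return list(included = logical, reason, ageAtIndex).
#' @export
applyEligibility <- function(patient, indexWeek, config) {
  age <- (indexWeek - patient$birth_week) / WEEKS_PER_YEAR_EXACT
  ev <- patientEvents(patient)
  firstWeek <- if (nrow(ev)) min(ev$week) else 0L
  span <- (patient$record_end_week - firstWeek) / WEEKS_PER_YEAR
  if (age < config$minAgeYears)
    return(list(included = FALSE, reason = sprintf("age<%g", config$minAgeYears),
                ageAtIndex = age))
  if (span < config$minHistoryYears)
    return(list(included = FALSE,
                reason = sprintf("history<%gy", config$minHistoryYears),
                ageAtIndex = age))
  list(included = TRUE, reason = NA_character_, ageAtIndex = age)
}

#' Extract the observation window preceding the index date
#'
#' Events with \code{indexWeek - windowWeeks <= week < indexWeek} are
#' kept (half-open on the right: the index week itself is excluded) and
#' grouped by channel as deduplicated, sorted code sets.
#'
#' @param patient a patient record.
#' @param indexWeek index week.
#' @param config a \code{\link{cohortConfig}}.
#' @return list(DX=, RX=, PROC=) of character vectors.
#' @export
extractWindow <- function(patient, indexWeek, config = cohortConfig()) {
  ww <- config$observationWindowYears * WEEKS_PER_YEAR
  ev <- patientEvents(patient)
  keep <- ev$week >= indexWeek - ww & ev$week < indexWeek
  ev <- ev[keep, , drop = FALSE]
  out <- lapply(VALID_CHANNELS, function(ch) sortC(ev$code[ev$channel == ch]))
  names(out) <- VALID_CHANNELS
  out
}

#' High/low comorbidity risk stratum of an observation window
#'
#' High risk iff any DX code in the window prefix-matches the known
#' ADRD comorbidity list.
#'
#' @param window output of \code{\link{extractWindow}}.
#' @param defn a \code{\link{caseDefinition}}.
#' @return \code{"high"} or \code{"low"}.
#' @export
assignRiskStratum <- function(window, defn) {
  if (prefixMatchAny(window$DX, defn$comorbidity)) "high" else "low"
}

#' Build a labeled, windowed cohort from patient records
#'
#' Runs labeling, index assignment, eligibility filtering, window
#' extraction and risk stratification over a list of patients, with
#' CONSORT-style accounting of every exclusion reason. Counts are
#' conserved: included plus excluded-by-each-reason equals the input
#' count.
#'
#' @param patients list of patient records (\code{\link{readPatients}}).
#' @param defn a \code{\link{caseDefinition}}.
#' @param config a \code{\link{cohortConfig}}.
#' @return list with \code{table} (one row per included patient:
#'   patient_id, label, index_week, age_at_index, sex, risk_stratum),
#'   \code{windows} (named list of per-channel code sets) and
#'   \code{consort} (data.frame reason/count over all input patients).
#' @export
buildCohort <- function(patients, defn, config = cohortConfig()) {
  n <- length(patients)
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  reasons <- character(n)
  rows <- vector("list", n)
  windows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- patients[[i]]
    lab <- labelPatient(p, defn)
    if (lab$label == "excluded") { reasons[i] <- lab$reason; next }
    idx <- assignIndex(p, lab$label, defn, config)
    if (is.na(idx$indexWeek)) { reasons[i] <- idx$reason; next }
    eli <- applyEligibility(p, idx$indexWeek, config)
    if (!eli$included) { reasons[i] <- eli$reason; next }
    w <- extractWindow(p, idx$indexWeek, config)
    windows[[i]] <- w
    reasons[i] <- "included"
    rows[[i]] <- data.frame(patient_id = p$patient_id, label = lab$label,
                            index_week = idx$indexWeek,
                            age_at_index = eli$ageAtIndex,
                            sex = p$sex,
                            risk_stratum = assignRiskStratum(w, defn),
                            stringsAsFactors = FALSE)
  }
  keep <- reasons == "included"
  tab <- if (any(keep)) do.call(rbind, rows[keep]) else
    data.frame(patient_id = character(0), label = character(0),
               index_week = integer(0), age_at_index = numeric(0),
               sex = character(0), risk_stratum = character(0))
  windows <- windows[keep]
  names(windows) <- ids[keep]
  consort <- as.data.frame(table(reason = reasons), stringsAsFactors = FALSE)
  names(consort) <- c("reason", "count")
  list(table = tab, windows = windows, consort = consort)
}

#' Read / write patients as JSON lines
#'
#' One JSON object per line with fields \code{patient_id}, \code{sex}
#' ("male"/"female"), \code{birth_week} (weeks relative to the first DX
#' code, non-positive), \code{record_end_week} and \code{events}, a list
#' of \code{\{channel, code, week\}} objects sorted by week.
#'
#' @param path file path.
#' @return \code{readPatients}: list of patient records.
#' @export
readPatients <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    p <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    p$events <- as.data.frame(p$events, stringsAsFactors = FALSE)
    p
  })
}

#' @rdname readPatients
#' @param patients list of patient records.
#' @return \code{writePatients}: the path, invisibly. Output is
#'   byte-deterministic given the same patient list.
#' @export
writePatients <- function(patients, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (p in patients) {
    obj <- list(patient_id = p$patient_id, sex = p$sex,
                birth_week = p$birth_week,
                record_end_week = p$record_end_week,
                events = p$events[, c("channel", "code", "week")])
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows"),
               con, sep = "\n")
  }
  invisible(path)
}

#' Validate patient records against the shipped schema
#'
#' Structural validation of the JSON-lines patient format: required
#' fields, types, sorted non-negative event weeks, known channels and a
#' record end no earlier than the last event. The machine-readable
#' schema ships at \code{system.file("extdata", "patient-schema.json",
#' package = "adscreen")}.
#'
#' @param patients list of patient records.
#' @return data.frame(patient_id, valid, problem); invisibly stops with
#'   an error when \code{stopOnError} and any record is malformed.
#' @param stopOnError abort on first malformed record?
#' @export
validatePatients <- function(patients, stopOnError = FALSE) {
  checkOne <- function(p) {
    if (!is.character(p$patient_id) || !nzchar(p$patient_id)) return("missing patient_id")
    if (!p$sex %in% c("male", "female")) return("sex must be male/female")
    if (!is.numeric(p$birth_week) || p$birth_week > 0) return("birth_week must be <= 0")
    if (!is.numeric(p$record_end_week)) return("missing record_end_week")
    ev <- patientEvents(p)
    if (nrow(ev)) {
      if (!all(ev$channel %in% VALID_CHANNELS)) return("unknown channel")
      if (any(ev$week < 0)) return("negative event week")
      if (is.unsorted(ev$week)) return("events not sorted by week")
      if (p$record_end_week < max(ev$week)) return("record_end_week before last event")
    }
    NA_character_
  }
  problems <- vapply(patients, checkOne, character(1))
  bad <- !is.na(problems)
  if (stopOnError && any(bad))
    stop("malformed patient record(s): ", paste(unique(problems[bad]), collapse = "; "))
  data.frame(patient_id = vapply(patients, `[[`, character(1), "patient_id"),
             valid = !bad, problem = problems, stringsAsFactors = FALSE)
}

#' Read a role-tagged code list
#'
#' Plain text, one prefix per line; a header line of the form
#' \code{# role: case} (roles: case, anti-dementia-rx, exclusion,
#' comorbidity) tags the list. Blank lines and further comments are
#' ignored.
#'
#' @param path file path.
#' @return list(role, codes).
#' @export
readCodeList <- function(path) {
  lines <- readLines(path)
  roleLine <- grep("^#\\s*role\\s*:", lines, value = TRUE)
  role <- if (length(roleLine)) trimws(sub("^#\\s*role\\s*:", "", roleLine[1])) else NA_character_
  codes <- trimws(lines[!grepl("^#", lines)])
  list(role = role, codes = codes[nzchar(codes)])
}
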