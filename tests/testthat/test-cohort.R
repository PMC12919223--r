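defn <- caseDefinition(adrdDx = c("G30", "F03"), antiDementiaRx = "rxNCH",
                       exclusion = "G31", comorbidity = c("E11", "I10"))

test_that("labeling partitions patients into case, control, excluded", {
  p_case <- makePatient(channel = "DX", code = "G309", week = 300L)
  p_rx <- makePatient(channel = "RX", code = "rxNCH1", week = 300L)
  p_ctl <- makePatient(channel = "DX", code = "E11", week = 10L)
  p_exc <- makePatient(channel = "DX", code = c("E11", "G319"), week = c(1L, 9L))
  expect_identical(labelPatient(p_case, defn)$label, "case")
  expect_identical(labelPatient(p_rx, defn)$label, "case")
  expect_identical(labelPatient(p_ctl, defn)$label, "control")
  lab <- labelPatient(p_exc, defn)
  expect_identical(lab$label, "excluded")
  expect_match(lab$reason, "dementia-associated")
  # a case with an exclusion code is still a case (exclusion screens controls)
  p_both <- makePatient(channel = "DX", code = c("G319", "G300"), week = c(1L, 200L))
  expect_identical(labelPatient(p_both, defn)$label, "case")
})

test_that("index assignment anchors cases to first ADRD evidence and controls to end of record", {
  cfg <- cohortConfig(horizonYears = 1)
  p <- makePatient(channel = c("DX", "DX"), code = c("E11", "G309"),
                   week = c(0L, 520L), end_week = 540L)
  expect_identical(assignIndex(p, "case", defn, cfg)$indexWeek, 468L)
  ctl <- makePatient(channel = "DX", code = "E11", week = 0L, end_week = 520L)
  expect_identical(assignIndex(ctl, "control", defn, cfg)$indexWeek, 416L)
  # earliest qualifying evidence of either kind sets the anchor
  p2 <- makePatient(channel = c("DX", "RX", "DX"), code = c("E11", "rxNCH1", "G309"),
                    week = c(0L, 400L, 520L), end_week = 540L)
  expect_identical(assignIndex(p2, "case", defn, cfg)$indexWeek, 400L - 52L)
  # under three years of record before first ADRD evidence: excluded
  early <- makePatient(channel = c("DX", "DX"), code = c("E11", "G309"),
                       week = c(0L, 100L), end_week = 200L)
  idx <- assignIndex(early, "case", defn, cfg)
  expect_true(is.na(idx$indexWeek))
  expect_match(idx$reason, "<3 years")
  # controls need four years of history
  short <- makePatient(channel = "DX", code = "E11", week = 0L, end_week = 150L)
  expect_match(assignIndex(short, "control", defn, cfg)$reason, "history<4y")
})

test_that("eligibility enforces age and history minima at the index date", {
  cfg <- cohortConfig()
  p <- makePatient(birth_week = as.integer(round(416 - 49.5 * 52.1775)),
                   channel = "DX", code = "E11", week = 0L, end_week = 520L)
  e <- applyEligibility(p, 416L, cfg)
  expect_false(e$included)
  expect_match(e$reason, "age<50")
  old <- makePatient(birth_week = -3000L, channel = "DX", code = "E11",
                     week = 300L, end_week = 430L)
  e2 <- applyEligibility(old, 416L, cfg)
  expect_false(e2$included)
  expect_match(e2$reason, "history<3")
  ok <- makePatient(birth_week = -3000L, channel = "DX", code = "E11",
                    week = 0L, end_week = 520L)
  expect_true(applyEligibility(ok, 416L, cfg)$included)
})

test_that("observation windows are half-open 104-week channel partitions", {
  p <- makePatient(channel = c("DX", "DX", "DX"), code = c("A00", "B00", "C00"),
                   week = c(300L, 403L, 404L))
  w <- extractWindow(p, 404L)
  expect_identical(w$DX, c("A00", "B00"))  # index week itself excluded
  expect_identical(w$RX, character(0))
  # channel-faithful partition of an interleaved six-event fixture
  p6 <- makePatient(channel = c("DX", "RX", "PROC", "DX", "RX", "PROC"),
                    code = c("E11", "rxA1", "9921", "I10", "rxB2", "8800"),
                    week = c(310L, 320L, 330L, 340L, 350L, 200L))
  w6 <- extractWindow(p6, 404L)
  expect_identical(w6$DX, c("E11", "I10"))
  expect_identical(w6$RX, c("rxA1", "rxB2"))
  expect_identical(w6$PROC, "9921")  # week 200 is before index - 104
  empty <- extractWindow(p6, 100L)
  expect_identical(lengths(empty), c(DX = 0L, RX = 0L, PROC = 0L))
})

test_that("risk stratification matches comorbidity prefixes within the window", {
  p <- makePatient(channel = c("DX", "DX"), code = c("E119", "K21"),
                   week = c(350L, 360L))
  expect_identical(assignRiskStratum(extractWindow(p, 404L), defn), "high")
  expect_identical(assignRiskStratum(extractWindow(p, 100L), defn), "low")
  outside <- makePatient(channel = "DX", code = "E119", week = 100L)
  expect_identical(assignRiskStratum(extractWindow(outside, 404L), defn), "low")
})

test_that("cohort construction conserves CONSORT counts and recovers truth", {
  fx <- smallCohort()
  co <- fx$cohort
  expect_identical(sum(co$consort$count), length(fx$gen$patients))
  expect_identical(sum(co$consort$count[co$consort$reason == "included"]),
                   nrow(co$table))
  truth <- fx$gen$truth$labels
  merged <- merge(co$table, truth, by = "patient_id")
  expect_identical(as.integer(merged$label == "case"), merged$trueLabel)
  # no malformed records from the generator
  expect_true(all(validatePatients(fx$gen$patients)$valid))
  # control confirmation buffer: no ADRD evidence after a control's index
  dd <- defaultCaseDefinition()
  ctl <- merged$patient_id[merged$label == "control"]
  byId <- setNames(fx$gen$patients,
                   vapply(fx$gen$patients, `[[`, character(1), "patient_id"))
  for (id in ctl[1:25]) {
    ev <- byId[[id]]$events
    expect_false(any(startsWith(ev$code[ev$channel == "DX"], "G30")))
  }
})

test_that("raising the horizon never rescues an excluded case", {
  # ages chosen so longer horizons push age at index below 50
  mk <- function(age) {
    idx1 <- 520L - 52L
    makePatient(birth_week = as.integer(round(idx1 - age * 52.1775)),
                channel = c("DX", "DX"), code = c("E11", "G309"),
                week = c(0L, 520L), end_week = 560L)
  }
  cfgAt <- function(h) cohortConfig(horizonYears = h)
  includedAt <- function(p, h) {
    idx <- assignIndex(p, "case", defn, cfgAt(h))
    if (is.na(idx$indexWeek)) return(FALSE)
    applyEligibility(p, idx$indexWeek, cfgAt(h))$included
  }
  for (age in c(49, 50.5, 53, 60)) {
    p <- mk(age)
    inc <- vapply(1:8, function(h) includedAt(p, h), logical(1))
    expect_true(all(diff(as.integer(inc)) <= 0))  # monotone exclusion
  }
})

test_that("JSON-lines round trip preserves patients byte for byte", {
  fx <- smallCohort()
  pats <- fx$gen$patients[1:20]
  f1 <- tempfile(fileext = ".jsonl"); f2 <- tempfile(fileext = ".jsonl")
  writePatients(pats, f1)
  back <- readPatients(f1)
  expect_identical(length(back), 20L)
  expect_identical(back[[3]]$patient_id, pats[[3]]$patient_id)
  expect_identical(back[[3]]$events$code, pats[[3]]$events$code)
  writePatients(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(all(validatePatients(back)$valid))
})

test_that("schema validation flags malformed records", {
  bad1 <- makePatient(sex = "unknown")
  bad2 <- makePatient(channel = "DX", code = "E11", week = 700L, end_week = 600L)
  bad3 <- makePatient(birth_week = 10L)
  v <- validatePatients(list(bad1, bad2, bad3, makePatient()))
  expect_identical(v$valid, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(validatePatients(list(bad1), stopOnError = TRUE), "malformed")
})

test_that("role-tagged code lists parse", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("# role: comorbidity", "E11", "I10", "", "# a comment", "I50"), f)
  cl <- readCodeList(f)
  expect_identical(cl$role, "comorbidity")
  expect_identical(cl$codes, c("E11", "I10", "I50"))
})
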