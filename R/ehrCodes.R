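#' Normalize an EHR code string
#'
#' Codes are compared in a dotless, uppercase, whitespace-free form
#' (ICD-10 "I25.10" and "i2510" are the same code).
#'
#' @param code character vector of raw codes.
#' @return Normalized character vector.
#' @examples
#' normalizeCode(c("I25.10", " e11 "))
#' @export
normalizeCode <- function(code) {
  gsub("[.[:space:]]", "", toupper(as.character(code)))
}

#' Hierarchical prefix expansion of a code
#'
#' Returns the code together with every prefix whose length is in the
#' channel's tracked set and strictly shorter than the code, ordered
#' short to long with the full code last. The full code is always
#' included, whether or not its own length is tracked.
#'
#' @param code a single non-empty code (normalized form; see
#'   \code{\link{normalizeCode}}).
#' @param channel a \linkS4class{CodeChannel}.
#' @return Character vector of deduplicated prefixes plus the code.
#' @examples
#' expandPrefixes("I2510", codeChannel("DX"))   # "I" "I2" "I25" "I2510"
#' expandPrefixes("rxCHD4", codeChannel("RX"))  # "rxC" "rxCH" "rxCHD" "rxCHD4"
#' @export
expandPrefixes <- function(code, channel) {
  stopifnot(is(channel, "CodeChannel"))
  if (length(code) != 1L || is.na(code) || !nzchar(code))
    stop("code must be a single non-empty string")
  lens <- channel@prefixLengths[channel@prefixLengths < nchar(code)]
  if (!length(lens)) return(code)
  unique(c(substring(code, 1L, lens), code))
}

# Prefix expansion of many codes at once; RX prefixes are taken on the
# normalized code but RX codes keep their literal "rx" casing upstream,
# so normalization is the caller's job.
expandPrefixSet <- function(codes, channel) {
  if (!length(codes)) return(character(0))
  unique(unlist(lapply(unique(codes), expandPrefixes, channel = channel),
                use.names = FALSE))
}

#' Build a channel vocabulary from per-patient code sets
#'
#' The vocabulary is the union, over the supplied records, of each
#' observed code's hierarchical prefix expansion, sorted
#' lexicographically (C locale) for determinism. Records must come from
#' the designated code-inference (training) split only.
#'
#' @param records list of character vectors, one per patient record.
#' @param channel a \linkS4class{CodeChannel}.
#' @param fingerprint optional identifier hash of the records used
#'   (see \code{\link{splitFingerprint}}), stored for leakage checks.
#' @return A \linkS4class{CodeVocabulary}.
#' @examples
#' buildVocabulary(list(c("E11"), c("E119")), codeChannel("DX"))
#' @export
buildVocabulary <- function(records, channel, fingerprint = "") {
  stopifnot(is(channel, "CodeChannel"), is.list(records) || length(records) == 0)
  if (!length(records)) {
    warning("empty record collection: returning an empty vocabulary")
    entries <- character(0)
  } else {
    codes <- unique(unlist(records, use.names = FALSE))
    codes <- codes[!is.na(codes) & nzchar(codes)]
    entries <- sortC(expandPrefixSet(codes, channel))
  }
  new("CodeVocabulary", channel = channel, entries = entries,
      sourceCount = length(records), fingerprint = fingerprint)
}

# locale-independent lexicographic sort
sortC <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  sort(unique(x))
}

#' Write / read a plain-text vocabulary
#'
#' One entry per line; the channel name is embedded in the file name
#' (\code{vocabulary_DX.txt} etc.).
#'
#' @param vocab a \linkS4class{CodeVocabulary}.
#' @param dir directory to write into.
#' @return \code{writeVocabulary} returns the path invisibly;
#'   \code{readVocabulary} returns a \linkS4class{CodeVocabulary}.
#' @export
writeVocabulary <- function(vocab, dir) {
  stopifnot(is(vocab, "CodeVocabulary"))
  path <- file.path(dir, sprintf("vocabulary_%s.txt", vocab@channel@name))
  writeLines(vocab@entries, path)
  invisible(path)
}

#' @rdname writeVocabulary
#' @param path path to a vocabulary file written by \code{writeVocabulary}.
#' @param channel a \linkS4class{CodeChannel}; defaults to the channel
#'   parsed from the file name.
#' @export
readVocabulary <- function(path, channel = NULL) {
  if (is.null(channel)) {
    nm <- sub("^vocabulary_([A-Z]+)\\.txt$", "\\1", basename(path))
    channel <- codeChannel(nm)
  }
  entries <- readLines(path)
  new("CodeVocabulary", channel = channel, entries = sortC(entries),
      sourceCount = NA_integer_, fingerprint = "")
}

#' Compose a therapeutic RX code
#'
#' The custom prescription coding scheme concatenates an \code{"rx"}
#' prefix, one character each for therapeutic group, class and subclass
#' (placeholder \code{"X"} when the attribute is absent or
#' not-elsewhere-classifiable), and an unpadded ordinal identifying the
#' generic drug within its five-character therapeutic stem.
#'
#' @param group,class,subclass single-character therapeutic attributes;
#'   \code{NA}, empty strings or values in \code{necSentinels} become
#'   \code{"X"}.
#' @param ordinal positive integer rank of the generic drug.
#' @param necSentinels values treated as not-elsewhere-classifiable.
#' @return The RX code string.
#' @examples
#' buildRxCode("C", "H", "D", 4)   # "rxCHD4"
#' buildRxCode(NA, NA, NA, 1)      # "rxXXX1"
#' @export
buildRxCode <- function(group, class, subclass, ordinal,
                        necSentinels = c("", "NEC")) {
  stopifnot(length(ordinal) == 1L, ordinal >= 1, ordinal == as.integer(ordinal))
  fill <- function(x) {
    if (length(x) != 1L || is.na(x) || x %in% necSentinels) "X" else as.character(x)
  }
  paste0("rx", fill(group), fill(class), fill(subclass), format(as.integer(ordinal)))
}

#' Map NDC identifiers to therapeutic RX codes
#'
#' All NDC package variants of one generic drug share a single RX code;
#' within each five-character therapeutic stem, distinct generic names
#' are numbered 1..k in lexicographic order of generic name, so the
#' mapping is a pure function of the table contents, invariant to row
#' order.
#'
#' @param table data.frame with columns \code{ndc}, \code{generic_name},
#'   \code{therapeutic_group}, \code{therapeutic_class},
#'   \code{therapeutic_subclass} (empty or \code{NA} = absent).
#' @param necSentinels see \code{\link{buildRxCode}}.
#' @return Named character vector, NDC -> RX code.
#' @examples
#' tab <- data.frame(ndc = c("1", "2", "3"),
#'                   generic_name = c("alprazolam", "alprazolam", "diazepam"),
#'                   therapeutic_group = "C", therapeutic_class = "H",
#'                   therapeutic_subclass = "D")
#' assignRxOrdinals(tab)
#' @export
assignRxOrdinals <- function(table, necSentinels = c("", "NEC")) {
  if (!nrow(table)) return(setNames(character(0), character(0)))
  req <- c("ndc", "generic_name", "therapeutic_group", "therapeutic_class",
           "therapeutic_subclass")
  stopifnot(all(req %in% names(table)))
  if (anyDuplicated(table$ndc)) stop("duplicate NDC identifiers in drug table")
  fill1 <- function(x) ifelse(is.na(x) | x %in% necSentinels, "X", as.character(x))
  stem <- paste0("rx", fill1(table$therapeutic_group),
                 fill1(table$therapeutic_class), fill1(table$therapeutic_subclass))
  out <- character(nrow(table))
  for (s in sortC(stem)) {
    idx <- which(stem == s)
    generics <- sortC(table$generic_name[idx])
    out[idx] <- paste0(s, match(table$generic_name[idx], generics))
  }
  setNames(out, table$ndc)
}

#' Read a drug attribute table
#'
#' TSV with header \code{ndc}, \code{generic_name},
#' \code{therapeutic_group}, \code{therapeutic_class},
#' \code{therapeutic_subclass}; empty cells denote absent attributes.
#'
#' @param path path to the TSV file.
#' @return data.frame of character columns.
#' @export
readDrugTable <- function(path) {
  read.delim(path, colClasses = "character", na.strings = NULL,
             stringsAsFactors = FALSE)
}

# Vectorized position-weighted checksum over the sorted identifier set.
# Not cryptographic; it only needs to distinguish training splits for the
# train/eval leakage guard.
#' Fingerprint a patient-identifier split
#'
#' @param ids character vector of patient identifiers.
#' @return Hex-style string hash, invariant to ordering of \code{ids}.
#' @export
splitFingerprint <- function(ids) {
  s <- paste(sortC(as.character(ids)), collapse = "\x1f")
  v <- utf8ToInt(s)
  i <- seq_along(v)
  h1 <- sum(v * ((i %% 97) + 1)) %% 2147483647
  h2 <- sum(v * ((i %% 101) * (i %% 89) + 1)) %% 2147483647
  sprintf("%x-%x-%d", h1, h2, length(ids))
}
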