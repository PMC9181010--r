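# Stage 1 of the pipeline: whitespace cleaning, organ-based section
# filtering of the findings text, and sentence splitting.

#' Clean raw report text
#'
#' Replaces line breaks inside sentences by single spaces, collapses runs
#' of whitespace to one space and strips leading/trailing whitespace.  No
#' other characters are altered.  Idempotent.
#'
#' @param raw Character vector of raw text.
#' @return Cleaned character vector of the same length.
#' @export
clean_text <- function(raw) {
  trimws(gsub("[\\s]+", " ", raw, perl = TRUE))
}

#' Partition a findings text by organ headers
#'
#' The cleaned findings text is partitioned at the positions of
#' `ORGAN_HEADER` lexicon mentions (e.g. "Esophagus:", "Stomach:",
#' "Duodenum:", their abbreviations and second-language forms).  Each
#' segment is keyed by the organ of its opening header (the upper-cased
#' canonical form of the header concept); text before any header is keyed
#' `NONE`.  Multiple segments of the same organ are concatenated in
#' document order.  Only the stomach segment flows on to concept mapping.
#'
#' @param findings_text Cleaned findings text (single string).
#' @param lexicon A `gastro_lexicon` with organ header entries.
#' @return Named list of segment texts (`NONE` plus one element per organ
#'   seen), with a character attribute `warnings` (non-empty when no
#'   stomach segment was found in a non-empty text).
#' @export
segment_organs <- function(findings_text, lexicon) {
  warnings <- character(0)
  if (is.na(findings_text) || !nzchar(findings_text)) {
    out <- list(NONE = "", STOMACH = "")
    attr(out, "warnings") <- warnings
    return(out)
  }
  heads <- match_terms(findings_text, lexicon, "FINDINGS",
                       classes = "ORGAN_HEADER")
  e <- lexicon$entries
  organ_of <- function(cid) {
    toupper(e$canonical[match(cid, e$concept_id)])
  }
  segs <- list(NONE = character(0))
  n <- nchar(findings_text)
  if (!nrow(heads)) {
    segs$NONE <- findings_text
  } else {
    pre <- substr(findings_text, 1L, heads$start[1])
    pre <- trimws(pre)
    if (nzchar(pre)) segs$NONE <- pre
    for (i in seq_len(nrow(heads))) {
      from <- heads$end[i] + 1L
      to <- if (i < nrow(heads)) heads$start[i + 1] else n
      body <- substr(findings_text, from, to)
      body <- trimws(sub("^[:\\-\\s]+", "", body, perl = TRUE))
      organ <- organ_of(heads$concept_id[i])
      segs[[organ]] <- c(segs[[organ]] %||% character(0), body)
    }
  }
  out <- lapply(segs, function(x) paste(x[nzchar(x)], collapse = " "))
  if (is.null(out$STOMACH)) {
    out$STOMACH <- ""
    warnings <- c(warnings, "no stomach header found in findings text")
  }
  attr(out, "warnings") <- warnings
  out
}

# dotted tokens that do not end a sentence
DOTTED_ABBREVS <- c("approx", "vs", "cf", "dr", "no", "r/o")

#' Split cleaned text into sentences
#'
#' Splits on sentence terminators (`.`, `!`, `?`) and on bullet/numbered
#' item markers (`- `, `1) `).  Decimal points inside numbers (`1.5 cm`)
#' and a small set of dotted abbreviations do not split.  Empty fragments
#' are dropped.
#'
#' @param segment Cleaned text (single string).
#' @return Data frame of sentences with columns `text`, `index` (0-based,
#'   consecutive) and `start`, `end` (0-based half-open span into
#'   `segment`; the slice at the span equals the sentence text).
#' @export
split_sentences <- function(segment) {
  empty <- data.frame(text = character(0), index = integer(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(segment) || !nzchar(segment)) return(empty)
  n <- nchar(segment)
  chars <- strsplit(segment, "", fixed = TRUE)[[1]]

  ends <- integer(0)   # 1-based position of a terminator that ends a sentence
  m <- gregexpr("[.!?]", segment)[[1]]
  if (m[1] != -1L) {
    for (p in as.integer(m)) {
      if (chars[p] == ".") {
        prev <- if (p > 1) chars[p - 1] else ""
        nxt <- if (p < n) chars[p + 1] else ""
        if (grepl("[0-9]", prev) && grepl("[0-9]", nxt)) next  # decimal
        # word immediately before the dot
        w <- sub(".*?([[:alnum:]/]+)$", "\\1", substr(segment, max(1, p - 12), p - 1))
        if (tolower(w) %in% DOTTED_ABBREVS) next
      }
      ends <- c(ends, p)
    }
  }
  starts <- integer(0)  # 1-based position where a new item begins
  bm <- gregexpr("(?<=\\s)(-|•|[0-9]+\\))(?=\\s)", segment, perl = TRUE)[[1]]
  if (bm[1] != -1L) starts <- as.integer(bm)

  cuts <- sort(unique(c(0L, ends, starts - 1L, n)))
  out <- list()
  for (k in seq_len(length(cuts) - 1L)) {
    a <- cuts[k] + 1L; b <- cuts[k + 1L]
    txt <- substr(segment, a, b)
    lead <- nchar(txt) - nchar(sub("^\\s+", "", txt))
    trail <- nchar(txt) - nchar(sub("\\s+$", "", txt))
    a2 <- a + lead; b2 <- b - trail
    if (a2 > b2) next
    txt <- substr(segment, a2, b2)
    # drop fragments that are bare bullet markers or punctuation
    if (!grepl("[[:alnum:]]", txt)) next
    out[[length(out) + 1L]] <- data.frame(
      text = txt, index = 0L, start = a2 - 1L, end = b2,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res$index <- seq_len(nrow(res)) - 1L
  res
}

#' Preprocess one EGD report
#'
#' Composition of [clean_text()], [segment_organs()] (findings only) and
#' [split_sentences()].  The impressions section is cleaned and split but
#' not organ-filtered: screening impressions are short diagnosis lists and
#' organ headers are inconsistent there; gastric-versus-other
#' discrimination in impressions is done by the lexicon's disease terms.
#'
#' @param report One-row data frame (or list) with `report_id`,
#'   `findings_text`, `impressions_text`.
#' @param lexicon A `gastro_lexicon`.
#' @return List with `report_id`, `findings_sentences` (stomach segment
#'   only), `impressions_sentences` (sentence data frames as returned by
#'   [split_sentences()]) and `warnings`.
#' @export
preprocess_report <- function(report, lexicon) {
  segs <- segment_organs(clean_text(report$findings_text[1]), lexicon)
  warnings <- attr(segs, "warnings") %||% character(0)
  list(
    report_id = report$report_id[1],
    findings_sentences = split_sentences(segs$STOMACH),
    impressions_sentences = split_sentences(clean_text(report$impressions_text[1])),
    warnings = warnings
  )
}
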