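# Stages 2-4 of the pipeline: link impression diagnoses to findings key
# sentences, extract location/extent/stage/size concepts, and summarize
# into one record per report per disease.

#' Pipeline options
#'
#' @param negation Apply the negation rule (default `TRUE`).  When off,
#'   negation cues are ignored and every mention counts as asserted.
#' @param rule_out_positive Treat "r/o" (rule-out) prefixed diagnoses as
#'   present (default `TRUE`, the screening convention).  When `FALSE`,
#'   "r/o" and "rule out" act as additional pre-posed negation cues.
#' @param size_tolerance_cm Tolerance used when scoring size agreement
#'   (default 0.1 cm).
#' @return List of options for [summarize_report()] and [run_pipeline()].
#' @export
pipeline_options <- function(negation = TRUE, rule_out_positive = TRUE,
                             size_tolerance_cm = 0.1) {
  list(negation = negation, rule_out_positive = rule_out_positive,
       size_tolerance_cm = size_tolerance_cm)
}

# token start positions (1-based) of whitespace-delimited tokens
token_starts <- function(text) {
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Detect whether a concept mention is negated
#'
#' A mention is negated when a negation-cue surface occurs in the same
#' sentence within a window of 5 word tokens before the mention (EN cues,
#' e.g. "no", "without", "no evidence of", "negative for") or anywhere
#' after the mention in the sentence (post-posed second-language cues).
#'
#' @param sentence_text Cleaned sentence text containing the mention.
#' @param mention One-row mention data frame (from [match_terms()]) with a
#'   span into `sentence_text`.
#' @param lexicon A `gastro_lexicon`.
#' @param opts Options from [pipeline_options()].
#' @return Logical scalar.
#' @export
detect_negation <- function(sentence_text, mention, lexicon,
                            opts = pipeline_options()) {
  if (!opts$negation) return(FALSE)
  cues <- match_terms(sentence_text, lexicon, mention$section[1],
                      classes = "NEGATION_CUE")
  extra <- NULL
  if (!opts$rule_out_positive) {
    extra <- ro_cues(sentence_text, mention$section[1])
    cues <- rbind(cues, extra)
  }
  if (!nrow(cues)) return(FALSE)
  langs <- cue_language(cues, lexicon)
  toks <- token_starts(sentence_text)
  tok_of <- function(pos0) sum(toks <= pos0 + 1L)  # token ordinal of a 0-based char pos
  m_tok <- tok_of(mention$start[1])
  for (i in seq_len(nrow(cues))) {
    if (langs[i] == "EN") {
      if (cues$start[i] < mention$start[1] &&
          m_tok - tok_of(cues$start[i]) <= 5L) return(TRUE)
    } else {
      if (cues$start[i] >= mention$end[1]) return(TRUE)
    }
  }
  FALSE
}

# rule-out surfaces injected as cues when rule_out_positive is off
ro_cues <- function(text, section) {
  out <- empty_mentions()
  for (surf in c("r/o", "rule out")) {
    esc <- gsub("([\\^$.|?*+()\\[\\]{}\\\\/])", "\\\\\\1", surf, perl = TRUE)
    m <- gregexpr(paste0("(?<![[:alnum:]])", esc, "(?![[:alnum:]])"),
                  text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    out <- rbind(out, data.frame(
      concept_id = "N_RO", concept_class = "NEGATION_CUE",
      start = as.integer(m) - 1L,
      end = as.integer(m) - 1L + attr(m, "match.length"),
      section = section, sentence_index = 0L, negated = FALSE,
      surface = surf, stringsAsFactors = FALSE
    ))
  }
  out
}

cue_language <- function(cues, lexicon) {
  e <- lexicon$entries
  vapply(seq_len(nrow(cues)), function(i) {
    if (cues$concept_id[i] == "N_RO") return("EN")
    cand <- e$language[e$concept_id == cues$concept_id[i] &
                         tolower(e$surface) == tolower(cues$surface[i])]
    if (length(cand)) cand[1] else "EN"
  }, character(1))
}

# scan sentences of one section, fill sentence_index and negated flags
scan_section <- function(sentences, lexicon, section, opts) {
  mentions <- match_sentences(sentences$text, lexicon, section)
  if (!nrow(mentions)) return(mentions)
  for (i in seq_len(nrow(mentions))) {
    s <- mentions$sentence_index[i] + 1L
    mentions$negated[i] <- detect_negation(sentences$text[s],
                                           mentions[i, , drop = FALSE],
                                           lexicon, opts)
  }
  mentions
}

#' Detect disease diagnoses in the impressions section
#'
#' One diagnosis mention per `DISEASE_DIAGNOSIS` lexicon match, mapped to
#' its disease label through the lexicon's disease-target map, with the
#' negation flag set by [detect_negation()].  Negated diagnoses are
#' retained (for evidence) but excluded from presence downstream.
#'
#' @param impressions_sentences Sentence data frame from
#'   [split_sentences()].
#' @param lexicon A `gastro_lexicon`.
#' @param opts Options from [pipeline_options()].
#' @return Data frame: `disease` plus the mention columns.
#' @export
detect_diagnoses <- function(impressions_sentences, lexicon,
                             opts = pipeline_options()) {
  mentions <- scan_section(impressions_sentences, lexicon, "IMPRESSIONS", opts)
  mentions <- mentions[mentions$concept_class == "DISEASE_DIAGNOSIS", , drop = FALSE]
  disease <- unname(lexicon$disease_targets[mentions$concept_id])
  out <- cbind(data.frame(disease = disease, stringsAsFactors = FALSE), mentions)
  out[!is.na(out$disease), , drop = FALSE]
}

#' Map diagnoses to key findings sentences
#'
#' For each non-negated diagnosis, returns every findings sentence
#' containing at least one non-negated phenotype mention whose concept is
#' linked to the diagnosis concept through the lexicon's phenotype map.
#' Sentences may serve several diseases; a disease with no matching
#' sentence gets an empty list (its presence is still recorded from the
#' impression).
#'
#' @param diagnoses Output of [detect_diagnoses()].
#' @param findings_sentences Sentence data frame (stomach segment).
#' @param lexicon A `gastro_lexicon`.
#' @param opts Options from [pipeline_options()].
#' @return List with `key_sentences` (named list: disease label -> integer
#'   vector of 0-based findings sentence indices), `findings_mentions`
#'   (all findings mentions with negation flags) and `warnings`.
#' @export
map_key_sentences <- function(diagnoses, findings_sentences, lexicon,
                              opts = pipeline_options()) {
  f_mentions <- scan_section(findings_sentences, lexicon, "FINDINGS", opts)
  warnings <- character(0)
  active <- unique(diagnoses$disease[!diagnoses$negated])
  key <- stats::setNames(vector("list", length(active)), active)
  for (d in active) {
    diag_concepts <- names(lexicon$disease_targets)[lexicon$disease_targets == d]
    phen <- unique(unlist(lexicon$phenotype_of[diag_concepts], use.names = FALSE))
    hit <- f_mentions$concept_class == "FINDING_PHENOTYPE" &
      f_mentions$concept_id %in% phen & !f_mentions$negated
    key[[d]] <- sort(unique(f_mentions$sentence_index[hit]))
    if (!length(key[[d]]))
      warnings <- c(warnings, paste0("no key findings sentence for diagnosis ", d))
  }
  list(key_sentences = key, findings_mentions = f_mentions,
       warnings = warnings)
}

#' Extract stomach regions mentioned in a disease's key sentences
#'
#' Union over the key sentences of the regions that the lexicon's
#' subsite-region map assigns to each `LOCATION_SUBSITE` mention
#' (e.g. prepyloric area and angle map to the antrum; lower/mid/upper
#' body and cardia to the body; fundus to the fundus).
#'
#' @param findings_mentions Findings mentions (from [map_key_sentences()]).
#' @param sentence_indices 0-based indices of the disease's key sentences.
#' @param lexicon A `gastro_lexicon`.
#' @return Character vector, subset of `ANTRUM`, `BODY`, `FUNDUS`.
#' @export
extract_locations <- function(findings_mentions, sentence_indices, lexicon) {
  hit <- findings_mentions$concept_class == "LOCATION_SUBSITE" &
    findings_mentions$sentence_index %in% sentence_indices &
    !findings_mentions$negated
  regions <- unname(lexicon$subsite_region[findings_mentions$concept_id[hit]])
  sort(unique(regions[!is.na(regions)]))
}

#' Derive gastritis extent from the set of affected regions
#'
#' Antrum only -> `E1`; body and/or fundus only -> `E2`; antrum together
#' with body and/or fundus -> `E3`; no region -> `UNSPECIFIED`.
#'
#' @param regions Character vector, subset of `ANTRUM`, `BODY`, `FUNDUS`.
#' @return One of `"E1"`, `"E2"`, `"E3"`, `"UNSPECIFIED"`.
#' @export
derive_extent <- function(regions) {
  stopifnot(all(regions %in% STOMACH_REGIONS))
  has_a <- "ANTRUM" %in% regions
  has_bf <- any(c("BODY", "FUNDUS") %in% regions)
  if (has_a && has_bf) "E3"
  else if (has_a) "E1"
  else if (has_bf) "E2"
  else "UNSPECIFIED"
}

#' Extract the ulcer stage from key sentences
#'
#' `STAGE` mentions map to active/healing/scar (stage-code abbreviations
#' A1/A2, H1/H2, S1/S2 are ordinary lexicon rows).  When several distinct
#' stages are mentioned the most severe wins (active > healing > scar);
#' none -> `UNSPECIFIED`.
#'
#' @inheritParams extract_locations
#' @return One of `"ACTIVE"`, `"HEALING"`, `"SCAR"`, `"UNSPECIFIED"`.
#' @export
extract_stage <- function(findings_mentions, sentence_indices, lexicon) {
  hit <- findings_mentions$concept_class == "STAGE" &
    findings_mentions$sentence_index %in% sentence_indices &
    !findings_mentions$negated
  ids <- findings_mentions$concept_id[hit]
  if (!length(ids)) return("UNSPECIFIED")
  e <- lexicon$entries
  canon <- toupper(e$canonical[match(ids, e$concept_id)])
  stages <- ifelse(canon %in% c("ACTIVE", "HEALING", "SCAR"), canon, NA)
  stages <- stages[!is.na(stages)]
  if (!length(stages)) return("UNSPECIFIED")
  for (s in c("ACTIVE", "HEALING", "SCAR")) if (s %in% stages) return(s)
  "UNSPECIFIED"
}

#' Extract the lesion size (in centimeters) from key sentences
#'
#' Numeric tokens adjacent to a measurement-unit surface are parsed;
#' millimeter values are divided by 10; dimension expressions such as
#' `"1.0 x 1.5 cm"` yield the maximum dimension; several sized lesions
#' yield the maximum size.  Non-positive parses are ignored with a
#' warning.
#'
#' @param sentence_texts Character vector of the disease's key sentence
#'   texts.
#' @param lexicon A `gastro_lexicon` (supplies the unit surfaces).
#' @return Positive numeric size in cm, or `NA_real_` when no size
#'   expression is present.
#' @export
extract_size <- function(sentence_texts, lexicon) {
  e <- lexicon$entries
  units <- e[e$concept_class == "MEASURE_UNIT", , drop = FALSE]
  if (!nrow(units) || !length(sentence_texts)) return(NA_real_)
  unit_alt <- paste(unique(units$surface), collapse = "|")
  num <- "[0-9]+(?:\\.[0-9]+)?"
  pat <- paste0("(", num, "(?:\\s*[xX×]\\s*", num, ")*)\\s*(", unit_alt, ")(?![[:alnum:]])")
  best <- NA_real_
  for (txt in sentence_texts) {
    m <- gregexpr(pat, txt, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    for (k in seq_along(m)) {
      expr <- substr(txt, m[k], m[k] + attr(m, "match.length")[k] - 1L)
      unit <- tolower(sub(paste0("^.*?(", unit_alt, ")$"), "\\1", expr,
                          ignore.case = TRUE))
      nums <- as.numeric(regmatches(expr, gregexpr(num, expr, perl = TRUE))[[1]])
      val <- max(nums)
      cm <- canonical_cm(val, unit, units)
      if (is.na(cm)) next
      if (cm <= 0) { warning("ignoring non-positive size in: ", expr); next }
      if (is.na(best) || cm > best) best <- cm
    }
  }
  best
}

canonical_cm <- function(value, unit_surface, units) {
  canon <- tolower(units$canonical[match(unit_surface, tolower(units$surface))])
  if (is.na(canon)) return(NA_real_)
  switch(canon, cm = value, mm = value / 10, NA_real_)
}

#' Summarize one report into ten disease records
#'
#' Presence is driven by the impressions section (a non-negated diagnosis
#' mention); the findings section supplies the attributes.  Gastritis
#' records get an extent derived from the regions in their key sentences;
#' non-gastritis records get locations, size, and (ulcers) the stage.
#' Dysplasia and cancer presence is later overridden by the pathology
#' module ([merge_pathology()]), which is authoritative for neoplasia.
#' The conditional-field record invariants are enforced on the result.
#'
#' @param report One-row report data frame.
#' @param preprocessed Output of [preprocess_report()].
#' @param diagnoses Output of [detect_diagnoses()].
#' @param key_map Output of [map_key_sentences()].
#' @param lexicon A `gastro_lexicon`.
#' @param opts Options from [pipeline_options()].
#' @return Data frame of 10 disease records (with `evidence` list column).
#' @export
summarize_report <- function(report, preprocessed, diagnoses, key_map,
                             lexicon, opts = pipeline_options()) {
  fm <- key_map$findings_mentions
  fs <- preprocessed$findings_sentences
  rows <- lapply(GASTRIC_DISEASES, function(d) {
    diag_d <- diagnoses[diagnoses$disease == d, , drop = FALSE]
    present <- any(!diag_d$negated)
    extent <- "UNSPECIFIED"; stage <- "UNSPECIFIED"
    locations <- character(0); size_cm <- NA_real_
    evidence <- diag_d[, names(empty_mentions()), drop = FALSE]
    if (present) {
      ks <- key_map$key_sentences[[d]] %||% integer(0)
      sent_hit <- fm$sentence_index %in% ks & !fm$negated &
        fm$concept_class %in% c("FINDING_PHENOTYPE", "LOCATION_SUBSITE", "STAGE")
      evidence <- rbind(evidence, fm[sent_hit, names(empty_mentions()), drop = FALSE])
      regions <- extract_locations(fm, ks, lexicon)
      if (d %in% GASTRITIS_DISEASES) {
        extent <- derive_extent(regions)
      } else {
        locations <- regions
        size_cm <- extract_size(fs$text[fs$index %in% ks], lexicon)
        if (d == "ULCER") stage <- extract_stage(fm, ks, lexicon)
      }
    }
    out <- data.frame(
      report_id = report$report_id[1], disease = d, present = present,
      extent = extent, stage = stage, size_cm = size_cm,
      stringsAsFactors = FALSE
    )
    out$locations <- list(locations)
    out$evidence <- list(evidence)
    out
  })
  records <- do.call(rbind, rows)
  validate_records(records)
  records
}

#' Run the full extraction pipeline over a corpus
#'
#' Preprocesses each report, detects impression diagnoses, maps key
#' findings sentences, extracts attributes, summarizes into ten records
#' per report and, when pathology reports are supplied, applies the
#' pathology override for the neoplastic diseases.
#'
#' @param reports Data frame of EGD reports.
#' @param lexicon A `gastro_lexicon`.
#' @param pathology Optional data frame of pathology reports.
#' @param opts Options from [pipeline_options()].
#' @return Data frame of `10 * nrow(reports)` disease records, with a
#'   character attribute `warnings`.
#' @export
run_pipeline <- function(reports, lexicon, pathology = NULL,
                         opts = pipeline_options()) {
  validate_reports(reports)
  warnings <- character(0)
  recs <- lapply(seq_len(nrow(reports)), function(i) {
    rep_i <- reports[i, , drop = FALSE]
    pp <- preprocess_report(rep_i, lexicon)
    diagnoses <- detect_diagnoses(pp$impressions_sentences, lexicon, opts)
    key_map <- map_key_sentences(diagnoses, pp$findings_sentences, lexicon, opts)
    w <- c(pp$warnings, key_map$warnings)
    if (length(w))
      warnings <<- c(warnings, paste0(rep_i$report_id, ": ", w))
    summarize_report(rep_i, pp, diagnoses, key_map, lexicon, opts)
  })
  records <- do.call(rbind, recs)
  if (!is.null(pathology)) {
    merged <- merge_pathology(records, pathology, lexicon, opts = opts)
    records <- merged$records
    warnings <- c(warnings, merged$warnings)
  }
  attr(records, "warnings") <- warnings
  records
}
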