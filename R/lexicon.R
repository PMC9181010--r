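#' Path to the shipped seed lexicon
#'
#' The package ships a seed bilingual lexicon (~150 entries) covering
#' diagnostic terms, finding phenotypes, anatomic sub-sites, ulcer stages,
#' negation cues, measurement units and organ headers for all ten target
#' diseases, together with the concept maps that link them.  Second-language
#' (L2) surfaces are romanized placeholders; the file is user-replaceable
#' with a site-specific dictionary of the same schema.
#'
#' @return Path to the tab-separated lexicon file.
#' @export
seed_lexicon_path <- function() {
  system.file("extdata", "seed_lexicon.tsv", package = "gastroie",
              mustWork = TRUE)
}

#' Load and validate a lexicon file
#'
#' Reads a UTF-8 tab-separated lexicon.  Ordinary rows have 6 columns
#' (`surface`, `language`, `concept_id`, `concept_class`, `section_scope`,
#' `canonical`); lines starting with `#` are comments.  Auxiliary map rows
#' have 3 columns and start with one of the reserved tokens
#' `MAP_PHENOTYPE_OF` (disease concept, phenotype concept),
#' `MAP_SUBSITE_REGION` (subsite concept, region `ANTRUM`/`BODY`/`FUNDUS`)
#' or `MAP_DISEASE_TARGET` (disease concept, one of [GASTRIC_DISEASES]).
#'
#' All structural invariants are checked: non-empty surfaces, unique
#' (surface, language, concept_id) triples, legal enum tokens, section
#' scopes compatible with concept classes (diagnosis terms live in
#' impressions or both, phenotypes in findings or both), map references
#' resolving to entries, and every disease label covered by at least one
#' diagnosis and one phenotype concept.
#'
#' @param path Path to the lexicon file.
#' @param complete If `TRUE`, additionally require that all ten disease
#'   labels are covered by at least one diagnosis concept (the shipped
#'   seed lexicon satisfies this; small custom lexicons need not).
#' @return A `gastro_lexicon` object: list with `entries` (data frame in
#'   file order, with a precompiled `pattern` column for EN surfaces),
#'   `phenotype_of` (named list: disease concept -> phenotype concept ids),
#'   `subsite_region` (named character: subsite concept -> region) and
#'   `disease_targets` (named character: disease concept -> disease label).
#' @export
load_lexicon <- function(path, complete = FALSE) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)

  surface <- character(0); language <- character(0); concept_id <- character(0)
  concept_class <- character(0); section_scope <- character(0)
  canonical <- character(0)
  phen_d <- character(0); phen_p <- character(0)
  sub_c <- character(0); sub_r <- character(0)
  tgt_c <- character(0); tgt_l <- character(0)
  map_tokens <- c("MAP_PHENOTYPE_OF", "MAP_SUBSITE_REGION", "MAP_DISEASE_TARGET")

  for (k in seq_along(idx)) {
    f <- trimws(fields[[k]])
    lineno <- idx[k]
    if (length(f) >= 1 && f[1] %in% map_tokens) {
      if (length(f) != 3)
        stop(sprintf("lexicon line %d: map row '%s' needs 3 columns, got %d",
                     lineno, f[1], length(f)))
      switch(f[1],
        MAP_PHENOTYPE_OF = { phen_d <- c(phen_d, f[2]); phen_p <- c(phen_p, f[3]) },
        MAP_SUBSITE_REGION = { sub_c <- c(sub_c, f[2]); sub_r <- c(sub_r, f[3]) },
        MAP_DISEASE_TARGET = { tgt_c <- c(tgt_c, f[2]); tgt_l <- c(tgt_l, f[3]) }
      )
    } else {
      if (length(f) != 6)
        stop(sprintf("lexicon line %d: entry row needs 6 columns, got %d",
                     lineno, length(f)))
      if (!f[2] %in% c("EN", "L2"))
        stop(sprintf("lexicon line %d: unknown language token '%s'", lineno, f[2]))
      if (!f[4] %in% CONCEPT_CLASSES)
        stop(sprintf("lexicon line %d: unknown concept_class token '%s'", lineno, f[4]))
      if (!f[5] %in% SECTION_SCOPES)
        stop(sprintf("lexicon line %d: unknown section_scope token '%s'", lineno, f[5]))
      surface <- c(surface, f[1]); language <- c(language, f[2])
      concept_id <- c(concept_id, f[3]); concept_class <- c(concept_class, f[4])
      section_scope <- c(section_scope, f[5]); canonical <- c(canonical, f[6])
    }
  }

  entries <- data.frame(
    surface = surface, language = language, concept_id = concept_id,
    concept_class = concept_class, section_scope = section_scope,
    canonical = canonical, stringsAsFactors = FALSE
  )
  phenotype_of <- split(phen_p, factor(phen_d, levels = unique(phen_d)))
  phenotype_of <- lapply(phenotype_of, unique)
  subsite_region <- stats::setNames(sub_r, sub_c)
  disease_targets <- stats::setNames(tgt_l, tgt_c)

  new_lexicon(entries, phenotype_of, subsite_region, disease_targets,
              complete = complete)
}

#' Construct a lexicon from in-memory components
#'
#' Validates all invariants and precompiles match patterns.  Used by
#' [load_lexicon()] and by tests that build tiny lexicons in code.
#'
#' @param entries Data frame with columns `surface`, `language`,
#'   `concept_id`, `concept_class`, `section_scope`, `canonical`.
#' @param phenotype_of Named list mapping disease concept ids to character
#'   vectors of phenotype concept ids.
#' @param subsite_region Named character vector mapping subsite concept ids
#'   to regions.
#' @param disease_targets Named character vector mapping disease concept ids
#'   to disease labels.
#' @param complete Require coverage of all ten disease labels.
#' @return A validated `gastro_lexicon` object.
#' @export
new_lexicon <- function(entries, phenotype_of = list(),
                        subsite_region = character(0),
                        disease_targets = character(0), complete = FALSE) {
  entries$surface <- trimws(entries$surface)
  problems <- character(0)
  if (any(!nzchar(entries$surface)))
    problems <- c(problems, "empty surface after whitespace trimming")
  key <- paste(entries$surface, entries$language, entries$concept_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(entries$surface[duplicated(key)])
    problems <- c(problems, paste0("duplicate (surface, language, concept_id): ",
                                   paste(dup, collapse = ", ")))
  }
  bad_enum <- !entries$concept_class %in% CONCEPT_CLASSES
  if (any(bad_enum))
    problems <- c(problems, paste0("unknown concept_class: ",
                                   paste(unique(entries$concept_class[bad_enum]), collapse = ", ")))
  bad_scope <- !entries$section_scope %in% SECTION_SCOPES
  if (any(bad_scope))
    problems <- c(problems, paste0("unknown section_scope: ",
                                   paste(unique(entries$section_scope[bad_scope]), collapse = ", ")))
  bad_diag <- entries$concept_class == "DISEASE_DIAGNOSIS" &
    !entries$section_scope %in% c("IMPRESSIONS", "BOTH")
  if (any(bad_diag))
    problems <- c(problems, paste0("DISEASE_DIAGNOSIS entries must be scoped IMPRESSIONS or BOTH: ",
                                   paste(unique(entries$surface[bad_diag]), collapse = ", ")))
  bad_phen <- entries$concept_class == "FINDING_PHENOTYPE" &
    !entries$section_scope %in% c("FINDINGS", "BOTH")
  if (any(bad_phen))
    problems <- c(problems, paste0("FINDING_PHENOTYPE entries must be scoped FINDINGS or BOTH: ",
                                   paste(unique(entries$surface[bad_phen]), collapse = ", ")))

  known <- unique(entries$concept_id)
  refd <- unique(c(names(phenotype_of), unlist(phenotype_of, use.names = FALSE),
                   names(subsite_region), names(disease_targets)))
  missing <- setdiff(refd, known)
  if (length(missing))
    problems <- c(problems, paste0("map rows reference unknown concept ids: ",
                                   paste(missing, collapse = ", ")))
  bad_region <- !subsite_region %in% STOMACH_REGIONS
  if (length(subsite_region) && any(bad_region))
    problems <- c(problems, paste0("unknown region in subsite map: ",
                                   paste(unique(subsite_region[bad_region]), collapse = ", ")))
  bad_label <- !disease_targets %in% GASTRIC_DISEASES
  if (length(disease_targets) && any(bad_label))
    problems <- c(problems, paste0("unknown disease label in target map: ",
                                   paste(unique(disease_targets[bad_label]), collapse = ", ")))

  if (length(disease_targets)) {
    diag_ids <- unique(entries$concept_id[entries$concept_class == "DISEASE_DIAGNOSIS"])
    not_diag <- setdiff(names(disease_targets), diag_ids)
    if (length(not_diag))
      problems <- c(problems,
                    paste0("disease target concepts without a DISEASE_DIAGNOSIS entry: ",
                           paste(not_diag, collapse = ", ")))
    # every mapped disease concept needs >= 1 phenotype concept
    no_phen <- vapply(names(disease_targets), function(d) {
      length(phenotype_of[[d]] %||% character(0)) == 0
    }, logical(1))
    if (any(no_phen))
      problems <- c(problems,
                    paste0("disease concepts with no mapped phenotype: ",
                           paste(names(disease_targets)[no_phen], collapse = ", ")))
  }
  if (complete) {
    uncovered <- setdiff(GASTRIC_DISEASES, unique(disease_targets))
    if (length(uncovered))
      problems <- c(problems, paste0("disease labels with no diagnosis concept: ",
                                     paste(uncovered, collapse = ", ")))
  }
  if (length(problems))
    stop("lexicon validation failed:\n  - ", paste(problems, collapse = "\n  - "))

  entries$entry_index <- seq_len(nrow(entries))
  entries$nchar <- nchar(entries$surface)
  # EN surfaces: case-insensitive, bounded by non-alphanumerics; L2: raw substring
  esc <- gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", entries$surface, perl = TRUE)
  entries$pattern <- ifelse(
    entries$language == "EN",
    paste0("(?<![[:alnum:]])", esc, "(?![[:alnum:]])"),
    NA_character_
  )
  structure(
    list(entries = entries, phenotype_of = phenotype_of,
         subsite_region = subsite_region, disease_targets = disease_targets),
    class = "gastro_lexicon"
  )
}

#' @export
print.gastro_lexicon <- function(x, ...) {
  cat("<gastro_lexicon> ", nrow(x$entries), " entries (",
      sum(x$entries$language == "EN"), " EN, ",
      sum(x$entries$language == "L2"), " L2); ",
      length(x$disease_targets), " disease concepts -> ",
      length(unique(x$disease_targets)), " labels\n", sep = "")
  print(table(x$entries$concept_class))
  invisible(x)
}

# concept ids of a given class
lexicon_concepts <- function(lexicon, class) {
  unique(lexicon$entries$concept_id[lexicon$entries$concept_class == class])
}

#' Scan a text for lexicon terms
#'
#' Finds all non-overlapping occurrences of in-scope surfaces
#' (`section_scope` equal to `section` or `BOTH`).  EN surfaces match
#' case-insensitively on word boundaries (no alphanumeric character may
#' abut the match); L2 surfaces match as exact substrings.  Overlaps are
#' resolved greedily: the longest candidate wins, ties broken by leftmost
#' start, then by lexicon file order.  The result is sorted by span start.
#'
#' @param text A single character string (a cleaned sentence or section).
#' @param lexicon A `gastro_lexicon`.
#' @param section `"FINDINGS"` or `"IMPRESSIONS"`.
#' @param classes Optional character vector restricting the concept classes
#'   scanned (default: all).
#' @param sentence_index Sentence ordinal stored on the returned mentions
#'   (default 0; the pipeline scans sentence by sentence).
#' @return A data frame of concept mentions with columns `concept_id`,
#'   `concept_class`, `start`, `end` (0-based half-open into `text`),
#'   `section`, `sentence_index`, `negated` (initialized `FALSE`) and
#'   `surface`.
#' @export
match_terms <- function(text, lexicon, section,
                        classes = NULL, sentence_index = 0L) {
  stopifnot(section %in% c("FINDINGS", "IMPRESSIONS"))
  empty <- data.frame(
    concept_id = character(0), concept_class = character(0),
    start = integer(0), end = integer(0), section = character(0),
    sentence_index = integer(0), negated = logical(0), surface = character(0),
    stringsAsFactors = FALSE
  )
  if (is.na(text) || !nzchar(text)) return(empty)
  e <- lexicon$entries
  in_scope <- e$section_scope %in% c(section, "BOTH")
  if (!is.null(classes)) in_scope <- in_scope & e$concept_class %in% classes
  e <- e[in_scope, , drop = FALSE]
  if (!nrow(e)) return(empty)

  starts <- integer(0); lens <- integer(0); rows <- integer(0)
  for (i in seq_len(nrow(e))) {
    if (e$language[i] == "EN") {
      m <- gregexpr(e$pattern[i], text, perl = TRUE, ignore.case = TRUE)[[1]]
    } else {
      m <- gregexpr(e$surface[i], text, fixed = TRUE)[[1]]
    }
    if (m[1] == -1L) next
    starts <- c(starts, as.integer(m))
    lens <- c(lens, attr(m, "match.length"))
    rows <- c(rows, rep.int(i, length(m)))
  }
  if (!length(starts)) return(empty)

  # greedy resolution: longest first, then leftmost, then file order
  ord <- order(-lens, starts, e$entry_index[rows])
  starts <- starts[ord]; lens <- lens[ord]; rows <- rows[ord]
  taken <- logical(nchar(text))
  keep <- logical(length(starts))
  for (j in seq_along(starts)) {
    span <- starts[j]:(starts[j] + lens[j] - 1L)
    if (!any(taken[span])) {
      keep[j] <- TRUE
      taken[span] <- TRUE
    }
  }
  starts <- starts[keep]; lens <- lens[keep]; rows <- rows[keep]
  o <- order(starts)
  starts <- starts[o]; lens <- lens[o]; rows <- rows[o]
  data.frame(
    concept_id = e$concept_id[rows], concept_class = e$concept_class[rows],
    start = starts - 1L, end = starts - 1L + lens,
    section = section, sentence_index = as.integer(sentence_index),
    negated = FALSE,
    surface = substring(text, starts, starts + lens - 1L),
    stringsAsFactors = FALSE
  )
}

# scan a vector of sentences, tagging sentence_index 0..n-1
match_sentences <- function(sentences, lexicon, section, classes = NULL) {
  if (!length(sentences)) {
    return(match_terms("", lexicon, section))
  }
  out <- lapply(seq_along(sentences), function(i) {
    match_terms(sentences[i], lexicon, section, classes = classes,
                sentence_index = i - 1L)
  })
  do.call(rbind, out)
}
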