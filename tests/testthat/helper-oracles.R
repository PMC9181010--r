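# Independent brute-force oracles used by the property tests.  These are
# deliberately written with different mechanics (character loops, token
# lists, per-report loops) than the package implementation.

# enumerate every surface occurrence by position scan, then apply the
# greedy longest / leftmost / file-order resolution
oracle_match <- function(text, surfaces) {
  n <- nchar(text)
  cands <- list()
  is_alnum <- function(ch) nzchar(ch) && grepl("[[:alnum:]]", ch)
  for (k in seq_len(nrow(surfaces))) {
    s <- surfaces$surface[k]
    L <- nchar(s)
    if (L == 0 || L > n) next
    for (pos in seq_len(n - L + 1)) {
      seg <- substr(text, pos, pos + L - 1)
      ok <- if (surfaces$language[k] == "EN") {
        tolower(seg) == tolower(s) &&
          !is_alnum(substr(text, pos - 1, pos - 1)) &&
          !is_alnum(substr(text, pos + L, pos + L))
      } else {
        seg == s
      }
      if (ok) cands[[length(cands) + 1]] <- c(start = pos, len = L, idx = k)
    }
  }
  if (!length(cands)) {
    return(data.frame(start = integer(0), len = integer(0), idx = integer(0)))
  }
  cands <- as.data.frame(do.call(rbind, cands))
  chosen <- list()
  while (nrow(cands)) {
    o <- order(-cands$len, cands$start, cands$idx)
    c1 <- cands[o[1], ]
    chosen[[length(chosen) + 1]] <- c1
    disjoint <- cands$start + cands$len - 1 < c1$start |
      cands$start > c1$start + c1$len - 1
    cands <- cands[disjoint, , drop = FALSE]
  }
  out <- do.call(rbind, chosen)
  out[order(out$start), , drop = FALSE]
}

# token-level negation window: cue within 5 tokens before the mention
# (EN) or anywhere after it (L2)
oracle_negated <- function(sentence, mention_surface, cue_surface, cue_lang) {
  toks <- strsplit(sentence, " +")[[1]]
  find_tok <- function(phrase) {
    ptoks <- strsplit(phrase, " +")[[1]]
    for (i in seq_len(length(toks) - length(ptoks) + 1)) {
      seg <- toks[i:(i + length(ptoks) - 1)]
      if (all(tolower(gsub("[[:punct:]]*$", "", seg)) == tolower(ptoks)))
        return(i)
    }
    NA_integer_
  }
  m <- find_tok(mention_surface)
  cu <- find_tok(cue_surface)
  if (is.na(m) || is.na(cu)) return(FALSE)
  if (cue_lang == "EN") cu < m && (m - cu) <= 5
  else cu > m
}

# per-report loop confusion counts for a binary vector pair
oracle_confusion <- function(pred, gold) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] && gold[i]) tp <- tp + 1L
    else if (pred[i] && !gold[i]) fp <- fp + 1L
    else if (!pred[i] && gold[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# a tiny in-code lexicon used by focused unit tests
tiny_lexicon <- function() {
  entries <- data.frame(
    surface = c("erosive gastritis", "gastritis", "gastric ulcer", "ulcer",
                "erosions", "ulceration", "antrum", "angle", "fundus",
                "lower body", "body", "no", "no evidence of", "without",
                "eopseum",
                "cm", "mm", "Esophagus", "Stomach", "Duodenum",
                "active", "healing", "scar", "S2"),
    language = c(rep("EN", 14), "L2", rep("EN", 9)),
    concept_id = c("D_EG", "D_EG", "D_ULCER", "D_ULCER",
                   "P_EROSION", "P_ULCER", "L_ANTRUM", "L_ANGLE", "L_FUNDUS",
                   "L_BODY", "L_BODY", "N_NO", "N_NO", "N_NO", "N_NO_L2",
                   "U_CM", "U_MM", "O_ESO", "O_STO", "O_DUO",
                   "S_ACTIVE", "S_HEALING", "S_SCAR", "S_SCAR"),
    concept_class = c("DISEASE_DIAGNOSIS", "DISEASE_DIAGNOSIS",
                      "DISEASE_DIAGNOSIS", "DISEASE_DIAGNOSIS",
                      "FINDING_PHENOTYPE", "FINDING_PHENOTYPE",
                      rep("LOCATION_SUBSITE", 5), rep("NEGATION_CUE", 4),
                      rep("MEASURE_UNIT", 2), rep("ORGAN_HEADER", 3),
                      rep("STAGE", 4)),
    section_scope = c("IMPRESSIONS", "IMPRESSIONS", "IMPRESSIONS",
                      "IMPRESSIONS", "FINDINGS", "FINDINGS",
                      rep("BOTH", 5), rep("BOTH", 4), rep("FINDINGS", 2),
                      rep("FINDINGS", 3), rep("FINDINGS", 4)),
    canonical = c("erosive gastritis", "erosive gastritis", "gastric ulcer",
                  "gastric ulcer", "erosion", "ulceration", "antrum",
                  "angle", "fundus", "body", "body", "no", "no", "no", "no",
                  "cm", "mm", "esophagus", "stomach", "duodenum",
                  "active", "healing", "scar", "scar"),
    stringsAsFactors = FALSE
  )
  new_lexicon(
    entries,
    phenotype_of = list(D_EG = "P_EROSION", D_ULCER = "P_ULCER"),
    subsite_region = c(L_ANTRUM = "ANTRUM", L_ANGLE = "ANTRUM",
                       L_BODY = "BODY", L_FUNDUS = "FUNDUS"),
    disease_targets = c(D_EG = "EROSIVE_GASTRITIS", D_ULCER = "ULCER")
  )
}

seed_lex <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_lexicon(seed_lexicon_path(), complete = TRUE)
    cache
  }
})

# random valid gold-record set for round-trip / evaluation tests
random_gold <- function(report_ids, seed = 1) {
  set.seed(seed)
  rows <- lapply(report_ids, function(rid) {
    recs <- lapply(GASTRIC_DISEASES, function(d) {
      present <- stats::runif(1) < 0.4
      extent <- "UNSPECIFIED"; stage <- "UNSPECIFIED"
      locations <- character(0); size_cm <- NA_real_
      if (present) {
        if (d %in% GASTRITIS_DISEASES) {
          extent <- sample(c("E1", "E2", "E3", "UNSPECIFIED"), 1)
        } else {
          locations <- sample(c("ANTRUM", "BODY", "FUNDUS"),
                              sample(0:2, 1))
          if (stats::runif(1) < 0.7) size_cm <- round(stats::runif(1, 0.2, 5), 1)
          if (d == "ULCER") stage <- sample(c("ACTIVE", "HEALING", "SCAR",
                                             "UNSPECIFIED"), 1)
        }
      }
      row <- data.frame(report_id = rid, disease = d, present = present,
                        extent = extent, stage = stage, size_cm = size_cm,
                        stringsAsFactors = FALSE)
      row$locations <- list(sort(locations))
      row
    })
    do.call(rbind, recs)
  })
  do.call(rbind, rows)
}
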