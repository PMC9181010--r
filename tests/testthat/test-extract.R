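mention_in <- function(text, lex, section, concept) {
  m <- match_terms(text, lex, section)
  m[m$concept_id == concept, , drop = FALSE][1, , drop = FALSE]
}

test_that("negation fires on pre-posed cues within the 5-token window", {
  lex <- seed_lex()
  m <- mention_in("no evidence of ulcer", lex, "IMPRESSIONS", "D_ULCER")
  expect_true(detect_negation("no evidence of ulcer", m, lex))

  m2 <- mention_in("active ulcer at antrum", lex, "IMPRESSIONS", "D_ULCER")
  expect_false(detect_negation("active ulcer at antrum", m2, lex))

  far <- "no prior history of any recent significant epigastric symptoms but ulcer"
  m3 <- mention_in(far, lex, "IMPRESSIONS", "D_ULCER")
  expect_false(detect_negation(far, m3, lex))

  # post-posed L2 cue negates anything before it in the sentence
  s4 <- "wigweyang eopseum"
  m4 <- mention_in(s4, lex, "IMPRESSIONS", "D_ULCER")
  expect_true(detect_negation(s4, m4, lex))

  # negation can be switched off
  expect_false(detect_negation("no evidence of ulcer", m, lex,
                               pipeline_options(negation = FALSE)))
})

test_that("negation agrees with a brute-force token-window oracle", {
  lex <- tiny_lexicon()
  fillers <- c("mild", "chronic", "lesion", "mucosa", "noted", "recent",
               "prior", "seen", "focal")
  set.seed(404)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    toks <- sample(fillers, n, replace = TRUE)
    cue_pos <- sample(n, 1)
    ment_pos <- sample(setdiff(seq_len(n), cue_pos), 1)
    cue <- sample(c("no", "without"), 1)
    toks[cue_pos] <- cue
    toks[ment_pos] <- "ulceration"
    sentence <- paste(toks, collapse = " ")
    m <- mention_in(sentence, lex, "FINDINGS", "P_ULCER")
    expect_equal(detect_negation(sentence, m, lex),
                 oracle_negated(sentence, "ulceration", cue, "EN"),
                 info = sentence)
  }
})

test_that("rule-out prefixes are positive by default and negating when configured", {
  lex <- seed_lex()
  s <- "r/o gastric ulcer"
  m <- mention_in(s, lex, "IMPRESSIONS", "D_ULCER")
  expect_false(detect_negation(s, m, lex))
  expect_true(detect_negation(s, m, lex,
                              pipeline_options(rule_out_positive = FALSE)))
})

test_that("impression diagnoses are detected with negation flags", {
  lex <- seed_lex()
  sent <- split_sentences(clean_text("Erosive gastritis. Gastric polyp."))
  d <- detect_diagnoses(sent, lex)
  expect_setequal(d$disease, c("EROSIVE_GASTRITIS", "POLYP"))
  expect_false(any(d$negated))

  d2 <- detect_diagnoses(split_sentences("No ulcer."), lex)
  expect_equal(d2$disease, "ULCER")
  expect_true(d2$negated)

  # abbreviations act as ordinary diagnosis surfaces
  d3 <- detect_diagnoses(split_sentences("IM. SMT."), lex)
  expect_setequal(d3$disease, c("INTESTINAL_METAPLASIA", "SMT"))
})

test_that("key sentences link diagnoses to phenotype sentences", {
  lex <- seed_lex()
  fs <- split_sentences(clean_text(
    "Multiple erosions in the antrum. Mucosal atrophy at the body. A 1.0 cm ulceration at the angle."))
  diag <- detect_diagnoses(split_sentences(
    "Erosive gastritis. Atrophic gastritis. Gastric ulcer."), lex)
  km <- map_key_sentences(diag, fs, lex)
  expect_equal(km$key_sentences$EROSIVE_GASTRITIS, 0L)
  expect_equal(km$key_sentences$ATROPHIC_GASTRITIS, 1L)
  expect_equal(km$key_sentences$ULCER, 2L)

  # a diagnosis with no phenotype sentence yields an empty list + warning
  km2 <- map_key_sentences(detect_diagnoses(split_sentences("Gastric polyp."), lex),
                           fs, lex)
  expect_length(km2$key_sentences$POLYP, 0)
  expect_match(km2$warnings, "POLYP")

  # one sentence can serve two diseases
  fs3 <- split_sentences("Erosions and ulceration at the antrum.")
  diag3 <- detect_diagnoses(split_sentences("Erosive gastritis. Gastric ulcer."), lex)
  km3 <- map_key_sentences(diag3, fs3, lex)
  expect_equal(km3$key_sentences$EROSIVE_GASTRITIS, 0L)
  expect_equal(km3$key_sentences$ULCER, 0L)

  # negated phenotype mentions do not anchor key sentences
  fs4 <- split_sentences("No erosions seen.")
  km4 <- map_key_sentences(detect_diagnoses(split_sentences("Erosive gastritis."), lex),
                           fs4, lex)
  expect_length(km4$key_sentences$EROSIVE_GASTRITIS, 0)
})

test_that("locations union sub-sites through the region map", {
  lex <- seed_lex()
  fs <- split_sentences("Erosions at the antrum. Erosions at the angle.")
  fm <- gastroie:::scan_section(fs, lex, "FINDINGS", pipeline_options())
  expect_equal(extract_locations(fm, c(0L, 1L), lex), "ANTRUM")

  fs2 <- split_sentences("Erosions at the fundus.")
  fm2 <- gastroie:::scan_section(fs2, lex, "FINDINGS", pipeline_options())
  expect_equal(extract_locations(fm2, 0L, lex), "FUNDUS")

  # random subsite multisets: union equals direct mapping of every mention
  subsites <- names(lex$subsite_region)
  en_surface <- function(cc) {
    e <- lex$entries
    e$surface[e$concept_id == cc & e$language == "EN"][1]
  }
  set.seed(55)
  for (i in 1:20) {
    picks <- sample(subsites, sample(1:4, 1), replace = TRUE)
    txt <- paste0("Erosions at the ", paste(vapply(picks, en_surface, ""),
                                            collapse = " and "), ".")
    fsr <- split_sentences(txt)
    fmr <- gastroie:::scan_section(fsr, lex, "FINDINGS", pipeline_options())
    expect_setequal(extract_locations(fmr, 0L, lex),
                    unique(unname(lex$subsite_region[picks])))
  }
})

test_that("extent derivation matches the exhaustive case analysis", {
  expect_equal(derive_extent("ANTRUM"), "E1")
  expect_equal(derive_extent(c("BODY", "FUNDUS")), "E2")
  expect_equal(derive_extent(c("ANTRUM", "FUNDUS")), "E3")
  expect_equal(derive_extent(character(0)), "UNSPECIFIED")
  for (a in c(TRUE, FALSE)) for (b in c(TRUE, FALSE)) for (f in c(TRUE, FALSE)) {
    regions <- c(if (a) "ANTRUM", if (b) "BODY", if (f) "FUNDUS")
    want <- if (a && (b || f)) "E3" else if (a) "E1"
            else if (b || f) "E2" else "UNSPECIFIED"
    expect_equal(derive_extent(regions), want)
  }
  expect_error(derive_extent("CARDIA"))
})

test_that("ulcer stage takes the most severe mention", {
  lex <- seed_lex()
  stage_of <- function(txt) {
    fs <- split_sentences(txt)
    fm <- gastroie:::scan_section(fs, lex, "FINDINGS", pipeline_options())
    extract_stage(fm, fs$index, lex)
  }
  expect_equal(stage_of("Active ulceration at the antrum."), "ACTIVE")
  expect_equal(stage_of("Ulceration with scar (S2)."), "SCAR")
  expect_equal(stage_of("Ulceration."), "UNSPECIFIED")
  # severity order over all permutations of mention placement
  words <- c(ACTIVE = "active", HEALING = "healing", SCAR = "scar")
  combos <- list(c("ACTIVE", "HEALING"), c("HEALING", "SCAR"),
                 c("ACTIVE", "SCAR"), c("ACTIVE", "HEALING", "SCAR"))
  for (combo in combos) {
    for (perm in list(combo, rev(combo))) {
      txt <- paste0("Ulceration ", paste(words[perm], collapse = " then "), ".")
      want <- c("ACTIVE", "HEALING", "SCAR")[min(match(combo, c("ACTIVE", "HEALING", "SCAR")))]
      expect_equal(stage_of(txt), want, info = txt)
    }
  }
})

test_that("sizes parse units, dimensions and maxima", {
  lex <- seed_lex()
  expect_equal(extract_size("a 1.5 cm polyp", lex), 1.5)
  expect_equal(extract_size("about 15 mm", lex), 1.5)
  expect_equal(extract_size("0.8 x 1.2 cm ulcer", lex), 1.2)
  expect_equal(extract_size("two lesions, 0.4 cm and 1.1 cm", lex), 1.1)
  expect_true(is.na(extract_size("no size stated", lex)))
  expect_true(is.na(extract_size(character(0), lex)))
  # max over a brute-force parse of all number-unit pairs
  set.seed(66)
  for (i in 1:15) {
    k <- sample(1:4, 1)
    vals <- round(runif(k, 0.2, 4), 1)
    units <- sample(c("cm", "mm"), k, replace = TRUE)
    txt <- paste(paste0(vals, " ", units, " lesion"), collapse = ", ")
    want <- max(ifelse(units == "mm", vals / 10, vals))
    expect_equal(extract_size(txt, lex), want, info = txt)
  }
})

test_that("summarize produces exactly ten invariant-satisfying records", {
  lex <- seed_lex()
  empty_report <- data.frame(report_id = "R1", patient_id = "P1",
                             exam_date = "2015-01-01", age = 50L, sex = "MALE",
                             findings_text = "", impressions_text = "",
                             stringsAsFactors = FALSE)
  recs <- run_pipeline(empty_report, lex)
  expect_equal(nrow(recs), 10)
  expect_false(any(recs$present))

  # negated-only diagnosis stays absent
  neg <- empty_report
  neg$impressions_text <- "No gastric ulcer."
  recs2 <- run_pipeline(neg, lex)
  expect_false(recs2$present[recs2$disease == "ULCER"])

  # phenotype in findings without an impression diagnosis never sets presence
  phen_only <- empty_report
  phen_only$findings_text <-
    "Esophagus: clear. Stomach: Multiple erosions and ulceration at the antrum. Duodenum: clear."
  recs3 <- run_pipeline(phen_only, lex)
  expect_false(any(recs3$present))

  # full positive example
  pos <- empty_report
  pos$findings_text <-
    "Esophagus: clear. Stomach: A 1.2 cm active ulceration at the antrum. Duodenum: clear."
  pos$impressions_text <- "Gastric ulcer."
  recs4 <- run_pipeline(pos, lex)
  u <- recs4[recs4$disease == "ULCER", ]
  expect_true(u$present)
  expect_equal(u$locations[[1]], "ANTRUM")
  expect_equal(u$stage, "ACTIVE")
  expect_equal(u$size_cm, 1.2)
  expect_gt(nrow(u$evidence[[1]]), 0)
})

test_that("adding an antrum mention to an extent-2 report yields extent 3", {
  lex <- seed_lex()
  base <- data.frame(report_id = "R1", patient_id = "P1",
                     exam_date = "2015-01-01", age = 50L, sex = "MALE",
                     findings_text = "Esophagus: clear. Stomach: Erosions at the body. Duodenum: clear.",
                     impressions_text = "Erosive gastritis.",
                     stringsAsFactors = FALSE)
  r1 <- run_pipeline(base, lex)
  expect_equal(r1$extent[r1$disease == "EROSIVE_GASTRITIS"], "E2")
  more <- base
  more$findings_text <- sub("at the body", "at the body and antrum",
                            more$findings_text)
  r2 <- run_pipeline(more, lex)
  expect_equal(r2$extent[r2$disease == "EROSIVE_GASTRITIS"], "E3")
})
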