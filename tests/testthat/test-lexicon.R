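test_that("the seed lexicon loads, validates and covers all ten diseases", {
  lex <- load_lexicon(seed_lexicon_path(), complete = TRUE)
  expect_s3_class(lex, "gastro_lexicon")
  expect_setequal(unique(lex$disease_targets), GASTRIC_DISEASES)
  # every disease has >= 1 diagnosis concept and >= 1 phenotype concept
  for (d in GASTRIC_DISEASES) {
    diag <- names(lex$disease_targets)[lex$disease_targets == d]
    expect_gte(length(diag), 1)
    phen <- unique(unlist(lex$phenotype_of[diag]))
    expect_gte(length(phen), 1)
    expect_true(all(phen %in% lex$entries$concept_id))
  }
  # brute-force label count straight off the file
  lines <- readLines(seed_lexicon_path())
  tgt <- grep("^MAP_DISEASE_TARGET\t", lines, value = TRUE)
  labels <- vapply(strsplit(tgt, "\t"), `[`, character(1), 3)
  expect_setequal(labels, GASTRIC_DISEASES)
  expect_true(all(lex$subsite_region %in% c("ANTRUM", "BODY", "FUNDUS")))
})

test_that("a minimal single-disease lexicon file loads", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "atrophic gastritis\tEN\tD_AG\tDISEASE_DIAGNOSIS\tIMPRESSIONS\tatrophic gastritis",
    "mucosal atrophy\tEN\tP_ATROPHY\tFINDING_PHENOTYPE\tFINDINGS\tmucosal atrophy",
    "MAP_PHENOTYPE_OF\tD_AG\tP_ATROPHY",
    "MAP_DISEASE_TARGET\tD_AG\tATROPHIC_GASTRITIS"
  ), f)
  lex <- load_lexicon(f)
  expect_equal(sum(lex$entries$concept_class == "DISEASE_DIAGNOSIS"), 1)
  expect_equal(unname(lex$disease_targets["D_AG"]), "ATROPHIC_GASTRITIS")
})

test_that("malformed lexicon files are rejected with the offending line", {
  bad_row <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "only\ttwo"), bad_row)
  expect_error(load_lexicon(bad_row), "line 2")

  bad_enum <- withr::local_tempfile(fileext = ".tsv")
  writeLines("x\tEN\tC1\tNOT_A_CLASS\tBOTH\tx", bad_enum)
  expect_error(load_lexicon(bad_enum), "NOT_A_CLASS")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "ulcer\tEN\tD_U\tDISEASE_DIAGNOSIS\tIMPRESSIONS\tulcer",
    "ulcer\tEN\tD_U\tDISEASE_DIAGNOSIS\tBOTH\tulcer"
  ), dup)
  expect_error(load_lexicon(dup), "duplicate")

  scope <- withr::local_tempfile(fileext = ".tsv")
  writeLines("ulcer\tEN\tD_U\tDISEASE_DIAGNOSIS\tFINDINGS\tulcer", scope)
  expect_error(load_lexicon(scope), "IMPRESSIONS or BOTH")
})

test_that("term matching is case-insensitive with word boundaries for EN", {
  lex <- seed_lex()
  m <- match_terms("Atrophic gastritis.", lex, "IMPRESSIONS")
  expect_equal(nrow(m), 1)
  expect_equal(m$concept_id, "D_AG")
  expect_equal(m$start, 0L)
  expect_equal(m$end, 18L)
  # no match inside a longer word
  m2 <- match_terms("pseudopolyposis", lex, "IMPRESSIONS")
  expect_equal(nrow(m2), 0)
  # empty input
  expect_equal(nrow(match_terms("", lex, "IMPRESSIONS")), 0)
})

test_that("the longest surface wins over an embedded shorter surface", {
  lex <- tiny_lexicon()
  m <- match_terms("Erosive gastritis.", lex, "IMPRESSIONS")
  expect_equal(nrow(m), 1)
  expect_equal(m$surface, "Erosive gastritis")
  expect_equal(m$concept_id, "D_EG")
})

test_that("L2 surfaces match as raw substrings, EN need boundaries", {
  lex <- seed_lex()
  # wigweyang (gastric ulcer, L2) embedded with particles still matches
  m <- match_terms("wigweyang-ui sogyeon.", lex, "IMPRESSIONS")
  expect_true("D_ULCER" %in% m$concept_id)
  # L2 matching is case-sensitive
  m2 <- match_terms("Wigweyang.", lex, "IMPRESSIONS")
  expect_false("D_ULCER" %in% m2$concept_id)
})

test_that("matching agrees with the brute-force resolution oracle", {
  lex <- tiny_lexicon()
  surfaces <- lex$entries[lex$entries$section_scope %in% c("FINDINGS", "BOTH"),
                          c("surface", "language")]
  pool <- c(surfaces$surface, "the", "at", "with", "small", "seen", "mild")
  set.seed(202)
  for (rep in 1:40) {
    text <- paste(sample(pool, sample(3:10, 1), replace = TRUE), collapse = " ")
    got <- match_terms(text, lex, "FINDINGS")
    want <- oracle_match(text, surfaces)
    expect_equal(nrow(got), nrow(want), info = text)
    if (nrow(got)) {
      expect_equal(got$start, want$start - 1L, info = text)
      expect_equal(got$end - got$start, want$len, info = text)
      # never overlapping, sorted
      if (nrow(got) > 1) {
        expect_true(all(got$start[-1] >= got$end[-nrow(got)]), info = text)
      }
    }
  }
})

test_that("section scope filters matches and results are deterministic", {
  lex <- tiny_lexicon()
  # "erosions" is FINDINGS-scoped: invisible to an impressions scan
  expect_equal(nrow(match_terms("erosions seen", lex, "IMPRESSIONS")), 0)
  expect_equal(nrow(match_terms("erosions seen", lex, "FINDINGS")), 1)
  txt <- "erosions at the antrum and lower body"
  expect_identical(match_terms(txt, lex, "FINDINGS"),
                   match_terms(txt, lex, "FINDINGS"))
})
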