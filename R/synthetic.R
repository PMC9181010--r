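# Synthetic EGD + pathology report generator with known ground truth.
# Emulates multi-sentence screening-endoscopy narratives: organ-headed
# findings (esophagus / stomach / duodenum), diagnosis-list impressions,
# phenotype sentences with anatomic sub-sites and sizes, endoscopic
# abbreviations, negations, and mixed English / second-language surface
# forms -- using only surfaces from the supplied lexicon, so that with
# all noise disabled the extraction pipeline reproduces the gold exactly.

#' Generator configuration
#'
#' Defaults encode the development-cohort disease prevalences (44.0, 24.6,
#' 11.2, 59.8, 0.2 % for the five gastritis types; 8.2, 20.2, 4.0, 1.1,
#' 0.4 % for ulcer, polyp, submucosal tumor, dysplasia, cancer), a 61.4 %
#' male cohort with the screening age profile (2.4 % under 30, 38.0 %
#' 30-49, 54.6 % 50-69, 5.0 % 70+), extent distributions dominated by
#' extent 3 for atrophic gastritis and intestinal metaplasia and by
#' extent 1 for the other gastritis types, and lesion locations favouring
#' the antrum for ulcers and neoplasia, the body for polyps and the
#' fundus for submucosal tumors.  Sizes are log-uniform over 0.2-5.0 cm
#' (rounded to 0.1 cm, the reporting resolution).  All noise switches
#' default to zero: the default corpus is the clean closure corpus.
#'
#' @param prevalence Named per-disease presence probabilities.
#' @param extent_dist Named list (per gastritis label) of probabilities
#'   over extent `E1`, `E2`, `E3`, `UNSPECIFIED`; each sums to 1.
#' @param location_weights Named list (per non-gastritis label) of
#'   sampling weights over `ANTRUM`, `BODY`, `FUNDUS`.
#' @param p_multi_location Probability that a lesion occupies two regions.
#' @param p_unspecified_location Probability that no location is stated.
#' @param p_size Probability that a lesion sentence states a size.
#' @param size_range_cm Log-uniform size range in centimeters.
#' @param stage_dist Probabilities over ulcer stage `ACTIVE`, `HEALING`,
#'   `SCAR`, `UNSPECIFIED`; sums to 1.
#' @param p_male Probability of male sex.
#' @param age_dist Data frame with `lo`, `hi`, `p` age bins over 18-100;
#'   `p` sums to 1.
#' @param language `"EN"` or `"MIXED"` (second-language sentence forms).
#' @param p_l2 In MIXED mode, probability that a sentence uses the
#'   second-language template.
#' @param p_abbrev Abbreviation-substitution probability (noise).
#' @param p_synonym Synonym-substitution probability (noise).
#' @param p_negated_distractor Probability of adding a negated diagnosis
#'   of an absent disease to the impressions (noise).
#' @param p_nonstomach_distractor Probability of adding disease-phenotype
#'   distractor sentences to the esophagus/duodenum segments (noise).
#' @param filler_rate Probability of an extra neutral filler sentence in
#'   the stomach segment.
#' @param p_benign_pathology Probability of a benign (non-neoplastic)
#'   pathology report accompanying a report without sampled neoplasia.
#' @return Validated `gastro_gen_config` list.
#' @export
generator_config <- function(
  prevalence = c(
    ATROPHIC_GASTRITIS = 0.440, INTESTINAL_METAPLASIA = 0.246,
    SUPERFICIAL_GASTRITIS = 0.112, EROSIVE_GASTRITIS = 0.598,
    FOLLICULAR_GASTRITIS = 0.002,
    ULCER = 0.082, POLYP = 0.202, SMT = 0.040,
    DYSPLASIA = 0.011, CANCER = 0.004
  ),
  extent_dist = list(
    ATROPHIC_GASTRITIS = c(E1 = 0.15, E2 = 0.10, E3 = 0.65, UNSPECIFIED = 0.10),
    INTESTINAL_METAPLASIA = c(E1 = 0.15, E2 = 0.12, E3 = 0.63, UNSPECIFIED = 0.10),
    SUPERFICIAL_GASTRITIS = c(E1 = 0.50, E2 = 0.15, E3 = 0.20, UNSPECIFIED = 0.15),
    EROSIVE_GASTRITIS = c(E1 = 0.45, E2 = 0.20, E3 = 0.25, UNSPECIFIED = 0.10),
    FOLLICULAR_GASTRITIS = c(E1 = 0.55, E2 = 0.15, E3 = 0.20, UNSPECIFIED = 0.10)
  ),
  location_weights = list(
    ULCER = c(ANTRUM = 0.60, BODY = 0.30, FUNDUS = 0.10),
    POLYP = c(ANTRUM = 0.25, BODY = 0.55, FUNDUS = 0.20),
    SMT = c(ANTRUM = 0.20, BODY = 0.30, FUNDUS = 0.50),
    DYSPLASIA = c(ANTRUM = 0.60, BODY = 0.35, FUNDUS = 0.05),
    CANCER = c(ANTRUM = 0.45, BODY = 0.45, FUNDUS = 0.10)
  ),
  p_multi_location = 0.15, p_unspecified_location = 0.10,
  p_size = 0.90, size_range_cm = c(0.2, 5.0),
  stage_dist = c(ACTIVE = 0.35, HEALING = 0.25, SCAR = 0.25, UNSPECIFIED = 0.15),
  p_male = 0.614,
  age_dist = data.frame(lo = c(18, 30, 50, 70), hi = c(29, 49, 69, 100),
                        p = c(0.024, 0.380, 0.546, 0.050)),
  language = c("EN", "MIXED"), p_l2 = 0.5,
  p_abbrev = 0, p_synonym = 0,
  p_negated_distractor = 0, p_nonstomach_distractor = 0,
  filler_rate = 0.3, p_benign_pathology = 0.05
) {
  language <- match.arg(language)
  cfg <- list(
    prevalence = prevalence, extent_dist = extent_dist,
    location_weights = location_weights,
    p_multi_location = p_multi_location,
    p_unspecified_location = p_unspecified_location,
    p_size = p_size, size_range_cm = size_range_cm,
    stage_dist = stage_dist, p_male = p_male, age_dist = age_dist,
    language = language, p_l2 = p_l2,
    p_abbrev = p_abbrev, p_synonym = p_synonym,
    p_negated_distractor = p_negated_distractor,
    p_nonstomach_distractor = p_nonstomach_distractor,
    filler_rate = filler_rate, p_benign_pathology = p_benign_pathology
  )
  probs <- c(prevalence, p_multi_location, p_unspecified_location, p_size,
             p_male, p_l2, p_abbrev, p_synonym, p_negated_distractor,
             p_nonstomach_distractor, filler_rate, p_benign_pathology)
  if (any(probs < 0 | probs > 1)) stop("generator probabilities must lie in [0, 1]")
  if (!setequal(names(prevalence), GASTRIC_DISEASES))
    stop("prevalence must name all ten diseases")
  for (d in GASTRITIS_DISEASES) {
    if (abs(sum(extent_dist[[d]]) - 1) > 1e-8)
      stop("extent distribution for ", d, " must sum to 1")
  }
  if (abs(sum(stage_dist) - 1) > 1e-8) stop("stage distribution must sum to 1")
  if (abs(sum(age_dist$p) - 1) > 1e-8) stop("age distribution must sum to 1")
  if (size_range_cm[1] <= 0 || size_range_cm[2] < size_range_cm[1])
    stop("invalid size range")
  structure(cfg, class = "gastro_gen_config")
}

# ---- surface selection ------------------------------------------------

surfaces_of <- function(lexicon, concept) {
  e <- lexicon$entries
  e[e$concept_id == concept, , drop = FALSE]
}

is_abbrev_surface <- function(s) grepl("^[A-Z][A-Za-z0-9]{1,3}$", s)

# pick a surface for a concept honouring language mode and noise switches
pick_surface <- function(lexicon, concept, config, prefer_l2 = FALSE) {
  s <- surfaces_of(lexicon, concept)
  en <- s$surface[s$language == "EN"]
  l2 <- s$surface[s$language == "L2"]
  if (prefer_l2 && length(l2)) return(sample(l2, 1))
  if (!length(en)) return(sample(l2, 1))
  abbrevs <- en[is_abbrev_surface(en)]
  plain <- en[!is_abbrev_surface(en)]
  canonical <- if (length(plain)) plain[1] else en[1]
  if (length(abbrevs) && stats::runif(1) < config$p_abbrev)
    return(sample(abbrevs, 1))
  syn <- setdiff(plain, canonical)
  if (length(syn) && stats::runif(1) < config$p_synonym)
    return(sample(syn, 1))
  canonical
}

# subsite concepts of a region
region_subsites <- function(lexicon, region) {
  names(lexicon$subsite_region)[lexicon$subsite_region == region]
}

# first diagnosis concept of a disease label
diagnosis_concept <- function(lexicon, disease) {
  ids <- names(lexicon$disease_targets)[lexicon$disease_targets == disease]
  ids[1]
}

# phenotype concept preferred for findings sentences, per disease
FINDINGS_PHENOTYPE <- c(
  ATROPHIC_GASTRITIS = "P_ATROPHY", INTESTINAL_METAPLASIA = "P_IMPLAQUE",
  SUPERFICIAL_GASTRITIS = "P_ERYTHEMA", EROSIVE_GASTRITIS = "P_EROSION",
  FOLLICULAR_GASTRITIS = "P_NODULARITY",
  ULCER = "P_ULCER", POLYP = "P_POLYP", SMT = "P_SMT",
  DYSPLASIA = "P_ADENOMA", CANCER = "P_MASS"
)

STAGE_CONCEPT <- c(ACTIVE = "S_ACTIVE", HEALING = "S_HEALING", SCAR = "S_SCAR")

NEUTRAL_FILLERS <- c(
  "Mucosal folds were regular.",
  "Otherwise unremarkable.",
  "Good distension was obtained.",
  "The remainder of the examination was normal."
)
ESO_FILLERS <- c("Unremarkable mucosa.", "Z-line was clear.")
DUO_FILLERS <- c("Bulb and second portion unremarkable.")
ESO_DISTRACTORS <- c("Mild esophagitis with erosions.",
                     "Small ulceration above the Z-line.")
DUO_DISTRACTORS <- c("Few erosions at the bulb.",
                     "Small ulceration at the bulb.")

cap_first <- function(x) {
  # capitalize only a leading ASCII letter; L2 surfaces are matched
  # case-sensitively and must stay untouched
  sub("^([a-z])", "\\U\\1", x, perl = TRUE)
}

fmt_size <- function(cm) formatC(cm, format = "f", digits = 1)

# ---- report assembly --------------------------------------------------

sample_regions <- function(lexicon, config, disease) {
  if (stats::runif(1) < config$p_unspecified_location) return(character(0))
  w <- config$location_weights[[disease]]
  k <- if (stats::runif(1) < config$p_multi_location) 2L else 1L
  sample(names(w), k, prob = w)
}

# choose concrete subsite concepts realizing a target extent category
subsites_for_extent <- function(lexicon, extent) {
  ant <- region_subsites(lexicon, "ANTRUM")
  bf <- c(region_subsites(lexicon, "BODY"), region_subsites(lexicon, "FUNDUS"))
  switch(extent,
    E1 = sample(ant, sample(1:2, 1)),
    E2 = sample(bf, sample(1:2, 1)),
    E3 = c(sample(ant, 1), sample(bf, 1)),
    UNSPECIFIED = character(0)
  )
}

gastritis_sentence <- function(lexicon, config, disease, subsites, l2) {
  phen <- pick_surface(lexicon, FINDINGS_PHENOTYPE[[disease]], config,
                       prefer_l2 = l2)
  surfs <- vapply(subsites, function(cc)
    pick_surface(lexicon, cc, config, prefer_l2 = l2), character(1))
  if (l2) {
    if (length(surfs)) paste0(paste(surfs, collapse = " mich "), " ", phen, " gwanchal.")
    else paste0("mimanseong ", phen, " gwanchal.")
  } else {
    if (length(surfs)) cap_first(paste0(phen, " at the ", paste(surfs, collapse = " and "), "."))
    else cap_first(paste0("diffuse ", phen, " was noted."))
  }
}

lesion_sentence <- function(lexicon, config, disease, subsites, size_cm,
                            stage, l2) {
  phen <- pick_surface(lexicon, FINDINGS_PHENOTYPE[[disease]], config,
                       prefer_l2 = l2)
  size_part <- NULL
  if (!is.na(size_cm)) {
    style <- stats::runif(1)
    if (style < 0.25) {
      # dimension expression; the maximum dimension is the recorded size
      other <- max(round(size_cm * stats::runif(1, 0.4, 0.95), 1), 0.1)
      size_part <- paste0(fmt_size(other), " x ", fmt_size(size_cm), " cm")
    } else if (style < 0.45) {
      size_part <- paste0(round(size_cm * 10), " mm")
    } else {
      size_part <- paste0(fmt_size(size_cm), " cm")
    }
  }
  stage_part <- NULL
  if (disease == "ULCER" && stage != "UNSPECIFIED") {
    sc <- STAGE_CONCEPT[[stage]]
    surf <- pick_surface(lexicon, sc, config)
    stage_part <- if (is_abbrev_surface(surf)) paste0("(", surf, ")") else surf
  }
  surfs <- vapply(subsites, function(cc)
    pick_surface(lexicon, cc, config, prefer_l2 = l2), character(1))
  if (l2) {
    parts <- c(if (length(surfs)) paste(surfs, collapse = " mich "),
               size_part, phen,
               if (!is.null(stage_part)) stage_part, "gwanchal.")
    paste(parts, collapse = " ")
  } else {
    head <- paste(c(size_part,
                    if (!is.null(stage_part) && !grepl("^\\(", stage_part)) stage_part,
                    phen), collapse = " ")
    tail_stage <- if (!is.null(stage_part) && grepl("^\\(", stage_part)) stage_part
    loc <- if (length(surfs)) paste0(" at the ", paste(surfs, collapse = " and "))
    cap_first(paste0(paste(c(head, tail_stage), collapse = " "),
                     loc %||% "", "."))
  }
}

use_l2 <- function(config) {
  config$language == "MIXED" && stats::runif(1) < config$p_l2
}

#' Generate one synthetic EGD report with gold annotations
#'
#' Diseases are sampled independently by prevalence; attributes come from
#' the configured distributions; the findings text is assembled from an
#' organ-header template (esophagus filler / stomach phenotype sentences /
#' duodenum filler) using only lexicon surfaces; the impressions list the
#' diagnosis surfaces; sampled dysplasia or cancer emits a linked
#' pathology report with a matching histologic diagnosis.  The gold
#' records reflect the sampled truth exactly.
#'
#' Consumes the R random number stream: seed it (or use
#' [generate_corpus()]) for reproducibility.
#'
#' @param config A `gastro_gen_config` from [generator_config()].
#' @param lexicon A `gastro_lexicon` (default: the seed lexicon).
#' @param report_id,patient_id Identifiers for the generated report.
#' @param force Optional named list (by disease label) of attribute
#'   overrides, e.g. `list(ULCER = list(present = TRUE, stage = "ACTIVE",
#'   locations = "ANTRUM", size_cm = 1.2))`; forces that disease's sampled
#'   truth before the text is assembled.
#' @return List with `report` (one-row data frame), `pathology` (data
#'   frame or `NULL`) and `gold` (ten-row annotation data frame).
#' @export
generate_report <- function(config, lexicon = NULL, report_id = "R00001",
                            patient_id = "P00001", force = NULL) {
  if (!inherits(config, "gastro_gen_config")) stop("invalid generator config")
  if (is.null(lexicon)) lexicon <- load_lexicon(seed_lexicon_path())

  # demographics
  sex <- if (stats::runif(1) < config$p_male) "MALE" else "FEMALE"
  bin <- sample(nrow(config$age_dist), 1, prob = config$age_dist$p)
  age <- sample(config$age_dist$lo[bin]:config$age_dist$hi[bin], 1)
  exam_date <- sprintf("%04d-%02d-%02d", sample(2010:2019, 1),
                       sample(1:12, 1), sample(1:28, 1))

  present <- stats::runif(length(GASTRIC_DISEASES)) <
    config$prevalence[GASTRIC_DISEASES]
  names(present) <- GASTRIC_DISEASES

  truth <- list()
  for (d in GASTRIC_DISEASES) {
    t <- list(present = unname(present[d]), extent = "UNSPECIFIED",
              subsites = character(0), locations = character(0),
              stage = "UNSPECIFIED", size_cm = NA_real_)
    if (t$present) {
      if (d %in% GASTRITIS_DISEASES) {
        ext <- sample(names(config$extent_dist[[d]]), 1,
                      prob = config$extent_dist[[d]])
        t$subsites <- subsites_for_extent(lexicon, ext)
        regions <- unique(unname(lexicon$subsite_region[t$subsites]))
        t$extent <- derive_extent(regions)
      } else {
        regions <- sample_regions(lexicon, config, d)
        t$subsites <- vapply(regions, function(r)
          sample(region_subsites(lexicon, r), 1), character(1))
        t$locations <- sort(unique(regions))
        if (stats::runif(1) < config$p_size)
          t$size_cm <- max(round(exp(stats::runif(
            1, log(config$size_range_cm[1]), log(config$size_range_cm[2]))), 1),
            config$size_range_cm[1])
        if (d == "ULCER")
          t$stage <- sample(names(config$stage_dist), 1,
                            prob = config$stage_dist)
      }
    }
    truth[[d]] <- t
  }

  # forced overrides (before text assembly; gold always equals truth)
  for (d in names(force %||% list())) {
    f <- force[[d]]
    t <- truth[[d]]
    t$present <- f$present %||% TRUE
    if (!t$present) {
      t <- list(present = FALSE, extent = "UNSPECIFIED",
                subsites = character(0), locations = character(0),
                stage = "UNSPECIFIED", size_cm = NA_real_)
    } else if (d %in% GASTRITIS_DISEASES) {
      if (!is.null(f$extent)) {
        t$subsites <- subsites_for_extent(lexicon, f$extent)
        t$extent <- derive_extent(unique(unname(lexicon$subsite_region[t$subsites])))
      }
    } else {
      if (!is.null(f$locations)) {
        t$locations <- sort(unique(f$locations))
        t$subsites <- vapply(t$locations, function(r)
          sample(region_subsites(lexicon, r), 1), character(1))
      }
      if (!is.null(f$size_cm)) t$size_cm <- f$size_cm
      if (d == "ULCER" && !is.null(f$stage)) t$stage <- f$stage
    }
    truth[[d]] <- t
  }

  # findings: stomach sentences
  sto <- character(0)
  for (d in GASTRIC_DISEASES) {
    t <- truth[[d]]
    if (!t$present) next
    l2 <- use_l2(config)
    if (d %in% GASTRITIS_DISEASES) {
      sto <- c(sto, gastritis_sentence(lexicon, config, d, t$subsites, l2))
    } else {
      sto <- c(sto, lesion_sentence(lexicon, config, d, t$subsites,
                                    t$size_cm, t$stage, l2))
    }
  }
  if (!length(sto) || stats::runif(1) < config$filler_rate)
    sto <- c(sto, sample(NEUTRAL_FILLERS, 1))

  eso <- sample(ESO_FILLERS, 1)
  duo <- sample(DUO_FILLERS, 1)
  if (stats::runif(1) < config$p_nonstomach_distractor) {
    eso <- c(eso, sample(ESO_DISTRACTORS, 1))
    duo <- c(duo, sample(DUO_DISTRACTORS, 1))
  }
  hdr <- function(concept) {
    l2 <- use_l2(config)
    paste0(pick_surface(lexicon, concept, config, prefer_l2 = l2), ":")
  }
  findings_text <- paste(
    hdr("O_ESO"), paste(eso, collapse = " "),
    hdr("O_STO"), paste(sto, collapse = " "),
    hdr("O_DUO"), paste(duo, collapse = " ")
  )

  # impressions: diagnosis list plus optional negated distractor;
  # L2 surfaces are matched case-sensitively and must not be capitalized
  is_l2_surface <- function(concept, surf) {
    s <- surfaces_of(lexicon, concept)
    surf %in% s$surface[s$language == "L2"]
  }
  imp <- character(0)
  for (d in GASTRIC_DISEASES) {
    if (!truth[[d]]$present) next
    l2 <- use_l2(config)
    dc <- diagnosis_concept(lexicon, d)
    surf <- pick_surface(lexicon, dc, config, prefer_l2 = l2)
    imp <- c(imp, paste0(if (is_l2_surface(dc, surf)) surf else cap_first(surf), "."))
  }
  if (stats::runif(1) < config$p_negated_distractor) {
    absent <- GASTRIC_DISEASES[!vapply(truth, `[[`, logical(1), "present")]
    if (length(absent)) {
      d <- sample(absent, 1)
      l2 <- use_l2(config)
      surf <- pick_surface(lexicon, diagnosis_concept(lexicon, d), config,
                           prefer_l2 = l2)
      imp <- c(imp, if (l2) paste0(surf, " eopseum.")
                    else paste0("No ", surf, "."))
    }
  }
  if (!length(imp)) imp <- "No remarkable findings."
  impressions_text <- paste(imp, collapse = " ")

  # pathology report for sampled neoplasia (or occasional benign biopsy)
  pathology <- NULL
  specimens <- list()
  path_dx <- list(
    DYSPLASIA = c("tubular adenoma with low grade dysplasia",
                  "tubular adenoma with high grade dysplasia",
                  "tubulovillous adenoma"),
    CANCER = c("adenocarcinoma, moderately differentiated",
               "poorly differentiated adenocarcinoma",
               "neuroendocrine tumor", "MALT lymphoma")
  )
  for (d in c("DYSPLASIA", "CANCER")) {
    t <- truth[[d]]
    if (!t$present) next
    site <- if (length(t$subsites)) {
      sub_surf <- surfaces_of(lexicon, t$subsites[1])
      en <- sub_surf$surface[sub_surf$language == "EN"]
      paste0("stomach, ", if (length(en)) en[1] else sub_surf$surface[1])
    } else "stomach"
    specimens[[length(specimens) + 1L]] <-
      data.frame(site_text = site,
                 diagnosis_text = sample(path_dx[[d]], 1),
                 stringsAsFactors = FALSE)
  }
  if (!length(specimens) &&
      stats::runif(1) < config$p_benign_pathology) {
    specimens[[1L]] <- data.frame(
      site_text = "stomach, antrum",
      diagnosis_text = "chronic gastritis, no neoplastic change",
      stringsAsFactors = FALSE
    )
  }
  if (length(specimens)) {
    pathology <- data.frame(report_id = paste0("PATH-", report_id),
                            egd_report_id = report_id,
                            stringsAsFactors = FALSE)
    pathology$specimens <- list(do.call(rbind, specimens))
  }

  report <- data.frame(
    report_id = report_id, patient_id = patient_id, exam_date = exam_date,
    age = as.integer(age), sex = sex, findings_text = findings_text,
    impressions_text = impressions_text, stringsAsFactors = FALSE
  )

  gold_rows <- lapply(GASTRIC_DISEASES, function(d) {
    t <- truth[[d]]
    row <- data.frame(report_id = report_id, disease = d,
                      present = t$present, extent = t$extent,
                      stage = t$stage, size_cm = t$size_cm,
                      stringsAsFactors = FALSE)
    row$locations <- list(t$locations)
    row
  })
  gold <- do.call(rbind, gold_rows)
  validate_records(gold)
  list(report = report, pathology = pathology, gold = gold)
}

#' Generate a synthetic corpus
#'
#' Deterministic for fixed `(config, n, seed)`: regeneration with the
#' same arguments yields identical corpora.
#'
#' @param config A `gastro_gen_config`.
#' @param n Number of reports.
#' @param seed Integer seed.
#' @param lexicon A `gastro_lexicon` (default: the seed lexicon).
#' @return List with `reports` (n rows), `pathology` (0+ rows) and `gold`
#'   (`10 * n` rows).
#' @export
generate_corpus <- function(config, n, seed, lexicon = NULL) {
  if (is.null(lexicon)) lexicon <- load_lexicon(seed_lexicon_path())
  set.seed(as.integer(seed))
  reports <- vector("list", n); gold <- vector("list", n)
  pathology <- list()
  for (i in seq_len(n)) {
    g <- generate_report(config, lexicon,
                         report_id = sprintf("R%05d", i),
                         patient_id = sprintf("P%05d", i))
    reports[[i]] <- g$report
    gold[[i]] <- g$gold
    if (!is.null(g$pathology)) pathology[[length(pathology) + 1L]] <- g$pathology
  }
  list(
    reports = do.call(rbind, reports),
    pathology = do.call(rbind, pathology) %||% empty_pathology(),
    gold = do.call(rbind, gold)
  )
}

#' Write a generated corpus to disk
#'
#' @param corpus Output of [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written file paths.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    reports = file.path(dir, "reports.jsonl"),
    pathology = file.path(dir, "pathology.jsonl"),
    gold = file.path(dir, "gold.jsonl")
  )
  write_reports(corpus$reports, paths[["reports"]])
  write_pathology(corpus$pathology, paths[["pathology"]])
  write_gold(corpus$gold, paths[["gold"]])
  paths
}
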