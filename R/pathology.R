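# Pathology-based classification of the two neoplastic diseases and the
# merge with the endoscopic extraction.  Pathology is authoritative for
# dysplasia/cancer presence in both directions: the dysplasia category is
# defined by adenomas of any grade, the cancer category by
# adenocarcinoma, neuroendocrine tumor and lymphoma, all of which are
# histologic terms.

#' Classify one pathology specimen diagnosis text
#'
#' `DYSPLASIA` when a non-negated adenoma/dysplasia surface matches
#' (adenomas of all grades belong to the dysplasia category); `CANCER`
#' when a non-negated adenocarcinoma, neuroendocrine tumor or lymphoma
#' surface matches; `CANCER` takes precedence when both match (carcinoma
#' text frequently co-mentions an adenoma background); otherwise `OTHER`.
#'
#' Matching uses the lexicon's phenotype concepts mapped to the dysplasia
#' and cancer disease concepts, scanned over the cleaned diagnosis text
#' with the findings-section scope.
#'
#' @param diagnosis_text Free-text specimen diagnosis.
#' @param lexicon A `gastro_lexicon`.
#' @param opts Options from [pipeline_options()].
#' @return One of `"DYSPLASIA"`, `"CANCER"`, `"OTHER"`.
#' @export
classify_specimen <- function(diagnosis_text, lexicon,
                              opts = pipeline_options()) {
  txt <- clean_text(diagnosis_text)
  sent <- data.frame(text = txt, index = 0L, start = 0L, end = nchar(txt),
                     stringsAsFactors = FALSE)
  mentions <- scan_section(sent, lexicon, "FINDINGS", opts)
  mentions <- mentions[!mentions$negated, , drop = FALSE]
  if (!nrow(mentions)) return("OTHER")
  concepts_of <- function(label) {
    diag <- names(lexicon$disease_targets)[lexicon$disease_targets == label]
    unique(unlist(lexicon$phenotype_of[diag], use.names = FALSE))
  }
  if (any(mentions$concept_id %in% concepts_of("CANCER"))) return("CANCER")
  if (any(mentions$concept_id %in% concepts_of("DYSPLASIA"))) return("DYSPLASIA")
  "OTHER"
}

#' Merge pathology results into extracted disease records
#'
#' For the `DYSPLASIA` and `CANCER` records of every report, presence is
#' set to the pathology flag (pathology is authoritative in both
#' directions: an endoscopic impression without histologic confirmation
#' becomes absent, and a histologic finding without an endoscopic
#' impression becomes present).  Location and size are retained from the
#' endoscopic extraction when the impression also flagged the disease;
#' otherwise locations are inferred from the specimen site text through
#' the subsite-region map when parseable.  All other disease records are
#' unchanged.
#'
#' @param egd_records Disease records from [summarize_report()] /
#'   [run_pipeline()].
#' @param pathology_reports Pathology data frame (see [read_pathology()]).
#'   Reports with no linked pathology row count as pathology-negative.
#' @param lexicon A `gastro_lexicon`.
#' @param opts Options from [pipeline_options()].
#' @return List with `records` (updated), `results` (one row per pathology
#'   report: `egd_report_id`, `dysplasia_present`, `cancer_present`) and
#'   `warnings`.
#' @export
merge_pathology <- function(egd_records, pathology_reports, lexicon,
                            opts = pipeline_options()) {
  warnings <- character(0)
  report_ids <- unique(egd_records$report_id)

  res_rows <- lapply(seq_len(nrow(pathology_reports)), function(i) {
    sp <- pathology_reports$specimens[[i]]
    cls <- vapply(sp$diagnosis_text, classify_specimen, character(1),
                  lexicon = lexicon, opts = opts, USE.NAMES = FALSE)
    data.frame(
      egd_report_id = pathology_reports$egd_report_id[i],
      dysplasia_present = any(cls == "DYSPLASIA"),
      cancer_present = any(cls == "CANCER"),
      stringsAsFactors = FALSE
    )
  })
  results <- do.call(rbind, res_rows) %||%
    data.frame(egd_report_id = character(0), dysplasia_present = logical(0),
               cancer_present = logical(0), stringsAsFactors = FALSE)
  dangling <- setdiff(results$egd_report_id, report_ids)
  if (length(dangling))
    warnings <- c(warnings,
                  paste0("pathology report for unknown EGD report id: ", dangling))

  # aggregate per linked EGD report (several pathology reports may link)
  flag_for <- function(rid, col) {
    rows <- results[results$egd_report_id == rid, col]
    length(rows) > 0 && any(rows)
  }
  site_regions <- function(rid, label) {
    idx <- which(pathology_reports$egd_report_id == rid)
    regs <- character(0)
    for (i in idx) {
      sp <- pathology_reports$specimens[[i]]
      for (j in seq_len(nrow(sp))) {
        if (classify_specimen(sp$diagnosis_text[j], lexicon, opts) != label) next
        m <- match_terms(clean_text(sp$site_text[j]), lexicon, "FINDINGS",
                         classes = "LOCATION_SUBSITE")
        regs <- c(regs, unname(lexicon$subsite_region[m$concept_id]))
      }
    }
    sort(unique(regs[!is.na(regs)]))
  }

  for (rid in report_ids) {
    for (d in c("DYSPLASIA", "CANCER")) {
      k <- which(egd_records$report_id == rid & egd_records$disease == d)
      if (!length(k)) next
      path_flag <- flag_for(rid, if (d == "DYSPLASIA") "dysplasia_present" else "cancer_present")
      egd_flag <- egd_records$present[k]
      if (egd_flag && !path_flag)
        warnings <- c(warnings,
                      paste0(rid, ": endoscopic ", d,
                             " impression without histologic confirmation"))
      egd_records$present[k] <- path_flag
      if (!path_flag) {
        egd_records$locations[[k]] <- character(0)
        egd_records$size_cm[k] <- NA_real_
        egd_records$extent[k] <- "UNSPECIFIED"
        egd_records$stage[k] <- "UNSPECIFIED"
      } else if (!egd_flag) {
        # histology-only positive: infer locations from the specimen site text
        egd_records$locations[[k]] <- site_regions(rid, d)
        egd_records$size_cm[k] <- NA_real_
      }
    }
  }
  validate_records(egd_records)
  list(records = egd_records, results = results, warnings = warnings)
}
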