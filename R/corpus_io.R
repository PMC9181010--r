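# Line-delimited record I/O (one JSON object per line, UTF-8) for EGD
# reports, pathology reports, gold annotations and extracted disease
# records, plus the structural validators behind them.

report_columns <- c("report_id", "patient_id", "exam_date", "age", "sex",
                    "findings_text", "impressions_text")

#' Validate EGD report records
#'
#' Checks the structural invariants of a report data frame: all fields
#' present, unique report ids, age within 18-100, sex `MALE`/`FEMALE`,
#' parseable ISO-8601 exam dates, and section texts that may be empty but
#' not absent.
#'
#' @param reports Data frame of EGD reports.
#' @return The reports, invisibly; stops with an informative error naming
#'   the offending report on the first violation.
#' @export
validate_reports <- function(reports) {
  miss <- setdiff(report_columns, names(reports))
  if (length(miss)) stop("report records missing fields: ", paste(miss, collapse = ", "))
  if (anyDuplicated(reports$report_id))
    stop("duplicate report_id: ",
         paste(unique(reports$report_id[duplicated(reports$report_id)]), collapse = ", "))
  bad_age <- which(is.na(reports$age) | reports$age < 18 | reports$age > 100)
  if (length(bad_age))
    stop("age out of range 18-100 for report(s): ",
         paste(reports$report_id[bad_age], collapse = ", "))
  bad_sex <- which(!reports$sex %in% c("MALE", "FEMALE"))
  if (length(bad_sex))
    stop("invalid sex for report(s): ", paste(reports$report_id[bad_sex], collapse = ", "))
  bad_date <- which(is.na(as.Date(reports$exam_date, format = "%Y-%m-%d")))
  if (length(bad_date))
    stop("unparseable ISO-8601 exam_date for report(s): ",
         paste(reports$report_id[bad_date], collapse = ", "))
  if (any(is.na(reports$findings_text)) || any(is.na(reports$impressions_text)))
    stop("findings_text/impressions_text may be empty but not absent")
  invisible(reports)
}

#' Validate extracted disease records or gold annotations
#'
#' Enforces the conditional-field invariants of a disease record: when
#' `present` is `FALSE` the extent and stage are `UNSPECIFIED`, locations
#' empty and size absent; extent is only specified for gastritis labels,
#' stage only for ulcers, size only for non-gastritis labels and positive
#' when present.
#'
#' @param records Data frame with columns `report_id`, `disease`,
#'   `present`, `extent`, `locations` (list of character vectors), `stage`,
#'   `size_cm` (`NA` = absent), optionally `evidence`.
#' @return The records, invisibly; stops with an informative error on the
#'   first violated invariant.
#' @export
validate_records <- function(records) {
  need <- c("report_id", "disease", "present", "extent", "locations",
            "stage", "size_cm")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("disease records missing fields: ", paste(miss, collapse = ", "))
  ctx <- function(i) paste0(records$report_id[i], "/", records$disease[i])
  for (i in seq_len(nrow(records))) {
    d <- records$disease[i]
    if (!d %in% GASTRIC_DISEASES) stop("unknown disease label: ", d)
    if (!records$extent[i] %in% EXTENT_LEVELS)
      stop("invalid extent for ", ctx(i))
    if (!records$stage[i] %in% ULCER_STAGES)
      stop("invalid stage for ", ctx(i))
    locs <- records$locations[[i]]
    if (length(locs) && !all(locs %in% STOMACH_REGIONS))
      stop("invalid locations for ", ctx(i))
    if (!records$present[i]) {
      if (records$extent[i] != "UNSPECIFIED" || length(locs) ||
          records$stage[i] != "UNSPECIFIED" || !is.na(records$size_cm[i]))
        stop("absent disease carries attributes for ", ctx(i))
    }
    if (records$extent[i] != "UNSPECIFIED" && !d %in% GASTRITIS_DISEASES)
      stop("extent specified for non-gastritis label for ", ctx(i))
    if (length(locs) && d %in% GASTRITIS_DISEASES)
      stop("locations specified for gastritis label for ", ctx(i))
    if (records$stage[i] != "UNSPECIFIED" && d != "ULCER")
      stop("stage specified for non-ulcer label for ", ctx(i))
    if (!is.na(records$size_cm[i])) {
      if (d %in% GASTRITIS_DISEASES)
        stop("size specified for gastritis label for ", ctx(i))
      if (records$size_cm[i] <= 0)
        stop("non-positive size for ", ctx(i))
    }
  }
  invisible(records)
}

write_jsonl <- function(objects, path) {
  lines <- vapply(objects, function(o) {
    as.character(jsonlite::toJSON(o, auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null"))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

read_jsonl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
             error = function(e) stop("malformed record at line ", i, " of ",
                                      path, ": ", conditionMessage(e)))
  })
}

req_field <- function(obj, field, line) {
  if (is.null(obj[[field]]))
    stop("record line ", line, ": missing field '", field, "'")
  obj[[field]]
}

#' Read EGD reports from a line-delimited record file
#'
#' One JSON object per line with fields `report_id`, `patient_id`,
#' `exam_date` (ISO-8601), `age`, `sex` (`MALE`/`FEMALE`),
#' `findings_text`, `impressions_text`.
#'
#' @param path Input file path.
#' @return Data frame of reports (one row per report), validated.
#' @export
read_reports <- function(path) {
  objs <- read_jsonl(path)
  rows <- lapply(seq_along(objs), function(i) {
    o <- objs[[i]]
    data.frame(
      report_id = as.character(req_field(o, "report_id", i)),
      patient_id = as.character(req_field(o, "patient_id", i)),
      exam_date = as.character(req_field(o, "exam_date", i)),
      age = as.integer(req_field(o, "age", i)),
      sex = as.character(req_field(o, "sex", i)),
      findings_text = as.character(req_field(o, "findings_text", i)),
      impressions_text = as.character(req_field(o, "impressions_text", i)),
      stringsAsFactors = FALSE
    )
  })
  reports <- do.call(rbind, rows) %||% empty_reports()
  validate_reports(reports)
  reports
}

empty_reports <- function() {
  data.frame(report_id = character(0), patient_id = character(0),
             exam_date = character(0), age = integer(0), sex = character(0),
             findings_text = character(0), impressions_text = character(0),
             stringsAsFactors = FALSE)
}

#' Write EGD reports to a line-delimited record file
#' @param reports Data frame as returned by [read_reports()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_reports <- function(reports, path) {
  validate_reports(reports)
  objs <- lapply(seq_len(nrow(reports)), function(i) {
    list(report_id = reports$report_id[i], patient_id = reports$patient_id[i],
         exam_date = reports$exam_date[i], age = reports$age[i],
         sex = reports$sex[i], findings_text = reports$findings_text[i],
         impressions_text = reports$impressions_text[i])
  })
  write_jsonl(objs, path)
}

#' Read pathology reports
#'
#' One JSON object per line with fields `report_id`, `egd_report_id` and
#' `specimens`, an array of objects with `site_text` and `diagnosis_text`.
#'
#' @param path Input file path.
#' @param reports Optional EGD report data frame; when supplied, pathology
#'   rows whose `egd_report_id` does not occur among the reports are
#'   collected into a `dangling` attribute and a warning is raised.
#' @return Data frame with a `specimens` list column (each element a data
#'   frame of `site_text`, `diagnosis_text`).
#' @export
read_pathology <- function(path, reports = NULL) {
  objs <- read_jsonl(path)
  rows <- lapply(seq_along(objs), function(i) {
    o <- objs[[i]]
    sp <- req_field(o, "specimens", i)
    sp <- as.data.frame(sp, stringsAsFactors = FALSE)
    if (!nrow(sp)) stop("record line ", i, ": specimens must be non-empty")
    if (!all(c("site_text", "diagnosis_text") %in% names(sp)))
      stop("record line ", i, ": specimens need site_text and diagnosis_text")
    df <- data.frame(report_id = as.character(req_field(o, "report_id", i)),
                     egd_report_id = as.character(req_field(o, "egd_report_id", i)),
                     stringsAsFactors = FALSE)
    df$specimens <- list(sp[, c("site_text", "diagnosis_text"), drop = FALSE])
    df
  })
  path_df <- do.call(rbind, rows) %||% empty_pathology()
  if (!is.null(reports)) {
    dangling <- setdiff(path_df$egd_report_id, reports$report_id)
    attr(path_df, "dangling") <- dangling
    if (length(dangling))
      warning("pathology reports reference unknown EGD report ids: ",
              paste(dangling, collapse = ", "))
  }
  path_df
}

empty_pathology <- function() {
  out <- data.frame(report_id = character(0), egd_report_id = character(0),
                    stringsAsFactors = FALSE)
  out$specimens <- list()
  out
}

#' Write pathology reports
#' @param pathology Data frame as returned by [read_pathology()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_pathology <- function(pathology, path) {
  objs <- lapply(seq_len(nrow(pathology)), function(i) {
    list(report_id = pathology$report_id[i],
         egd_report_id = pathology$egd_report_id[i],
         specimens = pathology$specimens[[i]])
  })
  write_jsonl(objs, path)
}

record_to_obj <- function(records, i, with_evidence) {
  o <- list(
    report_id = records$report_id[i], disease = records$disease[i],
    present = records$present[i], extent = records$extent[i],
    locations = as.character(records$locations[[i]]),
    stage = records$stage[i],
    size_cm = if (is.na(records$size_cm[i])) NULL else records$size_cm[i]
  )
  if (with_evidence) {
    ev <- records$evidence[[i]]
    o$evidence <- if (is.null(ev) || !nrow(ev)) list() else ev
  }
  o
}

obj_to_record <- function(o, i, with_evidence) {
  df <- data.frame(
    report_id = as.character(req_field(o, "report_id", i)),
    disease = as.character(req_field(o, "disease", i)),
    present = as.logical(req_field(o, "present", i)),
    extent = as.character(req_field(o, "extent", i)),
    stage = as.character(req_field(o, "stage", i)),
    size_cm = if (is.null(o$size_cm)) NA_real_ else as.numeric(o$size_cm),
    stringsAsFactors = FALSE
  )
  df$locations <- list(as.character(unlist(o$locations)))
  if (with_evidence) {
    ev <- o$evidence
    if (is.null(ev) || (is.list(ev) && !length(ev))) {
      df$evidence <- list(empty_mentions())
    } else {
      ev <- as.data.frame(ev, stringsAsFactors = FALSE)
      ev$start <- as.integer(ev$start); ev$end <- as.integer(ev$end)
      ev$sentence_index <- as.integer(ev$sentence_index)
      ev$negated <- as.logical(ev$negated)
      df$evidence <- list(ev[, names(empty_mentions()), drop = FALSE])
    }
  }
  df
}

empty_mentions <- function() {
  data.frame(concept_id = character(0), concept_class = character(0),
             start = integer(0), end = integer(0), section = character(0),
             sentence_index = integer(0), negated = logical(0),
             surface = character(0), stringsAsFactors = FALSE)
}

#' Write extracted disease records
#'
#' Ten records per report (one per disease); the conditional-field
#' invariants are asserted before anything is written.
#'
#' @param records Data frame of disease records (with `evidence`).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_records <- function(records, path) {
  validate_records(records)
  has_ev <- "evidence" %in% names(records)
  objs <- lapply(seq_len(nrow(records)), function(i)
    record_to_obj(records, i, with_evidence = has_ev))
  write_jsonl(objs, path)
}

#' Read extracted disease records
#' @param path Input file path.
#' @return Validated data frame of disease records with `evidence`.
#' @export
read_records <- function(path) {
  objs <- read_jsonl(path)
  out <- do.call(rbind, lapply(seq_along(objs), function(i)
    obj_to_record(objs[[i]], i, with_evidence = TRUE))) %||% empty_records(TRUE)
  validate_records(out)
  out
}

#' Write gold annotations (disease records without evidence)
#' @param gold Data frame of gold annotations.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_gold <- function(gold, path) {
  validate_records(gold)
  objs <- lapply(seq_len(nrow(gold)), function(i)
    record_to_obj(gold, i, with_evidence = FALSE))
  write_jsonl(objs, path)
}

#' Read gold annotations
#' @param path Input file path.
#' @return Validated data frame of gold annotations.
#' @export
read_gold <- function(path) {
  objs <- read_jsonl(path)
  out <- do.call(rbind, lapply(seq_along(objs), function(i)
    obj_to_record(objs[[i]], i, with_evidence = FALSE))) %||% empty_records(FALSE)
  validate_records(out)
  out
}

empty_records <- function(with_evidence) {
  out <- data.frame(report_id = character(0), disease = character(0),
                    present = logical(0), extent = character(0),
                    stage = character(0), size_cm = numeric(0),
                    stringsAsFactors = FALSE)
  out$locations <- list()
  if (with_evidence) out$evidence <- list()
  out
}
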