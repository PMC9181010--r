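# Per-variable evaluation of pipeline output against gold-standard
# annotations: binary confusion counts per (disease, field, level) and
# the four metrics (sensitivity, PPV, accuracy, F1), with pooled
# micro-averaged Overall rows.

#' Binary confusion counts for one evaluation variable
#'
#' Variables are: presence per disease; extent level (`E1`/`E2`/`E3`) per
#' gastritis label (binary: has that extent vs. not); location
#' (`ANTRUM`/`BODY`/`FUNDUS`) per non-gastritis label (per-location
#' binary); stage (`ACTIVE`/`HEALING`/`SCAR`) for ulcers; and `SIZE` for
#' the non-gastritis labels, where a report counts as agreeing when both
#' sizes are absent or both present and equal to within `tolerance_cm`
#' (a present-and-mismatched or spuriously present size counts as a false
#' positive, a missed size as a false negative).
#'
#' @param predictions Disease records from the pipeline.
#' @param gold Gold annotations covering the same report ids.
#' @param disease One of [GASTRIC_DISEASES].
#' @param field `"presence"`, `"extent"`, `"location"`, `"stage"` or
#'   `"size"`.
#' @param level The level evaluated (extent/location/stage variables).
#' @param tolerance_cm Size agreement tolerance (default 0.1 cm).
#' @return List with integer fields `tp`, `fp`, `fn`, `tn`
#'   (`tp+fp+fn+tn` equals the number of evaluated reports).
#' @export
confusion <- function(predictions, gold, disease, field, level = NULL,
                      tolerance_cm = 0.1) {
  p <- predictions[predictions$disease == disease, , drop = FALSE]
  g <- gold[gold$disease == disease, , drop = FALSE]
  unmatched <- c(setdiff(p$report_id, g$report_id),
                 setdiff(g$report_id, p$report_id))
  if (length(unmatched))
    stop("prediction/gold report ids do not match: ",
         paste(unique(unmatched), collapse = ", "))
  ord <- match(g$report_id, p$report_id)
  p <- p[ord, , drop = FALSE]

  if (field == "size") {
    pv <- p$size_cm; gv <- g$size_cm
    both_absent <- is.na(pv) & is.na(gv)
    both_match <- !is.na(pv) & !is.na(gv) & abs(pv - gv) <= tolerance_cm + 1e-9
    tp <- sum(both_match)
    tn <- sum(both_absent)
    fn <- sum(!is.na(gv) & is.na(pv))
    fp <- nrow(g) - tp - tn - fn
    return(list(tp = tp, fp = fp, fn = fn, tn = tn))
  }

  pb <- switch(field,
    presence = p$present,
    extent = p$present & p$extent == level,
    location = vapply(p$locations, function(l) level %in% l, logical(1)),
    stage = p$present & p$stage == level,
    stop("unknown evaluation field: ", field)
  )
  gb <- switch(field,
    presence = g$present,
    extent = g$present & g$extent == level,
    location = vapply(g$locations, function(l) level %in% l, logical(1)),
    stage = g$present & g$stage == level
  )
  list(tp = sum(pb & gb), fp = sum(pb & !gb),
       fn = sum(!pb & gb), tn = sum(!pb & !gb))
}

#' Metrics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, PPV `tp/(tp+fp)`, accuracy
#' `(tp+tn)/(tp+fp+fn+tn)` and F1 (harmonic mean of sensitivity and PPV).
#' Any metric with a zero denominator is undefined (`NA`), matching the
#' N/A cells of a zero-positive evaluation row; F1 is undefined when
#' either component is undefined or both are zero.
#'
#' @param counts List with `tp`, `fp`, `fn`, `tn`.
#' @return List with `sensitivity`, `ppv`, `accuracy`, `f1` (each numeric
#'   or `NA`).
#' @export
metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  acc <- if (tp + fp + fn + tn > 0) (tp + tn) / (tp + fp + fn + tn) else NA_real_
  f1 <- if (is.na(sens) || is.na(ppv) || (sens + ppv) == 0) NA_real_
        else 2 * sens * ppv / (sens + ppv)
  list(sensitivity = sens, ppv = ppv, accuracy = acc, f1 = f1)
}

# variable layout of the two performance tables
evaluation_variables <- function() {
  rows <- list()
  add <- function(group, disease, field, level)
    rows[[length(rows) + 1L]] <<- data.frame(
      group = group, disease = disease, field = field,
      level = level %||% "", stringsAsFactors = FALSE)
  for (d in GASTRITIS_DISEASES) {
    add("GASTRITIS", d, "presence", NULL)
    for (lev in c("E1", "E2", "E3")) add("GASTRITIS", d, "extent", lev)
  }
  for (d in LESION_DISEASES) {
    add("OTHER", d, "presence", NULL)
    for (lev in STOMACH_REGIONS) add("OTHER", d, "location", lev)
    if (d == "ULCER")
      for (lev in c("ACTIVE", "HEALING", "SCAR")) add("OTHER", d, "stage", lev)
    add("OTHER", d, "size", NULL)
  }
  do.call(rbind, rows)
}

#' Evaluate a corpus of predictions against gold annotations
#'
#' One row per evaluation variable in the canonical table order (per
#' gastritis label: presence then extent 1-3; per other disease: presence,
#' location antrum/body/fundus, ulcer stages, size), plus a pooled
#' micro-averaged `Overall` row per group computed from the summed
#' confusion counts.  Size rows report accuracy only (sensitivity, PPV
#' and F1 rendered as N/A).
#'
#' @param predictions Disease records from the pipeline.
#' @param gold Gold annotations for the same reports.
#' @param tolerance_cm Size agreement tolerance (default 0.1 cm).
#' @param average `"micro"` (pooled counts, default) or `"macro"` (mean of
#'   the defined per-variable metrics) for the Overall rows.
#' @return Data frame with columns `group`, `disease`, `field`, `level`,
#'   `tp`, `fp`, `fn`, `tn`, `sensitivity`, `ppv`, `accuracy`, `f1`.
#' @export
evaluate_corpus <- function(predictions, gold, tolerance_cm = 0.1,
                            average = c("micro", "macro")) {
  average <- match.arg(average)
  vars <- evaluation_variables()
  out <- vars
  out$tp <- out$fp <- out$fn <- out$tn <- NA_integer_
  out$sensitivity <- out$ppv <- out$accuracy <- out$f1 <- NA_real_
  for (i in seq_len(nrow(vars))) {
    cts <- confusion(predictions, gold, vars$disease[i], vars$field[i],
                     level = if (nzchar(vars$level[i])) vars$level[i] else NULL,
                     tolerance_cm = tolerance_cm)
    m <- metrics(cts)
    out$tp[i] <- cts$tp; out$fp[i] <- cts$fp
    out$fn[i] <- cts$fn; out$tn[i] <- cts$tn
    out$sensitivity[i] <- m$sensitivity; out$ppv[i] <- m$ppv
    out$accuracy[i] <- m$accuracy; out$f1[i] <- m$f1
    if (vars$field[i] == "size") {
      out$sensitivity[i] <- NA_real_; out$ppv[i] <- NA_real_
      out$f1[i] <- NA_real_
    }
  }
  overall <- lapply(unique(out$group), function(gr) {
    sub <- out[out$group == gr, , drop = FALSE]
    row <- data.frame(group = gr, disease = "Overall", field = "", level = "",
                      tp = sum(sub$tp), fp = sum(sub$fp), fn = sum(sub$fn),
                      tn = sum(sub$tn), stringsAsFactors = FALSE)
    if (average == "micro") {
      m <- metrics(list(tp = row$tp, fp = row$fp, fn = row$fn, tn = row$tn))
    } else {
      m <- list(sensitivity = mean(sub$sensitivity, na.rm = TRUE),
                ppv = mean(sub$ppv, na.rm = TRUE),
                accuracy = mean(sub$accuracy, na.rm = TRUE),
                f1 = mean(sub$f1, na.rm = TRUE))
    }
    row$sensitivity <- m$sensitivity; row$ppv <- m$ppv
    row$accuracy <- m$accuracy; row$f1 <- m$f1
    row
  })
  rbind(out, do.call(rbind, overall))
}

#' Write a metrics table as CSV
#'
#' Renders undefined cells as `"N/A"`, metric columns named Sensitivity,
#' PPV, Accuracy, F1-Score.
#'
#' @param table Output of [evaluate_corpus()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_metrics_csv <- function(table, path) {
  fmt <- function(x) ifelse(is.na(x), "N/A", formatC(x, digits = 3, format = "f"))
  df <- data.frame(
    Group = table$group, Disease = table$disease, Variable = table$field,
    Level = table$level,
    Sensitivity = fmt(table$sensitivity), PPV = fmt(table$ppv),
    Accuracy = fmt(table$accuracy), `F1-Score` = fmt(table$f1),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
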