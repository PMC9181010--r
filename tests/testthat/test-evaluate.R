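flip_presence <- function(records, disease, which_ids) {
  for (rid in which_ids) {
    k <- records$report_id == rid & records$disease == disease
    records$present[k] <- !records$present[k]
    records$extent[k] <- "UNSPECIFIED"
    records$stage[k] <- "UNSPECIFIED"
    records$locations[k] <- list(character(0))
    records$size_cm[k] <- NA_real_
  }
  records
}

test_that("confusion counts match direct per-report comparison", {
  ids <- sprintf("R%02d", 1:10)
  gold <- random_gold(ids, seed = 12)
  # perfect agreement
  cts <- confusion(gold, gold, "POLYP", "presence")
  npos <- sum(gold$present[gold$disease == "POLYP"])
  expect_equal(cts, list(tp = npos, fp = 0L, fn = 0L, tn = 10L - npos))

  # one flipped positive becomes a false negative
  pos_ids <- gold$report_id[gold$disease == "POLYP" & gold$present]
  pred <- flip_presence(gold, "POLYP", pos_ids[1])
  cts2 <- confusion(pred, gold, "POLYP", "presence")
  expect_equal(cts2$fn, 1L)

  # randomized vectors against the oracle loop, all variable kinds
  set.seed(88)
  for (i in 1:10) {
    g <- random_gold(ids, seed = 100 + i)
    p <- random_gold(ids, seed = 200 + i)
    for (v in list(list(d = "ULCER", f = "presence", l = NULL),
                   list(d = "EROSIVE_GASTRITIS", f = "extent", l = "E2"),
                   list(d = "SMT", f = "location", l = "FUNDUS"),
                   list(d = "ULCER", f = "stage", l = "ACTIVE"))) {
      cts <- confusion(p, g, v$d, v$f, v$l)
      bin <- function(r) {
        r <- r[r$disease == v$d, ]
        r <- r[order(r$report_id), ]
        switch(v$f,
          presence = r$present,
          extent = r$present & r$extent == v$l,
          location = sapply(r$locations, function(x) v$l %in% x),
          stage = r$present & r$stage == v$l)
      }
      expect_equal(cts, oracle_confusion(bin(p), bin(g)))
    }
  }
})

test_that("size agreement contributes true counts at the 0.1 cm tolerance", {
  ids <- c("R1", "R2", "R3", "R4")
  gold <- random_gold(ids, seed = 5)
  k <- gold$disease == "POLYP"
  gold$present[k] <- TRUE
  gold$size_cm[k] <- c(1.0, 2.0, NA, 3.0)
  pred <- gold
  pred$size_cm[k] <- c(1.05, 2.5, NA, NA)   # within tol / mismatch / both absent / missed
  cts <- confusion(pred, gold, "POLYP", "size")
  expect_equal(cts, list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  m <- metrics(cts)
  expect_equal(m$accuracy, 0.5)
})

test_that("metrics reproduce the formulas and the N/A pattern", {
  perfect <- metrics(list(tp = 2, fp = 0, fn = 0, tn = 8))
  expect_equal(unlist(perfect), c(sensitivity = 1, ppv = 1, accuracy = 1, f1 = 1))

  # zero-positive row: sensitivity/PPV/F1 undefined, accuracy defined
  zp <- metrics(list(tp = 0, fp = 0, fn = 0, tn = 10))
  expect_true(is.na(zp$sensitivity) && is.na(zp$ppv) && is.na(zp$f1))
  expect_equal(zp$accuracy, 1.0)

  m <- metrics(list(tp = 9, fp = 1, fn = 1, tn = 89))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$ppv, 0.9)
  expect_equal(m$accuracy, 0.98)
  expect_equal(m$f1, 0.9)

  # brute-force check on random confusion matrices + harmonic-mean identity
  set.seed(99)
  for (i in 1:12) {
    cts <- as.list(stats::setNames(sample(0:30, 4, replace = TRUE),
                                   c("tp", "fp", "fn", "tn")))
    m <- metrics(cts)
    sens <- if (cts$tp + cts$fn > 0) cts$tp / (cts$tp + cts$fn) else NA
    ppv <- if (cts$tp + cts$fp > 0) cts$tp / (cts$tp + cts$fp) else NA
    expect_equal(m$sensitivity, sens)
    expect_equal(m$ppv, ppv)
    expect_equal(m$accuracy,
                 (cts$tp + cts$tn) / (cts$tp + cts$fp + cts$fn + cts$tn))
    if (!is.na(m$f1)) {
      expect_lt(abs(m$f1 - 2 * sens * ppv / (sens + ppv)), 1e-12)
    }
    # scaling invariance
    m3 <- metrics(lapply(cts, `*`, 3L))
    expect_equal(m3, m)
  }
})

test_that("evaluate_corpus pools Overall rows from summed counts", {
  ids <- sprintf("R%02d", 1:12)
  gold <- random_gold(ids, seed = 44)
  tab <- evaluate_corpus(gold, gold)
  defined <- tab$accuracy[!is.na(tab$accuracy)]
  expect_true(all(defined == 1))
  # size rows never report sensitivity/PPV/F1
  expect_true(all(is.na(tab$sensitivity[tab$field == "size"])))

  # overall equals metrics of the hand-summed counts
  for (gr in c("GASTRITIS", "OTHER")) {
    sub <- tab[tab$group == gr & tab$disease != "Overall", ]
    ov <- tab[tab$group == gr & tab$disease == "Overall", ]
    want <- metrics(list(tp = sum(sub$tp), fp = sum(sub$fp),
                         fn = sum(sub$fn), tn = sum(sub$tn)))
    expect_equal(ov$sensitivity, want$sensitivity)
    expect_equal(ov$f1, want$f1)
    expect_equal(ov$tp, sum(sub$tp))
  }

  # permutation invariance in report order
  perm <- gold[sample(nrow(gold)), ]
  tab2 <- evaluate_corpus(perm, gold)
  expect_equal(tab2$tp, tab$tp)
  expect_equal(tab2$accuracy, tab$accuracy)

  # mismatched ids are an error naming the stray id
  extra <- random_gold("R99", seed = 1)
  expect_error(evaluate_corpus(rbind(gold, extra), gold), "R99")
})

test_that("metrics CSV renders undefined cells as N/A", {
  ids <- sprintf("R%02d", 1:5)
  gold <- random_gold(ids, seed = 3)
  tab <- evaluate_corpus(gold, gold)
  f <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(tab, f)
  csv <- utils::read.csv(f, check.names = FALSE, colClasses = "character")
  expect_equal(nrow(csv), nrow(tab))
  expect_true(all(c("Sensitivity", "PPV", "Accuracy", "F1-Score") %in% names(csv)))
  expect_true(any(csv$`F1-Score` == "N/A") || all(tab$f1[tab$field != "size"] == 1))
  expect_true(all(csv$`F1-Score`[csv$Variable == "size"] == "N/A"))
})
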