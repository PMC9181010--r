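# gastroie

Rule-based information extraction from upper-endoscopy (EGD) reports.

Screening EGD reports are free text: a *findings* narrative describing the
esophagus, stomach and duodenum, and an *impressions* list naming the
diagnoses, with linked pathology reports for biopsied lesions.  `gastroie`
turns each report into ten structured disease records — presence,
anatomical extent (gastritis), locations, ulcer stage, and lesion size in
centimeters — for five chronic gastritis types (atrophic gastritis,
intestinal metaplasia, superficial, erosive, follicular) and five other
gastric diseases (ulcer, polyp, submucosal tumor, dysplasia, cancer).

The pipeline runs in four stages:

1. **Preprocessing** — whitespace cleaning, organ-header segmentation
   (only stomach text flows on), sentence splitting;
2. **Concept mapping** — dictionary lookup against a bilingual lexicon
   (English surfaces match case-insensitively on word boundaries,
   second-language surfaces as raw substrings; longest match wins), then
   linking of each impression diagnosis to the findings *key sentences*
   containing its phenotype terms;
3. **Concept extraction** — sub-sites mapped to antrum/body/fundus;
   gastritis extent derived as antrum-only → 1, body/fundus-only → 2,
   both → 3; ulcer stage (active > healing > scar); sizes parsed from
   number–unit expressions (mm/10, max of dimensions);
4. **Summarizing** — exactly ten records per report, negated mentions
   excluded from presence, with pathology authoritative for dysplasia
   (adenomas of any grade) and cancer (adenocarcinoma, neuroendocrine
   tumor, lymphoma).

Evaluation scores each variable against gold annotations with
sensitivity = tp/(tp+fn), PPV = tp/(tp+fp), accuracy = (tp+tn)/n and F1
(harmonic mean of sensitivity and PPV), rendering zero-denominator cells
as N/A and pooling Overall rows from summed confusion counts.  A
synthetic report generator with known ground truth, a gold-vs-prediction
evaluator, and cohort aggregation (prevalence by sex/age bin,
extent/location distributions) complete the toolchain.

## Worked example

```r
library(gastroie)
lex <- load_lexicon(seed_lexicon_path(), complete = TRUE)

report <- data.frame(
  report_id = "R1", patient_id = "P1", exam_date = "2018-05-14",
  age = 57L, sex = "MALE",
  findings_text = paste(
    "Esophagus: Z-line was clear.",
    "Stomach: Mucosal atrophy at the antrum and lower body.",
    "A 1.2 cm active ulceration (A1) at the angle.",
    "Duodenum: Bulb and second portion unremarkable."),
  impressions_text = "Chronic atrophic gastritis. Gastric ulcer. No SMT.")

records <- run_pipeline(report, lex)
records[records$present,
        c("disease", "present", "extent", "locations", "stage", "size_cm")]
#>              disease present      extent locations       stage size_cm
#> 1 ATROPHIC_GASTRITIS    TRUE          E3           UNSPECIFIED      NA
#> 6              ULCER    TRUE UNSPECIFIED    ANTRUM      ACTIVE     1.2
```

The atrophic gastritis impression is linked to the atrophy sentence, whose
sub-sites (antrum + lower body) give extent 3.  The ulcer impression is
linked to the ulceration sentence: the angle maps to the antrum, "active"
and the stage code "(A1)" give the stage, and "1.2 cm" the size.  "No
SMT." is negated, so the submucosal-tumor record stays absent, as do the
seven other diseases (absent records carry no attributes).

A full synthetic round trip:

```r
cfg <- generator_config()                      # clean screening corpus
co  <- generate_corpus(cfg, n = 500, seed = 42)
pred <- run_pipeline(co$reports, lex, co$pathology)
tab  <- evaluate_corpus(pred, co$gold)         # every defined cell 1.000
```

Command-style wrappers (`cmd_generate`, `cmd_extract`, `cmd_evaluate`,
`cmd_aggregate`) operate on files, and `inst/cli/gastroie` is a thin
Rscript front end over them.

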