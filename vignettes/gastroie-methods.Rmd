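---
title: "Rule-based extraction of gastric disease information from endoscopy reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based extraction of gastric disease information from endoscopy reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastroie)
```

## The problem

Screening esophagogastroduodenoscopy (EGD) produces free-text reports with
two sections: a *findings* narrative describing what the endoscopist saw in
the esophagus, stomach and duodenum, and an *impressions* list naming the
diagnoses.  Biopsied lesions additionally generate linked pathology reports.
The clinical content — which of ten gastric diseases is present, how far a
gastritis extends, where a lesion sits, what stage an ulcer is in, how large
a lesion is — is locked inside unstructured, often bilingual prose full of
endoscopic abbreviations.  `gastroie` implements a rule-based pipeline that
turns each report into ten structured disease records, plus the evaluation
and cohort-aggregation machinery around it, and a synthetic report generator
that makes the whole chain testable without any patient data.

The ten targets are five chronic gastritis types (atrophic gastritis,
intestinal metaplasia, superficial gastritis, erosive gastritis, follicular
gastritis) and five other diseases (gastric ulcer, polyp, submucosal tumor,
dysplasia, cancer).  Gastritis records carry an anatomical *extent*; the
others carry *locations*, a *size* in centimeters, and — for ulcers — a
*stage* (active / healing / scar).

## Pipeline

The pipeline runs in four stages.

**1. Preprocessing.**  Stray line breaks and whitespace runs are collapsed
(`clean_text()`, idempotent).  The findings text is partitioned at organ
header mentions ("Esophagus:", "Sto:", second-language forms) and only the
stomach segment flows on; esophagus and duodenum descriptions can therefore
never contribute a gastric record (`segment_organs()`).  Segments are split
into sentences on `.`, `!`, `?` and bullet markers, with decimal points
("1.5 cm") and a small dotted-abbreviation list protected
(`split_sentences()`).  Impressions are split but *not* organ-filtered:
screening impressions are short diagnosis lists with inconsistent headers,
and gastric-versus-other discrimination there is done by the lexicon's
disease terms.

**2. Concept mapping.**  A tab-separated lexicon drives all matching.  Each
entry carries a surface form, a language tag (`EN` or `L2`), a concept id,
a concept class (diagnosis, phenotype, sub-site, stage, negation cue, unit,
organ header), and a section scope.  English surfaces match
case-insensitively on word boundaries; second-language surfaces match as
raw substrings, because the agglutinative second language suffixes
particles directly onto terms and no tokenizer is assumed.  Overlapping
candidates are resolved greedily — longest match first, ties to the
leftmost start, then to lexicon file order — so "erosive gastritis" always
beats the embedded "gastritis".  The matching strategy is a package
decision; several resolution orders are defensible, and the chosen one is
pinned down by a brute-force oracle in the test suite.

When a non-negated diagnosis term is found in the impressions, the pipeline
maps *key sentences*: every findings sentence containing a non-negated
phenotype term linked to that diagnosis through the lexicon's phenotype map
("erosions" for erosive gastritis, "ulceration" for ulcers, and so on).
Presence is driven by the impressions; findings phenotypes alone never set
presence, they only supply attributes.

**3. Concept extraction.**  From the key sentences of each disease the
pipeline collects sub-site mentions and maps them to the three stomach
regions (prepyloric area and angle to the antrum; lower/mid/upper body and
cardia to the body; fundus to the fundus).  Gastritis extent is then a pure
function of the region set: antrum only is extent 1, body/fundus only is
extent 2, both is extent 3, none leaves the extent unspecified.  Ulcer
stage words and codes (A1/A2, H1/H2, S1/S2) map to active/healing/scar;
when several stages co-occur the most severe wins (active > healing >
scar).  Sizes are parsed from number–unit expressions; millimeters are
divided by 10, dimension products ("0.8 x 1.2 cm") yield the maximum
dimension, and several sized lesions yield the maximum size — the
conservative clinical summary.

**4. Summarizing.**  Every report yields exactly ten records, one per
disease, absent diseases included with `present = FALSE`.  Explicit
negatives make the evaluation denominators (true negatives, hence
accuracy) well-defined.  Conditional-field invariants — absent records
carry no attributes, extent only for gastritis, stage only for ulcers,
size only for lesions and positive — are enforced at summarization and
again at write time.

**Pathology.**  Dysplasia and cancer are histologic categories: adenomas
of any grade define dysplasia, and adenocarcinoma, neuroendocrine tumor
and lymphoma define cancer.  The pathology report is therefore
authoritative for these two diseases in both directions — an endoscopic
impression without histologic confirmation becomes absent (with a
warning), and a histologic finding without an endoscopic impression
becomes present, with locations inferred from the specimen site text.
Cancer takes precedence over dysplasia within one specimen, since
carcinoma text frequently co-mentions its adenoma background.  The eight
non-neoplastic diseases are provably untouched by this module.

**Negation.**  The source procedure for this kind of pipeline rarely
documents negation handling, but both real and synthetic reports contain
negated statements ("No ulcer."), so a window rule is included and can be
switched off (`pipeline_options(negation = FALSE)`): a mention is negated
when a cue ("no", "without", "no evidence of", "negative for") occurs
within five word tokens before it in the same sentence, or — for
post-posed second-language cues — anywhere after it in the sentence.
"r/o" (rule-out) diagnoses are treated as present by default, the
screening convention; `rule_out_positive = FALSE` turns them into
negations.

## The lexicon

The shipped seed lexicon (~150 entries, `seed_lexicon_path()`) covers all
ten diseases with diagnosis terms, synonyms and endoscopic abbreviations
("IM", "SMT", "CAG", "EGC"), phenotype terms, sub-sites, stage codes,
negation cues, units and organ headers, plus the three concept maps
(phenotype-of, subsite-region, disease-target).  Second-language forms are
romanized placeholders: the mechanism under test is the substring matching
path, not the orthography, and romanization keeps every fixture
encoding-simple.  The file is user-replaceable by any lexicon with the
same schema; validation checks surface uniqueness, enum tokens, scope
compatibility (diagnoses live in impressions, phenotypes in findings) and
referential integrity of the maps, and reports *all* violations at once.
Abbreviations are ordinary rows — one matching mechanism, no separate
expansion pass.

## The synthetic generator

`generator_config()` defines the corpus the package tests itself on.  Its
defaults are the package's study conditions:

* per-disease prevalences from a screening development cohort
  (44.0 / 24.6 / 11.2 / 59.8 / 0.2 % for the gastritis types;
  8.2 / 20.2 / 4.0 / 1.1 / 0.4 % for ulcer, polyp, SMT, dysplasia,
  cancer);
* a 61.4 % male cohort aged 18–100 with the screening age profile
  (2.4 % under 30, 38.0 % 30–49, 54.6 % 50–69, 5.0 % 70+);
* extent distributions with extent 3 dominant (65 %) for atrophic
  gastritis and intestinal metaplasia and extent 1 dominant for the other
  three gastritis types, echoing the qualitative pattern reported for
  screening cohorts — exact shares are not published, so these are the
  package's choice;
* lesion locations favouring the antrum for ulcers/dysplasia/cancer, the
  body for polyps and the fundus for submucosal tumors; 15 % of lesions
  span two regions and 10 % state no location;
* sizes log-uniform over 0.2–5.0 cm, rounded to 0.1 cm (the reporting
  resolution); ulcer stages 35/25/25/15 % active/healing/scar/unstated.

Reports are assembled from an organ-header template using *only lexicon
surfaces*, so that with all noise switches at zero the pipeline reproduces
the gold annotations exactly — the closure property that anchors the
acceptance suite.  Noise switches substitute abbreviations or synonyms,
add negated diagnoses of absent diseases to the impressions, and add
phenotype distractor sentences to the esophagus/duodenum segments; these
target the negation and organ-filtering rules specifically.  In `MIXED`
language mode half the sentences use second-language templates, exercising
the substring-matching path end to end.  Sampled dysplasia or cancer emits
a linked pathology report with a matching histologic diagnosis, and a
small share (5 %) of benign biopsies exercises the OTHER branch.

What the generator does *not* emulate: free narrative style, typographical
errors, out-of-lexicon synonyms, inconsistent sectioning, and genuinely
ambiguous wording.  Passing the closure and noise tests therefore shows
that the rules are internally coherent and robust to the modeled
perturbations — not that the pipeline reaches any particular performance
on real hospital reports, whose headline numbers require the original
(non-public) corpus.

## Evaluation

Extraction is scored per variable against gold annotations: presence per
disease; each extent level per gastritis, each region per lesion disease
and each stage for ulcers as one-vs-rest binaries; and size as an
agreement row (both absent, or both present within 0.1 cm) that reports
accuracy only.  `metrics()` computes sensitivity, PPV, accuracy and F1,
leaving any zero-denominator cell undefined (rendered `N/A`), so a
zero-positive row shows the characteristic `N/A N/A 1.000 N/A` pattern.
Overall rows pool the confusion counts across a table's variables
(micro-average); the averaging method is not fixed by the source
procedure, so a macro-average is available via `evaluate_corpus(...,
average = "macro")`.  Location sets are scored per region, not by set
equality, matching the per-region table rows.

## Aggregation

`prevalence_table()` stratifies presence by sex and by the fixed age bins
18–19, 20–29, …, ≥80, with reports (not unique patients) as denominators —
`dedup_patients = TRUE` switches to one report per patient.
`extent_distribution()` shares sum to exactly 100 % (extent is
single-valued); `location_distribution()` shares may sum above 100 %
(multi-location lesions) or below (unspecified locations), by convention.

## Numerical and design choices

* Character spans are 0-based half-open; mention spans index the cleaned
  sentence they were found in, and each sentence carries its own span into
  the cleaned section text.  One unambiguous coordinate chain.
* Sentence source spans refer to the cleaned segment text: whitespace
  collapsing makes raw-text offsets unrecoverable without an alignment
  map, which nothing downstream needs.
* Tie-breaks: matching prefers longest, then leftmost, then file order;
  stage conflicts resolve to the most severe; sizes to the maximum;
  locations to the union.  Findings are authoritative over impressions
  for locations.
* Size agreement tolerance is 0.1 cm — the reporting resolution.
* Degenerate inputs: empty sections yield empty sentence lists and
  all-absent records; a findings text without a stomach header yields an
  empty stomach segment plus a warning, never an error.
* The suite's corpus-level checks run at n = 500 (clean closure) and
  n = 1000 (noise and sampling fidelity) with one fixed corpus seed; the
  per-disease 3-standard-error sampling check is a ~2 % false-alarm
  lottery per seed by construction, which is why the generator's
  binomial exactness is additionally established by its long-run rate.

## Limitations

The pipeline is a rule system: it can only find what its lexicon names,
and reports with unconventional formatting or terminology need lexicon
and rule updates, not retraining.  The negation window is fixed at five
tokens and sentence-bounded; scope constructions ("no X but Y") are
handled only insofar as the window captures them.  No stemming, spelling
correction or terminology-system linking is attempted.  Severity
classifications that require grades absent from narrative reports
(Kimura–Takemoto, Sydney) are out of scope, as is lesion-level (rather
than disease-level) output.
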