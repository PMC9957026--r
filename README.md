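# msitr

Identifying a history of military service from free-text clinical notes.

UK health records carry no universal marker of veteran status, so whether a
patient ever served in the Armed Forces must be inferred from what
clinicians write in free text. `msitr` implements a Military Service
Identification Tool (MSIT)-style pipeline for psychiatric secondary-care
notes, for researchers who need a patient-level veteran flag plus the
screening statistics to defend it:

1. **Stage 1 — keyword rule.** A document shows evidence of service iff it
   contains a military-lexicon phrase (e.g. *veteran*, *army*, *served in
   the forces*) whose match span is not contained in a confounder phrase
   (*Salvation Army*, *military precision*, ...) and is not attributed to
   another person (a relation word such as *father* or *husband* within a
   5-token window deletes the mention).
2. **Stage 2 — TF-IDF + linear classifier.** Notes are preprocessed in four
   ordered steps (strip punctuation; remove other-person service mentions;
   remove stop words and over-frequent terms, military terms exempt; delete
   confounder phrases), vectorized with smoothed TF-IDF
   (`idf(t) = ln((1+N)/(1+df(t))) + 1`, L2 rows, unigrams + bigrams) and
   scored by ridge logistic regression. Positive calls are then **gated**
   by the stage-1 evidence check, so a positive without a surviving
   military term is flipped back to negative.
3. **Aggregation & evaluation.** Patient label = OR over document labels.
   Against self-reported truth the package reports, from the 2×2 table
   (a = both say non-veteran, b = tool non-veteran/truth veteran, c = tool
   veteran/truth non-veteran, d = both say veteran):
   agreement `(a+d)/n`, PPV `d/(c+d)`, NPV `a/(a+b)`,
   sensitivity/specificity in two explicit orientation conventions, and
   the Youden index `J = sens + spec − 1`.

A template-based synthetic corpus generator (`generate()`), an eligibility
screen with cohort-flow reporting (`filter_eligible()`,
`flow_percentages()`) and JSONL/CSV I/O make the whole pipeline runnable
and testable without access to any record system.

## Worked example

```r
library(msitr)

co  <- generate(sim_config(n_patients = 100, seed = 7))   # synthetic corpus
res <- run_msit(co$documents,
                as.integer(co$note_annotations$contains_self_service),
                seed = 7)                                 # train + predict + gate + aggregate
cm  <- cross_tabulate(res$patient_decisions, co$patients)
print(cm)
print(validation_report(cm))
```

```
MSIT classifications vs patient-reported classification
                 True Non-Veteran True Veteran Total
MSIT Non-veteran               73            0    73
MSIT Veteran                    0           27    27
Total                          73           27   100
Validation report (n = 100, convention: paper)
  agreement    1.00 (100.0%)
  sensitivity  1.00
  specificity  1.00
  PPV(veteran) 1.00   NPV(veteran) 1.00
  Youden J     1.00
  tool classifications: 73.0% non-veteran / 27.0% veteran
```

On this clean synthetic corpus every patient is recovered: off-diagonal
cells are zero, so agreement, both predictive values and `J` are all 1.
Synthetic notes are far easier than real ones — see the vignette for what
this does and does not demonstrate.

The packaged external-validation table (146 surveyed patients) shows
realistic numbers:

```r
print(validation_report(reference_validation_counts()))
```

```
Validation report (n = 146, convention: paper)
  agreement    0.84 (83.6%)
  sensitivity  0.83
  specificity  0.92
  PPV(veteran) 0.32   NPV(veteran) 0.99
  Youden J     0.75
  tool classifications: 76.7% non-veteran / 23.3% veteran
```

Here `convention: paper` means sensitivity is the detection rate of
*non-veterans* (111/134 = 0.83) and specificity the recovery of veterans
(11/12 = 0.92); pass `convention = "veteran_positive"` for the standard
orientation (the two simply swap). The low veteran PPV (11/34) reflects the
heavy non-veteran majority: most tool positives in a low-prevalence sample
are false.

A command-line front end wrapping the same functions ships in
`inst/cli/msit.R`:

```sh
Rscript inst/cli/msit.R simulate --n-patients 400 --seed 42 --out work/
Rscript inst/cli/msit.R train    --docs work/documents.jsonl --annotations work/annotations.csv --out work/
Rscript inst/cli/msit.R predict  --docs work/documents.jsonl --model work/model.rds --engine ml+post --out work/
Rscript inst/cli/msit.R evaluate --pred work/predictions.csv --truth work/truth.csv --out work/
```

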