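# mdslisten

Social-media listening for myelodysplastic syndrome (MDS) patient forums: a
tested, reusable R pipeline that turns raw forum posts into
cohort-stratified insight tables about what patients and caregivers — and
the high-risk (HR-MDS) subgroup in particular — discuss, feel, and need.

It is aimed at patient-experience / real-world-evidence researchers who
have scraped forum corpora (posts, threads, users) and need the full
analysis chain behind an infodemiology study:

1. **Corpus I/O and cleaning** — JSONL/CSV loading with record validation,
   duplicate removal keyed on (user, normalized text), UTF-8 validation,
   edit-distance-1 spell autocorrection, and inclusive study-window plus
   no-personal-experience exclusion filters.
2. **De-identification** — lexicon+title name scrubbing (`NAME`,
   `PROVIDER NAME`, `PRODUCT MANUFACTURER`), removal of emails/phones/links,
   institution allowlisting, brand→INN drug-name normalization
   (Venclexta → venetoclax, ...), salted username tokenization that keeps a
   user's posts linkable, and exclusion of clinical-trial /
   investigational-drug posts.
3. **Role attribution** — per-post patient/caregiver labels from key phrases
   ("I have MDS" vs. "My husband was diagnosed with MDS"), aggregated per
   user by an inclusive 80% majority rule with a chronological fallback.
4. **HR-MDS extraction** — guideline-aligned treatment surrogates
   (hypomethylating agents, venetoclax, transplantation, donor lymphocyte
   infusion, erythropoietin failure, multiple transfusions, intensive
   chemotherapy, AML progression), explicit "high-risk" self-reports, and
   blast-percentage parsing with an inclusive ≥20% rule: prevalence of a
   marker anywhere in a user's history labels the user high risk.
5. **Themes** — seven broad categories and a five-root theme hierarchy with
   keyword-seeded scoring, plus bottom-up latent topic discovery (LDA, LSA,
   k-means, spectral, agglomerative, DBSCAN, OPTICS). Theme prevalence is
   the number of unique *discussions* (threads) mentioning a theme;
   major/minor status applies an inclusive threshold; a co-mention network
   weights theme pairs by shared discussions.
6. **Sentiment** — multilabel emotion classification over
   {neutral, sadness, joy, surprise, fear, disgust, anger} (pluggable
   scorer; transparent cue-lexicon default), HR sub-sentiment buckets
   (concern, anxiety, frustration, fear, confusion, information-seeking)
   with theme attribution, and user-denominated prevalence tables with
   integer percentages rounded half away from zero.
7. **Engagement and temporal analysis** — activity spans, ~1% superuser
   detection with per-discussion contribution capping, thematic-saturation
   curves over chronological batches, and the pre/post-COVID split
   (2018-01-01..2020-02-29 vs. 2020-03-01 onward).

A seedable synthetic forum generator (`generate_corpus()`) emits
forum-shaped corpora with exact ground-truth labels (roles, risk, emotions,
themes, PII spans, duplicates, trial mentions), so the whole pipeline is
testable without redistributing scraped data.

## Worked example

```r
library(mdslisten)

g <- generate_corpus(synth_config(n_users = 300, seed = 42))
report <- run_pipeline(g$corpus, pipeline_config(seed = 42))
report
#> <run_report>
#>   corpus: 3642 posts / 495 threads / 300 users
#>   cohorts: hr_users=105, hr_patients=64, hr_caregivers=41
#>   saturation index: 1

head(report$sentiment_prevalence[
  report$sentiment_prevalence$cohort == "hr_users", ], 6)
#>   cohort   label                   n denominator   pct
#> 1 hr_users information_seeking    54         105    51
#> 2 hr_users anxiety                49         105    47
#> 3 hr_users concern                48         105    46
#> 4 hr_users confusion              46         105    44
#> 5 hr_users frustration            43         105    41
#> 6 hr_users fear                   38         105    36
```

Of the 300 synthetic users, 105 carry a high-risk surrogate marker and form
the HR cohort; the table reports how many of those users expressed each
sub-sentiment in at least one post (`n`), the cohort denominator, and the
rounded integer percentage. Theme prevalence counts discussions, not posts:

```r
head(report$theme_prevalence, 5)
#>   node                prevalence status actionable
#> 1 clinical                   409 major  TRUE
#> 2 transplants                360 major  TRUE
#> 3 physical                   352 major  TRUE
#> 4 treatments                 351 major  TRUE
#> 5 education_logistics        345 major  TRUE
```

`export_summary(report, "out/")` writes all tables (per-source volumes with
a Total row, prevalence tables, the co-mention edge list and GraphML,
saturation curve, COVID split, stage counts) plus a JSON run report. A thin
command-line wrapper ships in `inst/cli/mdslisten` with subcommands
`generate`, `anonymize`, `classify roles|risk`, `themes`, `sentiment`,
`saturation`, and `run-all`.

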