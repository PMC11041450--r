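---
title: "Criteria-based health news evaluation: models, explanations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Criteria-based health news evaluation: models, explanations and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthnewseval)
```

## The problem

Expert instruments for appraising health news score an article against
concrete quality criteria. This package automates three of them — whether
the article discusses the **cost** of the intervention, explains or
quantifies its **harm**s, and identifies **conflict**s of interest — and,
crucially, explains each automatic verdict by highlighting the sentences
that support it. Two independent explanation pipelines are provided so
their behavior can be compared: a *hybrid* keyword pipeline and a
*typology* sentence-classification pipeline.

Ratings are three-valued (`satisfactory`, `unsatisfactory`,
`not_applicable`). Each criterion is modeled as a binary task in which
`not_applicable` is folded into the negative class: an article that a
criterion does not apply to provides no evidence for that criterion, so
the positive class is exactly the articles whose text should contain
evidence sentences. Story and press-release sources are pooled; the source
type is kept as metadata only.

## Preprocessing and features

`preprocess()` applies, in this order: lower-casing; accent stripping;
tokenization on alphanumeric runs; removal of tokens containing digits, of
single-character tokens and of stop words (a fixed list shipped under
`extdata/`, so no external resource can drift); a small rule-based plural
lemmatizer; and the Porter stemmer. Lemmatize-then-stem is iterated to a
fixpoint and the stop-word filter is re-applied to the normalized forms,
which makes preprocessing idempotent on its own output — a property the
keyword-matching stage relies on, since curated phrases and surrogate
n-grams are compared in normalized space.

`fit_tfidf()` builds a unigram+bigram vocabulary capped at `max_features`
terms by total corpus frequency (ties broken lexicographically) and uses
the smoothed inverse document frequency

$$\mathrm{idf}(t) = \ln\frac{1+N}{1+\mathrm{df}(t)} + 1,$$

with raw-count term frequency and L2 normalization per document. Bigrams
are included because the global keyword rankings are reported over
"bigram or unigram" features; the exact idf variant is fixed in code so
that unit-test oracles can be computed by hand. Models serialize to JSON
at 17 significant digits, which round-trips IEEE doubles exactly.

Two consequences of normalized matching are worth knowing. Stop-word
removal happens before bigram formation, so a curated phrase can match
across an elided stop word ("side of the effect" matches *side effect*);
and all matching is on stems, so "risks" folds onto *risk*.

## Document classifiers

Four families are supported behind one `model_spec()` surface: logistic
regression (glmnet), multinomial naive Bayes, a support vector machine
(e1071) and a random forest (ranger). The naive Bayes variant is
implemented in-package because the Gaussian formulation that ships with
e1071 degenerates on sparse TF-IDF columns whose within-class variance is
zero; the multinomial variant with Laplace smoothing is the standard
choice for term-weight features. Hyperparameters keep the field's
conventional names (`n_estimators`, `min_samples_split`,
`max_features = "sqrt"`, ...) and are mapped internally (`bootstrap =
FALSE` becomes sampling the full data without replacement, `max_depth =
NA` means unlimited).

`random_search()` samples specifications uniformly from declared
per-family grids crossed with candidate TF-IDF feature counts and scores
each by stratified 5-fold mean AUC. The shipped per-criterion defaults
(`default_model_spec()`) are random forests — 600 trees / 1000 features
for cost, 1400 / 2000 for harm, 1200 / 1000 for conflict — and each value
sits inside the declared grid, so the defaults are reachable by the
search. Whether the inner folds are stratified was an open choice; they
are, because the conflict criterion's extreme imbalance (about 98%
negative in real review data, reproduced by the generator's stress
configuration) makes unstratified folds degenerate.

`repeated_kfold_auc()` (default 50 × 10) refits the TF-IDF vectorizer
inside every training fold, so no vocabulary or idf information leaks from
held-out documents; the AUC is the Mann–Whitney rank-sum statistic, which
equals the trapezoidal ROC area and is cross-checked against an
independent implementation in the tests. The decision threshold for the
binary label is 0.5; probabilities are retained for explanation.

## The local surrogate explainer

The hybrid pipeline needs per-document keyword attributions for an
arbitrary black-box classifier, so the package implements the
perturbation-based local surrogate from first principles.

For a document with $u$ distinct in-vocabulary n-grams, binary masks
$z \in \{0,1\}^u$ are sampled (the first mask is all ones; the rest keep
each feature independently with probability 0.5). Masking zeroes the
corresponding TF-IDF weights and re-normalizes, the black box returns a
probability for each masked variant, and a ridge regression of probability
on mask bits — weighted by the proximity kernel
$\exp(-d^2/\sigma^2)$ with $d$ the cosine distance from the all-ones
mask — yields one signed weight per n-gram. The intercept is unpenalized;
features are penalized with `ridge_penalty` (default 1.0).

Numerical defaults: kernel width $\sigma = 0.75$ on cosine distance and
5000 samples. Neither is dictated by the method; both follow common
practice for this family of explainers and are exposed as arguments.
The perturbation unit is the *type* (distinct n-gram), not the token
position: masking "risk" removes every occurrence at once, which matches
the removal-of-word-features view and keeps the mask dimension small. A
consequence is that unigrams and the bigrams containing them are masked
independently; the ridge surrogate absorbs the resulting collinearity.

`exact_surrogate()` enumerates all $2^u$ masks (refusing documents beyond
`max_features = 12`) and solves the same weighted ridge problem exactly.
It is the oracle for three tested guarantees: exact recovery of a black
box that is linear in mask space as the penalty vanishes; zero weights
for a constant black box and for never-varying features; and rank
agreement of the sampled explainer with the exact solution as the sample
count grows.

`global_ranking()` provides both readings of a "top 30 features" summary:
`lime_aggregate` averages signed surrogate weights over the documents
predicted satisfactory (a document lacking an n-gram contributes zero),
and `model_importance` reports the classifier's intrinsic importances
(impurity importance for forests, coefficients for the linear model).
Which of the two a published figure shows is ambiguous in general, so the
package ships both rather than guessing; on separable synthetic data they
agree on the majority of the top entries, which the tests assert.

## The hybrid highlighter

Positive-weight surrogate keywords ("contributed to a satisfactory
prediction") are merged with the curated per-criterion keyword lists
(cost: *price, cost, charge, insurance, pay*; harm: *side effect, adverse
reaction, adverse event, complication, risk*; conflict: *fund, sponsor,
grant, spokesman, professor, director*). Deduplication on normalized form
keeps the curated tier. The rule that curated keywords outweigh automatic
ones is encoded lexicographically — a sentence's score is the pair
`(tier, magnitude)` with the curated tier strictly above — rather than by
inflating a numeric weight, so no magic constant can be overtaken.
Within a tier, the magnitude sums the absolute weights of matched
surrogate entries plus a bonus of 1.0 per curated-phrase occurrence
(summation rather than max was an open choice; it is exposed as an
argument), and ties break toward the earlier sentence.

Surrogate keywords join the merge only when the document is predicted
satisfactory. A document predicted unsatisfactory has no satisfactory
verdict to justify — removing words from it does not change the verdict —
so only the rule-based curated list applies there. Without this rule,
small-magnitude noise weights on background vocabulary would generate
spurious highlights on negative documents.

The known failure mode is inherited deliberately: a sentence like
"long term use of the drug *reduces the risk* of fractures" shares the
keyword *risk* with genuine harm evidence, and a stock-price sentence
shares *price* with cost evidence. The generator plants exactly such
confounders, and a test asserts that the hybrid highlighter does pick
them up at a nonzero rate — the limitation is documented, not hidden.

## The typology highlighter

The annotation protocol is modeled explicitly: two extractors mark
evidence sentences; sentences both marked are evidence; sentences marked
by exactly one go to a referee, whose decision is final; a disagreement
without a referee decision is an error. `interannotator_agreement()`
reports the extraction counts and a simple agreement percentage,
`100 · n_both / n_final` — the share of the final evidence set that both
extractors found independently. The underlying counts are all exposed
because more than one agreement ratio can reasonably be formed from them.

The sentence dataset takes all approved evidence sentences as positives
and samples an equal number of other sentences — corpus-wide, not
per-article, which gives better coverage at small sample sizes — as
negatives. The sentence classifier then reuses the document pipeline
unchanged at sentence granularity. At prediction time every sentence of an
article is scored and the top k by evidence probability are highlighted,
ties toward the earlier sentence, with sentences below probability 0.5
excluded even when fewer than k qualify: ranking alone would happily fill
the window with irrelevant sentences, which is precisely the weakness the
probability floor avoids. The floor is exposed as an argument.

## Highlighting accuracy and window selection

`highlight_accuracy()` is pooled (micro) accuracy: 100 × correctly
highlighted sentences over all highlighted sentences, across the test
articles; articles contributing no highlights contribute to neither
count. Pooling across articles (rather than averaging per-article rates)
was an open choice, flagged here; pooled matches the "for all highlighted
sentences" reading and is the variant the tests' brute-force recount
verifies. With no highlights at all the accuracy is reported as
not-applicable rather than zero.

`select_window()` uses an inclusive threshold with a prefix rule: the
window is the largest k such that accuracy at every j ≤ k is ≥ the
threshold (default 75%). Inclusive comparison is the only reading
consistent with reference tables in which cells printed exactly 75.00
count as passing; the prefix rule (rather than "the last k above
threshold") is adopted because the window is meant as a usable *range* of
highlight counts. Applied to the shipped reference accuracy curves for
the typology approach, it selects windows of 2 (cost), 4 (harm) and
1 (conflict) sentences at the 75% threshold.

## The synthetic corpus generator

Real review corpora with per-criterion expert ratings are no longer
retrievable, so the generator is a first-class, tested module that
produces the statistical structure the system assumes:

* per-criterion satisfactory fractions, defaulting to the class ratios
  observed in real review data (cost ≈ 0.25, harm ≈ 0.45, conflict ≈ 0.02
  satisfactory. The conflict setting is a deliberate stress
  configuration; tests that need statistical power use balanced 0.5
  fractions instead);
* articles of 10–60 sentences by default, with 1–6 planted evidence
  sentences per satisfactory criterion, instantiated from closed
  template vocabularies in which every evidence sentence contains at
  least one curated keyword for its criterion;
* confounder sentences (benefit-phrased risk sentences, stock-price
  sentences, uninvolved-expert sentences) inserted per criterion with a
  configurable rate and never marked gold;
* neutral background sentences from a vocabulary disjoint from the
  template vocabulary;
* gold evidence recorded as 0-based sentence indices, validated against
  the package's own sentence splitter at construction time.

Everything is drawn from a single seeded stream, so one seed yields a
byte-identical corpus. When several criteria draw large evidence counts
for the same article, the counts are walked down toward the range minimum
until they fit the article's sentence budget; a configuration whose
minimum requirements cannot fit at all is rejected.

What the generator does *not* emulate: linguistic realism, topical
correlation between criteria, paraphrase beyond slot-filling, or
class-conditional document length. Passing tests on this corpus therefore
demonstrate that the pipeline's machinery is correct and that its
documented failure modes occur — not that real-world accuracy figures
would be reproduced.

## Sentence splitting

No sentence splitter is canonical for this task, so a deterministic
rule-based one is used: a sentence ends at a run of `.?!` (plus closing
quotes) followed by whitespace and an upper-case letter, digit or opening
quote, with an abbreviation exception list (Dr., Mr., Mrs., Ms., St.,
U.S., e.g., i.e., Fig., No., vs.). Offsets are 0-based and half-open
throughout, and the splitter never produces empty sentences. Determinism
was preferred over model-based splitting because gold evidence indices
must be stable across runs and machines.

## Problem sizes and numerical checks

The shipped checks use desk-scale problem sizes chosen once: separability
and planted-evidence recovery use 400 training / 20 test articles per
criterion with 10–30-sentence articles and no confounders (held-out AUC ≥
0.95; both highlighters ≥ 90% accuracy at k = 1 against gold); the
dilution property (accuracy weakly decreasing in k when positives carry
only 1–2 gold sentences) uses 120/30 articles; the chance-level no-leakage
check permutes labels on 500 articles with 5 × 5-fold CV (mean AUC in
[0.45, 0.55]); surrogate correctness uses exhaustive enumeration up to 10
features and 5000-sample runs over 20 seeds. Unit tests use smaller
corpora (60–120 articles) with fixed seeds throughout.

## Known limitations

* Published real-data figures (document AUCs, table-level accuracies,
  inter-annotator rates) depend on a defunct corpus and human judges and
  are out of reach by design; the package reproduces the *procedures* and
  verifies them on synthetic data.
* Keyword matching carries no semantics: benefit-phrased risk sentences
  and stock-price sentences are highlighted by the hybrid approach, as
  documented above.
* Type-level masking cannot distinguish two occurrences of the same
  n-gram in different sentences; sentence scores aggregate matched
  keyword weights instead.
* The rule-based sentence splitter will over- or under-split unusual
  punctuation (ellipses, inline lists); its behavior is deterministic and
  fully specified, which the gold-index bookkeeping requires.
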