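---
title: "Methods: a calibrated linear tagger for human-related citations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a calibrated linear tagger for human-related citations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`humtag` scores a citation record with a calibrated linear model. Writing
$x$ for the sparse feature vector of a record and $y \in \{-1, +1\}$ for
whether the curated MeSH *Humans* heading applies, the package fits

$$\min_w \tfrac{1}{2}\lVert w\rVert^2 + C \sum_i \max(0,\, 1 - y_i w^\top x_i)$$

— an L2-regularized hinge-loss linear SVM — and then maps the signed margin
$m(x) = w^\top x + b$ through a monotone calibration function
$g : \mathbb{R} \to [0,1]$, reporting $\hat p(x) = g(m(x))$ as the
probability that the article concerns humans. The two stages have distinct
jobs: the margin model does the ranking, the calibration map makes the
scores interpretable as probabilities (among records scored $\approx p$, a
fraction $\approx p$ should truly be positive).

The modelling assumptions are the usual ones for linear text
classification: class evidence is approximately additive in token counts,
and a single global threshold direction separates the classes well. For
bag-of-token features under class-conditional multinomials, the Bayes
log-posterior-odds *is* linear in the counts, which is why the synthetic
benchmark (below) can meaningfully compare the fitted model against an
exact ceiling.

Only title, abstract, author, journal, and pagination fields ever reach the
design matrix. MeSH descriptors are used solely to derive the training
label, never as predictors, so a trained tagger applies unchanged to
not-yet-indexed and non-MEDLINE records. Records without MeSH indexing are
treated as *unlabeled* — never as negatives — and are skipped by training
and evaluation.

## Feature classes

Features come in twelve classes, each the unit of forward selection:
uni/bi/trigrams over the tokenized title and abstract, count triplets per
field (word count, punctuation count, digit-containing-token count), author
name tokens, author count, journal name, and page count. Tokenization
splits on whitespace and ASCII punctuation, lower-cases, drops stop words,
and applies no stemming; n-grams are windows over the post-stop-word token
sequence, never crossing the title/abstract boundary (no sentence
segmentation is attempted within a field). Token features enter as raw
counts; numeric features enter as single raw-valued columns that are
z-scored with training-set statistics stored in the tagger, keeping their
magnitudes commensurate with count features for a margin classifier.

Some concrete conventions the package had to pin down:

* **Punctuation** means the ASCII punctuation set, both for splitting and
  for the punctuation count — the reproducible baseline.
* **Numeric term count** counts whitespace-delimited tokens containing at
  least one digit (so `p53` counts), not only pure numbers.
* **Page count** expands MEDLINE shorthand: `334-41` means pages 334–341,
  hence 8 pages; a lone page number counts 1; electronic article ids
  (`e0123456`) and unparseable strings count 0, the latter with a warning.
* **Structured abstracts** contribute only their section bodies,
  concatenated with single spaces; section labels like `METHODS:` are not
  part of the text.
* **Vocabulary pruning**: token features need a document frequency of at
  least `min_df = 2` (hapax pruning). At desk-scale corpus sizes this
  controls vocabulary growth without changing the method; numeric classes
  always keep their fixed columns.
* **Column order** is deterministic — canonical class order, then C-locale
  lexicographic — so identical corpora give identical design matrices.

## Solver and its controls

The SVM is fitted by dual coordinate descent (one dual variable per record,
$\alpha_i \in [0, C]$), the standard approach for large sparse linear
problems where quadratic-programming kernel solvers are impractical. The
bias is handled by a constant augmented feature and is therefore
regularized, the convention of sparse linear-SVM solvers. Coordinates are
visited in a freshly shuffled order each epoch using a private PRNG seeded
from the training seed, making fits bit-reproducible. Convergence is
declared when the largest projected dual gradient in an epoch falls below
`svm_tol = 0.05` (default cap `svm_max_epochs = 300`); these defaults trade
a little optimization slack for speed, which matters during
cross-validated selection where hundreds of fits run. `c_param` defaults to
1 and is exposed in `tagger_config()`.

## Calibration

The calibration literature offers several monotone margin-to-probability
maps; the package implements two behind one interface and treats the choice
as a configuration option:

* **Isotonic regression** (default): pool-adjacent-violators on the 0/1
  labels ordered by margin, clipped to $[\varepsilon, 1-\varepsilon]$ with
  $\varepsilon = 10^{-4}$, linearly interpolated between knots and constant
  beyond the fitted range. Nonparametric, monotone by construction, and
  saturates fully at the extremes.
* **Platt-style sigmoid**: $g(m) = 1/(1 + e^{Am + B})$ fitted by maximum
  likelihood with smoothed targets, which keeps the coefficients finite
  under perfect separation. If the fitted direction is not non-decreasing
  (pathological anti-correlated input) the map falls back to the constant
  prevalence rather than violate monotonicity.

Calibration quality hinges on *what the map is fitted on*: fitting on the
same records the SVM saw gives optimistically steep maps. `train_tagger()`
therefore holds out a stratified `calibration_split = 0.2` fraction of the
labeled records, fits the SVM on the remaining 80%, fits the calibration
map on the held-out margins, and then refits the SVM on all records,
keeping the map. The margin scales of the 80% and 100% fits differ
slightly; the benchmark below shows the residual calibration error this
leaves at the package's operating sizes.

Degenerate inputs are handled explicitly: single-class label vectors are
errors everywhere (an AUC or a calibration map is undefined), empty inputs
error, and the MCC returns 0 when any confusion-table marginal is zero.
At the default 0.5 threshold a score of exactly 0.5 counts as positive.

## Forward selection under 5×2 cross-validation

Feature classes are selected greedily. A fold plan of five independent
label-stratified 50/50 partitions is drawn once per selection run and
shared by every candidate evaluation, so candidates are compared on
identical folds (paired comparisons, lower variance). Each candidate set is
scored by training a full tagger on one half and evaluating AUC and MCC on
the other, for all ten (iteration, half) arrangements; the ten values are
averaged rather than pooled — a documented choice; pooling predictions
before computing metrics is the main alternative and would weight folds by
test-half size.

The improvement rule at each stage: candidates that lower either averaged
metric beyond the tolerance `eps` are inadmissible; among the admissible,
the largest AUC gain wins; if the best AUC gain is within `eps` of a tie,
the largest MCC gain decides; remaining exact ties fall back to the fixed
class enumeration order, making selection fully deterministic. Selection
stops when no admissible candidate improves either metric beyond `eps`.
`eps` defaults to $10^{-4}$: "no change in AUC" needs a numeric meaning,
and this absorbs floating-point jitter without masking real gains. A
consequence of the rule is that the per-stage AUC and MCC sequences of
every selection trace are non-decreasing.

## The synthetic generator

`generate_corpus()` draws labeled corpora with a *known* posterior, so
calibration and ranking can be checked against an exact reference instead
of another model. Labels are Bernoulli with `prevalence` (default 0.65,
the MEDLINE-like setting for the Humans heading). Title and abstract tokens
come from class-conditional multinomials in which an `informative_fraction`
of the field vocabulary is shifted by exactly `± separation` on the
per-token log-odds scale — the shifted tokens get equal base mass, half up
and half down, so both class distributions share one normalizer and the
posterior has the closed form

$$\mathrm{logit}\, P(y{=}1 \mid \text{record}) =
  \mathrm{logit}(\pi) + \textstyle\sum_t c_t \,\ell_t + \ell_{journal},$$

with $c_t$ the token counts and $\ell_t \in \{+s, -s, 0\}$. Journals are a
class-skewed categorical with log-odds `± journal_skew`; author names,
author count, pagination, year, and the length distributions are drawn
independently of the class and carry no signal. Ten percent of records lack
an abstract, mirroring MEDLINE field availability.

The default preset (`separation = 1`, `informative_fraction = 0.1`, title
length ≈ NB(mean 8), abstract length ≈ NB(mean 60), 200 journals) was
chosen once to represent *many weakly informative tokens* rather than a few
decisive ones: per-record log-odds then accumulate over roughly seven
informative draws, spreading the true posteriors over the whole unit
interval instead of piling them at 0 and 1. That makes calibration checks
meaningful across all score bins while keeping the Bayes ceiling high — the
regime the real tagger operates in.

What the generator does *not* emulate: real English word frequencies,
syntactic structure (bigrams arise only from adjacent independent draws),
topic correlation between title and abstract, journal–topic coupling, or
MeSH co-assignment structure. Tests passing on this corpus therefore
demonstrate that the machinery — feature extraction, optimization,
calibration, selection, metrics — is correct and well-calibrated under a
model whose truth is known; they do not by themselves establish the
performance level reachable on curated MEDLINE data.

## Benchmark sizes and what the package's checks compute

The package's own validation runs at deliberately modest sizes, chosen as
the point where the statistical claims are testable but a full run stays
comfortable on a single core:

* **Calibration recovery**: 20 000 generated records under the default
  preset, 16 000 for training and 4 000 held out, three feature classes
  (title unigrams, abstract unigrams, journal name — the classes the
  generator actually makes informative). Checked: held-out AUC within 0.03
  of the exact Bayes AUC, and mean absolute calibration error — the
  bin-weighted mean difference between binned predicted scores and binned
  true posteriors, bin width 0.05 — below 0.05. The binned definition
  isolates systematic score bias from per-record estimation noise, which is
  what "calibration" means in a reliability diagram.
* **Calibration adjusted R²** is reported both over all populated bins and
  over bins holding at least 100 records: at 4 000 test records, singleton
  bins contribute observed proportions of 0 or 1 that dominate an
  unweighted regression, so the dense-bin variant is the informative
  analogue of a large-corpus reliability fit.
* **Planted-signal selection**: 1 600 records where only title tokens are
  informative (`separation_title = 1.5`) and the abstract (800-token
  vocabulary) and journal (150 journals) fields are pure noise, ten seeds.
  The noise vocabularies are deliberately sizeable: irrelevant
  high-dimensional classes measurably hurt out-of-fold AUC, which is
  exactly the behavior that makes forward selection exclude them.
* **Metric oracles**: the rank-based AUC is checked against brute-force
  pairwise counting on a thousand random instances (n ≤ 200, tie-heavy
  score grids included); MCC, F1, and Brier against closed-form arithmetic.

The review-agreement arithmetic (the 2×3 blinded-review table of extreme
disagreements, with UNCERTAIN calls counted as non-matches) is purely
deterministic and is checked exactly.

## Known limitations

* The calibration map is fitted on margins from the 80% model but applied
  to margins from the 100% refit; the residual error this introduces is
  part of the measured calibration error and shrinks with corpus size.
* The bias term is regularized (augmentation convention), so the solver's
  solution differs very slightly from formulations with a free bias.
* Isotonic calibration can be piecewise-constant over wide margin ranges
  when the calibration split is small, quantizing scores; the sigmoid
  alternative trades that for a parametric shape assumption.
* `AUTHOR_COUNT`, `PAGE_COUNT`, and the count triplets are z-scored with
  training statistics; a distribution shift in these fields (e.g. very
  different pagination conventions) shifts their standardized values.
* The stop-word list is a bundled snapshot of a standard English list; a
  user-supplied list can replace it wherever a `stopwords` argument is
  accepted.
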