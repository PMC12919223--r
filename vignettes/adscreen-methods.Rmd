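---
title: "Methods: zero-burden ADRD risk screening and noise-corrected effect sizes"
author: "adscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zero-burden ADRD risk screening and noise-corrected effect sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adscreen)
```

## The screening problem

Alzheimer's disease and related dementias (ADRD) are usually diagnosed
late. Routine claims-style electronic health records — time-stamped
diagnosis (DX), prescription (RX) and procedure (PROC) codes — carry a
longitudinal comorbidity signal that precedes the first recorded
dementia diagnosis by years. `adscreen` implements a complete pipeline
for turning such code streams into a passive screening score, and for
estimating per-code effect sizes that remain honest when the
case/control labels themselves are noisy.

The pipeline has five stages, each an exported module surface:

1. **Code systems** (`codeChannel`, `expandPrefixes`, `buildVocabulary`,
   `assignRxOrdinals`): hierarchical prefix handling and a custom
   therapeutic coding of prescriptions.
2. **Cohort construction** (`labelPatient`, `assignIndex`,
   `applyEligibility`, `extractWindow`, `buildCohort`): phenotype
   labeling, index dates, observation windows, CONSORT accounting.
3. **Features** (`computePresence`, `fitORDictionary`,
   `computeOREmbedding`, `assembleFeatures`): binary presence vectors
   over codes-plus-prefixes and 12-dimensional cubed odds-ratio
   embeddings, per channel.
4. **Risk model** (`trainBase`, `trainMeta`, `trainEnsemble`,
   `predictRisk`): six gradient-boosted base learners stacked under a
   meta classifier with sex and age.
5. **Evaluation and attribution** (`rocAuc`, `metricReport`,
   `standardizedPredictiveValues`, `lambdaOR`, `volcanoTable`):
   screening metrics at a specificity anchor and the
   misclassification-corrected Λ-OR estimator.

A synthetic cohort generator (`simConfig`, `generateCohort`) provides
ground-truthed inputs for every stage.

## Cohort geometry

Time is measured in integer weeks since each patient's first DX code;
a year is 52 weeks for window arithmetic and 52.1775 weeks for age (the
only quantity where the fractional week matters over decades). For a
prediction horizon of $h$ years:

* **Cases** (any DX event matching the ADRD code list, or any RX event
  matching the anti-dementia prescription list — the *earliest* of the
  two anchors the phenotype) get their index date $\max(1, h)$ years
  before the first qualifying event. Cases with under three years of
  record before that event are excluded.
* **Controls** get their index date $\max(b, h + 1)$ years before end
  of record, where $b$ is the control confirmation buffer (default 2
  years): the label "control" is only trusted if the record stays
  ADRD-free for at least a year beyond the horizon. Controls with under
  four years of history are excluded, as are patients carrying any
  code from the exclusion list (conditions associated with or causally
  related to dementia).
* Everyone must be at least 50 years old at index with at least 3
  years of record span.

The **observation window** is the $w$ = 2 years (104 weeks) preceding
the index date, half-open on the right: an event in the index week
itself is *not* visible to the model. All features derive exclusively
from this window, so the model never sees the prediction gap.
`buildCohort` reports every exclusion reason in a CONSORT table whose
counts always sum to the input count.

## Feature embeddings

**Presence block.** For each channel, the vocabulary is the set of all
full codes plus their tracked-length prefixes observed in the
*code-inference set* (the training split): lengths 1, 2, 3, 5, 6 for
DX, 3, 4, 5, 8 for RX (the "rx" marker counts toward length), and 1–5
for PROC. A patient's presence vector sets a bit for every vocabulary
entry that is a window code or a tracked prefix of one; hierarchy is
therefore consistent by construction (a child bit implies its tracked
parents), and codes never seen in training contribute only through
their known prefixes. A full code whose own length is untracked is
still a vocabulary entry — membership is tested for codes and prefixes
alike.

**Odds-ratio block.** For each *full* code $c$ (prefixes are not
scored; configurable), the dictionary value is

$$\mathrm{OR}(c) = \left(
  \frac{\Pr(c \in \text{window} \mid \text{case})}
       {\Pr(c \in \text{window} \mid \text{control})} \right)^3,$$

estimated on the code-inference set with Haldane–Anscombe smoothing
($k + s$ over $n + 2s$, default $s = 0.5$) so empty cells never divide
by zero. Both probabilities are *per patient* ("does the window contain
the code at least once"), so within-window repetition is ignored
throughout; cubing spreads the dynamic range while preserving ranking.
The multiset of dictionary values found in a patient's window is
summarized by 12 aggregation functions — min, max, mean, median,
standard deviation (0 for singletons), sum, count, the
10th/25th/75th/90th percentiles and the geometric mean — chosen to span
location, scale and extremes; the set is overridable but must have
exactly 12 members. An empty window maps to 0 in every coordinate,
which is neutral for tree learners and explicitly documented rather
than NA.

**Leakage control.** Vocabularies and dictionaries carry a fingerprint
of the patient identifiers they were fitted on. `assembleFeatures`
refuses maps fingerprinted to the evaluation split, and the trained
ensemble refuses feature bundles whose per-block manifest differs from
its training manifest. These guards turn silent train/test leakage
into hard errors.

## The stacked risk score

Six gradient-boosted tree base learners (presence and OR blocks × three
channels; `xgboost`, shallow trees of depth 5, learning rate 0.1, 100
rounds, class-weighted) are cross-fitted with $K = 5$ folds: each
patient's base score comes from the model that never saw them, so the
meta stage trains on out-of-fold scores and cannot exploit in-fold
memorization. The meta classifier (small boosted trees by default,
logistic regression as an option) maps the six scores plus sex and age
to the final risk score in $[0, 1]$. Age and sex enter only at the meta
stage. All randomness sits behind one explicit seed recorded in the
model manifest, and single-threaded training makes runs bit-for-bit
reproducible; `saveModel`/`loadModel` round-trip the ensemble through a
model directory losslessly.

Note one subtlety of sparse inputs: `xgboost` treats *unstored* entries
of a sparse matrix as missing, not as zero, and learns default split
directions for them. For binary presence features this is equivalent in
effect; the ablation test in the suite constructs structurally empty
blocks (not zeroed values) for exactly this reason.

## Screening metrics

`rocAuc` is the Mann–Whitney pairwise concordance statistic (ties count
one half), computed through average ranks — exact, and invariant under
monotone transforms. Thresholds are anchored on the controls:
`thresholdAtSpecificity` returns the $\lceil t \cdot n \rceil$-th
control order statistic under the convention that scores *strictly
above* the threshold are flagged, which pushes ties toward fewer false
positives. PPV and NPV are *standardized* to an assumed prevalence
(default $\pi = 0.109$, i.e. 1 in 9) via Bayes' rule rather than taken
from the sample mix, because predictive values scale with prevalence
while discrimination does not; likelihood ratios and the
prevalence-weighted accuracy $se \cdot \pi + sp \cdot (1 - \pi)$
accompany them. `horizonDecay` summarizes temporal degradation as both
the endpoint decline and an OLS slope, in percent AUC per year.
Subgroup reports suppress strata below a minimum case/control count
instead of reporting unstable numbers, and bootstrap half-widths use
seeded, label-stratified patient resampling (the uncertainty convention
behind published ± columns is not standardized; both the estimate and
the interval are reported, neither claimed to match any external
table).

## The Λ-OR estimator

Observed case/control labels in large EHR studies are noisy: let $p$
be the sensitivity and $q$ the specificity of the labelling process.
With exposure indexing rows and status indexing columns, the observed
2×2 table satisfies, in expectation,

$$\tilde T = T \, K, \qquad
  K = \begin{pmatrix} p & 1-p \\ 1-q & q \end{pmatrix},$$

where $K$'s rows index the *true* status: observed case counts mix
true cases retained with probability $p$ and true controls leaking in
with probability $1 - q$. (Worked example: the true table
$\bigl(\begin{smallmatrix}40&10\\20&30\end{smallmatrix}\bigr)$ with
$p = 0.85$, $q = 0.95$ yields observed first-row entries
$40 \cdot 0.85 + 10 \cdot 0.05 = 34.5$ and
$40 \cdot 0.15 + 10 \cdot 0.95 = 15.5$; the unit tests invert exactly
this fixture. Keeping the multiplication on this side is load-bearing:
with the transposed correction, recovery simulations show a systematic
bias whenever $p \neq q$.)

The plain inverse $\tilde T K^{-1}$ can produce negative or unstable
counts, particularly near the degenerate surface $p + q = 1$ where the
labels carry no signal (the package refuses $|p + q - 1| < 10^{-3}$
outright). The estimator therefore uses a ridge-regularized inverse

$$T(\lambda) = \tilde T \,(K + \lambda I)^{-1}$$

with the *smallest* $\lambda \ge 0$ keeping every corrected entry
above a floor $\epsilon$ (default 0.5, the midpoint of the
conventional $[0.1, 1]$ range). Each corrected entry is a linear
polynomial over a positive quadratic in $\lambda$, so the feasible set
is an interval; `findMinLambda` locates its left edge by a
golden-section maximization of the minimum entry followed by bisection
to $10^{-9}$ relative tolerance, returns 0 when the plain inverse is
already feasible, and reports infeasibility as a flagged state rather
than an error. The corrected log odds ratio is
$\log \Lambda\text{-OR} = \log(ad/bc)$ on $T(\lambda)$.

**Variance.** The sampling variance is obtained by the delta method,
propagating the binomial noise of the observed table through the ridge
inverse $W = (K + \lambda I)^{-1}$: within each exposure row $i$ with
margin $n_i$,

$$\mathrm{Var}_i = \left[
  \frac{W_{11} - W_{21}}{a_i} - \frac{W_{12} - W_{22}}{b_i}
  \right]^2 \frac{\tilde a_i \tilde b_i}{n_i},$$

summed over the two rows ($a_i, b_i$ the corrected row entries,
$\tilde a_i, \tilde b_i$ the observed ones). For perfect labels
($W = I$) this reduces *algebraically* to the classical
$1/a + 1/b + 1/c + 1/d$, which is how the package honors the classical
formula: as the noiseless special case of the delta-method variance.
Applying the classical formula verbatim to corrected counts ignores
the variance inflation of the inversion and, in our calibration
simulations, undercovers badly at realistic noise levels — this
reading is a deliberate design decision, validated by the coverage
suite in the tests. When $p$ and $q$ are themselves estimated from a
validation cohort of size $n_{val}$, an extra-variance term

$$\mathrm{Var}_{extra} =
 \left(\frac{1-q}{(p+q-1)^2}\right)^2 \frac{2p(1-p)}{n_{val}} +
 \left(\frac{1-p}{(p+q-1)^2}\right)^2 \frac{2q(1-q)}{n_{val}}$$

is added (zero when $p, q$ are known exactly; vanishing as
$n_{val} \to \infty$ and at $p = q = 1$ — the printed form of this
term is typographically ambiguous in its source material, so the
implementation pins it down by these limit checks). Wald inference
follows: $Z = \log\Lambda\text{-OR} / \sqrt{\mathrm{Var}_{total}}$,
two-sided normal p-value, $(1-\alpha)$ confidence interval.

For attribution, exposures are cross-tabulated against
*model-predicted risk strata* (`buildStratifiedTable`: scores above a
threshold form the empirical high-risk stratum) rather than against
raw outcome labels, and `volcanoTable` assembles per-code results with
Benjamini–Hochberg adjustment alongside the raw p-values.

## The synthetic generator

`generateCohort` emulates the statistical structure the method
assumes, not any real coding process. Its defaults are the package's
reference study conditions, fixed once: 2,000 cases and 20,000
controls; 30 planted codes (14 DX, 8 RX, 8 PROC) whose
class-conditional window rates have ratios between 2 and 4 over
control rates of 0.05–0.16; background codes at Poisson loads of 8/4/5
per channel inside the window plus a pre-window remainder that
exercises window extraction; age at index normal (means 74/71 for
cases/controls, sd 8, truncated to [52, 95]); 55% female; a 1-year
horizon with ADRD-defining evidence planted after the index so the
cohort module recovers the generative labels; 2% of controls carrying
an exclusion-list code; 15% of cases with prescription-only evidence.
Codes are sampled independently given class — no within-patient
correlation, no visit structure, no coding drift, no calendar
seasonality. Passing tests on this generator therefore demonstrate
correctness of the machinery and recoverability of planted effects,
*not* real-world ADRD performance; the published real-data accuracies
are out of reach by construction, since those cohorts are proprietary.

Label noise is a separate, composable step (`corruptLabels`) with
known $(p, q)$, which is what makes the Λ-OR recovery suites possible:
`make2x2` cross-tabulates window exposure against the corrupted
labels, and `lambdaOR` must recover the planted log odds ratio.

## Problem sizes and numerical conventions

The test and acceptance workloads were sized as the package's
reference experiments: ensemble checks run on the full 22,000-patient
default cohort with a 66/34 split; Λ-OR calibration uses tables of
n = 50,000 with 200 replicates per cell over effect sizes
$\{0, \pm\log 2, \pm\log 4\}$ and noise grids $p, q \in \{0.8, 0.9,
0.95\}$; ridge-search verification compares against a staged
dense-grid oracle on 1,000 random tables. Other conventions: codes are
normalized to dotless uppercase before any matching; code lists match
by *prefix* so a three-character entry catches its children; vocabulary
ordering is C-locale lexicographic for determinism; JSON-lines output
is byte-deterministic given a seed; percentile aggregations use R's
default (type 7) quantiles.

## Known limitations

* "Continuous history" is operationalized as record span; no
  enrollment-gap analysis is attempted.
* The generator's independence assumptions understate the correlation
  structure of real comorbidity data; an ensemble that excels here may
  still degrade on correlated real-world codes.
* Λ-OR treats exposure as measured without error; only outcome labels
  are corrected.
* The 12 aggregation functions are a documented default, not a claim
  about any external system's exact choice; they are configurable.
* Calibration of the score itself (reliability curves) is out of
  scope; thresholds are anchored on specificity instead.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- simConfig(nCase = 150, nControl = 700, seed = 11)
g <- generateCohort(cfg)
co <- buildCohort(g$patients, defaultCaseDefinition())

tab <- co$table
y <- as.integer(tab$label == "case")
set.seed(21)
tr <- sample(nrow(tab)) <= round(0.7 * nrow(tab))
chs <- setNames(c("DX", "RX", "PROC"), c("DX", "RX", "PROC"))
fp <- splitFingerprint(tab$patient_id[tr])
vocabs <- lapply(chs, function(ch)
  buildVocabulary(lapply(co$windows[tr], `[[`, ch), codeChannel(ch), fp))
dicts <- lapply(chs, function(ch)
  fitORDictionary(lapply(co$windows[tr], `[[`, ch), y[tr], codeChannel(ch),
                  fingerprint = fp))
seTr <- assembleFeatures(co$windows[tr], tab$sex[tr], tab$age_at_index[tr],
                         vocabs, dicts, labels = y[tr])
seTe <- assembleFeatures(co$windows[!tr], tab$sex[!tr], tab$age_at_index[!tr],
                         vocabs, dicts)
model <- trainEnsemble(seTr, seed = 42)
scores <- predictRisk(model, seTe)
metricReport(scores$score, y[!tr], prevalence = 0.109)
```
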