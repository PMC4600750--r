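---
title: "Modelling the expression impact of somatic mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the expression impact of somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xshadow)
```

## The question and the model

Most somatic mutations in a tumour are passengers.  When a mutation does
matter, it usually perturbs transcription — of the mutated gene itself
(*cis*: nonsense-mediated decay, truncated transcripts, homozygous
deletion) or of the genes its product regulates (*trans*: a broken
transcription factor dysregulates its targets).  `xshadow` asks, for every
recurrently mutated gene and for every individual mutation, whether the
observed expression of the relevant genes looks dysregulated in the mutated
patients — and expresses the answer as a posterior probability.

The generative model for one mutated gene couples four layers of latent
variables.  A gene-level indicator $D$ says whether the gene's mutations
impact expression at all, with prior $\theta_D$.  Given $D$, each mutation
(one per mutated patient $m$) carries its own indicator $F_m$ with
$P(F_m{=}1\mid D) = \theta_{F1\mid D}$; the identifiability constraint
$\theta_{F1\mid D=1} \ge \theta_{F1\mid D=0}$ gives $D$ its meaning.  Given
$F_m$, each connected gene $n$ is in a regulation state
$G_{m,n} \in \{\text{down}, \text{neutral}, \text{up}\}$: impactful
mutations draw it from a dysregulated table oriented by the gene's fixed
direction $H_n$, null mutations from a neutral-heavy null table.  The edge
weight $w_n \in [0,1]$ of the influence graph expresses prior confidence
that gene $n$ really responds; it enters as a convex mixture
$w_n\,\theta_{G\mid F=1,H_n} + (1-w_n)\,\theta_{G\mid F=0}$, which is a
proper probability table for every $w_n$ and reduces to the two pure cases
at $w_n \in \{0, 1\}$.  Finally the observed log2 expression $Y_{m,n}$ is
emitted from the $G_{m,n}$ component of that gene's Student's-t mixture.

Because one parameter set $\theta$ is shared by all mutated genes in an
analysis, expression evidence is pooled across genes and patients: this
"borrowing of strength" is what distinguishes a recurrent expression
signature from patient-level noise.  Per-gene parameters would be
unidentifiable at the handful of mutations per gene that real cohorts
provide.

## Inference and learning

Once every $H_n$ is fixed, the model is a tree, and the marginals $P(D)$,
$P(F_m)$ and $P(G_{m,n})$ are exact by sum-product belief propagation: each
leaf is collapsed by summing $G$ against its emission density, per-patient
evidence is aggregated into $D$, and cavity messages give the per-mutation
and per-leaf posteriors.  All message passing is done in log space with
log-sum-exp, so thousands of connected genes cannot underflow.  The cost is
linear in $M \times N$.  The test suite verifies the implementation against
exhaustive enumeration of all latent assignments on small submodels (to
$10^{-8}$), and `enumerate_posteriors()` remains exported as the reference.

$H_n$ is estimated before learning, from the mixture responsibilities of
the observed values averaged over mutated patients (direction with the
larger average wins; exact ties resolve to "up"), and held fixed
thereafter — re-estimating it inside EM would destroy the tree structure
that makes inference exact.  One refinement matters for honest null
behaviour: the direction orienting the leaf of patient $m$ is estimated
from the *other* mutated patients (a jackknife).  A direction picked from
the same observation it scores is biased — under a true null every
neighbour's direction would be chosen to match the scored patient's own
noise, inflating each leaf's likelihood ratio, and the bias accumulates
across the $N$ neighbours (roughly as $N/\sqrt{M}$); without the jackknife
it inflates the trained null impact rate $\theta_{F1|D=0}$ and the number
of permuted-data calls.  The permutation and parameter-recovery checks in
the test suite exercise exactly this behaviour.  Per-leaf fixed directions
leave the model a tree, so inference stays exact; the consensus direction
over all patients is what the fit reports per connected gene.

The $\theta$ tables are learned by EM.  The E-step is belief propagation
per gene; the M-step is normalised expected counts, with the edge-weight
mixture handled exactly by splitting each $F{=}1$ leaf's counts between the
dysregulated and null tables according to the mixture responsibility
$w_n\theta_1/(w_n\theta_1 + (1-w_n)\theta_0)$.  A pseudo-count of 0.5
(a Dirichlet(1.5) prior) keeps parameters off the 0/1 boundary on small
cohorts.  With the prior, the quantity EM provably increases is the
penalised objective (log marginal likelihood plus log prior), so `em_fit()`
records both the raw likelihood trace and the objective trace; with
`pseudo = 0` the two coincide and the raw likelihood is monotone.  Genes
with fewer than two mutations contribute no recurrence signal and are
excluded from pooling, but are scored with the fitted parameters.

EM defaults: start at $\theta_D = 0.5$, $\theta_{F1|D=1} = 0.8$,
$\theta_{F1|D=0} = 0.1$, null table $(0.1, 0.8, 0.1)$, dysregulated table
$(0.05, 0.45, 0.5)$ oriented by $H$; stop at relative objective change
$< 10^{-5}$ or 100 iterations.

## Emission densities

Expression of each gene across the cohort is modelled as a three-component
location mixture of Student's-t distributions — heavy tails absorb the
outliers that log-scale RNA-seq abundances routinely produce.  Estimation
uses the latent-Gamma EM representation, with the degrees of freedom
updated by bounded one-dimensional search ($\nu \in [2, 100]$) inside each
M-step and a scale floor of $10^{-3}$ against singular components.

Two deliberate departures from a fully free mixture:

* **Shared dispersion.** The three components share one scale and one
  $\nu$; they are location shifts of a common kernel.  With free
  per-component dispersions the side components of a three-component
  mixture are unidentifiable at cohort-scale $n$: EM collapses them into
  narrow outlier-catchers far from the bulk, which destroys the emission
  evidence exactly where the model needs it.  Free fitting remains
  available (`shared_dispersion = FALSE`).
* **Neutral-heavy weight prior.** Component weights carry a weak
  Dirichlet(2, 20, 2) prior: dysregulation is the exception, and for a
  unimodal gene the fit should say so instead of splitting the bulk.  The
  reported `loglik` is always the observed-data log-likelihood; the
  monotone trace is the EM objective.

Fitting uses two deterministic starts (a dispersed percentile start and a
neutral-dominant start) and keeps the better objective; this resolves the
label-symmetric local optima without randomised restarts.  Genes with fewer
than 30 observations fall back to a single neutral component with a
warning — a three-component fit is not identifiable there.  The inner EM is
compiled (Rcpp); a pure-R reference implementation with identical updates
is kept and the two are compared in the tests.

## Preprocessing

**Expressed-gene filter.** Mutations in unexpressed genes are unlikely to
be pathogenic.  Each gene is summarised by the 90th percentile of its
expression across patients — robust to the gene being deleted in a minority
of samples, which a median would not be — and the percentiles are modelled
as a two-component Gaussian mixture (fitted with `mclust`).  Outliers by
the boxplot rule (Tukey fences at 1.5 IQR, linear-interpolation quartiles)
are removed before fitting and re-assigned posterior 1 (high side) or 0
(low side).  A gene is called expressed at posterior $\ge 0.8$ in the
higher-mean component; failing genes are dropped both as mutated genes and
as neighbours.

**Copy-number compensation.** Before trans analysis, the dosage effect of
copy-number alterations on the same gene's expression is removed by
Gaussian-process regression of expression on the copy-number log2 ratio
(squared-exponential kernel plus noise).  Hyperparameters maximise the log
marginal likelihood by L-BFGS with analytic gradients, restarted from
lengthscales of 0.5, 1 and 2 times the SD of the covariate; the residuals
(observed minus posterior mean) proceed to modelling.  A constant covariate
degenerates gracefully to centred expression.

**Influence-graph conditioning.** Edges below confidence 0.4 (the customary
median-confidence cutoff for such networks) are dropped; duplicate edges
keep the maximum weight.  Each remaining connected gene is tested for
differential expression between mutated and non-mutated patients (Welch
two-sample t-test on log2 values, BH-adjusted within the neighbourhood,
$\alpha = 0.05$; at least 3 mutated patients required).  If any connected
genes pass, the neighbourhood is restricted to them with weights set to 1;
otherwise the original weighted neighbourhood is used unchanged.  An
optional cross-cohort mode promotes genes that are recurrently
differentially expressed elsewhere (Fisher-combined p-values at
FDR $\le$ 0.05).

## Driver-pattern annotation

Tumour suppressors accumulate distributed loss-of-function mutations
(nonsense, stop-gain, frameshift indel, splice site); oncogenes accumulate
hotspot mutations (missense or in-frame indels recurring at one codon —
at least two hits at the same codon here, and records without codon
positions never count).  For each pattern the per-gene counts
$(n_g, N_g)$ across the cohort are modelled as a two-component binomial
mixture (high success rate $p_1$ = driver-like, background $p_2$), fitted
by EM from $p = (0.3, 0.02)$, $\omega = (0.1, 0.9)$ with 0.5 pseudo-counts.
P(TSG) and P(OCG) are the posteriors of the high-rate component, called at
the deliberately permissive threshold 0.2 (inclusive): the binomial mixture
replaces the fixed 20%-of-mutations rule with rates learned from the cohort
and posteriors that respect each gene's total burden.

## The simulator and what passing means

`simulate_xshadow_data()` samples ancestrally from the model itself:
$D \sim$ Bernoulli(0.5), $F \mid D$, uniform directions $H$,
$G \mid F, H$, and expression from t mixtures whose adjacent locations sit
`delta` within-component SDs apart; non-mutated patients draw from the null
marginal.  The defaults are the benchmark conditions: 200 mutated genes,
$M = 30$ mutated patients per gene in a 200-patient cohort, $N = 20$
connected genes, $\nu = 8$ emissions, $\theta_{F1|D=1} = 0.85$,
$\theta_{F1|D=0} = 0.10$, dysregulation probability 0.5 in the $H$
direction with 5% null leak per tail, and `delta = 1.5` — the poorly
discriminative setting (3 and 0.75 give the easy and extreme-noise rows of
a benchmark grid).  The 200-patient cohort size is a typical per-tumour-type
scale for matched mutation/expression data; an optional `phenocopy`
fraction lets non-mutated patients mimic the dysregulated signature, as
epigenetic silencing does in real tumours (default 0).

`benchmark_simulation()` runs simulate-fit-score replicates and reports
AUROCs for recovering $D$ and $F$; `scripts/acceptance.R` reproduces the
headline numbers (10 replicates at the defaults; a few minutes on one
CPU).  Permutation analysis (`permute_inputs()`) probes the null behaviour:
patient or gene labels of the mutation table shuffled, neighbourhoods
replaced by random same-size draws, or both — the expression matrix is
never touched — and `estimate_permutation_fdr()` turns call counts into an
expected-calls-ratio FDR.  The protocol trains the model once on the
observed data and scores each permuted dataset with the trained parameters
(`predict()`): re-training on null data walks the unidentified
$(\theta_D, \theta_{F|D})$ ridge and re-levels the posteriors around an
arbitrary prior, which answers a different question than "how often would
the fitted model call permuted data".

The simulator draws from exactly the distribution the model assumes, so
passing benchmarks demonstrates correctness of inference and learning —
not robustness to what real tumours add: batch effects, subtype structure
in expression, copy-number confounding beyond the modelled dosage term,
mutual information between neighbouring genes' emissions, or misspecified
influence graphs.  The permutation machinery and the preprocessing
utilities exist precisely because real data violate the generative
assumptions.

## Post hoc statistics

**Stratification.** Within a gene, the per-patient P(F) values often split
into impactful and inert groups; `stratify_patients()` cuts at 0.5
(inclusive) and quantifies bimodality with Hartigan's dip statistic — the
sup-norm distance from the empirical CDF to the nearest unimodal CDF,
computed by greatest-convex-minorant / least-concave-majorant fits with
iterative narrowing of the modal interval.  The implementation is verified
in the tests against an exact linear-programming oracle over the unimodal
band-feasibility formulation.  P-values are Monte-Carlo against uniform
samples of the same size (the canonical least-favourable unimodal null;
2,000 draws by default, seeded and cached per sample size, add-one
estimator).

**Recurrence across tumour types.** For genes mutated in several cohorts,
co-occurrence of connected-gene dysregulation (P(G) $\ge 0.5$) with
high-probability mutations (P(F) $\ge 0.5$) is tested per direction with an
exact binomial upper tail against the pooled maximum-likelihood background
rate, BH-adjusted.  Trials are mutated patients per tumour type.

**Hypermutators.** Tumours with more mutations than
$Q3 + 4.5 \times IQR$ of their cohort (strict inequality,
linear-interpolation quartiles) are flagged; their abundant passengers
otherwise dilute per-mutation inference.

## Numerical and design notes

* Exact ties in direction estimation resolve to "up"; component labels are
  ordered by location after every mixture fit.
* All probability tables are kept strictly inside $(0,1)$ by the
  pseudo-counts; identifiability is re-imposed after each M-step by label
  swaps (D-swap when $\theta_{F1|D}$ inverts; H-table swap when both
  direction tables invert).
* Missing expression drops the affected (mutation, gene) leaf — it
  contributes no evidence and no expected counts; it is never imputed.
* Patients exactly at reporting thresholds are included (all thresholds
  inclusive).
* Problem sizes in the test suite are chosen to exercise every code path
  at desk scale: the benchmark runs 10 replicates of the full 200-gene
  setting, the oracle comparisons use submodels with $M, N \le 3$, and the
  dip calibration uses 200 uniform replicates of size 100.

## Limitations

A gene mutated several times in one patient is collapsed to a single
"complex" event — the model cannot attribute impact to one of several
co-occurring mutations.  Directions $H$ are estimated once from the data
rather than taken from pathway databases, so a gene whose targets split
between up- and down-regulation is represented by its dominant direction
per target.  The influence graph is taken as given: absent edges cannot be
discovered, and dense hub genes inflate $N$ without necessarily adding
independent evidence.
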