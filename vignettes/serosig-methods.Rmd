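---
title: "Rank-based serum signatures and network analysis: models and design choices"
author: "serosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based serum signatures and network analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

serosig implements a two-part analysis of case/control serum proteomics as
practised in Duchenne muscular dystrophy (DMD) biomarker studies on
aptamer-based assays (~1100 analytes, tens of subjects): a rank-based
subject-signature classifier that yields biomarker panels, and a network
layer that looks for transcription-factor-rooted sub-networks, pathway
over-representation, and seed-gene-to-pathway proximity. This vignette
explains the models, the tunable parameters, and the places where the
design was genuinely open — and what we chose there and why.

## The classifier

**Pre-filter.** On the training subjects only, every protein is tested with
a two-sided Wilcoxon rank-sum test (affected vs control) and retained when
`p <= filter_alpha`. We compute the exact tail from the cached
Mann–Whitney U distribution whenever a protein has no tied values (the
common case for continuous abundances), and fall back to the normal
approximation with tie and continuity correction otherwise. One practical
consequence worth knowing: the exact test has a floor of `2 / choose(n, n1)`,
so on well-separated data many proteins can tie at the smallest achievable
p-value and no threshold can distinguish among them.

**Fold-change preprocessing.** Each protein is divided by its mean
abundance over the training subjects (`foldchange_preprocess = TRUE` by
default), emphasising fold changes over absolute abundance. The divisor
means are stored and reapplied verbatim to held-out subjects. Because the
divisor pools both classes, it compresses deviations on the side where a
subject's own class is elevated: a protein up-shifted by `e` log2 units in
cases sits at only about `log2(n / n_affected)` above baseline in a case's
normalised profile, while the *depleted* side keeps its full separation.
This asymmetry matters for signature design (below).

**Signatures and distance.** Each subject's retained proteins are ranked by
descending normalised level, ties broken by ascending protein id. The
signature is the first `n1` plus the last `n2` proteins. Two subjects are
compared by a weighted running-sum enrichment score: walking subject B's
ranking, a protein from the query set at rank `r` adds
`(P + 1 - r)^w / sum(hit weights)` and a miss subtracts `1 / (P - |S|)`;
the score is the running-sum value of largest magnitude, in `[-1, 1]`,
with `w = 1` by default (`w = 0` reduces to the classical unweighted
statistic). The similarity of subjects A and B averages four terms —
A's top and bottom lists scored in B's ranking and vice versa, bottom terms
negated — and maps to `d = (1 - s) / 2` in `[0, 1]`. When one side of the
signature is empty the average runs over the defined terms only, which
preserves `d(A, A) = 0` exactly. Exact magnitude ties in the running sum
resolve to the positive extreme (with a 1e-12 guard so floating-point noise
cannot flip the sign).

**Classification and validation.** A held-out subject takes the label of
the training group with the smaller mean distance; exact ties go to
`control`, deterministically and with a warning. Evaluation uses stratified
k-fold cross-validation (k = 5, i.e. 20% held out per round; stratification
matters because the 42/28 class imbalance occasionally degenerates
unstratified folds). All fitting — pre-filter and normalisation means — is
done on the training fold only.

**Panels.** The biomarker panel is the union of all proteins appearing in
at least one subject signature, pooled across folds, with a record of which
subjects contributed each protein. We aggregate over cross-validation folds
rather than refitting on all data, so the panel reflects exactly the
signatures that produced the reported accuracy.

**Permutation test.** Class labels are shuffled `B = 1000` times and the
full cross-validation is re-run each time;
`p = (#\{null >= observed\} + 1) / (B + 1)`. The wording of permutation
protocols in this literature is sometimes ambiguous between permuting
feature identities and permuting sample labels; only the latter produces a
meaningful null for *classification accuracy*, so that is what we permute.
A shuffled labelling may leave fewer filtered proteins than `n1 + n2`; null
runs cap the signature lengths at the fold's retained count and fall back
to majority-class prediction if nothing is retained. Observed (unpermuted)
runs never clamp. Because cross-validated accuracies take few distinct
values, the permutation p-value is conservative (super-uniform) rather than
exactly uniform under the null — the property our tests assert.

**Genetic optimizer.** The search space is `(n1, n2, filter_alpha)`:
`n1, n2` in 0–40 and alpha on a 12-point log grid from 1e-12 to 0.05.
Fitness in *short* mode is lexicographic — mean CV accuracy first, then
smaller panel (implemented as `accuracy - 1e-6 * panel size`, safe because
accuracy granularity is 1/70 and panels are at most 1128); in *long* mode
it is the panel size, subject to accuracy `>= a_min = 0.98`, our concrete
reading of "accuracy close to 100%". Standard generational GA: tournament
selection (size 3), single-point crossover (rate 0.8), per-gene mutation
(rate 0.15), elitism, population 40, 60 generations — defaults chosen as
unremarkable GA practice, not tuned. Fold assignment is fixed by the seed
and per-fold Wilcoxon p-values are cached, so the search compares
parameters on identical folds and chromosome evaluations are memoised. The
initial population is seeded with a few minimal chromosomes at the loosest
alpha so the search starts from a feasible region even when strict filters
retain almost nothing.

**Why `n1 = 0` is allowed.** The signature type itself only requires
`n1 + n2 >= 1`, and the pooled-mean compression described above makes
bottom-only signatures genuinely better on strongly shifted markers: a
subject's own-class elevated proteins are compressed into the noise near
the top of their ranking, while down-shifted proteins (and the other
class's up-shifted ones) sit far below baseline. Restricting the search to
`n1, n2 >= 1` would force every signature to carry one noisy top protein
per subject and inflate the short panel several-fold. On the default
synthetic cohort the short-mode optimum is a bottom-only signature of
length 1–2 whose panel is exactly the six strong markers.

## Covariate screens

Age associations fit per-protein OLS of `log2(level)` on age, separately
within each group — matching the two-regression-lines presentation this
field uses — rather than a pooled model with an interaction term; the
per-group fit answers directly "does this protein drift with age in
patients, and not in controls". Treatment effects among affected subjects
use the same exact/approximate Wilcoxon machinery as the pre-filter. Both
screens apply Benjamini–Hochberg correction *within the tested protein
family*, normally the biomarker panel, not all 1128 analytes — the family
a practitioner actually reports. The age-matching check is a two-sample
Kolmogorov–Smirnov test on the age vectors.

## Enrichment

Tissue specificity follows the standard 5x transcript-ratio rules, applied
in precedence order: tissue enriched (one tissue at least 5x all others),
group enriched (smallest qualifying group of 2–7 tissues at least 5x the
rest), tissue enhanced (at least 5x the cross-tissue mean), expressed in
all, not detected, mixed. The detection threshold defaults to 1.0
expression unit (the conventional transcript-abundance cutoff) and is
config-exposed. Group search only considers the top-g tissues for
g = 2..7: a qualifying group, if any exists, must consist of the
top-expressed tissues. Panel-vs-background tissue enrichment is a
one-sided Fisher exact test per tissue; gene-set over-representation is
the upper-tail hypergeometric probability with BH correction across the
sets that intersect the background (empty intersections are recorded with
p = 1 and flagged, outside the BH family). Multi-gene analytes contribute
each mapped symbol once; the unannotated analyte is retained for
classification but excluded from every symbol-based analysis.

## Network layer

Differentially abundant proteins are called by a two-sided Welch t-test on
log2 values with BH across all assays (q < 0.05). This is a plain
per-protein test, not a moderated empirical-Bayes fit; with 70 subjects
the shrinkage would change little, and the DE set can be computed
externally and passed in wherever it is consumed.

For each transcription factor, the sub-network is the union over target
(panel) genes of one minimum-length directed path per target, chosen to
pass through the most DE intermediate nodes — an exact maximisation by
dynamic programming over the shortest-path DAG, with ties broken by
lexicographically smallest node sequence, so the output is deterministic
and testable against brute-force path enumeration. Every TF whose
sub-network yields a BH-significant pathway overlap (one-sided Fisher
against the network gene universe) is reported, and each significant
pathway is attributed to the TF with the smallest raw p — reproducing the
one-regulator-per-pathway shape of this analysis style without relying on
unpublished scoring internals. Pathway–pathway similarity is the overlap
coefficient `|A∩B| / min(|A|, |B|)` with the shared count.

Proximity: the observed statistic is the minimal unweighted shortest-path
distance from the seed gene (dystrophin, in the motivating application) to
any in-network pathway member on the undirected physical-interaction
network; the null re-computes it for `n_random = 1000` genes drawn
uniformly *without replacement* from the network (pathway members are not
excluded by default — a flag excludes them), and
`p = #\{null <= d_obs\} / n_random` with no add-one correction (a
`plus_one` option exists for conservative reporting). Unreachable nodes
count as infinitely distant. Degree-matched null sampling was considered
and deliberately left out of the default: the uniform null is what the
plain "random genes" protocol describes.

## The synthetic cohort

The generator emulates the structure the analysis assumes, not any real
assay's artifacts. On the log2 scale each protein has a Gaussian baseline
(mean 8–12, SD 0.3–0.8), 52 planted markers carry a signed class shift
(|shift| 1.0–2.5 for ordinary markers; for 6 strong markers at least
6 within-group SDs — drawn just above `6 * 0.8` so the guarantee holds for
any per-protein SD — half up, half down), 31 markers drift with age in
affected subjects only (slopes −0.30 to −0.08 log2/year, two exceptions
drifting upward), and 32 markers shift by 0.3–0.8 log2 units in the
treated affected subgroup (28 of 42). Ages are drawn uniformly on 4–15
years for both classes (age-matched by construction), and the age term is
centred at the midpoint so the planted class effect is not confounded by
the age drift. Abundances are `2^log2-value`, hence log-normal and
positive, as aptamer-based measurements are.

What the generator does *not* emulate: assay calibration and normalisation
artifacts, batch effects, missing values, and heteroscedastic
concentration-dependent noise. Passing tests therefore demonstrate the
pipeline's correctness and its behaviour under the planted statistical
structure, not robustness to real-world assay pathologies.

Two planted-recovery facts discovered with this generator are worth
stating. First, ~30 of the ordinary markers separate the classes
completely in a 56-subject training fold and tie with the strong markers
at the exact Wilcoxon floor, so the pre-filter alone cannot isolate the
strong six — the GA finds them through the panel-size objective instead.
Second, treatment shifts of 0.3–0.8 log2 against within-group SDs of
0.3–0.8, with 28 treated vs 14 untreated, give a mean rank-sum z around
2.7: only ~30–45% of planted treatment markers reach q < 0.05. That is a
property of the planted effect sizes (the motivating study itself found 32
of 52 panel proteins treatment-associated), and we report it rather than
inflating the planted shifts.

The synthetic networks are preferential-attachment graphs (edges oriented
from earlier- to later-attached nodes in the directed copy), with one
designated TF wired to every strong marker through dedicated DE relay
nodes at distance exactly 2, and a seed gene attached to the planted
pathway at a recorded distance in the undirected copy. Any connected
heavy-tailed topology would do for testing; preferential attachment is
simply the conventional choice.

## Problem sizes in the tests

The test-suite re-runs the full default cohort for the headline checks
(long-panel accuracy, 1000-permutation significance, short-panel
parsimony) and uses scaled-down cohorts — 18–36 subjects, 25–150 proteins,
reduced permutation counts — for the distributional property checks
(null validity of the permutation and proximity p-values across 150–200
replicates, exchangeability of generated ages across 100 seeds). The
scaled sizes are chosen so each property suite exercises a few thousand
model fits, which is where distributional statements become stable.

## Known limitations

- The ES-based distance is one faithful realisation of the weighted
  enrichment-score family; other symmetrisations (e.g. weighting top and
  bottom terms unequally) would also satisfy the same invariants.
- Long-mode panels maximise size under an accuracy floor; on data where
  extra noise proteins do not hurt accuracy the panel absorbs them, so its
  precision for planted markers is a property of the filter stringency the
  GA selects, not of the mode itself.
- The classifier is strictly two-class, and probabilistic outputs are out
  of scope by design.
- Network conclusions inherit the quality of the supplied edge lists; the
  package ships generators, not curated interactomes.
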