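---
title: "Benchmarking bioactivity models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking bioactivity models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pcmbench` benchmarks machine-learning methods for compound--target
bioactivity prediction on ChEMBL-style data. This vignette explains the
models and procedures the package implements, the tunable parameters and
their defaults, what the bundled synthetic generator does and does not
emulate, and the numerical and design choices made where the problem was
genuinely open.

## The modelling problem

The data are sparse measurements of pChEMBL values -- negative decadic
logarithms of a molar half-maximal activity (IC50, EC50, Ki, Kd) -- on a
compound x protein-target matrix. Public matrices are extremely sparse (a
typical curated literature extract is on the order of 0.1% complete), noisy
(heterogeneous assays contribute roughly 0.5 log units of error to IC50
data), and biased towards actives. A measurement is labelled *active* when
its pChEMBL value is at least 6.5 (about 300 nM, boundary inclusive); this
threshold splits typical literature data roughly 55/45 and is more relevant
to hit-finding than the permissive 10 uM convention, under which nearly
all measurements are "active".

Three model families are compared on the same curated table:

* **Single-target QSAR**: one binary classifier per target on compound
  features (naive Bayes, random forest, SVM, logistic regression, or a
  single-output regression network).
* **Multi-task (MC)**: one feed-forward network whose output layer carries
  one node per target, trained jointly on all targets through a masked
  loss.
* **Proteochemometrics (PCM)**: one model over compound--target *pairs*,
  with explicit protein descriptors concatenated to the compound features.
  Only PCM can score a target absent from training, provided its sequence
  is known.

## Curation

`curate()` reduces a raw activity table to a modelling set: assay
confidence class 9 (direct single-protein assignment -- note this is a
*classification*, not a quality score, so "at least 8" would mix
incompatible assay types), target type "single protein", literature
source, a present pChEMBL value, no duplicate or validity flags, and none
of the disqualifying activity comments (*not active*, *inactive*,
*inconclusive*, *undetermined*). Repeated measurements of a pair collapse
to their median (even-sized groups: mean of the two central values); the
surviving record keeps the earliest year and the union of document ids.
Target-level filters -- at least 30 distinct compounds from at least 2
publications -- are evaluated once on the post-row-filter snapshot.
Because the per-target counts do not depend on other targets, iterating
them to a fixed point (`fixpoint = TRUE`) converges immediately; the flag
exists so the invariance is checkable rather than asserted. Whether the
publication filter should precede the compound filter is not determined by
any ordering argument; both are evaluated on the same snapshot.

Activity classes are always recomputed from the stored pChEMBL value at
evaluation time, never cached.

## Descriptors

**Compounds.** Hashed circular substructure fingerprints
(extended-connectivity family, radius 3 bonds) computed by OpenBabel at
4096 bits and modulo-folded to the requested length (default 256). Folding
can only merge bits, so the population count at 256 bits never exceeds the
count at 4096 -- a property the tests exercise, alongside a golden-file
fixture that pins the exact bit pattern of ethanol. Optionally six
physicochemical descriptors are appended: AlogP, molecular weight,
hydrogen-bond acceptors and donors, fractional polar surface area, and
rotatable bonds. Fractional PSA is the topological PSA divided by an
approximate total surface area summed from atomic van der Waals sphere
areas; the approximation ignores sphere overlap, which deflates the
fraction uniformly -- acceptable because only the across-compound contrast
matters, and the value is clipped to [0, 1].

**Proteins.** An alignment-free 169-value descriptor: the sequence is cut
into 20 contiguous near-equal parts (the first `n %% 20` parts take the
extra residue), the mean of 8 residue properties is taken per part and
once globally, and the sequence length is appended (21 x 8 + 1 = 169).
The residue property table (stereo-atom count, logD and formal charge at
pH 7.4, H-bond acceptors/donors, rigidity, aromatic bonds, molecular
weight) was computed once from the free amino-acid structures with
OpenBabel plus standard pKa rules; logD is approximated as logP minus 3
per unit of formal charge. Published tables for this descriptor family
rely on a commercial logD engine, so absolute values here differ from
other implementations; the table is shipped as a documented constant and
every function accepts a user-supplied 20 x 8 replacement. "Rigidity" is
defined as the count of non-rotatable bonds between heavy atoms.
Non-standard residue letters are imputed with the unweighted mean property
vector (strict mode errors instead). The size-weighted mean of the part
blocks equals the global block exactly -- a checked invariant.

**Scaling.** Protein and physicochemical blocks are standardised to zero
mean and unit variance with statistics learned on *training rows only*;
fingerprint bits are never scaled; constant columns are left untouched.

## Models

Classical baselines use their established implementations behind the
package's uniform surface: random forest (1000 trees, 30% of features per
split, unlimited depth), RBF-kernel SVM (gamma = 1/d, cost 1), and
L2-regularised logistic regression capped at 100 iterations (the R stack
has no stochastic-average-gradient solver; ridge-penalised `glmnet` is the
closest behavioural match and is documented as such). Multinomial-event
naive Bayes over fingerprint bits is implemented in the package (no
multinomial NB exists in the installed stack, and it is itself a method
under benchmark): Laplace-smoothed bit counts per class, scored by
log-likelihood ratio.

The naive Bayes variant used for ranking standardises each target's raw
scores over *all* compounds in the collection to zero mean and unit
population SD (the z-score background). This is what makes NB scores
comparable across targets; it is also why NB is the slowest method at
scale, since it requires scoring the full matrix. Classification of the
z-variant uses z > 0 -- the ranking literature only fixes the ranking, so
the decision rule is a package choice and is configurable.

**Networks.** Feed-forward rectifier networks with linear outputs predict
pChEMBL values directly; classes are derived at the threshold afterwards.
Defaults: hidden layers 4000/2000/1000, no input dropout, 25% hidden
dropout, batches of 128, at most 2000 epochs. Training is plain
stochastic gradient descent with Nesterov momentum; the learning rate
anneals linearly from 0.005 to 0.0001 over the run and momentum grows
linearly from 0.8 to 0.999. The loss is the masked mean squared error:
only observed cells of the sparse output grid contribute, each observed
value with equal weight (inverse-size target weighting is exposed as an
option but off by default -- equal weighting is the documented default
behaviour). Early stopping monitors the masked loss on a seeded,
unstratified 20% split of the training rows, halts after 200
non-improving epochs, and restores the best-epoch weights. Weight
initialisation is fan-scaled uniform (Glorot) from the run seed; with
dropout 0 two runs with the same seed are bit-identical, and with dropout
on they remain deterministic given the seed. A divergent (non-finite)
loss raises an error that recommends the documented batch-256 fallback
rather than switching silently. `width_scale` shrinks all hidden layers
proportionally so desk-scale studies can use the same code path; the
production widths stay the documented defaults.

## Validation

Two partitions are implemented. The **random split** first removes a 10%
holdout, then splits the remainder 70/30, both stages stratified on
(target, class) cells with at least 10 records; smaller cells are pooled
and split uniformly, and largest-remainder allocation makes the totals
exact. "Semi-stratified" partitioning in commercial pipeline tools is not
publicly specified; this rule preserves per-target class balance and
degrades gracefully, and is documented as the package's own definition.
The **temporal split** trains on publications before the cutoff year
(default 2013; the cutoff year itself is test data) and errors on records
with missing years rather than silently training on them -- a temporal
leak is worse than a hard failure.

Metrics are the Matthews correlation coefficient (robust to class
imbalance; defined as 0 when a confusion-matrix marginal is zero, the
natural value for uninformative predictions) and BEDROC at alpha = 20,
an exponentially rank-weighted enrichment score for which the top 8% of
the ranked list carries about 80% of the weight. BEDROC ties are broken
pessimistically (inactives above actives at equal score). Each metric is
computed twice -- pooled over all pairs, and per target averaged over
targets where it is defined (single-class targets are skipped and
counted) -- and the reported value is the mean of the two with its SEM.
Pairs a method cannot score receive a uniform random score in (0, 1)
(active above 0.5) so that all methods are compared on the full pair set
at chance-level cost instead of cherry-picking coverage.

Methods are ranked by standardising each experiment's metric across
methods (sample SD; the published two-decimal values cannot distinguish
sample from population SD, so the conventional n-1 is used) and averaging
the four z-scores per method. Pairwise differences are probed with four
two-sided tests: paired t, F on variances, Wilcoxon (rank-sum by default
-- "same median" phrasing suggests the unpaired variant; signed-rank is a
flag), and Kolmogorov--Smirnov. Degenerate inputs (zero variance where a
test needs one) are flagged, not given fabricated p values.

## Grid search and ensembles

The default grid crosses 3 modes x 3 descriptor specifications (256 bits;
4096 bits; 4096 + physicochemical) x 7 architecture/dropout variants at an
epoch cap of 500, giving 63 configurations. The seven variants are the
four architectures [1000], [2000,1000], [4000,2000,1000], [8000,4000,2000]
under normal dropout plus the three deeper ones under increased dropout
(25% input / 50% hidden); the published count does not pin the exact
factorisation, so the grid is fully user-overridable and the default is
the package's documented choice. Ensembles combine member prediction sets
by majority vote (even ties resolve towards the class with the higher
mean member score) or by score averaging on a shared scale; thresholding
the averaged score is checked against a brute-force recombination oracle.

## The synthetic generator

`generate_synthetic()` plants a bilinear latent model on a sparse matrix:

$$\mathrm{pchembl}(c,t) = \mu + a_c + b_t + u_c v_t + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2)$$

This is the minimal structure under which the three model families are
distinguishable: the additive compound term rewards any QSAR, the target
term rewards multi-task sharing, and the interaction factor can only be
exploited for unseen targets by PCM. Compound effects are sums of
per-fragment contributions over a 16-fragment SMILES grammar (5 fragments
per compound, sampled without replacement), so circular fingerprints can
see them; target effects tilt the hydrophobic ($v_t$) and charged ($b_t$)
residue fractions of the generated sequences, so the composition-based
protein descriptor can see them. Realised effects are centred so that
$\mu$ is the grand mean for every seed -- with only 16 shared fragments
the raw realisation would drift by tenths of a log unit and the
documented activity balance would not hold.

Defaults are the package's study conditions: 20 targets x 500 compounds
at density 0.2 (2000 measurements), mu = 6.61 calibrated so that the
6.5 threshold yields about 55% actives, effect SDs 0.6 (compound), 0.4
(target), 0.5 (interaction factors), noise sigma = 0.5 matching the
typical experimental error of public IC50 data (recovery experiments use
sigma = 0.25 so the planted signal, not the noise floor, limits the
score), years uniform on 2006--2016 around the 2013 cutoff. The optional
chemistry-drift flag swaps part of the fragment vocabulary after the
cutoff year, so temporal validation faces genuinely new chemistry -- the
mechanism believed to make temporal splits harder than random ones.

What the generator does **not** emulate: real chemical space and scaffold
diversity (16 fragments versus tens of thousands of scaffolds), assay
heterogeneity, the extreme 0.13% sparsity and the long-tailed per-target
compound counts of real extracts, or inter-laboratory systematic error.
Passing recovery tests therefore demonstrates that the implementations
learn what they claim to learn from data of this structure -- not that
they would reach any particular score on real ChEMBL data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the recovery benchmark at
20 targets x 500 compounds with a [512, 256]-unit multi-task network for
up to 800 epochs -- small enough to train on one CPU core in about a
minute, large enough that chance-level MCC has a standard error of about
0.04 on the 540-pair test set, so the planted-signal (MCC >= 0.5) and
permutation-control (|MCC| <= 0.15) bands are separated by many standard
errors. Early-stopping improvements smaller than 1e-12 are ignored;
schedule interpolation is linear in the 1-based epoch; the empty
observation set contributes a loss of exactly 0; evaluation requires at
least one record and both classes for BEDROC, erroring otherwise.

## Known limitations

* Fingerprints come from OpenBabel's extended-connectivity implementation;
  bit patterns differ from other toolkits' circular fingerprints, so
  models and golden files are not portable across fingerprint backends.
* The residue property table is an open approximation; descriptor values
  differ numerically from tables built with commercial logD engines,
  though the descriptor geometry (what is similar to what) is preserved.
* Logistic regression uses a ridge penalty with a fixed small lambda, not
  an exact replica of stochastic-average-gradient behaviour.
* The network trainer is a reference implementation in base R: correct
  and deterministic, but not suitable for the full published widths on
  ChEMBL-scale inputs without substantial compute.
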