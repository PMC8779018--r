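---
title: "Methods: posterior correction, metadata fusion and their exact oracles"
author: "fungifuse developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posterior correction, metadata fusion and their exact oracles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fungifuse)
```

## The problem

Species-recognition services for citizen scientists sit on top of an image
classifier, but much of their accuracy comes from what happens to the
classifier's probabilities afterwards. This package implements that
post-processing layer for long-tailed, fine-grained recognition — the
regime of fungal atlases, where a few common species dominate and most of
the ~1600 classes are rare — together with a synthetic world in which
every formula can be checked against exact Bayes by enumeration.

## Models and assumptions

### Prior-shift correction

A classifier trained by cross-entropy on data with class prior $p(s)$
estimates $p(s \mid x)$ under that prior. If deployment data follow a
different prior $p_e(s)$ while the class-conditional appearance
$p(x \mid s)$ is unchanged (the *label shift* assumption), Bayes' rule
gives

$$p_e(s \mid x) \propto p(s \mid x)\,\frac{p_e(s)}{p(s)},$$

renormalized over species; the evidence terms cancel. `adjust_posteriors()`
implements this; `adjust_to_uniform()` is the special case $p_e(s) = 1/K$
used for balanced evaluation sets. Both require the *target* prior to be
known: estimating an unknown deployment prior from unlabeled data is a
different problem and out of scope here.

Zero-handling is strict by design: a species with $p(s) = 0$ is allowed
only if no posterior row places mass on it (the class is consistently
absent). Positive mass on a zero-prior species raises an error instead of
clamping, because the ratio is undefined and clamping silently hides a
train/deployment mismatch.

### Metadata fusion

Each observation may carry categorical metadata: habitat, substrate, and
month (treated as 12 unordered categories, not a cyclic variable —
consistent with relative-frequency estimation). The fusion rule assumes
the visual appearance of a species does not depend on the metadata *given
the species*:

$$p(i \mid s) = p(i \mid s, d)
\quad\Longrightarrow\quad
p(s \mid i, d) \propto \frac{p(s \mid i)\, p(s \mid d)}{p(s)},$$

and with several metadata types, assuming their mutual independence given
the species,

$$p(s \mid i, d_1 \dots d_m) \propto
p(s \mid i)\, \prod_{j=1}^{m} \frac{p(s \mid d_j)}{p(s)}.$$

$p(s \mid d)$ is estimated by `fit_frequency_model()` as the relative
frequency of species $s$ among training observations with value $d$,
optionally with an additive pseudocount $\alpha$ per type
($(c_{sd}+\alpha)/(c_d + K\alpha)$; default $\alpha = 0$, i.e. pure
relative frequency).

Three boundary rules matter in deployment and were genuinely open design
choices:

* **Missing metadata** contributes no factor for that observation ($m$
  decreases); an observation with all selected fields missing passes
  through unchanged. The alternative — imputing a value — would inject
  information the record does not contain.
* **Unseen values** (a substrate never observed in training) fall back to
  $p(s \mid d) = p(s)$, making the factor a no-op rather than an error:
  deployment data routinely contain categories absent from training.
* **Joint estimation** of $p(s \mid d_1, d_2)$ by relative frequency is
  available (`joint = TRUE`, used for tuples with at least
  `min_joint_count` training records) but off by default: independence is
  the baseline model, and joint tables are extremely sparse in a
  long-tailed training set.

### TTA geometry and pooling

`tta_crop_specs()` emits the 14 deterministic views: full image, central
crop at 80% of width and height, central 60% crop, four 60% crops anchored
flush to the corners, and the horizontal mirror of each. The percentages
are fractions of width/height, not of area, and mirroring is horizontal
only — vertical flips are a training-time augmentation, not an evaluation
view. Fractional boxes become pixel rectangles via round-half-away-from-
zero on each edge (half-open), which keeps centered crops symmetric and is
deterministic across platforms.

`pool_sum()` averages probabilities and renormalizes (identical to
sum-then-normalize by scale invariance). `pool_mode()` lets each view or
model vote its arg-max; ties are broken first by the probability summed
over the stack, then by species order. The tie-break is an artifact
choice — any deterministic rule that uses the available evidence would do,
and the test suite pins this one. Whether prior adjustment is applied
before or after sum pooling is left to the caller's composition order; the
two orders differ in general because the adjustment is nonlinear
(renormalization), and the pipeline runner executes whatever order the
configuration states.

### Evaluation

The rank of the true species is defined as one plus the number of species
with strictly higher probability, ties broken by species order. Top-k
accuracy, mean per-class accuracy (unweighted over species present in the
truth; species with no test observations are excluded rather than scored
zero) and rank shares all derive from this single definition, which makes
`rank_shares()[["1"]] * 100` equal `topk_accuracy(k = 1)` exactly. Whether
a tie at the k-th rank counts as a hit is unspecified in common reporting
practice; the deterministic rule here never counts it (the tied earlier
species occupies the rank).

`species_split()` assigns exactly $\lceil f \cdot n \rceil$ of each
species' $n$ observations to training (default $f = 0.9$), sampled
uniformly under a fixed seed. The ceiling means a species needs
$n \ge 10$ at $f = 0.9$ to contribute a test observation at all — the
structural reason such benchmarks restrict themselves to species with
more than 30 records.

## The simulator: a stated world, not a dial

`build_model()` replaces images by a discrete visual token: species $s$
emits token $v$ with probability drawn once from a symmetric Dirichlet.
Habitat (10 categories), substrate (8) and month (12) are separate
per-species categorical channels. Two properties are true *by
construction*, not approximately:

* visual token and metadata are conditionally independent given the
  species — exactly the fusion assumption; and
* all posteriors are enumerable: `exact_posterior_visual()` and
  `exact_posterior_full()` compute brute-force Bayes over the discrete
  observable space.

The simulated classifier in `sample_dataset()` outputs the exact
train-prior posterior of each observation's token — i.e. it is
Bayes-optimal under the training distribution, which is the premise of
the prior-shift formula. An optional `temperature` power-transforms the
rows to emulate over- or under-confidence; the default 1 keeps the
classifier exact so that formula tests can assert equalities rather than
directions.

Defaults are chosen once as a realistic desk-scale world and not tuned:
$K = 50$ species, $V = 200$ tokens, train prior Zipf with exponent 1.2
(a pronounced long tail at $K = 50$), Dirichlet concentration 0.1 for the
visual channel (informative but far from perfectly separable; in-domain
top-1 around 55–60%) and 0.5 for metadata channels (each type helps by a
few points, all three together substantially — the direction, not the
magnitude, of the real systems' gains). Test suites use $N = 10{,}000$
observations for directional checks and $N = 50{,}000$ for parameter
recovery, which keeps the full suite well under a minute.

What a green test does **not** establish: real classifiers are not
Bayes-optimal nor calibrated; real metadata violates conditional
independence (substrate changes the image background); real categories
are noisy free text. The simulator isolates the probability algebra from
representation learning — that isolation is its purpose, and its limit.

## Numerical choices

* Probabilities are stored in linear space; all products (prior ratios,
  fusion factors) are accumulated in log space and renormalized with a
  row-max shift. Exact zeros in an input posterior remain exact zeros.
* Posterior row sums may drift below $10^{-6}$ (silently renormalized);
  larger drift is an error — accumulated float noise is expected,
  structural drift is a bug. Priors use the tighter $10^{-9}$. Both are
  artifact choices; no canonical tolerance exists for "is a posterior".
* CSV output carries 9 significant digits: below validation tolerance,
  above every test tolerance, so round trips are lossless in practice.
* All randomness flows through an explicit integer seed
  (`withr::with_seed`), so datasets, models and splits are
  bit-reproducible and never disturb the caller's RNG state.

## Statistical notes on the test suite

The parameter-recovery check compares every fitted $p(s \mid d)$ cell to
the model's implied conditional. With ~300 (value, species) cells, a hard
per-cell 3-standard-error bound fails with $\approx 55\%$ probability even
when the estimator is exactly correct (expected chance exceedances
$\approx 0.8$). The suite therefore asserts the 3-SE property in
aggregate — exceedance rate below 2% against a binomial expectation of
0.27% — plus a Bonferroni-corrected bound on the worst standardized
deviation. This multiplicity correction is the statistically well-posed
reading of "within 3 SE", not a loosened tolerance.

The headline error-reduction figures checked in the acceptance suite are
derived from published accuracies printed to two decimals; the derived
ratio therefore carries an uncertainty of a few hundredths of a
percentage point, and the checks assert agreement within that printed-
precision band.

## Known limitations

* No calibration (temperature scaling etc.): fusion quality on real,
  overconfident classifiers depends on calibration that this package
  deliberately does not provide.
* No estimation of unknown deployment priors from unlabeled data.
* Month is categorical; phenology with smooth seasonal structure would
  motivate a cyclic model the frequency estimator cannot express.
* The pipeline configuration accepts JSON only (no YAML parser in the
  supported dependency set).
* Image handling stops at crop geometry; decoding, resizing and
  interpolation belong to the inference stack, not the probability layer.
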