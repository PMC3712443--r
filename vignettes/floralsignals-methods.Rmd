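---
title: "Methods: floral signal convergence from a bee's eye view"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: floral signal convergence from a bee's eye view}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floralsignals)
library(dplyr)
```

## The question the package addresses

Roughly a third of orchid species offer their pollinators no reward. One way
a rewardless flower can still be visited is by resembling a rewarding
species well enough that the pollinator cannot tell the difference — floral
Batesian mimicry. In the Neotropics, several rewardless orchids of subtribe
Oncidiinae carry yellow flowers strikingly similar to those of oil-rewarding
Malpighiaceae shrubs and lianas, and both groups are visited by
oil-collecting bees. Whether that similarity is meaningful has to be judged
through the sensory system of the pollinator, not the human eye.

`floralsignals` implements the quantitative core of such a study as a
reusable pipeline: (i) a trichromatic bee colour-vision model that converts
reflectance spectra into colour loci; (ii) community statistics asking
whether a focal species is chromatically distinct from its co-flowering
community and whether the putative mimicry guild clusters in colour space;
(iii) open-curve eigenshape morphometrics of floral outlines with a
two-group canonical variates analysis; and (iv) parsimony mapping of the
bee-UV-green character on a phylogeny to count independent evolutionary
origins. A synthetic-data module generates spectra, outlines and trees with
known ground truth so that every stage is testable without field data.

## The colour hexagon model

Bees in many lineages are trichromats with UV, blue and green receptors of
broadly conserved spectral sensitivity. For a stimulus with reflectance
$I(\lambda)$ viewed under illuminant photon flux $D(\lambda)$ against an
adaptation background $I_B(\lambda)$, the relative quantum catch of receptor
$i$ with sensitivity $S_i(\lambda)$ is

$$P_i = R_i \sum_{\lambda=300}^{700} I(\lambda)\,S_i(\lambda)\,D(\lambda)\,\Delta\lambda,
\qquad
R_i = \Big(\sum_\lambda I_B(\lambda)\,S_i(\lambda)\,D(\lambda)\,\Delta\lambda\Big)^{-1}.$$

The von Kries factor $R_i$ scales the background to a catch of exactly 1 in
every receptor. Phototransduction saturates as $E_i = P_i/(P_i+1)$, so the
background excites every receptor at 0.5, and the hexagon coordinates

$$x = \tfrac{\sqrt3}{2}(E_G - E_{UV}), \qquad
  y = E_B - \tfrac{E_{UV}+E_G}{2}$$

place the background at the origin and pure single-receptor stimuli at unit
distance. Euclidean distance in $(x, y)$ predicts discriminability;
empirically, free-flying bees reliably discriminate differences above 0.1
hexagon units, and `is_distinguishable()` applies that threshold strictly
(a distance of exactly 0.1 is *not* distinguishable).

### Defaults and why

The study design this package follows does not pin down receptor curves, an
illuminant or an adaptation background, so all three are pluggable and the
defaults are documented:

* **Receptors** — log-normal visual-pigment templates with
  $\lambda_{max} = 344, 436, 544$ nm (honeybee-like trichromat), the
  standard parameterisation when measured sensitivities are unavailable.
  Any tibble of tabulated sensitivities can be substituted.
* **Illuminant** — CIE D65 daylight, shipped as a tabulated energy spectrum
  and converted to relative photon flux (multiplication by $\lambda$),
  since quantum catch counts photons.
* **Background** — a synthetic green-leaf reflectance curve (low UV/blue,
  chlorophyll peak near 550 nm, red edge beginning near 700 nm). It is a
  parametric stand-in, adequate because the background only sets the
  neutral point of the space.

Integration uses the rectangle rule on a 1 nm grid over 300–700 nm — the
stated sensitive range of hymenopteran vision; at this density the
integration error is orders of magnitude below any biological signal.
Because the loci of measured field spectra depend on these choices, the
published headline value of 0.04 hexagon units between mimics and models is
dataset- and parameter-dependent context; the package's tests instead pin
down the model's exact analytic properties (background at the origin,
vertices at norm 1, closed-form transduction, classifier–oracle agreement).

Hue sectors are named for the dominating receptor contributions; sector
centres sit at the blue vertex (0°, measured clockwise from +y), blue-green
(60°), green (120°), UV-green (180°), UV (240°) and UV-blue (300°), with
boundaries at odd multiples of 30°. Within 0.05 units of the origin hue is
considered undefined ("achromatic-center"); this radius affects naming
only, never distances. Human-yellow flowers that combine long-wavelength
and UV reflectance land in the UV-green sector — the focal category of the
mimicry analysis.

## Community colour statistics

**Focal distinctness.** For focal species $f$ in a community of $n$ loci,

$$T = \operatorname{median}_{s \ne f} d(f, s) \;-\;
      \operatorname{median}_{s<s',\; s,s'\ne f} d(s, s'),$$

with midpoint medians throughout. $T$ measures how much farther the focal
species sits from the community than community members sit from one
another. Significance comes from reassigning the focal role: in each of
`n_boot` replicates the focal role is given to a species drawn uniformly
from the non-focal community, the observed focal is set aside, and $T^*$
recomputed; $p$ is the fraction of replicates with $T^* \ge T$.

The choice of null was the one genuinely open design decision here, and we
settled it by measuring calibration on synthetic communities (20 loci
uniform in a 0.1-unit disc, focal exchangeable). Reassignment with the
focal set aside rejects at 0.050 at $\alpha = 0.05$; adding
resample-with-replacement of the non-focal set (available as
`null = "resample"`) is conservative (rejection ≈ 0.02) because duplicated
species inject zero distances into the community median but not the focal
median, inflating $T^*$; permuting the focal label over all species
(`null = "permute"`) floors the attainable p-value near $1/n$ because a
genuinely distinct focal keeps re-entering its own null. The acceptance
suite re-measures calibration and the monotone growth of power with focal
displacement on every run.

**Guild clustering.** The UV-green group test collects all pairwise
distances among UV-green species (sample A) and among the remaining species
(sample B) and applies a one-sided Welch t-test of mean(A) < mean(B).
Pairwise distances are not independent observations, so the test is an
approximation — the result object carries that caveat and reports should
repeat it. Both samples need at least three species: with two, a group
contributes a single pairwise distance and the Welch variance is undefined.

## Eigenshape morphometrics of floral outlines

Outlines are open curves (for orchids, the labellum margin) anchored at two
landmarks. The pipeline is:

1. **Semi-landmarks.** `interpolate_semilandmarks()` places $m$ points at
   equal arc length along the digitised polyline, anchors preserved
   exactly. $m$ defaults to 100; the choice trades resolution against noise
   and is not critical once $m$ exceeds the digitisation density.
2. **Phi functions.** The $m-1$ step directions are unwrapped tangent
   angles; subtracting the anchor-to-anchor chord angle standardises
   rotation (deterministic and anchor-respecting; mean-angle subtraction is
   available as `rotation = "mean"`, and a zero-mean net-deviation variant
   via `zero_mean = TRUE`, both recorded in the output's attributes).
   Equal step lengths remove size; translation never enters. The first
   relative angle is reduced to the principal branch so that rotations
   across the atan2 branch cut change nothing.
3. **Decomposition.** The specimen-by-angle matrix is column-centred and
   decomposed by SVD — algebraically an eigendecomposition of the
   covariance (not correlation) matrix of phi functions. Axes are
   orthonormal modes of shape variation; squared singular values over
   $n-1$ are their variances; scores are projections of centred rows.
4. **Retention.** `retain_axes()` keeps the smallest leading set of axes
   reaching a cumulative variance fraction, conventionally 0.90.
5. **Model proximity.** For each non-Malpighiaceae specimen, the Euclidean
   distance in retained score space to the nearest Malpighiaceae specimen;
   the one-sided Welch contrast asks whether yellow-flowered orchids sit
   closer to the models than other angiosperms do. Outlier exclusion is an
   explicit argument (`exclude`), never automatic.
6. **CVA.** With two groups the canonical variate is the Fisher
   discriminant $w = S_p^{-1}(\bar m_1 - \bar m_2)$ with the cut at the
   projected midpoint. Classification rates are reported under both
   resubstitution and leave-one-out cross-validation, since era-typical
   software did not state which it used; resubstitution is the optimistic
   of the two. If the pooled covariance is singular (retained axes
   approaching specimen count) a small ridge ($10^{-8}$ of the mean
   diagonal) is added and the fit flagged `regularized`.

## Parsimony mapping of the bee-UV-green character

For a binary, unordered character, minimum-change (Fitch) and linear
(Wagner) parsimony coincide. `fitch_parsimony()` implements the Fitch
downpass generalised to polytomies after Hartigan — each state is scored by
how many children carry it; the node keeps the argmax set and the score
grows by (children − max) — treating polytomies as hard, the appropriate
reading for consensus trees. Missing tip states are fully ambiguous.

`count_origins()` runs a Sankoff-style dynamic program over (node, state)
pairs that tracks, among reconstructions achieving the global parsimony
score, the minimum and maximum number of 0→1 transitions. When both root
states are optimal, both are explored and reported per root state. Note a
semantic subtlety: an MPR whose root is already in state 1 counts zero
gains (the derived state is ancestral and subsequently lost), so the
minimum over all MPRs answers "at least how many gains *must* have
happened", which is 0 whenever an all-ancestral reconstruction is equally
parsimonious. The genus-level reading — how many genera contain the derived
state — is a different quantity, computed by `genus_origin_summary()`; the
pipeline reports both and does not adjudicate between them.

## The synthetic world, and what a green test establishes

The generators state the world the tests live in; their defaults were fixed
once, before the tests were run, and are not tuned.

* **Spectra.** Parametric class templates plus Gaussian noise (sd 0.02,
  typical of field spectrometry), clipped to [0, 1]. The
  `bee-uv-green-yellow` class is a sigmoid long-pass (inflection 520 nm,
  i.e. human-yellow) plus a Gaussian UV bump (centre 360 nm) — exactly the
  long-wavelength-plus-UV structure of the mimicry guild. Blue, flat-white,
  UV-absorbing cream (the common bee-blue-green signal), human-red and a
  green-leaf class complete the palette. The default community (3 yellow of
  20, cream/white common) mirrors field surveys in which bee-blue-green is
  the commonest floral colour and the mimicry guild is rare.
* **Outlines.** Graphs of half-period sine series over the unit chord,
  $y(t) = \sum_k a_k \sin(k\pi t)$: anchors stay fixed by construction and
  every draw is a valid open curve. Group means for yellow orchids and
  Malpighiaceae are deliberately close (the convergence the pipeline should
  detect); within-group variation is Gaussian on the coefficients.
* **Trees.** Random topologies with the derived state painted onto planted
  clades (1–3 tips). Disjointness alone does not make the planted count an
  invariant of the most-parsimonious class: two clades whose roots are
  close can be merged by an equally parsimonious reconstruction, and a
  clade root adjacent to the tree root can be absorbed into an ancestral
  derived state. Counting boundary edges of any reconstruction shows that
  a pairwise root separation of at least 6 edges, with every planted root
  at least 2 edges below the tree root, makes any merging or ancestral
  reading strictly less parsimonious — so every MPR carries exactly the
  planted gains, and recovery is a sharp test, not a tendency. A
  rate-based mode (Markov jumps along branches) is available where
  homoplasy is wanted; there parsimony may legitimately undercount the
  recorded true gains.

What the synthetic world does *not* emulate: instrument noise structure and
specular artefacts of real spectra, digitisation error and anatomical
landmark ambiguity of real outlines, and phylogenetic uncertainty (the tree
is known, not estimated). A green suite therefore establishes internal
correctness — the model math, the statistics' calibration, the exactness of
the parsimony counts — not the field conclusions, which depend on data that
are not deposited in recomputable form (the published mimic–model distance
of 0.04 units, the habitat contrasts, the 19/31 retained axes, the 78 % CVA
rate and the "at least 14" origins on the real tree are all of that kind).

## Numerical choices

* Working grid 300–700 nm at 1 nm; linear interpolation; extrapolation
  forbidden. Reflectance in (1, 1.05] is clipped to 1 (white-standard
  noise); above 1.05 it is an error.
* Replicates are averaged as spectra, before the nonlinear transduction, so
  a colour locus is always the image of a single spectrum.
* Medians are midpoint medians; bootstrap p-values are plain fractions of
  replicates; every stochastic function takes a mandatory seed and is
  bit-reproducible given it.
* Eigenvalue/score agreement with an independent eigendecomposition is held
  to 1e-8; similarity invariance of the outline pipeline to 1e-8; sector
  classification ties on exact 30° boundaries go to the
  counter-clockwise sector by convention.

## Limitations

Alternative colour-vision models (receptor-noise limited), tetrachromacy
and achromatic channels are out of scope, as are closed-curve Fourier
outlines, 3-D shape, likelihood ancestral-state reconstruction and tree
inference. The Welch tests on pairwise distances inherit the
non-independence caveat above. Sites are tested separately without
multiple-testing correction, mirroring the reporting style of the study
design this package generalises.
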