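---
title: "Conformalized quantile regression for pixelwise MRI reconstruction uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformalized quantile regression for pixelwise MRI reconstruction uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mriuq)
```

## The problem

Parallel-imaging MRI shortens scans by undersampling k-space; reconstruction
quality degrades as the acceleration factor $R$ grows, and without a
fully-sampled reference there is no way to know *where* a reconstruction is
unreliable. `mriuq` implements a conformalized quantile-regression (QR)
add-on that wraps any reconstruction method and produces pixelwise
uncertainty intervals with a finite-sample coverage guarantee, plus the
evaluation suite needed to ask whether predicted uncertainty actually tracks
true error.

The package is a desk-scale laboratory for the method: it ships a multi-coil
Cartesian simulator so every stage — training, calibration, evaluation — runs
end to end in seconds on a single CPU with no external data.

## The model

Given a reconstruction $x$ and ground truth $y$, two per-pixel offset fields
$s_\ell, s_u \in [0,1]$ (sigmoid outputs) define raw quantile bounds

$$\tilde\ell(x) = x - s_\ell\, x, \qquad \tilde u(x) = x + s_u\, x,$$

so the bounds always bracket $x$ and scale with the image intensity. With
target interval coverage $1-a$ (default $0.90$, so $a = 0.10$), the offsets
are trained with the pinball loss at levels $a/2$ and $1-a/2$:

$$L_\tau(\hat q, y) = \begin{cases} \tau\,(y - \hat q) & y > \hat q \\
(1-\tau)\,(\hat q - y) & \text{otherwise,} \end{cases}$$

summed over the two bounds and averaged over pixels. The pinball loss is
minimized (for a constant predictor) by the empirical $\tau$-quantile, which
is what makes the trained offsets quantile estimates rather than error-scale
heuristics. The residual-magnitude baseline (ResM) instead trains a single
symmetric half-width $s\,x$ by least squares against $|x - y|$.

Trained quantiles are not automatically calibrated. Conformal calibration
rescales the *offsets* by a factor $\lambda$:

$$\tilde\ell_b = x - \lambda\,(x - \tilde\ell), \qquad
  \tilde u_b = x + \lambda\,(\tilde u - x),$$

and chooses the smallest $\lambda$ on a grid such that a conservative upper
bound $\hat R^+(\lambda)$ on the calibration-set miscoverage (the fraction of
pixels whose ground truth falls outside the interval) does not exceed $a$.
The bound adds the one-sided Hoeffding slack
$\sqrt{\log(1/\delta)/(2I)}$ to the empirical risk over $I$ bounded
$[0,1]$ risk variables.

## Design choices that were genuinely open

**Risk aggregation and the Hoeffding bound.** Two readings of "average
fraction of pixels across the calibration set" are implemented:
`per_image` treats each calibration image's miscoverage fraction as one
bounded variable ($I$ = number of images), `pooled` treats the pooled pixel
fraction as the risk ($I$ = number of pixels). The per-image reading is the
default of `calibrate_lambda()`, but it has a hard arithmetic consequence at
small calibration sizes: with $I = 100$ images and $\delta = 0.1$ the slack
is $\sqrt{\ln 10 / 200} \approx 0.107 > a = 0.10$, so *no* $\lambda$ can
satisfy the bound regardless of the data, and calibration is reported
infeasible (flagged, never silent). The packaged coverage experiments
therefore use the pooled reading, whose slack at $100$ slices of $64^2$
pixels is $\approx 0.0017$. With hundreds of calibration volumes both
readings are operative.

**$\delta$.** Not dictated by the calibration procedure itself; the default
$\delta = 0.1$ follows common risk-controlling-prediction-set practice and is
configurable everywhere.

**$\lambda$ grid.** Default $0$ to $4$ in steps of $0.01$. Calibrated QR
scales on the synthetic study land near $1$, and published full-scale values
fall between $1$ and $2$, comfortably interior. Symmetric ResM offsets at
smoke-test sizes can need larger scales, so the comparison experiment uses a
$0$–$8$ grid; the correlation metrics are invariant to $\lambda$, so this
affects only feasibility flags.

**Notation reconciliation.** The pinball levels are written in terms of a
miscoverage $a$ while the coverage target is stated as a percentage; the
configuration stores the coverage (`alpha_coverage = 0.90`) and derives
$a = 1 -$ coverage for losses and calibration, the only reading that yields
90% intervals.

**Boundary handling.** Gaussian blurring (evaluation uses $\sigma = 2$) and
all windowed statistics use half-sample symmetric reflection with kernels
truncated at $4\sigma$; this conserves the image mean exactly, which the
test suite checks to $10^{-6}$.

**Eq.-level conventions.** Hard data consistency (measured lines replace
estimates) in the toy cascade; closed intervals count boundary pixels as
covered; pixels with $x = 0$ have zero-width intervals at every $\lambda$
and are included in the risk by default.

## The offset predictor

The reference architecture for the offset fields at full scale is a deep
convolutional encoder–decoder. `mriuq`'s default trainable predictor is a
*featurized sigmoid-linear model*: fixed per-pixel image features —
intensity, local standard deviation, gradient magnitude, high-frequency
residual, an 11-pixel context mean, aliasing-partner intensities (the image
at FOV/4, FOV/2 and 3FOV/4 shifts along the phase-encode axis, where
Cartesian ghosts land), and nonlinear expansions of these — combined
linearly and passed through a sigmoid, trained by full-batch Adam
(600 iterations, learning rate 0.05 by default; the loss plateau was
verified on the packaged study sizes). The aliasing-partner features matter:
without them the model cannot distinguish a ghost in air from true tissue,
the conditional lower quantile of $y$ is genuinely near zero across a wide
intensity range, and the lower offset saturates. QR mode trains two
independent weight vectors; ResM mode one shared vector (symmetric
intervals). Analytic predictors (arbitrary deterministic functions of $x$)
implement the same contract for tests and closed-form rules.

This predictor is deliberately small and convex; it is not a substitute for
a deep network's capacity, and the limitations section below spells out one
consequence.

## What the simulator emulates — and what it does not

`make_phantom()` draws nested smooth ellipses (a skull-like shell, interior
shells, ventricle-like hypointensities) plus small high-contrast ellipse
anomalies whose geometry is recorded exactly, so region masks are
recoverable in closed form. `make_coil_maps()` builds smooth complex coil
sensitivities normalized so the root sum of squares is exactly 1 at every
pixel — making the noiseless fully-sampled pipeline reproduce the phantom to
float tolerance, an identity the tests rely on. `simulate_kspace()` applies
the orthonormal centred 2-D Fourier transform per coil (so Parseval holds
exactly) and adds i.i.d. complex Gaussian noise in k-space, matching the
acquisition physics; the default `noise_sigma = 0.01` puts pixel-level noise
at a few percent of tissue intensity so that aliasing, not noise, dominates
the heteroscedastic error at $R = 4$ — the regime in which pixelwise
uncertainty is informative. Undersampling keeps `round(acs_fraction *
n_lines)` centred autocalibration lines out of a total budget of
`round(n_lines / R)` and spreads the remainder equispaced (deterministic
phase by default, seedable), reproducing the protocol's stated ACS fractions
and overall accelerations; whether the periphery is equispaced or uniformly
random is not fixed by the protocol, and equispaced is the fixed-mask
default.

Passing tests on this generator show that the *statistical machinery* —
quantile training, conformal calibration, coverage, correlation analysis —
behaves as claimed on data whose ground truth is known exactly. They do not
show anatomical realism, multi-contrast behaviour, scanner noise statistics,
or the performance of any deep reconstruction network; none of those are
claimed.

## Problem sizes in the packaged studies

The coverage study uses 20 repetitions of 20 training + 100 calibration +
100 held-out $64\times 64$ slices at $R = 4$ with 4 coils; the QR-vs-ResM
comparison uses 10 repetitions of 16 + 40 + 20 slices. These sizes give
per-repetition coverage standard errors of a few thousandths while keeping
the full suite comfortably within a coffee break on one CPU; they are the
package's fixed study conditions, not tuning knobs.

## Known limitations

- **ResM can out-correlate QR at this scale.** ResM's offset is an $L_2$
  regression directly onto $|x - y|$; with a convex, well-trained model
  evaluated in distribution it approximates $\mathbb{E}[\,\tilde e \mid
  \text{features}\,]$, which is by construction the Pearson-optimal
  predictor of the error among functions of those features. The QR width
  estimates a different functional (the conditional 5%–95% spread), so in
  this regime it can match but not beat ResM on Pearson correlation — and
  the packaged comparison experiment indeed finds ResM ahead. The
  full-scale reversal reported for deep networks rests on mechanisms this
  laboratory deliberately lacks: a reconstruction network that overfits its
  training set (making ResM's learned residuals smaller than test
  residuals) and deep-net $L_2$ training dynamics. The package reports both
  modes honestly rather than emulating those failure modes.
- Calibrated $\lambda$ values here (near 1 at $R=4$) characterize the
  synthetic study only; values from full-scale trained reconstructions are
  not reproducible at desk scale and are not asserted anywhere.
- The simulator's anomalies are intensity ellipses, not pathologies; claims
  about lesion-conditional uncertainty are limited to "elevated inside
  high-contrast regions".
- The mini-unrolled reconstructor is a fixed-denoiser cascade intended as a
  second Reconstructor-contract implementation, not a competitive
  reconstruction method.

## Reproducing the numbers

```{r, eval = FALSE}
# held-out coverage across 20 seeded repetitions (several minutes on 1 CPU)
res <- coverage_experiment(n_rep = 20, seed = 1)
summary(res$coverage)

# QR vs ResM blurred Pearson correlation, 10 repetitions
cmp <- qr_vs_resm_experiment(n_rep = 10, seed = 1)
colMeans(cmp[, c("pearson_qr", "pearson_resm")])
```

The same computations back `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`; the README shows a single worked pipeline run with
its printed output.
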