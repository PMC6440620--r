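---
title: "Methods: small SE-ResNet networks, the Gauss error scheduler, and the synthetic histology testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small SE-ResNet networks, the Gauss error scheduler, and the synthetic histology testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhcnet)
```

## The problem

Benign/malignant classification of breast-tumor histopathology images is a
small-data problem: labeled whole-slide collections hold a few thousand
images, so deep networks overfit unless the parameter count is kept low, and
final accuracy is sensitive to the learning-rate schedule. `bhcnet`
implements the two ideas this package is organized around — a *small*
squeeze-and-excitation residual module that cuts convolution weights by a
third, and a closed-form learning-rate schedule shaped by the Gaussian error
function — together with everything needed to exercise them end to end on a
CPU: architecture builders with analytic parameter audits, Nesterov-momentum
SGD, multiclass evaluation metrics, and a deterministic synthetic image
generator that emulates the BreakHis directory layout and census.

## The SE-ResNet module

A module receives an input $X_0$ with $C_{in}$ channels and computes a
convolutional branch, an attention gate over the branch's channels, and a
residual sum. The branch applies, per convolution, pre-activation ordering —
batch normalization, then ReLU, then the (bias-free) convolution — in one of
three layouts at width $C$:

| kind       | branch convolutions                                   | conv weights |
|------------|--------------------------------------------------------|-------------|
| basic      | $3{\times}3, C$ — $3{\times}3, C$                      | $18C^2$     |
| bottleneck | $1{\times}1, C$ — $3{\times}3, C$ — $1{\times}1, 4C$   | $17C^2$     |
| small      | $1{\times}3, C$ — $3{\times}1, C$ — $1{\times}3, C$ — $3{\times}1, C$ | $12C^2$ |

The *small* layout factorizes each $3\times3$ kernel into a $1\times3$ /
$3\times1$ pair, which preserves the receptive field while dropping the
equal-width weight count by $100(1 - 12/17) = 29.4\%$ versus the bottleneck
module and $100(1 - 12/18) = 33.3\%$ versus the basic module — ratios of
$C^2$ terms, hence width-independent. `module_conv_params()` returns the
closed forms; `audit_network()` proves them against the weight arrays of any
built network and itemizes everything the closed forms deliberately exclude
(SE gates, normalization, shortcut projections, the classifier).

The gate is the squeeze-and-excitation block. With branch output $O$
($C$ channels, $H\times W$ spatial):

* **squeeze**: $s_c = \frac{1}{HW}\sum_{i,j} o_c(i,j)$ (global average
  pooling) — `squeeze()`;
* **excitation**: $\tilde S = \sigma(W_2\,\delta(W_1 S))$ with two bias-free
  fully connected layers, $W_1 \in \mathbb{R}^{\bar C\times C}$,
  $W_2 \in \mathbb{R}^{C\times\bar C}$, ReLU $\delta$, sigmoid $\sigma$, and
  bottleneck width $\bar C = \max(1, \lfloor C/r\rfloor)$ at reduction ratio
  $r = 16$ — `excitation()`;
* **recalibration**: $\tilde o_c = \tilde s_c \, o_c$ — `recalibrate()`;
* **residual sum**: $\tilde X = X_0 + \tilde O$ — `residual_combine()`.

Because $\partial \tilde X / \partial X_0 = 1 + \partial \tilde O /
\partial X_0$, the shortcut keeps gradients from vanishing through deep
stacks; the test suite verifies this identity by finite differences on
identity-shortcut modules.

Design points that the source material left open, decided here once:

* **Pre-activation ordering** (BN → ReLU → conv) throughout, with the SE
  block after the last convolution and before the residual sum. No
  activation after the sum.
* **Shortcut**: identity when shapes match; otherwise a $1\times1$
  stride-matched projection convolution followed by batch normalization.
  Downsampling stride sits on the first branch convolution.
* **"Same" zero padding** of $\lfloor k/2\rfloor$ per side, so spatial size
  is preserved at stride 1 and halved (ceiling) at stride 2.
* **No convolution or gate biases**; normalization carries the shifts.
* $\bar C$ **floors at 1** so narrow widths (16 with $r=16$) stay valid.

Every module kind is validated against `reference_forward()`, an
explicit-loop re-implementation (direct convolution sums, scalar BN, two-loop
matrix-vector gate) that shares no numerical code with the fast im2col path;
analytic gradients are validated against central finite differences at the
module and whole-network level.

## Architectures

`se_resnet_spec(variant)` builds the 32×32-input family: a single
$3\times3$, 64, stride-1 stem (no initial max pooling — the large-image stem
of the original residual-network recipe is inappropriate at this input
size), four stages at widths 64/128/256/512 with downsampling entering
stages 2–4, global average pooling, and one softmax classifier layer.
Variants 18 (basic), 26 (bottleneck) and 34 (small) stack 2 modules per
stage; 50 (bottleneck) and 66 (small) stack (3, 4, 6, 3).

`bhcnet_spec(N)` is the histopathology network: one plain stem convolution,
three blocks of $N$ small modules, pooling, softmax. The channel ladder
16/32/64 is the smallest standard ladder whose audited totals fall inside
the published windows: BHCNet-3 audits at **193,906** trainable parameters
(published ≈ 198K) and BHCNet-6 at **392,146** (published ≈ 401K); the gap
reflects an unknown counting convention in the published totals, so the
tests assert windows rather than exact equality. SE-ResNet-18 audits at
11,261,002, within 0.1% of the published 11,272K. For inputs of 64 px or
more the stem switches to stride 2 plus a 2×2 stride-2 max pool to keep
activation maps tractable.

One exactness caveat the audit exposed: stacking twice as many modules per
block does *not* exactly double the block convolution weights, because each
block's first module carries the width transition (its first convolution has
`in_channels` equal to the previous width) and a projection shortcut. The
law that is exact, and that the tests assert, is the increment: every module
added beyond the first $N$ contributes exactly $12C^2$ weights per block.

Weights initialize He-style (normal, variance $2/\mathrm{fan}_{in}$),
normalization at unit gain/zero shift, so `build_network(spec, seed)` is
reproducible bit for bit.

## Learning-rate schedules

All schedules are per-epoch closed forms, 1-based, computed once at the top
of each epoch (the optimizer never changes the rate mid-epoch).

The **Gauss error scheduler** is
$$\varepsilon(e) = lr_{min} + \tfrac{lr_{max}-lr_{min}}{2}
  \left(1-\operatorname{erf}\!\left(\tfrac{e(\beta-\alpha)}{E}+\alpha\right)\right),
  \qquad e \in (0, E],$$
with $\alpha$ a negative and $\beta$ a positive integer. $|\alpha|$ sets how
long training holds near $lr_{max}$, $\beta$ how long it holds near
$lr_{min}$, and $|\alpha|/|\beta|$ the decay steepness; recommended defaults
are $\alpha=-3, \beta=3$ (with $\alpha=-4,\beta=4$ an alternative for the
40× binary task). $lr_{min}$ must be strictly positive — the schedule is
designed never to approach zero, where gradient noise dominates — so a zero
$lr_{min}$ is rejected for this scheduler (but allowed for cosine, whose
published default is 0). Because the error function is odd, $\beta=-\alpha$
gives the exact symmetry $\varepsilon(e)+\varepsilon(E-e) =
lr_{max}+lr_{min}$, which the tests check to machine precision, and the rate
is strictly inside $(lr_{min}, lr_{max})$ and non-increasing. `erf_value()`
evaluates the error function through the normal CDF and is tested against
direct quadrature of its defining integral to $10^{-10}$.

Comparators: **step** (a changepoint's rate applies from the *following*
epoch, the literal reading of "divide after the $k$-th epoch"); **step-R**,
which derives its two drop epochs from one ratio $R$ via
$E_2=\lfloor E/(1+R)\rfloor$, $E_1=\lfloor R E_2\rfloor$ (at $R=0.3$,
$E=200$: drops at 45 and 153) with division by 10 and initial rate 0.1 fixed
by construction; **cosine**, implemented by default with the printed
amplitude $(lr_{max}+lr_{min})/2$ and optionally with the conventional
annealing amplitude $(lr_{max}-lr_{min})/2$ — the two coincide at
$lr_{min}=0$, the only setting used in practice; and **exponential**,
$lr_0\lambda^e$.

## Optimization

`nesterov_step()` implements Nesterov-momentum SGD exactly as the classical
per-epoch loop: interim point $\tilde\theta = \theta + m v$, gradient $g$ at
$\tilde\theta$, velocity $v \leftarrow m v - \varepsilon g$, update
$\theta \leftarrow \theta + v$. Weight decay ($10^{-4}$ by default) enters
as a coupled L2 term added to the gradient at the interim point, and is
applied to all trainable parameters (convolutions, gates, normalization,
classifier) — the classical formulation, chosen over decoupled or
selectively-applied decay for fidelity to the stated algorithm. With $m=0$
the step reduces algebraically to plain SGD. The training loss is
categorical cross-entropy over softmax outputs (the softmax head is stated;
the loss is the standard choice for it). Defaults mirror the published
protocol: batch 20, momentum 0.9, decay $10^{-4}$, 300 epochs, three
repeats with consecutive seeds summarized as mean ± sd.

## Evaluation

`evaluate_network()` reports the confusion matrix (rows = true class),
accuracy, per-class and macro precision/recall/F-measure, the Matthews
correlation coefficient, and macro one-vs-rest AUC from predicted
probabilities (rank-statistic form, midranks for ties). Conventions for
degenerate inputs, fixed once: an empty predicted or true class contributes
precision/recall 0; MCC is 0 whenever a marginal is zero (e.g. an
all-one-class predictor); AUC is `NA` when no class has both positives and
negatives. Multiclass MCC uses the standard multi-category generalization
over the full confusion matrix, which reduces to the classical
TP/TN/FP/FN formula at $K=2$; the tests prove both equivalences against
from-definition oracles on hundreds of random matrices. Which probability
scale or multiclass AUC scheme produced the published AUC tables is
unstated; macro one-vs-rest on probabilities is used here and labelled as
such.

## The synthetic testbed

No histology images ship with the package. `generate_synthetic_breakhis()`
writes a dataset in the community BreakHis layout
(`class/subtype/patient/<mag>X/SOB_<B|M>_<subtype>-<patient>-<mag>-<idx>.png`)
whose default census is the published 8-subtype × 4-magnification table
(7,909 images; 2,480 benign / 5,429 malignant; 1,995 / 2,081 / 2,013 / 1,820
per magnification). Images are rendered as Gaussian random fields smoothed
by a subtype-specific correlation length around a class tint: benign
subtypes get long correlation lengths (smooth blob-like texture, smoothing
σ 4–7 px) and moderate amplitude; malignant subtypes get near-white-noise
speckle (σ 0.6–1.1 px) at higher amplitude. The generator *promises* a
separation of at least 500 (8-bit pixel-variance units) between the
class-mean per-image pixel variances, and the tests measure that promise
post hoc on 100 images per class. Everything is drawn from one seeded RNG
stream, so equal specs produce byte-identical PNG files.

What the generator emulates: the directory/filename dialect, the census and
its class imbalance, magnification stratification, deterministic
regeneration, and a texture contrast learnable by a small CNN. What it does
not emulate: stains and their variability, cellular morphology, patient-level
correlation (images of one synthetic "patient" are i.i.d.), or any
magnification-dependent content. A green learnability test therefore
establishes that the pipeline — generation, indexing, splitting,
preprocessing, training, evaluation — is correct and that the network can
exploit texture statistics; it says nothing about accuracy on real
histology.

Default image size is 64 px (tests use 16–32 px); the reference collection's
700×460 is supported but pointless for synthetic textures. Splits are random
*by image* within each magnification, stratified by label — stratification
is a choice (the protocol says only "randomly divided") that protects
small-scale runs from degenerate class imbalance; patient-level leakage
control is deliberately *not* applied, matching the image-level protocol
being emulated. Preprocessing is bilinear down-sampling plus per-channel
standardization with statistics computed on the training split only
("zero-mean normalization" is stated; the unit-variance division, with the
standard deviation floored at $10^{-6}$, is a documented choice).
Augmentation is the stated recipe: integer shifts up to 12.5% of each
dimension with constant fill (fill value 0, i.e. the post-standardization
mean — whether the original used 0 or an edge value is unstated) and
horizontal flips with probability 1/2.

## Numerical choices and limitations

* Batch normalization uses $\epsilon = 10^{-5}$, biased batch variance, and
  running statistics with momentum 0.9 (evaluation mode uses the running
  values). A variance of exactly zero is floored at 0 before the epsilon.
* The SE gate is mathematically strictly inside $(0,1)$, but in double
  precision `sigmoid(z)` rounds to 1.0 for $z \gtrsim 37$; the openness
  invariant is asserted at realistic activation scales only.
* The erf primitive is exact to machine precision (normal CDF); quadrature
  is used only as the independent oracle.
* Max pooling routes gradients to the first arg-max on ties.
* The smoke learnability check (BHCNet, $N=1$, 32×32, 200/100 images,
  20 epochs) trains *without* augmentation — the 20-epoch desk-scale budget
  is too short for augmentation to pay off, and the published protocol ties
  augmentation to 300-epoch training; it uses the published binary-task
  scheduler settings (ERF(−3, 3), $lr_{max}=0.01$, $lr_{min}=10^{-4}$)
  compressed to $E=20$. Observed behavior: all three seeds reach ≥ 99% test
  accuracy in roughly a minute each on one CPU.
* Full-scale reproduction of the published Cifar/BreakHis accuracy tables is
  out of scope: it requires the external datasets and GPU-scale training.
  The package's claims are the property-based ones its tests compute.

## Reproducibility

Every stochastic entry point (`build_network`, `split_index`,
`synthetic_spec`, `train_config`) takes an explicit seed and restores the
caller's RNG state afterwards. The CLI (`generate-data`, `schedule`,
`train`, `evaluate`, `count-params`) writes a manifest with every seed and
setting next to its outputs, so any artifact can be regenerated from its
config alone.
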