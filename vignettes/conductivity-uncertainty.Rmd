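---
title: "Conductivity uncertainty in EEG dipole reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conductivity uncertainty in EEG dipole reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eeguq)
```

## The problem

EEG source analysis infers the location, orientation and strength of
neural current sources from scalp potentials. The forward model that maps
a current dipole to electrode potentials depends on the electrical
conductivities of the head tissues — skin, skull, cerebrospinal fluid
(CSF), gray and white matter — and these are only known as literature
ranges, not as per-subject values. `eeguq` quantifies how that
uncertainty propagates into single-dipole reconstructions of a focal
source such as the somatosensory P20/N20 component: how much the
reconstructed depth, orientation, strength and goodness of fit move when
the conductivities are drawn from their priors.

The pipeline has four layers:

1. a **forward model**: an analytic multilayer concentric-sphere volume
   conductor and leadfield assembly;
2. an **inverse method**: goal-function scans (GFS) in fixed, rotating and
   moving variants;
3. a **surrogate**: a generalized polynomial chaos (gPC) expansion of the
   leadfield over the uncertain conductivities, fitted on Smolyak
   sparse-grid collocation nodes, with Sobol sensitivity indices read off
   the coefficients;
4. an **experiment layer** that samples the priors, scans each sampled
   leadfield, and summarises the distributions of the reconstruction
   parameters.

## Forward model

The head is modelled as nested concentric spherical shells, each with a
homogeneous isotropic conductivity. For spherical-harmonic degree $n$ the
potential in shell $j$ is

$$V_j(r) = A_j\,(r/r_j)^n + B_j\,(r_{j-1}/r)^{n+1} + V_p(r)\,[j = s],$$

where $V_p$ is the infinite-medium (primary) dipole potential expanded
about the origin and $s$ is the shell containing the source. The
coefficients solve, per degree, a small linear system expressing
continuity of potential and radial current density at every interface,
regularity at the origin, and a vanishing radial current at the scalp
(insulating exterior). The per-shell scaling of the radial basis keeps
every matrix entry of order one, so the systems remain well conditioned
up to degree 200. The series is truncated adaptively: degrees are added
until the relative contribution stays below `rtol` (default $10^{-8}$)
for three consecutive degrees; non-convergence at `n_max` raises an error
that names the achieved residual.

Two closed forms anchor the implementation and are enforced in the test
suite: a model with equal conductivities in every shell must reproduce
the homogeneous-sphere solution, and a central dipole in a homogeneous
sphere of radius $R$ and conductivity $\sigma$ must give the surface
potential $3\,(\mathbf{q}\cdot\hat{\mathbf{e}})/(4\pi\sigma R^2)$.

Leadfields are electrodes $\times$ (3 $\times$ sources) gain matrices:
column $3(k-1)+a$ holds the average-referenced potentials of a unit
dipole along axis $a$ at source $k$. The average reference is the
canonical reference for all stored leadfields and measurements; the
goodness of fit is only comparable when measurement and gain share one
reference, and the average reference is the idempotent choice.

The forward model is a pluggable provider: anything that produces a
leadfield for a conductivity set satisfies the downstream contract. The
sphere solver is the shipped implementation; a realistic
finite-element model would slot into the same interface.

### Default geometry

Shell boundaries sit at 70, 78, 80, 86 and 92 mm (white matter, gray
matter, CSF, skull, skin). These are conventional placeholder radii — the
package's choice, not measurements — and are configurable. The standard
conductivities and their uniform priors are (mS/m):

| tissue | lower | upper | standard |
|--------|------:|------:|---------:|
| skin   | 280.0 | 870.0 | 430.0 |
| skull  |   1.6 |  33.0 |  10.0 |
| csf    | 1769.6 | 1810.4 | 1790.0 |
| gm     | 220.0 | 670.0 | 330.0 |
| wm     |  90.0 | 290.0 | 140.0 |

All internal units are SI (m, S/m, V, A·m); millimetres and mS/m appear
only at file and configuration boundaries.

## Goal-function scans

For a referenced measurement $u$ and the $n\times 3$ gain block $L(x_i)$
of candidate position $x_i$, the goodness of fit is

$$\mathrm{GoF}(x_i) = 1 - \left(\frac{\lVert u - L L^{+} u\rVert_2}
{\lVert u\rVert_2}\right)^{2},$$

with $L^{+}$ the Moore–Penrose pseudoinverse (SVD, relative cutoff
$10^{-10}\sigma_{\max}$, so rank-deficient blocks of near-silent sources
cannot crash a scan). The three variants free successive degrees of
freedom: **fixed** (position and orientation fixed, strength free — a
single gain column), **rotating** (position fixed, orientation and
strength free — the full 3-column block), **moving** (everything free —
the argmax of GoF over the source space). Nesting implies
$\mathrm{GoF}_{\mathrm{fixed}} \le \mathrm{GoF}_{\mathrm{rotating}} \le
\mathrm{GoF}_{\mathrm{moving}}$, which the suite checks on random
measurements. Exact ties (GoF within $10^{-12}$ of the maximum) break to
the lowest index with a warning; the choice is arbitrary and therefore
logged.

Orientation changes are reported in an orthonormal frame built by
Gram–Schmidt from, in order, the reference reconstruction's orientation
($e_1$), the radial direction toward the inner skull ($e_2$; $+\hat r$ in
a sphere), and a configured interhemispheric-fissure direction ($e_3$,
default $+y$ — a sphere has no anatomy, so this must be explicit).
Elevation $\vartheta = \arcsin(\hat m\cdot e_2)$ grows as the source
turns more radial; azimuth $\varphi = \mathrm{atan2}(\hat m\cdot e_3,
\hat m\cdot e_1)$ is positive toward the fissure. Source depth is the
distance to the inner-skull surface (the CSF shell's outer radius).
Because no single scalar combining $\varphi$ and $\vartheta$ is uniquely
defined, the package reports both angles (plus the moment itself) and
leaves any aggregation to the user.

### Source spaces

The study design is two-step: a coarse lattice over the whole brain
(default spacing 8 mm) is scanned once with standard conductivities to
fix the reference position, orientation and frame; a fine cubic grid
(default: total extent 16 mm per axis at 4 mm spacing, a $5^3 = 125$-node
lattice) is then centred on that reference and reused for every sampled
scan. At the full study scale the fine grid would be $21^3 = 9{,}261$
nodes (30 mm at 1.5 mm); the desk-scale default keeps a full suite run in
minutes on one CPU while preserving the mechanism. Grid positions are
masked to the gray- and white-matter shells and to at least 2 mm below
the brain/CSF boundary (`min_csf_distance`, configurable): close to that
interface the conductivity jump degrades forward accuracy, and the
masking floor also produces the depth floor visible when very low skull
conductivities push sources as superficial as permitted. Positions
exactly on a shell boundary belong to the inner shell, so tissue
assignment is deterministic.

## Polynomial chaos surrogate

A moving scan over $K$ grid nodes needs a fresh leadfield for every
sampled conductivity set; at thousands of samples per experiment that is
the dominant cost, which is why the leadfield is replaced by a
vector-valued gPC surrogate. Uncertain conductivities are mapped
affinely to $\xi \in [-1,1]^d$ and the flattened leadfield is expanded in
the **orthonormal** Legendre tensor basis of total degree $\le 4$
($\binom{d+4}{4}$ terms; 70 for $d = 4$). Orthonormality (not mere
orthogonality) is deliberate: it makes the variance decomposition a plain
sum of squared coefficients.

Collocation nodes come from a Smolyak combination of 1-D Gauss–Legendre
rules with linear growth ($\ell$-point rule at level $\ell$) at level
$L = d + p$. This is the minimum level whose sparse rule integrates all
polynomials of total degree $2(L-d)+1 = 9 \ge 2p$ exactly — sufficient
for the degree-4 pseudo-spectral projection — and the suite verifies that
exactness by integrating random monomials in $d = 1, 2, 4$. In one
dimension the construction reduces to the plain 5-point Gauss–Legendre
rule. The full design (five univariate expansions plus the four-variate
skin/skull/gm/wm expansion, CSF dropped from the joint prior because its
$\pm 1.1\%$ interval is negligible) needs $5\times 5 + 385 = 410$
distinct conductivity sets, inside the 500-leadfield budget the study
design allows; `forward_evaluation_budget()` recomputes this count by
enumerating and deduplicating the node sets.

### Projection versus regression

`fit_pce()` defaults to pseudo-spectral projection,
$c_\alpha = \sum_k w_k f(\xi_k)\Psi_\alpha(\xi_k)$. For the leadfield
itself, however, `build_leadfield_pce()` fits by unweighted least squares
on the same nodes. The reason is empirical and specific to the skull:
near the lower skull-conductivity bound the leadfield amplitude varies
steeply, and the function's content beyond degree 4 aliases into the
retained coefficients under the quadrature rule, inflating the magnitude
error of the surrogate near that edge; least squares on the same
well-conditioned node set (385 nodes for 70 basis terms in $d=4$) roughly
halves the worst-case magnitude error on the default scenario. The two
fits coincide on any truth that is itself a polynomial of total degree
$\le 4$ — a property the suite asserts for both methods — so the choice
only affects how super-degree-4 content is handled. Surrogate quality is
always validated against the exact forward with the 10-draw RDM/lnMAG
protocol (`validate_surrogate()`), comparing per source position and
unit-moment direction; `analysis/02_surrogates.R` prints the realised
maxima. Evaluation outside the prior box is refused — the surrogate never
extrapolates.

### Sobol indices

With orthonormal coefficients, the variance of an output is
$\mathbb{V} = \sum_{\alpha \ne 0} c_\alpha^2$ and the conditional
variance of a variable subset is the sum over multi-indices supported
exactly on that subset; the Sobol index is their ratio
$S(i,\dots,j) = \mathbb{V}(i,\dots,j)/\mathbb{V}$. Summed over all
non-empty subsets the indices are exactly 1. Outputs whose variance is
zero up to roundoff (e.g. silent electrodes) are flagged and excluded
from ratios rather than divided. The suite cross-checks the
coefficient-based indices on analytic functions (where
$S_1 = S_2 = 3/7$, $S_{12} = 1/7$ is known exactly) and against an
independent Saltelli-type Monte Carlo estimator within three Monte Carlo
standard errors; a Parseval check ties the coefficient sum to the
sampled surrogate variance. Per-electrode sensitivity reports derive the
potential expansion of the fixed reference dipole linearly from the
leadfield coefficients, then report first- and second-order indices, the
residual to 100%, and the per-electrode standard deviation over sampled
potentials.

## Synthetic scenario

The generator supplies every input the analysis needs, so the pipeline
runs with no external data:

- **Electrodes**: 70 sensors (a 74-channel cap minus four excluded
  channels) on the upper hemisphere, Fibonacci-lattice spacing, labels
  `E001…E070`; the seed only rotates the layout about the vertical axis.
- **Truth dipole**: gray-matter shell at 8 mm depth below the inner
  skull, 10 nAm, oriented mostly tangentially with a small radial
  component — scenario defaults chosen as a plausible superficial
  somatosensory source, not subject-specific facts.
- **Measurement**: the average-referenced forward solution plus i.i.d.
  Gaussian channel noise with variance $\overline{u^2}/\mathrm{SNR}$,
  target SNR 7.5. The original SNR definition is a temporal power ratio
  (peak power over prestimulus power); with no time axis here it is
  reinterpreted as mean squared signal over noise variance across
  channels, preserving the single number the analysis conditions on.
  With `snr = Inf` the measurement equals the noiseless forward bitwise.

What the generator does **not** emulate: realistic head geometry (gyri,
skull thickness variation, anisotropy), correlated sensor noise,
artifacts, or a time dimension. Passing tests therefore demonstrate the
correctness of the machinery and the qualitative direction of
conductivity effects in a layered conductor — not quantitative agreement
with any subject's data. Subject-specific magnitudes (specific Sobol
percentages, millimetre depth shifts, best-fit conductivity values) are
expected to differ from any real-data study.

## Experiments and their defaults

`run_univariate()` and `run_multivariate()` draw $n$ conductivity sets
(study scale $n = 10{,}000$; the analysis scripts default to 2,000 and
the acceptance checks use the sizes they state), evaluate the surrogate
leadfield per sample, and run all three scan variants — fixed and
rotating at the reference node, moving over the fine grid. One master
seed drives everything; per-stage child seeds are derived
deterministically, so identical configuration and seed give bit-identical
experiment tables. Summaries mirror the study's headline analyses:
`best_fit()` (maximal moving-scan GoF and its conductivity set),
`depth_surface()` (binned median depth over the skin × skull plane with
isoline-ready CSV export), and `sensitivity_report()`.

On the default scenario the suite asserts the directional findings with
rank correlations: higher skull conductivity pulls the reconstructed
source deeper and lowers the fixed-scan strength; higher skin
conductivity does the opposite on both counts; the CSF interval moves the
depth by at most one grid spacing. One direction deliberately not
asserted: in this spherical geometry the fixed-scan strength *rises*
with white-matter conductivity, whereas the realistic-geometry study
reports the inverse — with the source in a thin spherical gray-matter
shell directly above the white-matter sphere, the volume-conduction path
differs qualitatively from a folded cortex.

## Numerical choices, degenerate inputs, limitations

- Series truncation: relative tolerance $10^{-8}$, `n_max` 200; the
  batched and per-dipole paths truncate independently and agree to the
  series tolerance, not bitwise.
- Pseudoinverse cutoff: $10^{-10}$ relative to the largest singular
  value.
- Degenerate prior intervals (lower = upper) cannot be mapped to the
  Legendre domain and are refused with a clear error naming the tissue;
  the near-degenerate CSF interval exercises the zero-variance path.
- Zero measurements make the GoF undefined and error; zero moments have
  undefined orientation angles and error; a zero-variance output
  requested as a Sobol ratio errors unless flagged.
- Electrode files are projected to the scalp sphere on read, warning
  beyond 2 mm displacement.
- Serialization is plain text (TSV matrices plus JSON metadata) behind
  `write_leadfield()`/`read_leadfield()` and `write_pce()`/`read_pce()`.
- Problem sizes: the default suite uses the 125-node fine lattice
  (84 retained after masking on the default scenario), 70 electrodes,
  2,000-sample experiments, and the 410-node surrogate design.

Known limitations: no realistic geometry or anisotropy, no MEG, no
multi-dipole or distributed inverse methods, single-topography (no
time-resolved) measurements, uniform priors only, and no adaptive or
anisotropic sparse grids. These are boundaries of scope, not of the
interfaces: the leadfield-provider contract is the intended extension
point.
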