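---
title: "Methods: 3D reconstruction and spatial screening of RNA tomography data"
author: "tomo3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D reconstruction and spatial screening of RNA tomography data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomo3d)
```

## The measurement this package models

RNA tomography (tomo-seq) profiles a specimen by cutting three *separate*
specimens along three orthogonal planes — transverse, horizontal and
sagittal — sequencing the RNA of every cryosection, and computationally
merging the three 1D read-count series into a 3D "digital expression" model.
Each voxel of the model is the intersection of one section from each plane;
at the 18 µm section thickness this package defaults to, a voxel is an 18 µm
cube. The approach trades cellular resolution for genome-wide coverage and a
robust, imaging-free protocol, and suits large embryos and organs where a
few tens of sections per axis cover the tissue.

The pipeline implemented here starts at the per-plane count tables
(genes × sections, with ERCC spike-in rows) and ends at ranked gene lists:

1. **Detection and normalization** (`detectExpressed()`,
   `normalizeBySpikein()`) — a gene is considered detected in a plane when
   at least 4 reads occur in at least 2 sections, evaluated before
   normalization; each section's counts are divided by the section's total
   spike-in reads.
2. **Reconstruction** (`digitizeMask()`, `reconstructAll()`) — iterative
   proportional fitting (IPF) of each gene's three 1D profiles onto a
   digitized binary volume mask.
3. **Screening** (`screenRegionalized()`, `coexpressionRanking()`) —
   Moran's spatial autocorrelation over a 3×3×3 voxel neighborhood to find
   regionalized genes, and all-pairs Pearson correlation over voxels to
   find co-expressed genes.

A synthetic phantom generator (`makeDataset()`) stands in for real section
series so every stage is testable offline against a known ground truth.

## Spike-in normalization

Sections differ in capture and amplification efficiency. With a fixed
spike-in input per section, a section's total spike-in reads estimate its
efficiency, so

$$v(g, s) = \frac{c(g, s)}{\sum_k \mathrm{spike}(k, s)} \cdot \bar{S},$$

where $\bar S$ is the plane's mean spike-in total. The rescale by $\bar S$
keeps normalized magnitudes comparable to raw counts; it is a plane-level
constant and does not change any within-plane shape. Note the consequence:
the per-section *ratios* are exactly invariant to arbitrary positive
per-section efficiencies, while absolute normalized values carry a factor
of the plane's mean efficiency through $\bar S$. All downstream statistics
(IPF after total harmonization, Moran's I, Pearson correlation) are
invariant to that plane-level factor.

Sections whose spike-in total is zero are set to *missing*, never to zero —
a zero would fabricate an expression trough. A plane with more than 20% such
sections is rejected. When a declared input amount is available the recovery
ratio (observed spike-in reads / declared input, summed over the plane) is
reported as QC.

## Harmonizing plane totals

The three section series come from three different specimens, so one gene's
total normalized expression differs between planes. IPF requires a single
target mass. Each plane's profile is rescaled to the *arithmetic mean* of
the positive plane totals. The geometric mean was considered and rejected:
it collapses to zero whenever one plane total is zero, which happens
routinely for weakly expressed genes, while the arithmetic mean degrades
gracefully (zero-total planes are flagged and excluded from the fit).

## Iterative proportional fitting

For gene $g$ with harmonized per-plane profiles $m_p(s)$, the field $x_v$ is
initialized to 1 on in-mask voxels and 0 outside (the maximum-entropy
start), then cycles over the planes in fixed order (transverse, horizontal,
sagittal) apply, for every section $s$ of plane $p$ with current slab sum
$M_p(s) = \sum_{v \in \mathrm{slab}(p,s)} x_v$:

$$x_v \leftarrow x_v \cdot \frac{m_p(s)}{M_p(s)} \quad (v \in \mathrm{slab}(p, s)).$$

Numerical choices, all surfaced as arguments:

* **Stopping rule** — iteration stops when
  $\max_{p,s} |M_p(s) - m_p(s)| / T < \texttt{tol}$ (with $T$ the common
  total), default `tol = 1e-6`, capped at `maxIter = 200` cycles. On
  noise-free, mutually consistent profiles convergence takes a handful of
  cycles; on noisy profiles the three marginals are mutually inconsistent
  and the discrepancy plateaus at the noise level, so the cap matters and
  the final discrepancy is reported per gene in the convergence slot.
* **Zeros** — a zero target ($m_p(s) = 0$) zeroes its slab permanently; the
  supports of the three profiles intersect multiplicatively. A positive
  target over a slab whose current mass is zero cannot be satisfied; it is
  recorded as an *infeasibility event* and left at zero rather than raising,
  because non-identical replicate specimens make such conflicts expected in
  real data.
* **Missing sections** — excluded from both the update and the convergence
  check; their slab values are then driven entirely by the other two
  planes.
* **Order dependence** — the plane order is fixed for reproducibility; on
  feasible inputs the converged solution is insensitive to it (the test
  suite bounds the effect at 100·tol).

Two exactness properties anchor the implementation: on a full cuboid with a
separable truth $f \otimes g \otimes h$, IPF from a uniform start recovers
the truth to machine precision (the independence solution is exact); and on
any feasible input the converged marginals reproduce the harmonized
profiles to `tol`.

A structural caveat of the method, not of the implementation: IPF returns a
*product-form* field consistent with the three marginals. Voxel-scale
dispersed ("salt-and-pepper") truths have nearly flat marginals, so their
reconstructions are smooth separable fields whose voxel-to-voxel
fluctuations are coupled along axes. Autocorrelation measured on such a
reconstruction reflects the product structure, not the truth. For this
reason the class-separation validation of the Moran screen (below) is run
on models built directly from ground-truth fields (`truthModel()`), which
is what the statistic itself claims to discriminate. Real single-cell-scale
patterns live far below section resolution and average to flat profiles,
landing in the low-index, high-p region.

## Moran's I over the voxel neighborhood

For field values $x_i$ on the $N$ in-mask voxels and binary weights
$w_{ij} = 1$ when voxel $j$ lies in the 3×3×3 cube centred on voxel $i$
(both in-mask, $i \neq j$):

$$I = \frac{N}{W} \cdot
\frac{\sum_{ij} w_{ij} (x_i - \bar x)(x_j - \bar x)}
     {\sum_i (x_i - \bar x)^2}, \qquad W = \sum_{ij} w_{ij}.$$

Regionalized genes concentrate similar values in neighboring voxels and
score high; under spatial randomness $E[I] = -1/(N-1) \approx 0$. Constant
fields (ubiquitous expression, or all-zero genes) have no defined index and
are reported as *unscreenable* rather than silently dropped.

Inference options:

* **Analytic (default)** — one-sided upper-tail p-value from
  $z = (I - E[I]) / \sqrt{\mathrm{Var}[I]}$ with the Cliff–Ord variance
  under the randomization assumption (moments of $I$ over all permutations
  of the observed values; uses $S_1$, $S_2$, $W$ and the sample kurtosis).
  This matches the permutation distribution's mean and variance exactly and
  is the only practical choice at genome scale.
* **Permutation** — Monte-Carlo p over random relabelings of in-mask
  values, used for validation: the analytic p agrees with a
  20,000-permutation p within Monte-Carlo error on smooth fields, and
  analytic p-values of permuted fields are uniform (KS-tested in the
  acceptance suite).

The screen's default pass rule is the one in standard use for this assay:
$I > 0.1$ together with a p-value that underflows double precision
("p-value = 0"; equivalently $-\ln p = \infty$). With $N \sim 10^4$ voxels
the randomization standard deviation of $I$ is $\sim 2\times 10^{-3}$, so
any genuinely regionalized pattern sits hundreds of standard deviations
above the null and underflow is the norm, not an edge case. Genes with
total digital expression below 100 are flagged: with so little mass the
reconstruction support is a few scattered voxels and the index is
unreliable. The five sectors of the $(I, -\ln p)$ plane
(`sectorClassify()`) implement the sampling bands used to survey genes of
increasing regionalization; the second band is taken as $0.06 < I < 0.07$ —
a negative-index band there would contradict the bands' ordering by
increasing autocorrelation.

Weight style defaults to binary symmetric; row-standardized weights are
also supported (indexes shift slightly between styles, and thresholds like
0.1 are style-dependent — the choice is recorded in the weights object).
No multiple-testing correction is applied: the screen reports raw p-values
and an index threshold, keeping ranked exploration the primary use.

## Co-expression ranking

Pearson correlation between two genes' digital expressions, over in-mask
voxels only — including out-of-mask voxels, structurally zero for every
gene, would inflate every correlation. Rankings are invariant to positive
affine rescaling of any volume, so the normalization scale ambiguity above
is immaterial here. The default reporting threshold is $\mathrm{Cor} > 0.4$.

## What the phantom generator emulates — and what it does not

`makeDataset()` generates: a connected head-like mask (union of ellipsoids,
in-mask fraction ~0.35 of a (30, 33, 34) grid, matching the three section
counts of the assay's typical series); six territory classes (compact
connected blobs grown to a target volume fraction, axial gradients,
left-restricted domains, midline stripes, Bernoulli salt-and-pepper,
uniform); per-section capture efficiencies; an 8-species spike-in ladder
with fixed relative abundances; and Poisson counting noise at
`meanDepth = 2000` expected reads per gene per plane, the order of
magnitude a ~200M-read run spread over ~30,000 genes and three series
gives. Replicate-specimen disagreement is emulated by a small random
translation per plane (`embryoJitter`, in voxels, trilinear resampling);
its default is 0 because no empirical magnitude is established for it —
it is a mechanism hook, not an estimate.

Poisson noise (not negative binomial) is a deliberate simplification:
sections pool thousands of cells, so biological overdispersion is secondary
to counting noise at the section level; an overdispersed model would slot
into `simulateSections()` without interface changes.

Passing tests on phantoms therefore demonstrate: marginal fidelity of the
fit, exact recovery where exactness is mathematically due, territory
recovery through realistic counting noise, and correct behavior of the
statistics on patterns with known spatial structure. They do not
demonstrate robustness to section-plane obliqueness, RNA degradation,
section loss, segmentation error in the mask, or inter-specimen biological
differences beyond rigid translation — all real phenomena this simulator
does not model.

## Validation problem sizes

The shipped acceptance checks (`scripts/acceptance.R`, mirrored in the test
suite) use: 50 mixed-class noiseless genes plus 5×20 noisy blob genes on
the (30, 33, 34) grid for reconstruction properties; 100 random masks up to
6³ against a brute-force double-sum Moran oracle; 50 smooth fields × 20,000
permutations plus 500 permuted null fields for inference calibration; 30
blob + 30 salt-and-pepper genes for screen separation; and 10 seeds of a
planted-duplicate experiment for co-expression retrieval. These sizes give
each check clear statistical headroom while keeping a full run in the
low minutes on one core.

## Known limitations

* IPF yields one consistent solution, biased toward product form; disjoint
  multi-domain territories along one axis can be blurred into their
  bounding box along that axis.
* Resolution is bounded by section thickness; no claim at or below the
  single-cell scale.
* The analytic p-value relies on asymptotic normality of $I$; at very small
  voxel counts (a few dozen) the permutation method is preferable.
* Screening reconstructions inherits reconstruction artifacts (see the IPF
  caveat above); corroborating a hit by inspecting its digital sections
  (`exportSectionImages()`) is recommended practice.

## A worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(shape = c(30, 33, 34), seed = 1)
ds <- makeDataset(cfg, nGenes = c(blob = 5, salt_and_pepper = 5))
profiles <- lapply(ds$tables, normalizeBySpikein)
model <- reconstructAll(ds$truth@mask, profiles)
weights <- buildWeights(ds$truth@mask)
screen <- screenRegionalized(model, weights)
subset(screen, pass, select = c(gene, I, negLogP, totalDigitalExpression))
```

The same flow runs from a config file via `runPipeline()`, which writes
profiles, volumes, screen tables and a checksummed manifest.
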