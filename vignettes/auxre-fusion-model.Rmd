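---
title: "Evidence fusion for AuxRE prediction: model, design choices and limits"
author: "AuxREfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence fusion for AuxRE prediction: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AuxREfusion)
```

# The problem and the model

Auxin-response elements (AuxREs) are short cis-regulatory motifs, built
around the TGTCTC core, through which auxin-dependent transcription factors
activate plant genes. Single-signal motif scanners (consensus matching,
position weight matrices) flood promoter scans with false positives because
any one signal — sequence composition, overrepresentation, positional bias —
is weakly informative on its own. This package implements a data-fusion
predictor: several weak signals are each converted into a *basic probability
assignment* over the two-hypothesis frame

\[ \Theta = \{H_1: \text{AuxRE},\; H_2: \text{not AuxRE}\}, \]

and merged with Dempster's orthogonal sum. A mass function on this frame has
three components, \(m(H_1)\), \(m(H_2)\) and \(m(H_1 \cup H_2)\); the last
one carries *ignorance*, which is what distinguishes evidence theory from a
plain probabilistic combination: a source that has seen nothing relevant
assigns mass 1 to the union and leaves the decision to the other sources.

Two mass functions combine as
\[ (m_a \oplus m_b)(A) = \frac{1}{1-K}\sum_{B \cap C = A} m_a(B)\,m_b(C),
\qquad K = m_a(H_1)m_b(H_2) + m_a(H_2)m_b(H_1), \]
where \(K\) is the conflict. The *credibility* of a candidate window is the
fused belief in \(H_1\), which on a two-hypothesis frame equals the fused
singleton mass \(m(H_1)\); windows are called AuxREs when the credibility
reaches a threshold, 0.9 by default (inclusive).

## The seven features and the three learning graphs

Each candidate window (6-mers and 8-mers by default) is described by seven
features, computed against a *reference promoter collection* that plays the
role of the genome-scale background:

* **P** — distance from the window's 5' end to the translational start, in
  bp (promoters are upstream regions ending at the ATG; only the last
  1000 bp are scanned).
* **Sc** — an overrepresentation z-score:
  \((\mathrm{observed} - \mathrm{expected})/\sqrt{\mathrm{expected}}\) under
  an i.i.d. base background. This is a documented stand-in for a
  pattern-discovery significance score: it preserves the feature's role (how
  much more often a word occurs than chance predicts) behind the
  `significanceScore()` interface, where an alternative scorer can be
  plugged in.
* **O** — total occurrence of the word in the reference collection
  (forward strand by default; overlapping matches count; N never matches).
* **D** — density: the fraction of the word's matches that fall in
  promoters of 2-fold auxin-responsive genes. A word absent from the
  collection has an undefined density (0/0); this sentinel makes the whole
  occurrence/density evidence source vacuous — absence of evidence is
  ignorance, not evidence against.
* **x1, y1, z1, gc** — the Z-curve composition contrasts
  (purine−pyrimidine, amino−keto, weak−strong) and the GC fraction,
  projected onto two fixed discriminant axes to give **f1** and **f2**.

The features feed three *learning graphs*: (P, Sc), (O, D) and (f1, f2).
Each graph is a grid of confidence regions; every region carries a graded
proposition — P1 (total ignorance), P2 (low preference, high doubt), P3
(strong preference, low doubt), P4 (certainty) for one hypothesis — which
resolves to masses 0 / 0.33 / 0.67 / 1 on the preferred hypothesis, the
remainder on the union. The constants are stored exactly as the two-decimal
values the region tables are calibrated with (not 1/3 and 2/3), so the
mapping is reproduced bit-exactly:

```{r}
masses(massFromProposition("P3", "H1"))
```

## Fuzzification

Hard region boundaries would let two windows a base pair apart receive
opposite certainties. Every feature axis therefore carries a trapezoidal
fuzzy partition — a set tiling in which neighbouring sets share
complementary transition bands, so memberships sum to one everywhere and at
most two adjacent sets are active. The graph mass at a feature point is the
membership-weighted mixture of the cell masses,
\[ m(S) = \sum_{i,j} \mu_i(x)\,\mu_j(y)\, m_{R_{ij}}(S), \]
which is a valid mass function because the bilinear weights sum to one, is
continuous across region boundaries, and reduces to the discrete region
lookup when the trapezoids degenerate to rectangles. Because the first and
last set of every partition extend to infinity, out-of-range feature values
are effectively clamped to the boundary set — a scan of an arbitrary
promoter can never step outside the model's domain.

The candidate's final mass is
\(m_{\mathrm{fusion}} = (m_{ScP} \oplus m_{OD}) \oplus m_{f1f2}\); the
orthogonal sum is associative, so the grouping is immaterial.

# The shipped model configuration

All breakpoints, cell propositions, discriminant axes and the threshold live
in one YAML file (`inst/extdata/default_model.yaml`), fully overridable. The
choices that deserve explanation:

**Region tables.** The three grids transcribe published confidence-region
tables: per region, the percentage of training AuxREs it contains and the
proposition assigned to it (e.g. cell R23, 80% AuxRE, carries P3(H1); cell
Q22, 70% AuxRE, carries P3(H1); the pure zones carry P4). The source tables
label cells `Rij`, `Dij`, `Qij` by row and column of figures that are not
reproducible from the text, so the *orientation* of each grid is a
transcription decision. The position rows of the score/position table are
anchored by the accompanying description (the far-from-ATG rows contain only
AuxREs; known non-AuxRE elements such as TATA boxes cluster near the start).
The score columns are not anchored, and the two possible orders give
radically different models: mapping column 1 to the *lowest* score band
declares low-scoring windows far from the ATG to be certain AuxREs, which
floods any scan with credibility-1 false calls and contradicts every
qualitative property the method is supposed to have (false positives
vanishing at high credibility, precision maximal at the 0.9 cutoff). Mapping
column 1 to the *highest* band yields the only self-consistent model: words
occurring at background rates are dismissed with certainty and
overrepresented words away from the start codon are AuxRE-certain. The
shipped config therefore declares `axis2_label_order: descending` for that
table, while preserving the printed cell labels verbatim (`R23` still
resolves to the 80% proposition):

```{r}
mdl <- defaultFusionModel()
cellPropositions(mdl@tablePosSc)
propositionForCell(mdl@tablePosSc, "R23")
```

The occurrence/density and f1/f2 tables are 4 x 3 grids — their label sets
run to index 4 on the first axis, so the occurrence and f1 axes carry four
fuzzy sets even though three would match the named set lists; the printed
labels win.

**Breakpoints.** No membership shapes or breakpoints are published; the
shipped trapezoids are calibrated to the packaged synthetic world and are
the model's operating point, chosen once:

* *position*: core 0–200 bp, proximal 250–450, distal beyond 550 (50–100 bp
  transition bands) — AuxREs in the training structure sit away from the
  ATG, other elements cluster near it;
* *score*: the "small" plateau ends at z = 2, where background words live;
  the long transition to the "average" plateau at z = 5 keeps words that are
  overrepresented by chance (a handful of extra copies of an 8-mer) in
  blended, low-commitment masses instead of certainty cells; the "high"
  plateau 8–14 is where deliberately planted motifs land;
* *occurrence*: average plateau 8–38, high plateau 45–150. The narrow
  transition matters: 6-mer subwords shared between planted 8-mer variants
  occur at roughly twice the background rate and must fall crisply in the
  high-occurrence row, whose cells all dismiss — otherwise every background
  occurrence of a subword would be certainty-absorbed into a false call;
* *density*: small below 0.25, average 0.35–0.65, high above 0.75; the
  background density equals the responsive fraction of the collection
  (0.25), planted variants sit near 0.5;
* *f1/f2*: bands placed so the TGTCTC-family variant compositions project
  into the single strong-preference cell Q22, AT-rich (TATA-like) and
  GC-rich compositions into dismissing cells.

**Discriminant axes.** The default model ships fixed unit-norm axes over
(x1, y1, z1, gc) — the base-composition contrast (0.8, 0.6, 0, 0) and the
weak/strong-vs-GC contrast (0, 0, 0.9, −0.436) — consistent with the
synthetic training set's construction, rather than refitting at load time.
`fitLda()` is the user-facing trainer (Fisher's multi-class criterion, the
two leading eigenvectors of \(S_W^{-1} S_B\), unit-norm,
largest-loading-positive sign convention, ridge fallback
\(\varepsilon = 10^{-6}\,\mathrm{tr}(S_W)/4\) for singular scatter).

# Dempster absorption, conflict, and why they shape the scanner

Two algebraic facts drive the scan dynamics and are worth stating plainly:

* **Certainty absorbs.** \((1,0,0) \oplus m = (1,0,0)\) for every \(m\) with
  \(m(H_2) < 1\). Once one graph is certain, no amount of graded
  counter-evidence moves the result; only an opposite *certainty* can.
* **Opposite certainties are undefined.** \(K = 1\) has no orthogonal sum.
  The package raises a classed error (`auxref_conflict_error`) rather than
  returning NaN; the scanner catches it per candidate and reports such
  windows in a *rejects* table. A rejected window is treated as a non-hit at
  every threshold: contradictory certainties are not a detection. On random
  sequence this is the normal fate of most windows (for example a
  background-rate word far from the ATG: position/score certainty for
  \(H_1\) against occurrence/density certainty for \(H_2\)).

The threshold comparison is inclusive (credibility ≥ 0.9 is a hit), and the
0.9 default is the operating point at which the benchmark's precision peaks.

# The synthetic world

The real training measurements behind the region tables are unpublished, so
the package ships generators, not data files.

**Training fixture** (`makeTrainingFixture()`): 64 elements across five
classes (AuxRE 16, ABRE 12, TATA 16, Ypatch 11, DRE 9). Feature values are
drawn uniformly from boxes placed inside the plateau of each element's
designated grid cell, with the per-cell class counts chosen to invert the
printed region percentages (4 AuxRE + 1 other in R23 gives the 80% cell; 14
AuxRE + 6 Ypatch in Q22 gives the 70% cell, with Ypatch as the documented
confounder). Composition features are constructed by placing target (f1, f2)
scores on the reference axes and adding isotropic noise (sd 0.06), with
sampling boxes padded about two noise standard deviations inside plateau
crossovers so the generated values land in their designated regions. What
this emulates is the *summary structure* of a training set — class counts
and per-region proportions — not real measurements: sequences and feature
values are decoupled, classes are unimodal-by-design within each graph, and
inter-feature correlations of real promoter data are absent. Tests passing
on this fixture validate the machinery, not biological performance.

A refit of the discriminant model on the fixture recovers the construction
plane (principal angle well under 45 degrees) with the designed class layout
along the first axis. Exact reproduction of the f1/f2 grid proportions from
a refit is *not* expected at n = 64: the second axis carries only a few
percent of the between-class variance, so its fitted scale and rotation are
sampling-dominated — a deliberate, documented limit of the synthetic world.

**Reference collection** (`makeReferenceCollection()`): 120 random 1000-bp
promoters, 30 flagged auxin-responsive, with each of the 14 AuxRE variants
(TGTCTC-family cores with A/T flanks) planted 14 times, 7 copies in
responsive promoters. This pins the variants' features to the model's
supportive bands: occurrence ~16 (average), density ~0.5 (average),
z-score ~9–12 (high). The collection stands in for a genome-scale
background; a real application would pass its own `PromoterCollection`.

# The gold-standard benchmark

`runBenchmark()` regenerates the evaluation protocol: 100 random 1000-bp
sequences, each spiked with exactly one variant at a uniform random
position, scanned against the fixed reference collection, swept over
credibility cutoffs 0.1–0.9. Scoring is element-level for sensitivity: a
truth element counts as detected if some hit overlaps at least half of it
(configurable to exact or any-overlap); surplus windows detecting an
already-detected element are removed from the evaluated universe rather than
counted as errors; every other hit is a false positive and remaining
candidates are true negatives. Two metric conventions are inherited from the
evaluation this reproduces and differ from textbook usage: **FPR = 100 −
PPV** and **FNR = 100 − NPV** (complements of the predictive values, not
fall-out and miss rates). The Youden index, Yule's Q and the Pearson
chi-square of the 2 x 2 table complete the panel. Metrics with empty
denominators are `NA`, never 0. The argmax-PPV cutoff resolves ties to the
lowest cutoff; in practice the sweep is strictly increasing up to 0.9.

Typical behaviour on the default model (seeds 1–3): sensitivity 72–80 at the
0.9 cutoff (the missed spikes sit in the core region near the ATG, the
model's designed blind spot — in training only non-AuxRE elements live
there), precision maximal at 0.9 on every seed, fused ROC dominating both
single methods, and the single methods drowning (>90% false among their
positives) at permissive cutoffs.

Two structural limits are worth knowing. First, all evidence is word- and
position-level, so a *chance* occurrence of a variant word in random
sequence is indistinguishable from a spiked copy; with ~200,000 scanned
windows, a library is expected to contain a dozen or two such occurrences,
which form an irreducible false-positive floor at high credibility. Second,
the discriminant graph's strongest proposition is P3, so the
discriminant-only "method 2" caps at credibility 0.67 and makes no calls at
all at 0.9 — comparisons against it at that cutoff are vacuous.

# Numerical contracts

* Mass validity tolerance 1e-9; inputs beyond it are rejected, not
  renormalized; table constants survive bit-exactly.
* Combination flags total conflict when \(1 - K \le 10^{-12}\).
* Partition-of-unity and fused-mass normalization hold to 1e-9 on dense
  grids (tested).
* The orthogonal sum is implemented once, vectorized, and verified against
  an independent brute-force enumeration of all focal-set intersections to
  1e-12 on a thousand random pairs.
* Scans are deterministic: identical inputs give identical output tables,
  ordered by credibility, then promoter and position.
* Generators are fully determined by their integer seeds.

Problem sizes throughout (64-element fixture, 120-promoter reference, 100
spiked sequences, three benchmark seeds) are the package's chosen study
conditions; they keep a full benchmark run in the tens of seconds on one
core while leaving every band of the model exercised.
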