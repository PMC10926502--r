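---
title: "Methods: models, defaults, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodx)
```

This vignette documents the quantitative models the package implements,
their parameter defaults and units, the scope of the synthetic generators,
and the rationale behind the design decisions that were open choices
rather than forced by any formula.

## 1. Distances and trees

**TN93 distance.** `tn93_distance()` implements the closed-form
Tamura–Nei estimator with base frequencies pooled empirically per sequence
pair and pairwise deletion of sites containing gaps or ambiguity codes.
Pairs whose transition/transversion proportions push a logarithm argument
to zero or below are flagged `saturated` (distance `NA`) rather than
silently clamped. For two-sequence alignments the implementation agrees
with `ape::dist.dna(model = "TN93", pairwise.deletion = TRUE)` to
machine precision, and collapses to the Jukes–Cantor value at low
divergence (first-order agreement in the substitution proportion *p*).

**Neighbor joining.** `neighbor_joining()` is the Saitou–Nei algorithm
with a deterministic tie-break (the Q-minimal pair with the lowest
original label indices) so repeated runs give byte-identical trees.
Negative branch estimates are clamped to zero with the deficit moved to
the sister branch, preserving path lengths. On additive matrices the
recovered tree's patristic distances equal the input exactly (tested to
1e-9 over random 6–10-leaf trees). Branch support comes from a
delete-half jackknife (`jackknife_support()`, default 1000 replicates,
deletion fraction 0.5, seeded): columns are resampled without
replacement, trees rebuilt, and bipartition frequencies mapped back.

## 2. The statistical-parsimony network

`parsimony_connection_limit()` computes, for an alignment of length *L*
(default ungapped core, here 420 nt), the largest step count *j* whose
parsimony probability stays at or above `alpha = 0.95`. The probability
model treats per-site mutation hits as Poisson with rate
`lambda = -0.75 * log(1 - 4p/3)` (the Jukes–Cantor expected hits at
observed proportion `p = j/L`) and asks that every observed difference be
explainable by a single hit:

`P(L, j) = (lambda * exp(-lambda) / p_diff)^j * (exp(-lambda) / p_same)^(L-j)`

This is our own formalization of the "probability of no superimposed
change" idea; it was validated against a Monte-Carlo oracle (simulate
Poisson hits per site, a site differs after *h* hits with probability
`3/4 - 3/4 * (-1/3)^h`) before being frozen, agreeing to well within the
test tolerance of 0.05. At *L* = 420 the limit is 6 steps.

`build_network()` joins haplotype pairs in nondecreasing step order under
a minimum-spanning-forest rule; `force_connect = TRUE` additionally
bridges residual components through their closest pair, expanding
multi-step edges into unsampled intermediate nodes (`x1`, `x2`, ...), so
graph shortest paths equal mutational steps. `path_metrics()` then
reports per-subgroup haplotype counts, step diameters, variable
positions, and between-subgroup separations.

## 3. Oligo thermodynamics

Two melting-temperature engines coexist deliberately:

* `tm_salt_adjusted()` — the salt-adjusted GC formula
  `Tm = 100.5 + 41 * (nGC/N) - 820/N + 16.6 * log10(Na)` (°C, `Na` molar,
  default 0.05 M), rounded to 0.1 °C. This is the legacy formula under
  which the five published assay oligos evaluate to 62.5 / 54.3 / 58.4 /
  58.4 / 58.4 °C, and it is kept verbatim so those numbers reproduce
  exactly.
* `tm_nearest_neighbor()` — unified nearest-neighbor thermodynamics
  (duplex initiation with terminal A·T penalties, symmetry correction for
  self-complementary oligos), with a salt entropy correction
  `dS + 0.368 * (N-1) * ln(Na_eq)` where
  `Na_eq = mono + 120 * sqrt(max(div - dntp, 0) * 1000) / 1000` (molar;
  defaults: monovalent 0.05 M, divalent 1.5 mM, dNTPs 0.6 mM, total
  strand concentration 50 nM). All candidate filtering and ranking uses
  this engine; the GC formula is reporting-only.

`structure_screen()` reports maximal hairpin stem length (loop >= 3),
maximal self/hetero-annealing complementarity, dimer Tm of the best
annealing register, homopolymer run length, and 3'-end stability (the
nearest-neighbor stability of the last five bases).

## 4. Assay design

`snv_density_scan()` splits the alignment into segments (default 100 nt,
capped at the 25 best-scoring), scores each position by fixed differences
between target and nontarget samples minus intra-target variation, and
places three non-overlapping oligo windows (forward, probe, reverse; 30
nt each) by an exhaustive probe-position sweep: for every admissible
probe window the best forward window left of it (prefix argmax) and best
reverse window right of it (suffix argmax) are combined, and the triple
maximizing (total covered fixed differences, then forward coverage, then
probe coverage, then leftmost probe) wins. The sweep is O(n) per segment
after precomputing window scores and is tested against an O(n^3) brute
force. Exhaustive placement was chosen over greedy seeding because
segments are short (problem sizes: alignment <= a few kb, segment 100 nt,
window 30 nt), so optimality is affordable.

`enumerate_candidates()` enumerates every substring in the role's length
band (primers 14–22–35, probes 18–20–36 nt as min–opt–max), filters by
Tm band (primers 50–55.5–60 °C, probes 57–60–63 °C), GC content
(20–50–80 %), homopolymer runs (<= 5), 3'-end stability (<= 9), and
self-dimer Tm (<= 47 °C), and ranks by the penalty
`|Tm - opt| + 0.05 |GC - opt| + 0.2 |len - opt|`, keeping the top 5 per
window. Tested equal to a brute-force enumeration on 40-nt windows.

`rank_assay_sets()` scores complete sets by total discriminative sites
covered (sites within 5 nt of an oligo's 3'-relevant end count double —
the *end-weighting* that rewards mismatches where polymerase extension is
most sensitive), then Tm differential between probe and primers, then
structure penalties.

**Control assay.** `design_control_assay()` designs on a conserved
companion locus (rDNA-like) with the constraint that each control oligo's
Tm never exceeds its diagnostic counterpart's, so the control never
out-competes the diagnostic reaction in multiplex. The cap is applied to
the enumeration constraints *before* per-window truncation (capping
afterwards can discard every admissible candidate).

**Specificity.** `in_silico_specificity()` predicts amplification for a
panel sample when each primer has <= 2 total mismatches and none in its
three 3'-terminal bases, and the probe has <= 1 mismatch; gaps and
unknown bases count as mismatches and IUPAC codes match what they cover.

## 5. qPCR interpretation

A channel is *amplified-positive* when its end RFU meets the channel
threshold (diagnostic 500, control 250 RFU) and its Cq lies in the window
[5, 30]. `classify_sample()` emits exactly one of four calls:
**positive** (both channels amplified, delta-Cq <= 7), **negative**
(control only — the non-target pattern), **failed** (neither — degraded
template), and **anomalous** (everything else). The anomalous category is
our explicit formalization of the "needs human review" outcomes: a
diagnostic Cq below the window paired with a control Cq above it (the
copy-number-imbalance pattern; rerun in singleplex), both channels
amplified but delta-Cq too large, or diagnostic amplification without the
control. The four calls are proven exhaustive and mutually exclusive by
grid enumeration in the tests. Note the calls are defined per *channel
role* (diagnostic vs control), not per fluorophore; mapping dyes to roles
is the instrument layer's job and is out of scope here.

`fit_standard_curve()` regresses Cq on log10(concentration) and reports
`E = 10^(-1/slope) - 1`; a slope of `-1/log10(2) ≈ -3.3219` gives exactly
100 % efficiency. The detection floor is the lowest concentration at
which every replicate amplified.

## 6. Synthetic generators: scope and limitations

`generate_barcode_dataset()` plants a known structure: a central
haplotype (60 members), 12 one-step and 1 two-step satellites, a
conspecific outlier at 20 steps, three nontarget species at 40/45/60
steps, and one outgroup at 80 steps, over a 420-nt locus, plus a
200-nt conserved control locus. Every mutation takes a fresh alignment
column (*no homoplasy*), so Hamming distances equal planted tree-path
sums and all network metrics are fixed by construction — that is what
makes exact assertions possible. The main group additionally carries a
*stem block*: 12 derived positions clustered at 4-nt spacing inside a
reserved region, shared by every main-group member and by no other
lineage. The stem models the target lineage's own apomorphies — the raw
material without which no diagnostic assay is designable — and is counted
inside the outer branch lengths so planted separations are unchanged.
Subspecies labels are assigned round-robin, deliberately discordant with
haplotype identity (mirroring the common empirical finding that
intraspecific taxonomy does not track barcode haplotypes).

Limitations: no recombination, no rate heterogeneity, no homoplasy, no
indels in generated data (the I/O layer handles gaps, the generator never
emits them), identical sequences within a haplotype. The generator is a
test harness, not a population-genetics simulator.

`generate_qpcr_run()` draws wells from per-class models (defaults: 110
positives, 4 anomalous, 3 negatives, 1 failed). Positives draw diagnostic
Cq from Normal(15.71, 4.38) truncated to the Cq window, a signed
half-Normal(1.50, 0.65) delta rejected until the control Cq is in-window
and the delta within the cutoff, and end RFUs from Normal(1359.33,
209.07) / Normal(1533.68, 546.79) floored just above the thresholds —
so generated positives satisfy the default call thresholds *by
construction* (a simulation convenience, not a biological claim). The
realized moments are validated in the tests against an independently
coded sampler of this documented model, not against the raw Normal
parameters, because the joint rejection step shifts the marginal means.

## 7. Reproducibility

All generators take explicit integer seeds and are byte-reproducible.
`scripts/acceptance.R --seed N --out f.json` writes the reference
quantities; they are seed-independent because the structure is planted.
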