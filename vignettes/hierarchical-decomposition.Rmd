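---
title: "Hierarchical protein decomposition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical protein decomposition: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peeldom)
```

This vignette is the package's own account of the science it
implements: the models, the tunables and their defaults, what the
synthetic fixtures do and do not show, and the places where the design
was genuinely open and a choice had to be made.

## The decomposition model

A protein chain is viewed at three levels: secondary structures,
Protein Units (PUs) and domains. The working object throughout is the
**contact-probability map**: for residues $i,j$ with C$\alpha$
distance $d_{ij}$,

$$p_{ij} = \frac{1}{1 + e^{(d_{ij} - d_0)/\delta}},$$

a logistic transform that replaces the usual hard contact cutoff with
a smooth weight. The underlying assumption is that C$\alpha$ geometry
alone carries enough signal to delineate compact regions; side chains,
hydrogen bonds and chemistry enter nowhere in the partitioning.

**Peeling.** A PU is a contiguous fragment with many internal and few
external contacts. A candidate split of a segment into $m \in \{2,3\}$
sub-segments with intra-segment masses $I_1..I_m$ and total
cross-segment mass $X$ is scored by

$$\mathrm{PI} = \frac{G - X^2}{G + X^2}, \qquad
  G = \Big(\prod_k I_k\Big)^{2/m} \in [-1, 1].$$

The functional form was an open design point: the requirements are
only that intra-contacts are rewarded, cross-contacts penalised, and
the score is comparable across segments of different size. The chosen
form is bounded, scale-free (both $G$ and $X^2$ are quadratic in
contact mass), equals 1 exactly when $X = 0$ with all $I_k > 0$, and
uses the geometric mean so that one near-empty sub-segment drags the
score down. It is isolated behind `partition_index()` so an
alternative (e.g. a Matthews-correlation-style score) can be swapped
without touching the search; the form's name is echoed in every result
bundle.

Peeling applies the globally best split among all frontier PUs at each
iteration (not round-robin), which yields a single well-ordered level
sequence: low levels contain few, long PUs. All 1-cut and 2-cut
positions are scanned exhaustively — the map's cumulative-sum table
makes each PI evaluation O(1), so exhaustive scanning is cheap — and
tie-breaks (fewest cuts, then leftmost) are deterministic, making
peeling reproducible bit-for-bit.

**Assembly.** Terminal PUs are merged agglomeratively. Merge
candidates are ranked by separation
$S = X_{AB}/\sqrt{I_A I_B}$ (contact mass between the units,
normalised by their cohesion) and, on ties, by the compactness
$C = I/|\text{unit}|$ of the merged domain. A beam of width 3 (default)
bounds the search while preserving the pure-greedy path as beam
rank 1; every state visited at every depth is kept, so the result is a
ladder of partitions from $|\mathrm{PUs}|$ domains down to 1. Domains
may be sequence-discontinuous unions of PUs, which real annotation
databases require.

**Quality and acceptability.** Each partition is scored 1–5 by a step
function over $\rho$ (inter-domain contact mass over the chain's total
non-local mass) and $\kappa$ (worst domain compactness over chain
compactness): 5 needs $\rho \le 0.03, \kappa \ge 0.9$; 4 needs
$\rho \le 0.06, \kappa \ge 0.8$; 3 needs $\rho \le 0.10,
\kappa \ge 0.7$; 2 needs $\rho \le 0.15, \kappa \ge 0.6$. These
thresholds are package defaults chosen so that, on reference fixtures,
a cut through a linker scores 4–5 while a cut through the middle of a
globule falls below acceptability; they are emitted in the output
metadata and should be treated as a discretisation of "acceptance",
not as physical constants. Quality $\ge 2$ defines the acceptance
range. A single-domain partition is assigned $\rho = 0,\kappa = 1$
(quality 5) by convention: with no second domain there is nothing to
separate, and this keeps the A-index of trivially single-domain
proteins small rather than undefined.

**Ambiguity and junctions.** The A-index is the largest $A$ such that
$A$ partitions have quality $\ge A$ — an h-index over qualities,
balancing how many alternatives exist against how good they are. A
junction is an inter-residue boundary used by a partition, either as
an inter-domain boundary or as an extremity of a PU used to build a
domain; PU extremities interior to a domain are included by default
(they mark probable cut zones even when a particular partition happens
to bury them) and can be excluded with a flag.

**Native-likeness (AUL).** Each PU/domain receives a pseudo-energy
$E = -\sum \mathrm{lo}[a_i, a_j]$ over its internal C$\alpha$ contacts
($d \le 8$ Å, $|i-j| \ge 3$), compared against $n$ sequence-shuffled
decoys — the unit's residue labels are permuted, coordinates held
fixed, so the decoys share the fold but not the sequence-structure
fit. With decoy mean $\mu$ and spread $\sigma$, $Z = (E-\mu)/\sigma$,
and the one-sided Chebyshev bound gives the Autonomous Unit
Likelihood:

$$\mathrm{AUL} = \begin{cases}
 100\,(1 - 1/Z^2) & Z \le -1\\ 0 & Z > -1.
\end{cases}$$

Chebyshev's inequality makes no normality assumption — decoy energies
are visibly non-normal — at the price of being conservative. The
bundled 20×20 propensity table is **synthetic**: a symmetric
hydrophobicity-derived log-odds surface
($\mathrm{lo}[a,b] = (h_a + h_b)/10$ on the Kyte–Doolittle scale),
labelled as such in its file header. Absolute energies from it are not
comparable to trained statistical potentials; only decoy-relative
quantities (Z, AUL) are meaningful, which is all the pipeline reports.
A degenerate decoy distribution ($\sigma = 0$, e.g. a homopolymer) is
reported as *n/a*, never as AUL 0, to keep "no signal" distinct from
"not native-like".

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `d0` | 8.0 | Å | logistic midpoint; conventional C$\alpha$ contact distance |
| `delta` | 1.5 | Å | logistic steepness; softness of the contact notion |
| `min_pu_size` | 15 | residues | smallest PU; keeps PUs between secondary structures and domains in size |
| `max_pus` | 16 | — | frontier size at which peeling stops |
| `max_cuts` | 2 | — | cuts per split (2 allows excising a central PU) |
| `pi_gain_threshold` | 0.05 | — | minimal PI for a split to count |
| `beam_width` | 3 | — | assembly beam; `Inf` = exhaustive agglomeration |
| `n_decoys` | 2000 | — | decoys per energy assessment |
| `cutoff` | 8.0 | Å | contact cutoff of the pseudo-energy |

All of them are echoed into `results.json` so outputs are
self-describing.

## The synthetic fixtures

`make_globule_chain()` emulates the one property the pipeline actually
exploits: contrast between contact-dense regions and contact-sparse
connectors. Each globule is a self-avoiding random walk (3.8 Å steps,
pairwise clearance ≥ 3.5 Å) confined to a 10 Å sphere; linkers are
near-straight jittered 3.8 Å-step paths; the first globule is built
backwards from its exit point so both junction geometries match.
Consecutive globule centres end up ≈ 35 Å apart, so inter-globule
non-local contact mass stays below 5 % of the total. Residue
identities are uniform over the 20 standard types.

What the fixtures do **not** emulate: real secondary-structure
packing, side chains, evolved sequences (so AUL on fixtures is
correctly ≈ 0 — their sequences carry no fold signal), domains that
exchange β-strands, and contact gradients milder than
globule/linker contrast. Passing the fixture suite therefore shows the
machinery is correct, not that the default thresholds are optimal for
borderline real proteins.

The reference study conditions used in the test suite are two 30-residue
globules joined by a 5-residue linker, 20 seeds; boundary recovery is
counted as the optimal partition having exactly 2 domains with its
boundary within ±2 residues of the linker midpoint. Oracle-equivalence
checks for the splitter run on 200 random maps of up to 40 residues;
the exact decoy-mean law is checked on units of ≤ 8 residues where the
permutation expectation has a closed form.

## Numerical choices and degenerate inputs

* Interval masses come from a cumulative-sum table (exact up to float
  associativity); set masses from direct summation. Mass conservation
  across any block partition holds to machine precision.
* PI with all-zero masses is defined as 0; CI and separation with zero
  denominators are 0; quality of a single domain is 5 by the
  convention above.
* Tie-breaks everywhere are deterministic: fewest cuts, then leftmost
  (peeling); highest $S$, then merged-domain $C$, then smallest PU
  index (assembly); fewest domains first in output ordering.
* Chains shorter than 5 residues get an all-C secondary structure with
  a warning; chains shorter than `min_pu_size` are returned as a
  single PU.
* Residues lacking a C$\alpha$ are dropped with a warning — they
  cannot enter any contact-based quantity. Alternate locations resolve
  to the highest occupancy, ties to the alphabetically first
  identifier. `MSE` and other modified residues are treated as
  non-standard and removed, mirroring the strict cleaning rule rather
  than remapping them.
* Every derived seed stays below $2^{31}$; decoy RNG is scoped so
  library calls do not disturb the caller's RNG state.

## Known limitations

* Secondary-structure annotation is reporting-only; the geometric
  C$\alpha$ fallback is deliberately crude (helix/extended windows on
  $i,i{+}2$ and $i,i{+}3$ distances) and flagged `approximate`; supply
  a DSSP file for faithful assignments.
* The quality step function's constants are calibrated on synthetic
  contrast, not benchmarked against curated domain databases.
* The propensity table is a surrogate; AUL magnitudes on real proteins
  will differ from those a trained potential would give, even though
  the Z → AUL mapping itself is exact.
* The beam bounds the enumeration of alternatives: with many PUs some
  acceptable partitions may be missed (beam rank 1 always preserves
  the greedy path).
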