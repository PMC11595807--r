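---
title: "Dereplicating Crambe crambe guanidine alkaloids: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dereplicating Crambe crambe guanidine alkaloids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CrambeDerep)
```

This vignette is the package's account of the science it implements: the
mass conventions, the parametric scaffold model, the fragmentation rules
and their evidence weights, the synthetic-data model used for
validation, and the numerical and design choices that were genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The annotation problem

*Crambe crambe* extracts contain two guanidine-alkaloid families. The
crambescins come in three sub-families — A (5,6-fused bicyclic core), B
(spiro core) and C (monocyclic core) — that share an upper alkyl chain
of (*n* + 2) methylene units and a lower guanidinoalkyl chain of
(*m* + 2) units. Members therefore form homologous series spaced by
14.0156 Da, frequently isobaric across (*m*, *n*) combinations with the
same sum, and they ionise mostly as [M+2H]2+ (crambescidins as [M+3H]3+).
Dereplication means: recover the neutral mass from a multiply charged
ion, enumerate which scaffold/chain combinations fit within ±5 ppm, and
use the MS2 fragmentation to fix the chain split and the core.

## Mass conventions

Two element mass tables are provided. The default `"paper"` table
(H 1.0078, C 12, N 14.0031, O 15.9949 Da) is the 4-decimal reporting
convention under which every printed value this package reproduces was
computed; the `"precise"` table carries full-precision monoisotopic
masses for new work. Protonation adds exactly one H mass per charge —
the electron mass is ignored everywhere, consistent with the neutral
mass formula `Mw = mz*z - z*M_H`. Reported values are rounded half away
from zero: m/z and masses to 4 decimals, ppm to 2.

A point worth documenting: ppm errors of *fragment* ions are referenced
to the full cation mass,

$$\Delta_{ppm} = 10^6\,\frac{mz_{obs} - mz_{theor}}{z \cdot mz_{theor}},$$

not to the m/z. For singly charged fragments the two coincide; for
doubly charged fragments only this convention reproduces the published
errors (e.g. 127.0863 observed vs. 127.0869 theoretical is −2.36 ppm on
the 254.17 Da cation scale, not −4.7 ppm on the m/z scale). The test
suite freezes thirteen published fragment errors under this convention.

## The scaffold library

Series formulas are linear in the chain parameters: with
$k = 14 + m + n$ for the chain-parameterised families and $k = 26 + m$
for the "3"-type families (whose upper chain is fixed and carries four
additional degrees of unsaturation),

| sub-family | formula | RDBE |
|---|---|---|
| A | C$_k$H$_{2k-4}$N$_6$O$_2$ | 6 |
| didehydro-A | C$_k$H$_{2k-6}$N$_6$O$_2$ | 7 |
| B, C | C$_k$H$_{2k-2}$N$_6$O$_3$ | 5 |
| A3 | C$_k$H$_{2k-12}$N$_6$O$_2$ | 10 |
| B3, C3 | C$_k$H$_{2k-10}$N$_6$O$_3$ | 9 |

The coefficients were fitted against every reported crambescin
assignment and the tests regenerate all 38 printed formulas from their
stated (*m*, *n*). The default enumeration ranges, m ∈ [2, 8] and
n ∈ [2, 12], cover all reported assignments with margin and are
configurable. The library is configured from a YAML file (series
coefficients, ranges, the closed crambescidin list), so a new scaffold
is a config edit, not a code change.

Crambescidins have no known homologue rule and are kept as a closed
list named by nominal mass, plus the crambescidin acid and a handful of
small guanidine compounds observed as singly charged ions.

## Fragmentation rules and scoring

Each sub-family's rules are instantiated at (*m*, *n*) as concrete
cations with a diagnostic weight:

* **A-type** — CH2N2 loss from the dication (weight 0.8); further upper
  chain loss C$_{n+3}$H$_{2n+6}$ (1.0, fixes *n*; C15H22 for A3, with
  the unsaturation retained in the neutral for didehydro-A);
  guanidinoalkyl [C$_{m+3}$H$_{2m+10}$N$_3$O]$^+$ (1.0, fixes *m*) and
  its dehydrated form (0.5); the core/ester-cleavage ion
  [C$_{n+10}$H$_{2n+14}$NO]$^+$ at weight 0.25 — it is generalised from
  only two observed assignments, is flagged provisional in the config,
  and must never dominate scoring; for A3 additionally the constant
  core ion [C23H34N3O2]$^+$ (384.2643).
* **B-type** — the retro-Diels–Alder pair
  [C$_{n+5}$H$_{2n+12}$N$_3$]$^+$ / [C$_{m+9}$H$_{2m+16}$N$_3$O$_3$]$^+$
  (1.0 each; fixed [C17H28N3]$^+$ for B3), the CH2N2 loss of the upper
  RDA ion (0.8), the constant spiroaminal ion [C6H7O2]$^+$ at 111.0444
  (0.5, shared by all B members), and the guanidinoalkyl pair.
* **C-type** — the doubly charged diagnostic
  [C$_{m+10}$H$_{2m+17}$N$_3$O$_3$]$^{2+}$ (1.0) plus the
  guanidinoalkyl pair.
* **Crambescidins** — the marker ions 264.1707, 246.1602 and 70.0655;
  a named call requires at least two of the three, otherwise the match
  is reported formula-only.

Fragment matching uses 5 ppm with a 0.002 Da absolute floor below
m/z 400: several published fragments deviate by 4–6 ppm at low m/z
where the ppm window is narrower than realistic centroid accuracy.
Candidates are ranked by summed weight of matched rules, ties broken by
absolute precursor ppm, then by fewer unmatched rules, then name — a
deterministic ordering that mirrors the evidence hierarchy (fragments
over mass accuracy alone); candidates with no matched fragment are kept
but flagged `formula-only`.

**B/C discrimination.** B and C members with equal (*m*, *n*) share a
molecular formula. The C core, with two conjugated double bonds,
undergoes the RDA fragmentation much less readily, so the decision is
intensity-based: with $I_C$ the C-diagnostic intensity and $I_B$ the
summed RDA pair, choose C when $I_C/(I_C + I_B) \ge \theta$ with
$\theta = 0.5$ by default. The published description is qualitative
("intense" vs. "significantly lower"), so θ sits at the symmetric
midpoint and is configurable; when neither diagnostic is found the pair
is reported as a single undetermined "B or C" annotation rather than
silently merged. The same machinery covers B3/C3.

A3 members detected as exactly two co-formula features are labelled by
expected relative polarity — earlier-eluting *cis*, later *trans*;
groups of any other size are left unlabelled with a warning, since
elution order alone cannot resolve them.

Features whose MS2 was triggered on a different protonation state can
be annotated under several charge interpretations (`try_charges`); the
A-type rule set includes the [M+H−CH2N2]$^+$ ion seen in such scans.

## The synthetic-data model

The generator is the forward model of the rules above. For each planted
compound it emits the precursor at its theoretical m/z for the
compound's charge state, an isotope envelope at 1.0033/z spacing, and an
MS2 spectrum holding the family's rule ions under a family intensity
profile. Choices that deserve justification:

* **Mass jitter** is Gaussian with σ = jitter/2, truncated at the
  configured bound (default 3 ppm), so recomputed errors never exceed
  the bound — matching the claimed instrument accuracy regime
  (Orbitrap, 70,000 resolution, <5 ppm).
* **Intensity profiles** encode the qualitative published statements as
  fixed ratios: the C diagnostic is the base peak of C spectra while
  the B-type ions appear there at 8% relative intensity; B spectra lack
  the C diagnostic entirely. Fragment intensities get log-normal
  multiplicative noise (σ = 0.15 on the log scale).
* **Residual precursor + first isotope** appear in MS2 at low
  intensity: with a ~1 Da isolation window a multiply charged precursor
  (isotope spacing 1/z Da) is co-isolated with its +1 isotope, and HCD
  at moderate energy leaves a precursor residual. This gives synthetic
  spectra the realistic property that any two spectra share two
  trivially shifted peaks.
* **Decoys** are drawn uniformly over m/z 60 to the precursor but
  rejected inside the ±(5 ppm ∨ 0.002 Da) windows of the planted
  compound's own ions, so the ground truth stays well defined; an
  adversarial mode places them inside those windows instead, for
  false-annotation studies.
* **The paper-like manifest** plants the 53 reported compounds at their
  reported retention times and charge states (plus the two internal
  standards at 9.80/12.59 min); closed-list entries carry their
  published fragment m/z lists so their spectra are distinguishable.
  The two compounds that shared a consensus feature in the source data
  are planted 0.03 min from their isobaric partners, as a co-elution
  stress case.

What the generator does **not** emulate: chromatographic peak shapes,
adducts and in-source fragments, isotope fine structure, and — most
importantly — the peak richness of real HCD spectra, which carry many
more ions than the diagnostic rule set. Passing round-trip tests
therefore demonstrates that the annotation logic inverts the rule set
under realistic mass error and decoy noise; it does not demonstrate
performance on real spectra with unmodelled chemistry.

## Validation sizes and numerical choices

The stochastic round-trip benchmark runs 200 seeded replicates of the
paper-like manifest (38 scored crambescins each, 3 ppm jitter, 10
decoys/spectrum) — large enough that a 95% recovery bound has
sub-percent Monte-Carlo error while keeping the suite inside a few
minutes. Charge inference accepts a median isotope spacing within
0.01 Da of 1/z (ties toward lower z); feature assembly groups centroids
at 5 ppm with a 0.2 min RT gap and takes the apex intensity — a
simplified scheme, adequate for synthetic data, in place of full
chromatographic feature detection, which is not this package's
contribution. MS2 linking uses the 0.02 Da precursor tolerance and a
0.2 min RT window (the linking tolerances are config defaults, not
published values). Degenerate inputs are handled explicitly: empty
spectra score zero in networking; empty candidate sets are legal; an
empty annotation set yields a header-only report.

## Molecular networking and its limits on homologous series

The modified cosine square-root-scales and L2-normalises intensities,
pairs peaks directly or shifted by the precursor m/z difference, and
solves a maximum-weight one-to-one assignment (via weighted bipartite
matching; a brute-force enumeration oracle checks it exactly on small
spectra). Edges require cosine ≥ 0.7 and ≥ 6 matched peaks at 0.02 Da
tolerances — the feature-based molecular-networking parameters used for
this chemistry. Top-K pruning is off by default (the upstream platform's
pruning parameters are not published) but available.

One structural observation, documented here because the test suite
measures it: on a *dense* homologue grid, components cannot be pure in
side-chain type. Two members with Δm = Δn are global m/z shifts of each
other — every m-dependent singly charged ion moves by 14.0156·Δm and
every composition-shifted doubly charged ion by 7.008·Δ(m+n), both equal
to the precursor m/z difference — so the modified cosine connects them
with near-perfect score *by design* (this is precisely why molecular
networking is good at grouping homologous series). Same-m neighbours
likewise connect through their shared lower-chain ions. On the full
(m, n) grid these edges merge each family's lattice into one component
whose side-chain-type purity is combinatorially ≈ 0.63, and no faithful
intensity profile can separate compounds differing only in chain
length. The type-level clustering reported for the real extract lives
on a sparse compound set with much richer spectra; the package reports
the measured purity rather than forcing the clustering.

## Known limitations

Annotation is rule-based and limited to the configured scaffolds: a
compound outside the library ranges, or a genuinely novel scaffold,
yields no annotation (never a forced one). Stereochemistry is out of
scope except for the polarity-based A3 cis/trans labels. The B/C
threshold θ has no published calibration; at 0.5 it is symmetric, and
the reported intensity ratio lets users audit borderline calls. The
fragment-coverage checks exclude one published fragment value that no
CHNO composition of its precursor can explain within tolerance.
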