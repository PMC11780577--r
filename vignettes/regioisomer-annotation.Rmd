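---
title: "Annotating lipid C=C regioisomers from ozone/nitrogen-oxide derivatized LC-MS/MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating lipid C=C regioisomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oznoxr)
```

## The measurement model

Ozone cleaves a carbon–carbon double bond; in an electrospray source
that also contains nitrogen and oxygen at high temperature, the
resulting secondary ozonide is captured by in-situ nitrogen dioxide
into nitrogen-oxide adducts of the intact lipid. The positive-mode
adduct, [M+NO4–H]⁺ (with an additional NH3 for classes that ionize as
ammonium adducts), has one m/z per lipid regardless of how many double
bonds it carries. Fragmenting it in a scheduled PRM experiment releases
product ions whose masses encode each double-bond position: a cleavage
at methyl-terminal position *n*-p on a chain that has *u* double bonds
at lower positions removes C~p~H~2p−2u~ and adds one oxygen. Everything
this package computes follows from that bookkeeping plus per-class
fragmentation rules.

Two properties of the arithmetic are worth stating because the engine
relies on them:

* the carboxyl-side product retains the whole rest of the molecule, so
  its m/z depends only on (p, u), not on which chain was cleaved — two
  chains with the same position give mass-degenerate products; and
* for classes that shed their headgroup before the C=C-site
  fragmentation (PE, PG, PI, PS, PA, LPG), the surviving fragment is
  headgroup-free, so classes sharing an acyl composition converge to
  identical diagnostic m/z whether their base adduct was [M+H]⁺ or
  [M+NH4]⁺. The headgroup neutral-loss table (PE C2H8NO4P 141.0191,
  PG C3H9O6P 172.0137, PS C3H8NO6P 185.0089, PI C6H13O9P 260.0297,
  PA H3PO4 97.9769) is the unique assignment satisfying that
  convergence, which the tests enforce.

Class diagnostic multiplicities per C=C: PC/LPC a pair (protonated
aldehyde and its CHO-radical loss), PE the pair both with and without
headgroup loss (four ions), the other diacyl classes the headgroup-lost
pair, LPE a trio (aldehyde, −H2O, −CHO), FA a trio (ammoniated
aldehyde, protonated aldehyde, −H2O). Collision energies are class
optima: FA 10, PC 15, LPE 15, PE 25, PG 25, PI 23, PS 23, LPG 23,
PA 29. LPC is not separately stated anywhere we could anchor it and
inherits the PC value — the one inferred entry in the table.

Deuterium labels of internal standards are assumed to sit on the
backbone/headgroup, so they are retained in every carboxyl-side
product; `d5-` prefixes parse accordingly. Negative-mode spectra of the
[M+N2O7]⁻ adduct are dominated by NO3⁻ (m/z 61.99) and carry no
position information; the package registers both the [M+N2O7]⁻ and
[M+N2O7–H]⁻ spellings of that adduct and defaults to the former rather
than adjudicating between them.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `ms1_tol_ppm` | 5 | ppm | match window for MS1 features at 30k resolution |
| `ms2_tol_ppm` | 10 | ppm | MS2 centroids are noisier than MS1 |
| `min_roles` | 2 | ions | a cleavage is called only when ≥2 of its class roles co-occur in a scan (2-of-2 for pairs, 2-of-3 for trios), guarding against single-peak noise |
| `min_scans` | 3 | scans | an event must recur across the elution profile |
| `probability_floor` | 0.01 | — | candidates below 1% score share are dropped before quantification |
| `prune_pct` | 1 | % | isomers projected below 1% relative abundance are pruned, then survivors renormalized once |
| `rt_window_min` | 0.5 | min | PRM scheduling half-window |
| `max_candidates` | 500 | — | above this, scores are reported without quantification (manual-curation regime) |
| `min_n`, `min_spacing` | 2, 2 | carbons | position legality: *n*-2 is the closest bond to the methyl end, and successive bonds must be ≥2 carbons apart, which still admits conjugated and non-methylene-interrupted patterns |

All of these live in `oznox_config()` and round-trip through JSON for
the command line.

## Candidate enumeration and scoring

Detected events are (p, u) pairs. A regioisomer candidate assigns each
chain exactly its double-bond count of events such that the k-th bond
(sorted by position) carries u = k−1 and positions respect the spacing
rule; for sum compositions (e.g. "PC 37:3") positions are enumerated on
a single pseudo-chain, which is how chain-unattributed position calls
are reported. Candidates whose expected-ion multisets coincide — two
chains swapping equal-length patterns — are merged with the chain
attribution marked ambiguous. The enumeration is validated against a
brute-force oracle (generate every legal pattern, keep those whose full
event set lies within the detected set) for all chains up to 22 carbons
and 3 double bonds.

The probability score is this package's own construction (the upstream
tool describes scan-by-scan probability scoring but not its formula):
per scan, a candidate earns coverage (fraction of its expected events
present) times purity (fraction of the scan's detected diagnostic
intensity it explains); scans are averaged weighted by their total
diagnostic intensity and the result normalized to sum to one over
candidates. The construction is invariant under uniform intensity
scaling, reduces to probability 1 for a candidate that alone explains
every ion, and degrades smoothly with missing events or foreign
intensity. It is validated by parameter recovery on simulations, not by
matching any external tool's scores. Replicate runs are merged by
intensity-weighted averaging of scores (`align_replicates()`), with
absent candidates contributing zero.

## Partitioning and quantification

Under the position-independence assumption — equal diagnostic-ion
yield per C=C wherever it sits — abundances follow from unique ions
when every surviving candidate owns at least one event no other
candidate expects; otherwise a 0/1 design matrix over expected events
is solved by non-negative least squares (Lawson–Hanson, via
`pracma::lsqnonneg`), with undetected expected events entering as
zeros. Pruning below 1% happens once, followed by one renormalization,
keeping the operation deterministic and order-independent. Position
independence is known to be only approximate for polyunsaturated PC,
where diagnostic intensity declines as the bond moves away from the
methyl end; the simulator exposes a `decline` factor precisely so that
robustness to that violation can be probed, but the quantification
model deliberately does not fit a decline.

Type I isotope correction divides areas by (1−0.0107)^nC using carbons
only (²H, ¹⁵N, ¹⁸O contributions are negligible at these masses and are
ignored). Absolute quantification is single-point against a
class-matched spiked standard; calibration-curve regression is out of
scope.

## The simulator, and what passing tests do not show

`simulate_run()` writes MS1 scans (precursor base adduct, derivatized
adduct at a configurable yield defaulting to the ~10% the chemistry
achieves, and per-cleavage aldehyde/Criegee products) and scheduled PRM
MS2 scans (class diagnostic ions per seeded isomer, intensity
proportional to amount × decline^rank), all Gaussian in retention time,
with optional log-normal intensity noise, Gaussian ppm jitter, and a
uniform additive baseline, from a single integer seed. Presets encode
the study's qualitative situations: the hexaunsaturated PC, the
mass-degenerate PE pair, seven coeluting FA 16:1 isomers (92.1% *n*-7,
6.9% *n*-9, five minors sharing ~1%), the LPC 22:4/18:1 coelution whose
*n*-15 aldehyde collides exactly with an LPC 18:1(*n*-11) aldehyde, and
a 75/25 LPC 18:1 recovery benchmark.

The simulator emulates peak positions, yields and noise — not
ozonolysis kinetics, isotope envelopes, detector saturation, or the
real co-isolation of near-isobaric precursors. Recovery of simulated
mixtures therefore demonstrates that the combinatorial logic, scoring
and partitioning are self-consistent and numerically correct under the
stated response model; it does not demonstrate instrument-level
accuracy on biological extracts, where ion yields, matrix effects and
chromatographic overlap are harsher.

Problem sizes were chosen for fast, deterministic test runs: scenarios
use one or two species over a ~0.5 min RT span at 0.02 min scan
spacing (about 20 MS2 scans per target), and the oracle-equivalence
sweep covers every legal single pattern plus sampled pattern unions for
chains of 6–22 carbons and 1–3 double bonds (a few thousand cases).

## Numerical choices

* m/z arithmetic includes the electron mass with the correct sign;
  monoisotopic element masses are fixed at 10 significant digits.
* Product-list de-duplication uses 1e−6 Da — only exact formula
  collisions merge.
* ppm match windows are boundary-inclusive; among several in-window
  peaks the most intense wins.
* RT intervals are half-open [start, end) minutes everywhere; a PRM
  scan eligible for several targets goes to the nearest precursor m/z.
* EIC areas are trapezoidal over RT; apex is the maximum-intensity
  scan.
* Profile-mode mzML is rejected rather than silently centroided.
* Saturated species, empty runs and all-pruned candidate sets return
  empty/flagged results instead of raising, except where the request is
  itself ill-posed (a derivatization adduct of a saturated lipid).

## Known limitations

Ether/plasmalogen chains, sphingoid bases and glycerolipids are not
parsed; cis/trans geometry is not resolved by the chemistry; negative
mode carries no position-diagnostic MS2 ions and is implemented only at
the precursor-adduct level; sn-position information is carried through
parsing but never used by mass logic, since cleavage masses are
sn-independent.
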