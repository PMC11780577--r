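# oznoxr

Annotation and quantification of lipid carbon–carbon double-bond (C=C)
regioisomers from LC-MS/MS runs in which lipids are derivatized in the
electrospray source by ozone and in-situ-generated nitrogen oxides.

## The problem

Lipids that share a class and acyl composition can still differ in where
their double bonds sit (e.g. palmitoleic-type FA 16:1(*n*-7) vs its
*n*-9 isomer, counting from the methyl terminus). Conventional
collision-induced dissociation cannot distinguish them. In-source
ozonolysis (OzESI) cleaves each C=C into an aldehyde whose mass encodes
the bond position, but those products appear at the MS1 level, where
coeluting lipids share product m/z and quantification becomes ambiguous.

When the ionization source contains nitrogen, oxygen and ozone, the
lipid secondary ozonide is captured by nitrogen dioxide into
nitrogen-oxide adducts: [M+N2O7]⁻ in negative mode (whose MS2 spectra
are dominated by NO3⁻ at m/z 61.99) and [M+NO4–H]⁺ in positive mode.
The positive adduct is a single-m/z ensemble over all C=C of the
molecule; mass-selecting it in a PRM experiment and fragmenting it
yields C=C-diagnostic product ions at the MS2 level, unambiguously tied
to their precursor. `oznoxr` implements the data processing around that
chemistry:

- **Mass bookkeeping.** A cleavage at position *n*-p with *u* double
  bonds closer to the methyl end changes the intact composition by
  −C~p~H~2p−2u~ + O; the carboxyl-side aldehyde keeps everything else,
  so its m/z is independent of which chain carried the bond. All adduct
  arithmetic is electron-mass corrected.
- **Class rules.** PC/LPC emit a product pair per C=C (aldehyde and
  loss of CHO); PE emits the pair with and without loss of its
  headgroup (141.0191); PG, PI, PS, PA and LPG emit the headgroup-lost
  pair, which makes classes with equal acyls converge to identical
  diagnostic m/z; LPE and FA emit trios (with loss of H2O, and for FA
  the ammoniated aldehyde). Per-class collision energies (NCE 10 for
  FA up to 29 for PA) populate PRM target lists.
- **Combinatorial chaining.** Detected (p, u) events are assigned to
  chains under the constraints that successive C=C sit at strictly
  increasing positions with at least two carbons spacing and that the
  k-th bond has exactly k−1 bonds below it. Candidates are scored scan
  by scan (coverage × explained-intensity purity, intensity-weighted)
  and normalized to probabilities.
- **Partitioning.** Signal is divided across surviving isomers by their
  unique diagnostic ions, or by non-negative least squares when ions
  are shared, assuming position-independent ion yield; isomers
  projected below 1% relative abundance are pruned. Type I ¹³C
  correction and single-point internal-standard quantification convert
  areas to concentrations.
- **Simulation.** A seeded synthetic-run generator emulates the
  acquisition (precursor, ~10% derivatization adduct yield, ozonolysis
  MS1 products, PRM MS2 diagnostics, Gaussian elution, ppm jitter,
  noise) with a known ground truth, so the whole pipeline is testable
  without instrument data.

## Worked example

Simulate LPC 18:1 as a 75/25 mixture of the *n*-9 and *n*-7 isomers and
annotate it:

```r
library(oznoxr)

sim <- simulate_run(preset_scenarios("lpc_18_1_mix"))
res <- annotate_run(sim$run, parse_annotations(
  tibble::tibble(annotation = "LPC 18:1", retention_time_min = 10)))
tidy(res)
#> # A tibble: 2 × 8
#>   annotation candidate     probability raw_relative relative_abundance basis      pruned n_scans_support
#>   <chr>      <chr>               <dbl>        <dbl>              <dbl> <chr>      <lgl>            <int>
#> 1 LPC 18:1   LPC 18:1(n-9)        0.75           75                 75 unique_ion FALSE               20
#> 2 LPC 18:1   LPC 18:1(n-7)        0.25           25                 25 unique_ion FALSE               20
```

Each row is one isomer of the queried lipid: `probability` is its
scan-by-scan score share, `relative_abundance` the percentage of the
lipid's signal assigned to it (here exactly the simulated 75/25), and
`basis` says the split used ions unique to each isomer. Theoretical
products are available directly, e.g. the diagnostic trio of oleic
acid:

```r
oznox_ms2_products("FA 18:1(n-9)")[, c("role", "formula", "mz")]
#>   role                   formula      mz
#> 1 ms2_aldehyde           C9H16O3  173.1172
#> 2 ms2_aldehyde_NH4       C9H19NO3 190.1438
#> 3 ms2_aldehyde_minus_H2O C9H14O2  155.1067
```

A command-line front end wraps the same functions:

```sh
inst/scripts/oznox simulate --preset fa_16_1_seven_isomers --out sim/
inst/scripts/oznox targets  --annotations annotations.tsv --out targets.tsv
inst/scripts/oznox annotate --run sim/run.tsv --annotations annotations.tsv --out report/
```

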