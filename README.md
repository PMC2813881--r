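# footprintr

Quantitative analysis of hydroxyl radical footprinting experiments on
structured RNAs, with cooperative Hill binding fits.

## The problem

Hydroxyl radicals generated by an Fe(II)-EDTA catalyst cleave the RNA
backbone roughly in proportion to solvent accessibility, so a
per-nucleotide cleavage profile is a map of which nucleotides face
solvent and which are buried. When a protein binds, cleavage drops at
its contact sites. High-throughput readouts (primer extension resolved
by capillary electrophoresis) turn one experiment into a
single-nucleotide-resolution profile of an RNA hundreds of nucleotides
long. `footprintr` implements the quantification conventions for this
kind of data:

- **Normalization.** Raw intensities are background-subtracted (the
  no-catalyst control channel measures reverse-transcription stops) and
  divided by the mean of the *reference set*: the 8% most reactive
  nucleotides after first excluding the top 2%. On the resulting 0 to
  ~1.5 scale, 1.0 is by construction the mean of the highly reactive
  nucleotides, and nucleotides at or below 0.5 (one-half the reference
  mean) are classified solvent inaccessible.
- **Difference mapping.** Protein-induced changes are read from
  bound-minus-free difference profiles: protections are negative,
  enhancements positive, and changes with |Δ| ≥ 0.2 normalized units
  (2-fold above typical replicate background) are called significant.
- **Motif assignment.** Significant calls are assigned to annotated
  structural elements, with special attention to GNRA tetraloop-receptor
  tertiary interactions (loop sequence G-N-R-A docking into the minor
  groove of a distal receptor helix). A protein that stabilizes such a
  motif leaves a three-part signature: protection of the tetraloop, of
  the receptor docking face, and of a receptor segment extending toward
  the RNA exterior.
- **Binding analysis.** Filter-partitioning titrations are fit to the
  cooperative Hill model

  fraction bound = *A* [P]ⁿ / ([P]ⁿ + *K*½ⁿ)

  by bounded multi-start nonlinear least squares, reporting *A*, the
  apparent Hill coefficient *n*, *K*½, and *R*².

A seeded synthetic-data module generates structure models with two
tetraloop-receptor motifs, two-channel cleavage profiles,
electropherogram-like peak trains with exponential signal decay, and
Hill binding curves, so the entire pipeline is testable end to end
without laboratory data.

## Worked example

```r
library(footprintr)

run <- run_pipeline(config = simulation_config(seed = 1))
run
#> <footprint_run> toy_bI3_like_540nt
#>   calls: 42 protections, 0 enhancements in 6 region(s)
#>   motif coverage: 100.0% of protections within/adjacent
#>   three-part signatures complete: 2/2 motif(s)

run$regions
#> # A tibble: 6 × 6
#>   region_id direction  start   end n_calls mean_magnitude
#>       <int> <chr>      <int> <int>   <int>          <dbl>
#> 1         1 protection    60    65       6          0.498
#> 2         2 protection   229   235       7          0.555
#> 3         3 protection   239   246       8          0.538
#> 4         4 protection   405   411       7          0.564
#> 5         5 protection   414   421       8          0.517
#> 6         6 protection   477   482       6          0.485
```

The six protected regions are exactly the two simulated footprints: the
L2 tetraloop (60-65 includes its closing pair), the two faces of its P8
receptor helix (229-246), the P5 receptor helix (405-421), and the L9
tetraloop (477-482). Both motifs show the complete three-part
signature:

```r
run$signatures
#> # A tibble: 2 × 5
#>   motif loop_protected receptor_protected extension_protected complete
#> 1 L2-P8 TRUE           TRUE               TRUE                TRUE
#> 2 L9-P5 TRUE           TRUE               TRUE                TRUE
```

Fitting a simulated titration (true *K*½ = 9.7 nM, *n* = 2.2,
measurement noise sd 0.02):

```r
d <- simulate_binding_curve(A = 0.95, n = 2.2, k_half = 9.7,
                            concentrations = hill_concentrations(12, 0.1, 3000),
                            noise_sd = 0.02, seed = 1)
fit <- fit_hill(d)
fit
#> <hill_fit> A = 0.964, n = 2.08, K1/2 = 9.97 nM, R^2 = 0.9992 (12 points)
glance(fit)
#> # A tibble: 1 × 6
#>       A     n k_half_nM r.squared converged  nobs
#> 1 0.964  2.08      9.97     0.999 TRUE         12
autoplot(fit)   # points + fitted curve on a log concentration axis
```

A single noisy 12-point curve recovers the generating parameters to
within a few percent; a Hill coefficient near 2 indicates cooperative
binding by at least two protein units.

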