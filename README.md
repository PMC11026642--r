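# ecmech

Quantitative analysis of decellularized lung extracellular matrix (ECM)
mechanics and imaging readouts, for researchers probing how aging and lung
inflation state change the micromechanical niche that engrafted cells
experience. The package covers the full analysis chain of an AFM + imaging
study of lung scaffolds measured at residual volume (RV, collapsed) versus
functional volume (FV, inflated) in young and aged animals:

- **AFM nanoindentation mechanics.** Each force–distance cycle is fit with
  the Hertz model for a rigid sphere indenting an elastic half-space,

  F = (4/3) · E/(1 − ν²) · √R · δ^{3/2},

  with the cantilever-compliance correction δ = (z − z₀) − F/k. The contact
  point z₀ is found by a joint residual search (linear pre-contact baseline
  + Hertz contact law, refit at every candidate), which stays robust at the
  sub-kPa moduli of soft ECM where the contact is gradual. Each curve also
  yields a hysteresis-based viscosity index (approach/withdrawal loop area
  ratio) and the pull-off adhesion force (magnitude of the most negative
  withdrawal force). Results aggregate replicate → point → region → animal,
  with group mean ± SE taken over animals.
- **ECM protein immunofluorescence.** Pixel intensities of each stain
  (collagen I, laminin, fibronectin) are profiled by Gaussian kernel
  density estimation; the profile reports the density peak, the normalized
  areas below/above the peak within a lower/upper threshold window, and
  the activated-pixel fraction, which is compared between age groups as a
  percent change with a two-sample t-test.
- **Recellularization imaging.** Nuclei are segmented by thresholding +
  8-connected labeling with a minimum-diameter artifact filter; Ki67
  proliferation is scored by dilation-based colocalization with the
  nuclear mask; live/dead viability is counted per field.
- **Statistics.** Pooled-variance t-tests and two-way (age × volume)
  factorial ANOVA with interaction, Type II sums of squares.
- **Synthetic data with known ground truth.** Generators for Hertz-type
  indentation curves (0.03 N/m lever, 5 µm bead, additive force noise,
  retract adhesion well, tunable hysteresis), fiber-textured intensity
  images with an exact activated fraction, and nuclei fields with known
  Ki67-positive and live fractions — so every stage is testable end to end
  without instrument data.

## Worked example

`run_demo()` builds a complete synthetic study — four age × volume groups
whose generating moduli and adhesion forces are set to realistic group
means (0.26–0.54 kPa, 1.0–2.3 nN) — and runs every analysis stage:

```r
library(ecmech)
demo <- run_demo(seed = 7)
demo
#> <ecm_demo> synthetic study, seed 7
#>
#> Group mechanics (mean +/- SE over animals):
#> # A tibble: 4 × 9
#>   age   volume     n E_Pa_mean E_Pa_se hysteresis_ratio_mean hysteresis_ratio_se
#>   <chr> <chr>  <int>     <dbl>   <dbl>                 <dbl>               <dbl>
#> 1 aged  FV         3      540.   0.220                 0.151           0.000111
#> 2 aged  RV         3      260.   0.158                 0.151           0.000511
#> 3 young FV         3      360.   0.184                 0.151           0.000333
#> 4 young RV         3      470.   0.157                 0.151           0.0000683
#>
#> Two-way ANOVA on per-animal Young's modulus:
#> # A tibble: 4 × 6
#>   term           sum_sq    df     mean_sq statistic   p_value
#>   <chr>           <dbl> <dbl>       <dbl>     <dbl>     <dbl>
#> 1 age           686.        1    686.         6940.  4.81e-13
#> 2 volume      21655.        1  21655.       218998.  4.87e-19
#> 3 age:volume 114350.        1 114350.      1156430.  6.26e-22
#> 4 Residuals       0.791     8      0.0989       NA  NA
#>
#> ECM protein comparisons (activated fraction):
#> # A tibble: 3 × 11
#>   protein  metric n_young n_aged mean_young mean_aged percent_change ...
#> 1 collagen activ…       4      4      0.400     0.476           19.0
#> 2 laminin  activ…       4      4      0.400     0.340          -15.0
#> 3 fibrone… activ…       4      4      0.400     0.460           15.0
```

The group means recover the generating moduli (e.g. 540 Pa for aged-FV)
within a fraction of a percent at 5 pN force noise; the dominant
age × volume interaction term says the effect of age on stiffness reverses
with lung volume, which is exactly how the ground truth was constructed
(young 0.47 → 0.36 kPa, aged 0.26 → 0.54 kPa from RV to FV). The ECM rows
recover the constructed +19 % (collagen-like), −15 % (laminin-like) and
+15 % (fibronectin-like) activated-fraction shifts.

Individual stages compose with the pipe:

```r
spec  <- curve_gen_spec(E_true = 470, adhesion_depth = 2.29e-9)
curves <- generate_curve_batch(spec, n_regions = 3, n_points = 3, n_replicates = 5)
results <- curves |> analyze_curve_batch()
results |> aggregate_hierarchy() |> tidy()
```

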