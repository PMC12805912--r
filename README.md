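# nichepart

Isotopic niche partitioning, individual specialisation and coexistence
mechanisms for repeated-measures stable-isotope data.

## What it does, and for whom

Trophic ecologists studying how similar sympatric species coexist often
measure δ¹³C and δ¹⁵N in several tissues of the same individual: each
tissue integrates diet over a different time window, so multi-tissue
sampling yields repeated measures of one individual's diet. `nichepart`
turns such tables into a variance decomposition of the bivariate isotopic
niche and posterior tests of coexistence mechanisms.

The core model, fitted per species × season group by Gibbs sampling, is the
bivariate linear mixed model

    y_it = X β + b_i + e_it,   b_i ~ N₂(0, G),   e_it ~ N₂(0, R)

with individual identity as a random intercept. The niche components are

* **WIC** = trace(R) — within-individual component,
* **BIC** = trace(G) — between-individual component,
* **TNW** = WIC + BIC — total niche width,
* **IS** = BIC/TNW — individual specialisation (computed per posterior
  draw, then summarised),

with inverse-Wishart priors on G and R and Gelman–Rubin convergence checks
across chains. Niches are drawn as 67% confidence ellipses on the total
covariance G + R; interspecific **directional overlap** (the fraction of
one species' ellipse covered by the other's) is computed at every posterior
draw by convex polygon clipping. Four coexistence mechanisms are scored as
posterior probabilities of directional differences: reduced interspecific
overlap in breeding (M1), higher IS in breeding (M2), larger TNW in
breeding (M3), larger WIC in breeding (M4).

Around the core, the package provides:

* within-tissue z-score standardisation with a stored, re-applicable
  transform;
* a synthetic-data generator mirroring the model, with a default
  two-cormorant study design (111 individuals in four species × season
  groups) whose ground truth is known — every stage is testable end to end;
* a phylogenetically weighted competition index
  `Nz = Σ N(z′) exp(−d²/(2σ²α))` from a community census and an ultrametric
  Newick tree (patristic distances max-normalised to [0, 1], σ²α = 0.05);
* prey richness and inverse Simpson diversity as ecological-opportunity
  indicators, with bootstrap seasonal contrasts.

## Worked example

Simulate the default study design (group sizes 25/18/31/37; true
niche-component traces set to the published posterior means, so the planted
pattern is the study's own) and run the whole pipeline:

```r
library(nichepart)
rec <- simulate_isotopes(default_study_design(), seed = 1)
ana <- niche_analysis(rec, mm_config(n_iterations = 6000, burn_in = 1500,
                                     thin = 5, n_chains = 2, seed = 1))
ana$metric_summary
#>    species    season       metric  mean     sd  q2.5 q97.5
#>  5 L_atriceps non_breeding BIC    2.02  0.712  1.00  3.77
#>  6 L_atriceps non_breeding IS     0.600 0.0958 0.399 0.775
#>  7 L_atriceps non_breeding TNW    3.30  0.710  2.27  4.98
#> 14 P_gaimardi non_breeding IS     0.347 0.0756 0.215 0.500
#> 15 P_gaimardi non_breeding TNW    1.28  0.170  1.00  1.65
#> ... (16 rows: 4 groups x 4 metrics)
```

The dispersive *L. atriceps* recovers a ~2.6-fold wider non-breeding TNW
than the resident *P. gaimardi* and a much higher IS (0.60 vs 0.35), and
the overlap is strongly asymmetric — the narrow resident niche sits almost
entirely inside the broad disperser niche, not conversely:

```r
ana$overlap_summary
#>   season       a          b          a_in_b_pct b_in_a_pct
#> 1 breeding     L_atriceps P_gaimardi       47.6       94.1
#> 2 non_breeding L_atriceps P_gaimardi       42.4       98.7

dplyr::select(ana$mechanisms, mechanism, label, probability)
#> 3 M2 P(IS_breeding > IS_non_breeding) [L_atriceps]  0.00333
#> 7 M4 P(WIC_breeding > WIC_non_breeding) [L_atriceps] 0.983
#> ... (8 rows)
```

The mechanism report recovers the planted seasonal story: *L. atriceps*'
individual specialisation collapses in breeding (M2 probability 0.003,
i.e. probability 0.997 for the decline) while its within-individual niche
expands (M4 probability 0.98).

`autoplot()` methods exist for standardised datasets, metric draws and
overlap distributions; `plot_niche_ellipses()` draws the fitted total and
within-individual ellipses.

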