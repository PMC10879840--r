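# mhcassoc

Tools for studying how parental MHC (major histocompatibility complex)
variation relates to reproductive success in wild bird populations with
biparental care. The package covers the full analysis chain used in
long-term barn-owl breeding studies:

* **Amplicon genotyping** — allele calling from per-amplicon variant-depth
  spectra with the Degree-of-Change and Threshold methods, chimera and
  non-functional-variant screening, method reconciliation and replicate
  reproducibility. Handles a co-amplified class I alpha amplicon (up to
  four alleles per bird) and the two class IIβ amplicons DAB1/DAB2.
* **Diversity summaries** — amino-acid p-distance and Grantham functional
  divergence between an individual's alleles, computed from residue
  composition, polarity and molecular volume:
  D(a,b) = ρ·[α(c_a−c_b)² + β(p_a−p_b)² + γ(v_a−v_b)²]^½ with the
  classical weights and ρ set so the 190 residue pairs average 100.
* **Supertypes** — clustering alleles on z-scale physicochemical
  descriptors of positively selected sites (k-means with BIC or silhouette
  k-selection, then a simplified discriminant re-assignment), population
  frequencies and per-individual presence.
* **Association models** — for clutch size (Poisson) and fledging success
  (binomial with clutch as trials): marginality-constrained sub-model
  enumeration over parental divergence terms, AICc ranking, ΔAICc ≤ 2
  retention, full model averaging with Burnham–Anderson unconditional SEs
  (`avg_glmm` objects with `print`/`summary`/`coef`/`confint`/`plot`
  methods); per-supertype presence/absence GLMMs with Benjamini–Hochberg
  correction and Tukey-style EMM contrasts; a cross-fostering mode that
  separates genetic-parent from social-parent effects.
* **A synthetic-data generator** that emulates the study system (allele
  pools with planted binding motifs, noisy amplicon spectra, cross-fostered
  nest records with injected effects), so every stage runs and is validated
  without external data.

Mixed models are fitted with `lme4`; EMM contrasts use `emmeans`; sequence
I/O uses `Biostrings`.

## A worked example

Simulate a genotyped population, inject a negative genetic-father effect on
fledging success, and run the cross-fostered model-averaging analysis:

```r
library(mhcassoc)

spec <- default_locus_specs()[["MHC-Ia"]]
pool <- generate_allele_pool(spec, seed = 11)
geno <- simulate_population(list(pool), n_individuals = 400, seed = 12)
div  <- divergence_table(geno, translate_alleles(pool))

eff <- effect_config(beta_div_genetic_father = -0.461)
nests <- simulate_breeding(geno, div, eff, n_nests = 250,
                           crossfoster_plan = "full",
                           effect_locus = "MHC-Ia", seed = 13)

avg <- run_divergence_analysis(nests, div, "MHC-Ia",
                               response = "fledging", mode = "crossfostered",
                               include_quadratics = FALSE,
                               include_interactions = FALSE)
avg
```

```
Model-averaged GLMM (full averaging over delta-AICc <= 2 set)
Candidates: 16, retained: 4

                    term estimate se_unc  ci_lo  ci_hi weight_sum significant
             (Intercept)    0.547  0.132  0.288  0.806      1.000        TRUE
      div_genetic_father   -0.442  0.137 -0.710 -0.174      1.000        TRUE
              mother_age   -0.192  0.127 -0.441  0.057      1.000       FALSE
              father_age    0.048  0.131 -0.209  0.305      1.000       FALSE
      laying_date_julian   -0.316  0.142 -0.594 -0.039      1.000        TRUE
 I(laying_date_julian^2)   -0.039  0.181 -0.394  0.316      1.000       FALSE
      div_genetic_mother   -0.020  0.048 -0.115  0.074      0.201       FALSE
       div_social_father   -0.013  0.039 -0.089  0.063      0.171       FALSE
       div_social_mother    0.015  0.042 -0.067  0.096      0.175       FALSE
```

The genetic father's standardized divergence slope is recovered at −0.442
(injected truth −0.461) and flagged significant — its 95% interval excludes
zero and it appears in every retained model (`weight_sum` 1). The other
parents' divergence terms carry no injected effect: they enter only some
competing models and shrink toward zero under full averaging. Estimates are
on the logit scale per 2 SD of divergence; covariates (ages, laying date)
are present in every model by design.

The same machinery runs end to end — simulate, genotype, diversify,
supertype, associate — via a single configuration object:

```r
report <- run_pipeline(run_config(seed = 1, n_individuals = 200,
                                  n_nests = 300, loci = "DAB2",
                                  responses = "fledging",
                                  include_quadratics = FALSE,
                                  include_interactions = FALSE))
report
```

A thin command-line wrapper is installed at
`inst/scripts/run_pipeline.R` (`Rscript run_pipeline.R --config cfg.yaml
--out-dir out/ --seed 1`).

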