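# paradiv

Functional-divergence analysis between paralogous gene clusters, for
molecular evolution and drug-target selectivity work.

After a gene duplication, the two descendant genes accumulate orthologs in
each lineage. Two kinds of divergence between the duplicate clusters are
informative about which residues tell the paralogs apart:

* **Type-I divergence** — a shift in the site-specific evolutionary rate: a
  residue is conserved in one cluster's orthologs but variable in the
  other's.
* **Type-II divergence** — a radical shift in a residue's physicochemical
  property on the branch between the duplicates, with the residue conserved
  within each cluster afterwards (e.g. fixed hydrophobic in one paralog's
  orthologs, fixed hydrophilic in the other's).

For drug targets with close paralogs — the worked example mirrors the
glucagon receptor (GCGR) vs the glucagon-like-peptide-1 receptor (GLP-1R),
both antidiabetic GPCR targets — type-II sites are candidate *selectivity
filters*: positions a ligand can exploit to bind one paralog but not the
other.

## The model

Sites are independent. Each site carries a relative rate
λ ~ Gamma(α, α) (mean 1). Per cluster *i* the within-cluster substitution
count is x_i | λ ~ Poisson(λ m_i), observed by Fitch parsimony on the
cluster subtree of a neighbor-joining tree built from Poisson-corrected
distances (d = −ln(1 − p)).

**Type-I.** With probability θ_I a site is rate-decoupled: its two cluster
rates are independent gamma draws; otherwise one λ is shared. Integrating
λ gives closed forms — a bivariate negative binomial f0 under sharing, a
product of negative binomials f1 under decoupling — and the likelihood
Σ_k log[(1−θ)f0_k + θf1_k] is maximised over (θ_I, α, m1, m2).

**Type-II.** The inter-cluster ("early") phase is summarised per site by
the change class between the two cluster-root residues inferred by Fitch
parsimony: `N` (no change), `C` (conserved: within one of the four
physicochemical groups K/R/H, D/E, S/T/N/Q/C/G/P, A/I/L/M/F/W/V/Y), or `R`
(radical: across groups). Under no divergence an early change fires with
probability 1 − e^(−λ d_e) and is radical with the scheme's neutral
probability π_R = 137/190; under type-II divergence (probability θ_II) the
early change is radical with certainty and the late-phase rates shrink by
a conservation factor ε. The gamma rate integrates analytically — no
discretisation.

Both fits report θ ± SE (observed information), a boundary-corrected LRT
against θ = 0 (50:50 mixture of a point mass and χ²₁), per-site posteriors
Q(k) with posterior ratios R(k) = Q/(1−Q), and divergent-site calls at the
conventional cutoff Q(k) > 0.67 (R > 2). Called sites can be screened for
the canonical type-II conservation pattern and tested for enrichment
within drug binding-site lists (Pearson chi-square without continuity
correction, or Fisher's exact test).

A synthetic-data generator (`simulate_family()`) emits duplicated-family
alignments with known θ_I, θ_II, per-site truth tables and the generating
tree, so every estimator is testable without downloads.

## Worked example

```r
library(paradiv)

# a simulated duplicated family: 8 + 8 orthologs, 1000 sites,
# true theta_II = 0.236
fam  <- simulate_family(sim_config(L = 1000, theta2 = 0.236, seed = 42))
mask <- build_site_mask(fam$alignment, fam$clusters)
tab  <- build_count_table(fam$alignment, fam$tree, fam$clusters, mask)

fit <- fit_type2(early_profile(tab))
fit
#> <divergence_fit> Type-II (property shift)
#>   theta = 0.2170 +/- 0.0166  (n = 1000 sites)
#>   logL = -3009.266  (null -3127.021)  LRT = 235.510  p = 1.87e-53
#>   nuisance: alpha = 1.105, m1 = 0.8172, m2 = 0.8592, d_e = 0.6451

post   <- type2_posteriors(early_profile(tab), fit)
called <- call_divergent_sites(post, cutoff = 0.67)
nrow(called)
#> [1] 235
autoplot(post)   # needle plot of Q_II(k) with the 0.67 cutoff line
```

The estimate recovers the generating coefficient (0.217 vs 0.236) and the
LRT firmly rejects θ_II = 0; 235 of 1000 sites exceed the 0.67 posterior
cutoff (the truth table `fam$truth` marks 243 sites as type-II). `tidy(fit)` and `glance(fit)` return the
estimates as tibbles; `run_divergence()` executes the whole pipeline from
files and writes a report bundle (mask, tree, count table, estimate JSONs,
site profiles, called sites, optional enrichment).

Enrichment of published type-II residues of the glucagon receptor among
the 12 MK-0893 binding sites:

```r
divergent <- c(34, 150, 291, 337, 345, 387, 405, 427)
binding <- read_binding_sites(system.file(
  "extdata", "mk0893_binding_sites_synthetic.tsv", package = "paradiv"))
enrichment_test(divergent, binding, total_length = 477)
#> <enrichment_result> chisq test
#>          binding
#> divergent yes  no
#>       yes   2   6
#>       no   10 459
#>   chi-square = 16.77, p = 4.214e-05
#>   odds ratio = 15.3
#>   Fisher exact p = 0.01496
#>   note: expected cell count < 5; consider the Fisher exact test
```

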