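# kinMMRR

Individual-based tests for **isolation by distance (IBD)**, **isolation by
environment (IBE)** and **isolation by community (IBC)** in continuous plant
(or animal) populations genotyped with dominant binary markers such as AFLPs.
It is written for landscape geneticists who have, per individual: a 0/1
band-presence matrix, GPS coordinates, a set of mapped environmental
variables, and a vegetation-association label with known co-occurring
species.

## The method

Pairwise kinship is estimated from the dominant phenotypes under
Hardy–Weinberg equilibrium: band frequency *f* gives the presence-allele
frequency *p* = 1 − √(1 − *f*), band carriers get expected dosage 1/(2 − *p*),
and a Loiselle-type moment estimator referenced to sample frequencies yields

> F<sub>ij</sub> = Σ<sub>l</sub> [(x<sub>il</sub> − p<sub>l</sub>)(x<sub>jl</sub> − p<sub>l</sub>) + c<sub>l</sub>] / Σ<sub>l</sub> p<sub>l</sub>(1 − p<sub>l</sub>)

with a small-sample correction c<sub>l</sub> that centres the estimator
exactly (mean off-diagonal kinship 0 on panmictic data).

The kinship matrix is then regressed on explanatory distance matrices —
geographic (haversine), environmental (per variable, or one PCA-combined
Euclidean metric), and community (Jaccard dissimilarity of association
species sets) — by **multiple matrix regression with AICc model averaging**:
every subset of the predictors is fitted by OLS on the unfolded,
standardized pair vectors, and each term's coefficient is averaged over the
submodels containing it with Akaike weights, carrying an unconditional
standard error. Significance requires both a 95% CI excluding zero and a
Mantel-style permutation test (the kinship matrix's rows/columns jointly
permuted, the full averaging re-run per permutation) passed at FDR 0.05
(Benjamini–Hochberg). Negative significant terms are classified
`isolation`, positive ones `counter-gradient`.

Two designs are built in — a *three-matrix* analysis (geography, combined
environment, community) and a *twelve-matrix* analysis (geography, each
variable separately after VIF > 5 screening, community) — plus
`compareModes()` to tabulate where amalgamating environmental variables
changes the conclusions.

A fully controllable synthetic-data generator (spatial genetic fields,
environmental effects, association-level effects, wind-aligned
counter-gradient dispersal) makes every stage testable without field data;
see the methods vignette (`vignettes/model-averaged-matrix-regression.Rmd`).

## Worked example

```r
library(kinMMRR)

cfg  <- simulationConfig(gammaG = 0.5, seed = 7)  # an IBD-only world
ds   <- simulateDataset(cfg)
geno <- dropMonomorphic(ds$genotypes)
run  <- runAnalysis(geno, ds$samples, ds$lookup, mode = "three",
                    B = 1000, seed = 7)
run
```

```
mmrrRun 'run1' (three-matrix mode): 60 individuals, 196 loci, B = 1000
            predictor estimate     se   ci_lo   ci_hi        p     q
            geography -0.16522 0.0235 -0.2112 -0.1192 0.000999 0.003
 environment_combined  0.00989 0.0241 -0.0374  0.0572 0.589411 0.589
            community -0.03180 0.0237 -0.0783  0.0147 0.169830 0.255
 significant_final direction
              TRUE isolation
             FALSE      none
             FALSE      none
```

The dataset was simulated with a spatial genetic field only, and the
analysis recovers exactly that: the geography coefficient (−0.165 in units
of kinship standard deviations per standard deviation of geographic
distance) is negative with a CI excluding zero and permutation p ≈ 0.001,
so geography is classified `isolation`; the environmental and community
terms stay at `none`. Effect sizes are comparable across runs because both
response and predictors are standardized.

Real data enter through delimited text: `readGenotypes()` (individuals ×
loci, 0/1/blank), `readSampleTable()` (id, lon, lat, association, one column
per environmental variable), `readAssociationLookup()` (association,
species long format) and `readAsciiRaster()`/`extractAtPoints()` for ESRI
ASCII grids. `filterLociByReplicates()` applies the replicate-mismatch
scoring-error filter before analysis. A thin command-line wrapper lives in
`inst/scripts/mmrr-pipeline.R` (subcommands `simulate` and `run`).

## Acceptance script

`scripts/acceptance.R` re-runs the package end to end from scratch: it
simulates one dataset per isolation mechanism (IBD, IBE, IBC at the
calibrated strong settings), runs both the three- and twelve-matrix analyses
with 1000 permutations each, reports the class assignments and their
concordance across designs, and writes the results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
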