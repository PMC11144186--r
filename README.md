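# famdpc — unsupervised protein family discovery by density peak clustering

`famdpc` discovers putative protein domain families from nothing but an
all-versus-all local-alignment table. It is aimed at sequence
catalogues — metagenomic protein sets in particular — where large
fractions of the proteins carry no family annotation and
reference-profile methods have nothing to match against.

## The method in brief

For each query protein $Q$, the aligned regions hitting it are
clustered by the overlap of their query footprints under the distance

$$d^Q_{ij} = 1 - \frac{|Q_i \cap Q_j|}{|Q_i \cup Q_j|},$$

using density peak clustering (DPC): 0 for identical footprints, 1 for
disjoint ones. The resulting *primary clusters* segment each query
into domain-like stretches. Primary clusters from different queries
are then clustered again — the distance between two of them is one
minus the number of members they share (subject regions with Jaccard
overlap > 0.8, matched one-to-one) normalised by the smaller cluster —
giving *metaclusters*, the putative families. Metaclusters at average
distance < 0.9 are merged (connected components), near-duplicate seeds
are collapsed, and the release filter keeps metaclusters with > 50
seeds and mean seed length > 50 aa. Seeds are finally pruned at 60%
identity for hand-off to external MSA/profile-HMM tools (`mafft`,
`hmmbuild`/`hmmsearch` wrappers included; search hits kept at domain
E-value ≤ 0.03 and protein E-value ≤ 0.01).

Validation analytics compare each metacluster against reference domain
annotations (dominant architecture, four nested match percentages, the
equivalent/reduced/extended/shifted overlap classes), label
metaclusters by residue composition (low-complexity/coiled-coil > 10%,
disordered > 50%, mean transmembrane segments ≥ 2), compute residue and
sequence coverage, and fit a generalized-Pareto tail to the family-size
CCDF by maximum likelihood.

A synthetic proteome generator with planted families and a built-in
Smith–Waterman aligner (Rcpp, affine gaps, BLOSUM62) lets the whole
pipeline run and be validated end to end with no downloads and no
external tools.

## Worked example

```r
library(famdpc)

design <- planted_design(n_families = 3, n_proteins = 30, seed = 1)
world  <- generate_proteome(design)
res    <- run_pipeline("out", world$proteins,
                       annotations = world$annotations,
                       tracks = world$tracks)
planted_recovery_score(res$metaclusters, world$truth)[c("ari", "family_recall")]
#> $ari
#> [1] 1
#> $family_recall
#> [1] 1

res$comparisons[, c("mc_id", "DA", "Percent_DA", "Label", "Fred", "Fext")]
#>    mc_id DA Percent_DA      Label        Fred      Fext
#> 1 MC0001 F3        100 equivalent 0.005113636 0.1671355
#> 2 MC0002 F2        100 equivalent 0.001994018 0.1278456
#> 3 MC0003 F1        100 equivalent 0.001457726 0.1318532

round(res$coverage, 2)
#>  residue_coverage sequence_coverage
#>             88.26            100.00
```

Reading this: the three planted families are recovered exactly
(adjusted Rand index 1, every family is the majority of one
metacluster). Every metacluster's dominant reference architecture is
held by 100% of its seeds; `Fred` ≈ 0 says the reference domains are
fully covered and `Fext` ≈ 0.13–0.17 says the seeds overhang the
planted boundaries by some 15% (local alignments run slightly past
domain ends), within the 0.2 band of the *equivalent* class. Seeds
cover 88% of all residues and every protein. The `out/` directory
holds every stage artifact: alignment table, primary-cluster and
metacluster TSVs, merge log, per-metacluster seed and pruned-seed
FASTAs, the comparison and property tables, the metacluster XML and a
run log with per-stage counts.

A command-line front end with one subcommand per stage lives at
`inst/cli/famdpc.R`:

```sh
Rscript inst/cli/famdpc.R synth --out world --families 3 --proteins 30 --seed 1
Rscript inst/cli/famdpc.R run --fasta world/proteins.fasta \
    --ann world/annotations.tsv --tracks world/tracks.tsv --out out
```

## Documentation

The methods vignette
(`vignettes/family-discovery-methods.Rmd`) describes the model, every
tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, tie-break and degenerate-input
conventions, and known limitations.
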