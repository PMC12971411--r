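# panfam

Pan-genome evolution analysis for plant gene families in R.

Gene families such as the UDP-glycosyltransferases (UGTs) — the enzymes
that glycosylate flavonoids, terpenoids and hormones and thereby shape
crop quality traits — vary strikingly between the genomes of a single
species. A pan-genomic view asks, across a collection of N genomes: which
orthogroups are **core** (present in all genomes), **soft-core**
(≥ 90% but not all), **dispensable**, or **private** (one genome)? Which
duplication mechanism produced each homologous pair — whole-genome
duplication (WGD), tandem (TD), proximal (PD), transposed (TRD) or
dispersed (DSD), assigned under the priority cascade
WGD > TD > PD > TRD > DSD? What selection pressure do the copies
experience (Ka/Ks by the Nei–Gojobori 1986 method, with Ka/Ks > 1
indicating positive and < 1 purifying selection)? Do structural variants
(SVs) in or near a gene (± 2 kb) shift its expression across genomes
(point-biserial correlation, p < 0.05)? And does a genome's family gene
count predict its total expression dosage (Pearson r of count versus
log2 total TPM)?

panfam implements that entire workflow as composable R functions plus a
one-call pipeline, and ships a synthetic pan-genome generator with a full
ground-truth table, so the whole analysis runs and is tested offline — no
genome downloads, no external aligners. Inputs, when you bring your own
data, are standard formats: GFF3, FASTA, OrthoFinder `Orthogroups.tsv`,
HMMER domtblout tables, BLAST outfmt-6 tables, VCF with per-sample depth,
and counts TSVs.

## Worked example

Run the complete pipeline on a simulated 10-genome pan-genome:

```r
library(panfam)
run <- run_pipeline(list(seed = 1))
print(run$report)
#> == pan-genome family report ==
#> family genes: 304 (atypical 25, typical 279)
#> orthogroups: 36
#>   core         12 (33.3%)
#>   soft-core     4 (11.1%)
#>   dispensable  16 (44.4%)
#>   private       4 (11.1%)
#> duplication pairs: 55
#>   WGD     5 (9.1%)
#>   TD      4 (7.3%)
#>   PD     12 (21.8%)
#>   TRD     2 (3.6%)
#>   DSD    32 (58.2%)
#> selection classes: positive 50, purifying 255, neutral 0, NA 1
#> structural variants kept: 30; significant SV-associated gene-tissue pairs: 9
#> dosage correlation (bud): r = 0.816, p = 0.00397 (n = 10)
#> dosage correlation (young_leaf): r = 0.799, p = 0.005604 (n = 10)
#> saturation: pan 24.59 -> 36, core 24.59 -> 12 over 10 genomes
```

Reading this: 304 genes passed the identification filters (domain E-value
≤ 1e-5, best reference identity > 50%), of which 279 carry the 44-residue
PSPG motif ("typical"). They fall into 36 orthogroups whose category
shares are shown with half-up one-decimal percentages. Of 55 intra-genome
homologous pairs, the five planted WGD pairs were recovered as collinear-
block anchors; the remaining shares reflect the planted tandem/proximal/
transposed events plus incidental copy-number pairs, which scatter into
DSD. Most cross-genome pairs are under purifying selection (the
generator's ω grid is mostly < 1); one pair is NA because its synonymous
divergence is zero. Both tissues show a significant gene-count/dosage
correlation, as expected when expression dosage accumulates over family
members. The saturation line summarises the pan (union) and core
(intersection) orthogroup curves over 100 random genome orderings.

Individual stages are plain functions if you want the pieces:

```r
est <- ng86_pair(simulate_codon_pair(300, omega = 0.5,
                                     branch_length = 0.3, seed = 1))
print(est)
#> NG86 estimate over 300 codons: Ka = 0.1447, Ks = 0.2342, Ka/Ks = 0.6177 (purifying)

classify_og(c(22, 20, 19, 1), n_genomes = 22)
#> [1] "core"        "soft-core"   "dispensable" "private"
```

(see `?classify_og`, `?chain_collinear`, `?classify_duplications`,
`?associate`, `?tpm`, `?generate_pangenome` and the methods vignette in
`vignettes/panfam-methods.Rmd` for the full surface).

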