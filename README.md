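# cdsannot

Fast, taxon-independent functional annotation of bacterial protein-coding
genes, built around **alignment-free sequence identification (AFSI)**: most
proteins in a newly assembled bacterial genome are byte-identical to
sequences already in public databases, so `cdsannot` identifies them by the
MD5 digest of the full-length amino-acid sequence (guarded by a
length-equality check against hash collisions) and only aligns the
remainder. Identification this way is exact, assigns stable public database
cross-references (UniRef100/UniRef90/UniRef50, RefSeq, COG, EC, GO), and
skips the pairwise alignments that dominate conventional annotation
runtimes.

The package is aimed at people building or studying annotation pipelines:
it implements the full CDS-annotation core — database compiler, annotation
engine, structural refinements, standard-format exports — as composable,
pipe-friendly R functions over tibbles, plus a deterministic synthetic-data
generator that plants genes with known coordinates and expected annotation
tiers for end-to-end validation.

## The method

Annotation evidence is gathered in tiers of decreasing precision over a
UniRef-style cluster hierarchy compiled into a single-file SQLite store:

1. **AFSI** — the protein's MD5 digest is looked up among the *unique
   protein sequences* (UPS); a hit requires equal sequence length and
   resolves to the UniRef100-level *identical protein sequence* (IPS) record
   and, via stored links, the preassigned cluster annotation. No alignment.
2. **Cluster homology** — AFSI misses are aligned against UniRef90-level
   *protein sequence cluster* (PSC) representatives. Hits need mutual
   coverage ≥ 80%; identity ≥ 90% assigns the PSC, identity in [50%, 90%)
   falls back to the UniRef50-level *cluster of clusters* (PSCC).
3. **Expert rules** — curated reference proteins with per-rule
   identity/coverage thresholds and priority ranks refine annotations of
   closely related proteins that clusters cannot separate.

Concluding annotation takes tier precedence `expert > ips > psc > pscc`,
fills gene/product gaps from lower tiers, unions dbxrefs, and marks
evidence-free proteins as hypothetical (characterized by molecular mass and
isoelectric point). The structural stage merges origin-spanning partial CDS
pairs on complete circular replicons, recovers small ORFs (7–29 aa) that
gene callers skip, and filters known spurious sequences through a pluggable
blocklist backend.

See `vignettes/methods.Rmd` for the full model, parameter rationale, and
limitations.

## Worked example

Everything below is generated — no external data needed. Build a toy
reference store with known cluster structure, plant genes in a synthetic
circular chromosome, and annotate it:

```r
library(cdsannot)

ref <- gen_reference(seed = 42)       # 20 clusters x 3 members + 5 small proteins
db  <- build_fixture_db(ref)
db
#> <ref_db> schema 1.0 | 65 UPS, 65 IPS, 20 PSC, 10 PSCC, 2 expert rules, 2 blocked digests

gen <- gen_genome(ref, seed = 1, n_exact = 50, n_mut_psc = 20,
                  n_mut_pscc = 20, n_sorfs = 10, n_sorf_known = 5)
ann <- annotate_genome(gen$genome, db)
ann
#> <genome_annotation> 672 features (543 CDS, 129 sORF) | AFSI-resolved: 55 | alignments: 73
#> tiers: expert=0, ips=55, psc=20, pscc=20, hypothetical=577
```

The 50 planted exact-copy genes and the 5 stored small proteins are all
identified alignment-free (`AFSI-resolved: 55`, zero alignments for them);
the ~95%-identity mutants land on the PSC tier and the ~70% mutants on the
PSCC tier, each judged by measured alignment identity against the cluster
representative. The remaining features are incidental ORFs from the
synthetic background and reverse strands, annotated as hypothetical
proteins. Results are tibbles throughout:

```r
tidy(ann) |>
  dplyr::filter(tier != "hypothetical") |>
  dplyr::select(locus_tag, feature_class, start, stop, strand, gene, product, tier)
#> # A tibble: 95 × 8
#>   locus_tag  feature_class start  stop strand gene   product               tier
#>   <chr>      <chr>         <int> <int> <chr>  <chr>  <chr>                 <chr>
#> 1 CDSA_00003 cds             197   893 +      <NA>   S006 family protein   pscc
#> 2 CDSA_00011 cds             950  1409 +      <NA>   S001 family protein   pscc
#> 3 CDSA_00017 cds            1465  2119 -      gen007 synthetic enzyme 007  ips
#> 4 CDSA_00024 cds            2170  2824 +      gen007 synthetic enzyme 007… ips
#> # …
```

`glance(ann)` gives the one-row run summary, `autoplot(ann)` the tier
composition per replicon, and the writers export GFF3
(origin-spanning genes as two lines sharing one ID), a versioned JSON result
document that round-trips the full model, feature/protein FASTA, and the
feature-summary and hypothetical-protein TSVs:

```r
write_gff3(ann$features, gen$genome, "out.gff3")
write_result_json(ann, "out.json")
```

A thin command-line wrapper (`inst/cli/cdsannot`) exposes the two
workflows as `cdsannot build-db …` and `cdsannot annotate …`; see
`?cli_build_db` and `?cli_annotate`.

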