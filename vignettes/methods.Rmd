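---
title: "Alignment-free identification and hierarchical annotation of bacterial CDS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free identification and hierarchical annotation of bacterial CDS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdsannot)
```

## The problem

Functional annotation of a bacterial genome assigns each protein-coding gene
a product name, a gene symbol where one is known, and stable cross-references
into public databases. The dominant cost in conventional pipelines is
pairwise sequence alignment of every predicted protein against a large
reference collection. Yet a large fraction of proteins in newly sequenced
bacterial genomes are *byte-identical* to sequences already deposited in
public databases, so most of those alignments re-discover an exact match the
hard way.

`cdsannot` implements the core of an annotation engine built around that
observation. Exact matches are found without alignment, by **alignment-free
sequence identification (AFSI)**: the MD5 digest of the full-length amino
acid sequence is looked up in a precompiled store, and a hit is accepted only
if the stored protein length equals the query length. Only proteins that
miss this exact-identity layer proceed to alignment-based homology search.

## The annotation hierarchy

The reference store is a four-tier hierarchy mirroring the UniRef clustering
levels:

| tier | level | keyed by | carries |
|------|-------|----------|---------|
| UPS  | unique protein sequence | 16-byte MD5 digest | length, external ids |
| IPS  | UniRef100 | `UniRef100_*` | gene, product, UniRef90 link |
| PSC  | UniRef90 | `UniRef90_*` | representative sequence, gene, product, COG/EC/GO, UniRef50 link |
| PSCC | UniRef50 | `UniRef50_*` | coarse product |

An AFSI hit resolves a protein to its IPS and, through the stored links,
inherits the preassigned PSC and PSCC annotation by id lookup — still
without any alignment. AFSI misses (for CDS only, see below) are aligned
against the PSC representative sequences. Hits must reach **mutual coverage
of at least 80%** (both query and subject); among those, **identity of at
least 90%** assigns the protein to the PSC, and identities **between 50 and
90%** fall back to the coarser PSCC. All thresholds are inclusive on the
accepting side: identity exactly 0.90 is a PSC assignment and exactly 0.50 a
PSCC assignment. Below 50% identity the protein remains unassigned.

On top of the cluster route sits an **expert-rule system**: a set of curated
reference proteins, each with its own identity and coverage thresholds and a
priority rank. A rule whose alignment against the query passes all three of
its thresholds is eligible; the highest-ranked eligible rule wins (ties break
by higher identity, then rule id). Expert rules exist to discriminate closely
related proteins that a UniRef90 cluster lumps together, so the expert tier
outranks all cluster-derived evidence. The final precedence is

```
expert > ips > psc > pscc
```

with the gene and product taken from the most specific tier providing them,
lower tiers filling gaps, and database cross-references unioned across all
tiers. A feature with no informative product from any tier is annotated
`hypothetical protein` and characterized by molecular mass and isoelectric
point.

## Hash collisions

MD5 is used for its speed and short digests. A false identification requires
two distinct proteins with equal digests *and* equal lengths; the length
check is the runtime guard. At build time digest uniqueness is checked
outright and a collision between distinct sequences aborts the build naming
both records. At annotation time a digest match with a length mismatch is
never resolved to the stored record: it is logged as a potential collision
and the protein continues down the homology route.

## Structural stage

CDS coordinates are either ingested from GFF3 (the intended production path,
fed by an external gene caller) or produced by the built-in naive ORF caller,
a plain maximal-ORF enumerator: every ORF from a start codon (ATG/GTG/TTG,
translation table 11) to the nearest in-frame stop, longest ORF per stop,
both strands, at least 30 residues by default. It has no statistical gene
model and will over-call on real genomes; it exists so the engine runs
self-contained.

Two structural refinements matter:

* **Origin-spanning genes.** On a complete circular replicon, a gene that
  spans the arbitrary linearization point is predicted as two partial CDS:
  one running off the sequence end, one off the start, on the same strand.
  Such pairs are merged into a single feature whose nucleotide sequence is
  concatenated across the origin, provided the merged sequence has a length
  divisible by three and translates without internal stops; otherwise both
  partials are kept. Only fragments whose partial ends sit exactly on the
  sequence edges are candidates; the merge never occurs on linear or
  incomplete replicons, or across strands.
* **sORFs.** Proteins shorter than 30 residues sit below the length cut-offs
  of de novo gene callers, so they are recovered by exhaustive six-frame
  scanning in a 7–29 residue window (both bounds configurable; the upper
  bound is exclusive). sORF candidates are deduplicated by coordinates and
  are subject to the same AFSI layer as CDS. sORF AFSI *misses* are **not**
  routed to cluster alignment: against full-length cluster representatives a
  peptide of fewer than 30 residues cannot reach the 80% mutual-coverage
  gate, so the alignment would be vacuous; unidentified sORFs go straight to
  the hypothetical route.

Known spurious sequences (e.g. shadow ORFs) are removed by a pluggable
predicate backend before identification; the default backend flags proteins
whose digest appears on a blocklist shipped with the database. Profile-HMM
based filtering is out of scope here, but any `function(aa) -> logical` can
be plugged in; a backend failure aborts the run rather than silently
skipping the filter.

### Circular scanning

Internally the ORF scan of a circular replicon uses three tandem copies of
the sequence and keeps only ORFs whose start codon lies in the middle copy.
Every such ORF then sees its complete upstream context (the previous
in-frame stop, wherever it sits on the circle), which makes the reported ORF
set a function of the circle itself: rotating the origin changes
coordinates but never the set of encoded proteins. Origin-spanning features
are represented internally as a single feature with `edge = TRUE` and a stop
coordinate beyond the replicon length; writers convert to the two-line GFF3
representation (two locations sharing one `ID`), which strict validators
accept.

## Coordinates and conventions

All internal coordinates are 0-based and half-open on the forward strand;
conversion to GFF3's 1-based inclusive convention happens only in writers.
Proteins never carry a terminal stop symbol; canonicalization uppercases,
strips a single trailing `*`, and rejects internal stops. The translation
table is fixed to the bacterial/archaeal code (table 11) with ATG/GTG/TTG
initiators rendered as methionine; the parameter is exposed but no other
table is implemented. Ambiguity residues (X, B, Z, J, U, O) are legal and
participate in digests verbatim, so digests are reproducible from reference
FASTA bytes; selenocysteine- or pyrrolysine-containing references are
digested as-is.

## Tunable parameters

| parameter | default | meaning |
|-----------|---------|---------|
| `min_coverage` | 0.80 | mutual query/subject coverage gate for cluster hits |
| `psc_identity` | 0.90 | identity at or above which a hit is a PSC assignment |
| `pscc_min_identity` | 0.50 | lower identity bound for PSCC fallback |
| `cds_min_aa` | 30 | minimum protein length for the naive ORF caller |
| `sorf_min_aa` / `sorf_max_aa` | 7 / 30 | sORF window (upper bound exclusive) |
| `top_n` | 50 | candidate representatives aligned per query |
| `kmer_k` | 5 | k-mer size for candidate preselection |
| `expert_min_kmers` | 5 | shared k-mers required before aligning an expert rule |
| `max_sorf_overlap` | 10 bp | tolerated sORF/CDS overlap |

The sORF upper bound deserves a note: "small protein" is defined here as
*shorter than 30 residues*, i.e. at most 29, and the bound is exposed
because the literature is not unanimous about whether the cut sits at 29 or
30. The lower bound of 7 residues is this package's choice: with no lower
bound the six-frame scan floods the candidate set with 1–6 residue ORFs that
no downstream evidence could ever support.

The production system this package models delegates homology search to a
seeded aligner over tens of millions of representatives. At package scale the
built-in aligner is a global alignment with free end gaps (unit
match/mismatch scoring, gap open 2 / extend 1), with identity defined as
matches over alignment columns and coverage as the aligned span over the
full sequence length. Candidate preselection by shared 5-mer count (top 50)
keeps the number of alignments per query small; the `aligner` config slot
accepts any replacement with the same interface. The same k-mer gate is
applied before aligning expert rules (with exact sequence equality
short-circuiting alignment entirely), so a protein already identified by
digest and unrelated to any rule sequence performs no alignments at all —
the run summary's `resolved_without_alignment` counts exactly these AFSI
resolutions, and `alignments_performed` counts cluster-search alignments.

## Product refinement and characterization

Product names pass a deterministic rewrite chain: whitespace is trimmed and
collapsed, one pair of wrapping quotes is stripped, a trailing `homolog`
token or `-like protein` suffix is dropped when a named protein remains, and
the spelling `uncharacterised` is normalized to `uncharacterized`. Products
equal (case-insensitively) to `hypothetical protein`,
`uncharacterized protein`, `putative protein` or
`conserved predicted protein` are treated as uninformative and normalized to
`hypothetical protein` at tier-assignment time — an AFSI-identified protein
can therefore legitimately be a hypothetical protein with cross-references.

Hypothetical proteins are characterized by molecular mass and isoelectric
point. Mass is the sum of average residue masses plus one water (18.0153
Da); `X` contributes the mean residue mass, `B`/`Z`/`J` the mean of their
constituent residues. The isoelectric point solves
`net charge(pH) = 0` for the Henderson–Hasselbalch charge sum over the
ionizable groups (amino terminus, K, R, H positive; carboxyl terminus, D, E,
C, Y negative) with an EMBOSS-style pKa table (`pka_set`), by bisection on
pH 0–14 down to an interval of 1e-9 — tight enough that the residual net
charge at the reported pI is far below 1e-4 even for long, charge-dense
sequences. Both constant tables are exported (`residue_masses`, `pka_set`)
and swappable.

## Overlap filtering

Two rules, applied after annotation so the evidence tier can exempt
features: exact duplicates (class, replicon, coordinates, strand) collapse
to one record, and an sORF overlapping a retained CDS by more than 10 bp on
either strand is removed *unless* it was identified at expert or ips tier —
an exact digest identification is stronger evidence than an overlap heuristic.
The production tool's precise overlap rules are not public; these two are
declared configuration, not a fidelity claim.

## The reference store

`build_ref_db()` compiles the hierarchy from a protein FASTA plus membership
and per-source annotation tables. Annotation sources carry a declared
specificity order (default `expert-curated > model-organism >
cluster-derived`); sources are applied from least to most specific, more
specific values supersede, and every insert, supersession and skipped
duplicate is appended to a TSV audit log. The persisted form is a single
SQLite file with digests as 16-byte BLOB keys and identifier prefixes
(`UniRef100_`, `UniRef90_`, `UniRef50_`, `WP_`) stripped on write and
restored on read; unregistered prefixes are stored verbatim. The store is
opened read-only at annotation time. The schema is versioned
`<major>.<minor>`; the engine accepts any minor version of the major it
supports and refuses anything else before producing output.

The first membership row of each UniRef90 cluster names its representative,
whose sequence is stored in the PSC table so the homology search is
self-contained.

## The synthetic test bed

`gen_reference()` and `gen_genome()` generate the entire test bed
deterministically from a seed. The reference fixture builds clusters from a
random representative (60–400 residues, uniform residue usage, leading M)
with members derived by point substitutions targeting declared identity
levels (the substitution count is `round((1 - level) * length)`, so measured
alignment identity lands within half a residue of the target). The genome
fixture back-translates planted proteins with random synonymous codons and
embeds them in stop-dense background: a 12-mer cassette with stop codons in
all six reading frames is inserted at least every ~60 bp, so the naive ORF
caller cannot produce a false-positive CDS of 20+ residues from background —
planted features are recoverable exactly, which is what makes truth-table
comparison clean. Planted mutants are generated fresh (digest-checked
against the store) so they exercise the homology route rather than AFSI.

These fixtures deliberately do **not** emulate real genomes: residue and
codon usage are uniform, there is no GC skew, no operon structure, no
sequencing error, and reverse strands of planted genes can contain incidental
ORFs (which the engine annotates as hypothetical extras — the tests treat
the truth set as a subset, exact on coordinates and tiers). Passing tests
demonstrate the identification, routing, merging and bookkeeping logic, not
gene-calling performance on real data.

Problem sizes used by the shipped checks — a 20-cluster/65-protein store
with a ~54 kb genome carrying 50 exact copies, 20 + 20 mutants and 10 sORFs
for the end-to-end run; 1,000 proteins × 10,000 queries for the
AFSI/oracle comparison; 100 random 10 kb replicons for the ORF-enumeration
cross-check — were chosen as the smallest scales at which every routing
branch and every boundary is exercised.

## Degenerate inputs and tie-breaks

* Empty genomes produce a valid zero-feature result document.
* Codons containing N translate to X; an all-N replicon yields no ORFs.
* Among equally scoring cluster hits the winner is decided by score, then
  identity, then subject id — ties are impossible to leave unresolved.
* If several partial-CDS pairs flank an origin, only the pair sitting
  exactly on the sequence edges merges; the rest are logged.
* A merged edge pair that fails frame or stop checks is abandoned, keeping
  both partials.
* Within one annotation source, the first entry for a key wins; later
  duplicates are logged and ignored.

## Known limitations

* The naive ORF caller is not a gene predictor; on real genomes, feed
  externally predicted CDS via GFF3.
* Only translation table 11 is implemented.
* The spurious filter ships a blocklist backend only; profile-HMM screening
  must be plugged in by the caller.
* Protein domain scanning of hypotheticals is a declared hook in the run
  summary, not implemented.
* EMBL/GenBank flat-file output and INSDC compliance filtering are out of
  scope; GFF3 + JSON carry the full information.
* dbxrefs are unioned across evidence tiers (with tier provenance retained
  in the result); whether a production annotator should instead keep only
  the winning tier's references is a design choice, made here in favor of
  the union.
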