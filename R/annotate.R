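#' The annotation engine
#'
#' Identification is attempted in order of decreasing precision:
#'
#' 1. **AFSI** (alignment-free sequence identification): the protein's MD5
#'    digest plus a length-equality check against the UPS index; an exact
#'    full-length identification that skips alignment entirely.
#' 2. **Cluster homology**: unidentified CDS proteins are aligned against
#'    PSC (UniRef90-level) representative sequences; hits with mutual
#'    coverage of at least 80% route to the PSC at identity of at least 90%,
#'    and to the coarser PSCC (UniRef50 level) at identities between 50 and
#'    90%.
#' 3. **Expert rules**: curated reference proteins with per-rule identity and
#'    coverage thresholds and a priority rank that can override
#'    cluster-derived annotation.
#'
#' All gathered evidence is combined with tier precedence
#' expert > ips > psc > pscc; features with no informative product are
#' annotated as hypothetical proteins and characterized by molecular mass
#' and isoelectric point.
#'
#' @name annotate
#' @keywords internal
NULL

## ---- configuration -----------------------------------------------------------

#' Annotation-engine configuration
#'
#' @param min_coverage Minimum mutual (query and subject) alignment coverage
#'   for cluster hits (default 0.80, inclusive).
#' @param psc_identity Minimum identity for PSC assignment (default 0.90,
#'   inclusive).
#' @param pscc_min_identity Minimum identity for PSCC assignment (default
#'   0.50, inclusive); hits below are discarded.
#' @param cds_min_aa Minimum protein length for the naive ORF caller
#'   (default 30 residues, the sORF boundary).
#' @param sorf_min_aa,sorf_max_aa sORF protein-length window: `sorf_min_aa`
#'   inclusive (default 7), `sorf_max_aa` exclusive (default 30).
#' @param top_n Number of candidate cluster representatives aligned per
#'   query after k-mer preselection (default 50).
#' @param kmer_k K-mer size for candidate preselection (default 5).
#' @param expert_min_kmers Minimum shared k-mers before an expert rule is
#'   aligned against a query (default 5; exact sequence equality bypasses
#'   alignment entirely).
#' @param max_sorf_overlap Maximum tolerated overlap (bp) of an sORF with a
#'   CDS before the sORF is discarded, unless identified at expert/ips tier
#'   (default 10).
#' @param tier_order Tier precedence, most specific first.
#' @param translation_table Genetic code (only 11 supported).
#' @param locus_prefix Locus-tag prefix.
#' @param supported_major Database schema major version the engine supports.
#' @param aligner Pairwise protein aligner `function(query, subject)`
#'   returning a one-row data frame with `identity`, `query_cov`,
#'   `subject_cov`, `score`; defaults to [align_protein()].
#' @return A named list of class `annot_config`.
#' @export
annot_config <- function(min_coverage = 0.80,
                         psc_identity = 0.90,
                         pscc_min_identity = 0.50,
                         cds_min_aa = 30L,
                         sorf_min_aa = 7L,
                         sorf_max_aa = 30L,
                         top_n = 50L,
                         kmer_k = 5L,
                         expert_min_kmers = 5L,
                         max_sorf_overlap = 10L,
                         tier_order = c("expert", "ips", "psc", "pscc"),
                         translation_table = 11L,
                         locus_prefix = "CDSA",
                         supported_major = 1L,
                         aligner = align_protein) {
  structure(
    list(
      min_coverage = min_coverage, psc_identity = psc_identity,
      pscc_min_identity = pscc_min_identity,
      cds_min_aa = cds_min_aa, sorf_min_aa = sorf_min_aa,
      sorf_max_aa = sorf_max_aa, top_n = top_n, kmer_k = kmer_k,
      expert_min_kmers = expert_min_kmers,
      max_sorf_overlap = max_sorf_overlap,
      tier_order = tier_order, translation_table = translation_table,
      locus_prefix = locus_prefix, supported_major = supported_major,
      aligner = aligner
    ),
    class = "annot_config"
  )
}

## ---- pairwise alignment --------------------------------------------------------

.aa_submat <- local({
  n <- length(.aa_alphabet)
  m <- matrix(-1, n, n, dimnames = list(.aa_alphabet, .aa_alphabet))
  diag(m) <- 1
  m
})

#' Global pairwise protein alignment with free end gaps
#'
#' Unit match/mismatch scoring; identity is matches over alignment columns,
#' coverage the aligned span over the full sequence length. Used for the
#' cluster-homology fallback and expert-rule screening.
#'
#' @param query,subject Amino-acid strings.
#' @return One-row tibble: `identity`, `query_cov`, `subject_cov`, `score`.
#' @export
align_protein <- function(query, subject) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject, type = "overlap",
    substitutionMatrix = .aa_submat, gapOpening = 2, gapExtension = 1
  )
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  cols <- nchar(as.character(p)) # alignment columns, gaps included
  tibble(
    identity = if (cols == 0) 0 else Biostrings::nmatch(aln) / cols,
    query_cov = (BiocGenerics::end(p) - BiocGenerics::start(p) + 1) /
      nchar(query),
    subject_cov = (BiocGenerics::end(s) - BiocGenerics::start(s) + 1) /
      nchar(subject),
    score = as.numeric(Biostrings::score(aln))
  )
}

## ---- k-mer preselection ----------------------------------------------------------

.seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

.kmer_index <- function(seqs, ids, k) {
  rows <- map2(seqs, ids, function(s, id) {
    km <- .seq_kmers(s, k)
    if (length(km) == 0) return(NULL)
    tibble(kmer = km, id = id)
  })
  list_rbind(compact(rows))
}

.db_cache <- function(db) {
  cache <- attr(db, "cache")
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
  }
  cache
}

.psc_kmer_index <- function(db, k) {
  cache <- attr(db, "cache")
  key <- sprintf("psc_kmer_%d", k)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  idx <- .kmer_index(db$psc$rep_seq, db$psc$uniref90_id, k)
  if (!is.null(cache)) cache[[key]] <- idx
  idx
}

.shared_kmer_counts <- function(query, index, k) {
  qk <- .seq_kmers(query, k)
  if (length(qk) == 0 || nrow(index) == 0) {
    return(tibble(id = character(0), n_shared = integer(0)))
  }
  index %>%
    filter(.data$kmer %in% qk) %>%
    dplyr::count(.data$id, name = "n_shared") %>%
    arrange(desc(.data$n_shared), .data$id)
}

## ---- AFSI -----------------------------------------------------------------------

# one-row empty annotation
.empty_annotation <- function() {
  tibble(gene = NA_character_, product = NA_character_,
         dbxrefs = list(character(0)), tier = NA_character_,
         rule_rank = NA_integer_)
}

#' Alignment-free sequence identification (AFSI)
#'
#' Identifies proteins by full-length MD5 digest plus length-equality check
#' against the UPS index and returns the IPS-level annotation (gene, product,
#' UniRef100/UniRef90/UniParc cross-references) for hits. No alignment is
#' performed.
#'
#' @param aa Character vector of canonicalized protein sequences.
#' @param db A `ref_db`.
#' @return Tibble, one row per query: `hit` plus annotation columns (`gene`,
#'   `product`, `dbxrefs`, `tier = "ips"` for hits).
#' @export
identify_afsi <- function(aa, db) {
  if (length(aa) == 0) {
    return(tibble(hit = logical(0), gene = character(0),
                  product = character(0), dbxrefs = list(),
                  tier = character(0)))
  }
  res <- lookup_ups(db, compute_digest(aa), nchar(aa))
  dbx <- pmap(
    list(res$uniref100_id, res$uniref90_id, res$uniparc_id),
    function(u100, u90, upi) {
      c(
        if (!is.na(u100)) paste0("UniRef:", u100),
        if (!is.na(u90)) paste0("UniRef:", u90),
        if (!is.na(upi)) paste0("UniParc:", upi)
      ) %||% character(0)
    }
  )
  tibble(
    hit = res$hit,
    gene = res$gene,
    product = res$product,
    dbxrefs = dbx,
    tier = if_else(res$hit, "ips", NA_character_),
    uniref90_id = res$uniref90_id
  )
}

## ---- cluster homology search -------------------------------------------------------

#' Route alignment hits to PSC / PSCC by coverage and identity
#'
#' Hits must reach mutual coverage (query and subject) of at least
#' `min_coverage`; among those, identity of at least `psc_identity` routes to
#' the UniRef90-level cluster (PSC) and identities in
#' `[pscc_min_identity, psc_identity)` to the UniRef50-level cluster of
#' clusters (PSCC). Lower identities are discarded. All thresholds are
#' inclusive on the accepting side.
#'
#' @param hits Tibble with `identity`, `query_cov`, `subject_cov`.
#' @param min_coverage,psc_identity,pscc_min_identity Thresholds.
#' @return Character vector: `"psc"`, `"pscc"` or `"none"` per hit.
#' @export
route_hits <- function(hits, min_coverage = 0.80, psc_identity = 0.90,
                       pscc_min_identity = 0.50) {
  dplyr::case_when(
    hits$query_cov < min_coverage | hits$subject_cov < min_coverage ~ "none",
    hits$identity >= psc_identity ~ "psc",
    hits$identity >= pscc_min_identity ~ "pscc",
    TRUE ~ "none"
  )
}

#' Homology search against cluster representative sequences
#'
#' Candidate UniRef90 representatives are preselected by shared k-mer count
#' (top `top_n`), aligned, filtered for mutual coverage, and routed by
#' identity ([route_hits()]). The best surviving hit is chosen by score,
#' then identity, then subject id.
#'
#' @param aa One canonicalized protein sequence.
#' @param db A `ref_db`.
#' @param config An [annot_config()].
#' @return One-row tibble (`subject_id`, `identity`, `query_cov`,
#'   `subject_cov`, `score`, `route`, `n_alignments`), or a zero-hit row with
#'   `route = "none"` when nothing qualifies.
#' @export
search_clusters <- function(aa, db, config = annot_config()) {
  none <- tibble(subject_id = NA_character_, identity = NA_real_,
                 query_cov = NA_real_, subject_cov = NA_real_,
                 score = NA_real_, route = "none", n_alignments = 0L)
  idx <- .psc_kmer_index(db, config$kmer_k)
  cand <- .shared_kmer_counts(aa, idx, config$kmer_k)
  cand <- head(cand, config$top_n)
  if (nrow(cand) == 0L) return(none)
  reps <- db$psc[match(cand$id, db$psc$uniref90_id), ]
  hits <- map(seq_len(nrow(reps)), function(i) {
    h <- config$aligner(aa, reps$rep_seq[i])
    h$subject_id <- reps$uniref90_id[i]
    h
  }) %>% list_rbind()
  n_aln <- nrow(hits)
  hits$route <- route_hits(hits, config$min_coverage, config$psc_identity,
                           config$pscc_min_identity)
  hits <- hits %>% filter(.data$route != "none")
  if (nrow(hits) == 0L) {
    none$n_alignments <- n_aln
    return(none)
  }
  best <- hits %>%
    arrange(desc(.data$score), desc(.data$identity), .data$subject_id) %>%
    slice(1) %>%
    select("subject_id", "identity", "query_cov", "subject_cov", "score",
           "route")
  best$n_alignments <- n_aln
  best
}

# annotation row for a routed cluster hit
.cluster_annotation <- function(hit, db) {
  if (hit$route == "none" || is.na(hit$subject_id)) return(NULL)
  psc <- lookup_psc(db, hit$subject_id)
  if (nrow(psc) == 0L) return(NULL)
  if (hit$route == "psc") {
    dbx <- c(
      paste0("UniRef:", psc$uniref90_id),
      if (!is.na(psc$uniref50_id)) paste0("UniRef:", psc$uniref50_id),
      if (!is.na(psc$cog_id)) paste0("COG:", psc$cog_id),
      if (!is.na(psc$ec) && nzchar(psc$ec)) {
        paste0("EC:", strsplit(psc$ec, ",", fixed = TRUE)[[1]])
      },
      if (!is.na(psc$go) && nzchar(psc$go)) {
        strsplit(psc$go, ",", fixed = TRUE)[[1]] # GO ids carry their prefix
      }
    )
    tibble(gene = psc$gene, product = psc$product, dbxrefs = list(dbx),
           tier = "psc", rule_rank = NA_integer_)
  } else {
    if (is.na(psc$uniref50_id)) return(NULL)
    pscc <- lookup_pscc(db, psc$uniref50_id)
    if (nrow(pscc) == 0L) return(NULL)
    tibble(gene = NA_character_, product = pscc$product,
           dbxrefs = list(paste0("UniRef:", pscc$uniref50_id)),
           tier = "pscc", rule_rank = NA_integer_)
  }
}

## ---- expert rules ----------------------------------------------------------------

#' Apply the expert-rule annotation system
#'
#' Each curated rule carries its own identity/coverage thresholds and a
#' priority rank. A rule is eligible when the query aligns to the rule's
#' reference sequence at or above all three thresholds; among eligible rules
#' the highest rank wins (ties: higher identity, then rule id). Exact
#' sequence equality short-circuits without alignment, and rules sharing
#' fewer than `expert_min_kmers` k-mers with the query are not aligned.
#'
#' @param aa One canonicalized protein sequence.
#' @param db A `ref_db` with expert rules loaded.
#' @param config An [annot_config()].
#' @return One-row annotation tibble (`tier = "expert"`), or `NULL` when no
#'   rule is eligible.
#' @export
apply_expert <- function(aa, db, config = annot_config()) {
  rules <- db$expert
  if (is.null(rules) || nrow(rules) == 0L) return(NULL)
  qk <- .seq_kmers(aa, config$kmer_k)
  elig <- list()
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if (identical(aa, r$seq)) {
      h <- tibble(identity = 1, query_cov = 1, subject_cov = 1,
                  score = nchar(aa))
    } else {
      shared <- sum(.seq_kmers(r$seq, config$kmer_k) %in% qk)
      if (shared < config$expert_min_kmers) next
      h <- config$aligner(aa, r$seq)
    }
    if (h$identity >= r$min_identity && h$query_cov >= r$min_query_cov &&
        h$subject_cov >= r$min_subject_cov) {
      elig[[length(elig) + 1L]] <- tibble(
        rule_id = r$rule_id, rank = r$rank, identity = h$identity,
        gene = r$gene, product = r$product, dbxrefs = r$dbxrefs
      )
    }
  }
  if (length(elig) == 0L) return(NULL)
  win <- list_rbind(elig) %>%
    arrange(desc(.data$rank), desc(.data$identity), .data$rule_id) %>%
    slice(1)
  dbx <- if (is.na(win$dbxrefs) || !nzchar(win$dbxrefs)) character(0) else {
    strsplit(win$dbxrefs, ",", fixed = TRUE)[[1]]
  }
  tibble(gene = win$gene, product = win$product, dbxrefs = list(dbx),
         tier = "expert", rule_rank = as.integer(win$rank))
}

## ---- concluding annotation ---------------------------------------------------------

.hypothetical_synonyms <- c(
  "hypothetical protein", "uncharacterized protein", "putative protein",
  "conserved predicted protein"
)

.is_informative_product <- function(p) {
  !is.na(p) & nzchar(p) & !(tolower(str_squish(p)) %in% .hypothetical_synonyms)
}

#' Combine per-tier evidence into the concluding annotation
#'
#' Tier precedence is expert > ips > psc > pscc. The assigned tier is the
#' most specific tier with evidence; gene and product are taken from the
#' most specific tier providing them (lower tiers fill gaps; products equal
#' to hypothetical-protein synonyms are not informative), and database
#' cross-references are the union across all tiers. With no evidence at all,
#' the feature is a hypothetical protein.
#'
#' @param expert,ips,psc,pscc One-row annotation tibbles or `NULL`.
#' @param tier_order Precedence, most specific first.
#' @return One-row annotation tibble.
#' @export
conclude_annotation <- function(expert = NULL, ips = NULL, psc = NULL,
                                pscc = NULL,
                                tier_order = c("expert", "ips", "psc",
                                               "pscc")) {
  cand <- list(expert = expert, ips = ips, psc = psc, pscc = pscc)
  cand <- cand[tier_order]
  present <- !vapply(cand, is.null, logical(1))
  if (!any(present)) {
    return(tibble(gene = NA_character_, product = "hypothetical protein",
                  dbxrefs = list(character(0)), tier = "hypothetical",
                  rule_rank = NA_integer_))
  }
  tier <- names(cand)[which(present)[1]]
  gene <- NA_character_
  product <- NA_character_
  rule_rank <- NA_integer_
  dbx <- character(0)
  for (nm in names(cand)) {
    a <- cand[[nm]]
    if (is.null(a)) next
    if (is.na(gene) && !is.na(a$gene) && nzchar(a$gene)) gene <- a$gene
    if (is.na(product) && .is_informative_product(a$product)) {
      product <- a$product
    }
    if (nm == "expert" && !is.na(a$rule_rank)) rule_rank <- a$rule_rank
    dbx <- c(dbx, a$dbxrefs[[1]])
  }
  if (is.na(product)) product <- "hypothetical protein"
  tibble(gene = gene, product = product, dbxrefs = list(unique(dbx)),
         tier = tier, rule_rank = rule_rank)
}

## ---- product refinement --------------------------------------------------------------

#' Refine product names toward nomenclature guidelines
#'
#' Deterministic rewrite chain: trim and collapse whitespace; strip a single
#' pair of wrapping quotes; drop a trailing "homolog" token or "-like
#' protein" suffix when a named protein remains; normalize the spelling
#' "uncharacterised" to "uncharacterized". Products matching the
#' hypothetical-protein synonym set are normalized to "hypothetical protein"
#' when tiers are assigned.
#'
#' @param product Character vector of product names.
#' @return Refined product names.
#' @export
refine_product <- function(product) {
  p <- str_squish(product)
  quoted <- !is.na(p) &
    ((startsWith(p, "\"") & endsWith(p, "\"")) |
       (startsWith(p, "'") & endsWith(p, "'")))
  p[quoted] <- str_squish(substr(p[quoted], 2L, nchar(p[quoted]) - 1L))
  # trailing "homolog" after a named protein
  has_homolog <- !is.na(p) & grepl("\\S\\s+homolog$", p)
  p[has_homolog] <- str_squish(sub("\\s+homolog$", "", p[has_homolog]))
  has_like <- !is.na(p) & grepl("\\S-like protein$", p)
  p[has_like] <- sub("-like protein$", "", p[has_like])
  p <- gsub("uncharacterised", "uncharacterized", p, ignore.case = FALSE)
  p <- gsub("Uncharacterised", "Uncharacterized", p, fixed = TRUE)
  ifelse(
    !is.na(p) & tolower(p) %in% .hypothetical_synonyms,
    "hypothetical protein", p
  )
}

## ---- sequence-based characterization -------------------------------------------------

#' Average residue masses (Da) and side-chain/terminal pKa values
#'
#' EMBOSS-style constant tables used for the molecular-mass and
#' isoelectric-point characterization of hypothetical proteins. `X` (unknown
#' residue) contributes the mean residue mass and no charge; `B`/`Z`/`J`
#' average their constituent residues.
#'
#' @format `residue_masses`: named numeric vector of average residue masses
#'   (Da); `pka_set`: named numeric vector of pKa values for ionizable side
#'   chains (C, D, E, H, K, R, Y) and the `nterm`/`cterm` groups.
#' @name characterization_constants
NULL

#' @rdname characterization_constants
#' @export
residue_masses <- local({
  m <- c(
    A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
  )
  c(m,
    X = mean(m), B = mean(m[c("N", "D")]), Z = mean(m[c("Q", "E")]),
    J = mean(m[c("I", "L")]), U = 150.0388, O = 237.3018)
})

.water_mass <- 18.0153

#' @rdname characterization_constants
#' @export
pka_set <- c(
  nterm = 8.6, cterm = 3.6,
  C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1
)

.residue_counts <- function(aa, letters) {
  chars <- strsplit(aa, "", fixed = TRUE)
  m <- t(vapply(chars, function(cs) {
    as.integer(table(factor(cs, levels = letters)))
  }, integer(length(letters))))
  colnames(m) <- letters
  m
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable groups: positive
#' contributions from the amino terminus, K, R and H; negative from the
#' carboxyl terminus, D, E, C and Y.
#'
#' @param aa Character vector of protein sequences.
#' @param ph pH value (scalar) or vector matching `aa`.
#' @param pka Named pKa vector (see [pka_set]).
#' @return Numeric vector of net charges.
#' @export
peptide_charge <- function(aa, ph, pka = pka_set) {
  pos_groups <- c("K", "R", "H")
  neg_groups <- c("D", "E", "C", "Y")
  counts <- .residue_counts(aa, c(pos_groups, neg_groups))
  pos <- 1 / (1 + 10^(ph - pka["nterm"]))
  neg <- -1 / (1 + 10^(pka["cterm"] - ph))
  for (g in pos_groups) {
    pos <- pos + counts[, g] / (1 + 10^(ph - pka[g]))
  }
  for (g in neg_groups) {
    neg <- neg - counts[, g] / (1 + 10^(pka[g] - ph))
  }
  unname(pos + neg)
}

#' Molecular mass and isoelectric point of proteins
#'
#' Mass is the sum of average residue masses plus one water; the isoelectric
#' point is the pH at which the Henderson-Hasselbalch net charge crosses
#' zero, found by bisection on \[0, 14\].
#'
#' @param aa Character vector of protein sequences.
#' @param pka Named pKa vector (see [pka_set]).
#' @param masses Named residue-mass vector (see [residue_masses]).
#' @return Tibble with `mass` (Da) and `pi`.
#' @export
characterize_protein <- function(aa, pka = pka_set, masses = residue_masses) {
  stopifnot(all(nzchar(aa)))
  counts <- .residue_counts(aa, names(masses))
  mass <- as.vector(counts %*% masses) + .water_mass
  lo <- rep(0, length(aa)); hi <- rep(14, length(aa))
  while (max(hi - lo) > 1e-9) {
    mid <- (lo + hi) / 2
    q <- peptide_charge(aa, mid, pka)
    pos <- q > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  tibble(mass = mass, pi = (lo + hi) / 2)
}

## ---- overlap filter --------------------------------------------------------------------

#' Filter features by overlap and annotation evidence
#'
#' Two rules: (1) an sORF overlapping a retained CDS by more than
#' `max_sorf_overlap` bp on either strand is removed unless identified at
#' expert or ips tier; (2) exact duplicate features (same class, replicon,
#' coordinates, strand) are collapsed. Removals are recorded in the
#' `removed` attribute with the id of the conflicting feature.
#'
#' @param features Annotated feature tibble.
#' @param max_sorf_overlap Overlap tolerance in bp.
#' @return Retained features.
#' @export
overlap_filter <- function(features, max_sorf_overlap = 10L) {
  dup <- duplicated(features[, c("feature_class", "replicon_id", "start",
                                 "stop", "strand")])
  removed <- features[dup, ] %>% mutate(removal_reason = "duplicate",
                                        conflict_id = NA_character_)
  f <- features[!dup, ]
  if (!"tier" %in% names(f)) f$tier <- NA_character_
  cds <- f %>% filter(.data$feature_class == "cds")
  sorfs <- f %>% filter(.data$feature_class == "sorf")
  drop_ids <- character(0)
  conflicts <- character(0)
  for (i in seq_len(nrow(sorfs))) {
    s <- sorfs[i, ]
    if (!is.na(s$tier) && s$tier %in% c("expert", "ips")) next
    cc <- cds %>% filter(.data$replicon_id == s$replicon_id)
    if (nrow(cc) == 0L) next
    ov <- pmin(cc$stop, s$stop) - pmax(cc$start, s$start)
    j <- which(ov > max_sorf_overlap)
    if (length(j) > 0L) {
      drop_ids <- c(drop_ids, s$feature_id)
      conflicts <- c(conflicts, cc$feature_id[j[1]])
    }
  }
  if (length(drop_ids) > 0L) {
    rm2 <- f %>% filter(.data$feature_id %in% drop_ids) %>%
      mutate(removal_reason = "overlaps CDS",
             conflict_id = conflicts[match(.data$feature_id, drop_ids)])
    removed <- bind_rows(removed, rm2)
    f <- f %>% filter(!.data$feature_id %in% drop_ids)
  }
  attr(f, "removed") <- removed
  f
}

## ---- full pipeline ------------------------------------------------------------------------

#' Annotate a genome
#'
#' Runs the full engine: CDS calling (or ingestion of pre-predicted
#' coordinates), origin-spanning CDS merging, sORF extraction, spurious
#' filtering, AFSI, cluster-homology fallback for AFSI misses, expert-rule
#' refinement, concluding annotation with product refinement,
#' characterization of hypothetical proteins, and overlap filtering. Locus
#' tags (`<prefix>_00001`, step 1) are assigned ordered by replicon, then
#' start coordinate.
#'
#' @param genome A genome object from [read_genome()].
#' @param db A `ref_db`.
#' @param config An [annot_config()].
#' @param cds_gff Optional GFF3 path of pre-predicted CDS; when absent the
#'   naive six-frame ORF caller is used.
#' @param spurious_backend Spurious-filter predicate; defaults to the
#'   database digest blocklist.
#' @return A `genome_annotation`: `features` tibble with annotation columns,
#'   the `genome`, and a run `summary` (per-tier counts, features resolved
#'   without alignment, alignments performed).
#' @export
annotate_genome <- function(genome, db, config = annot_config(),
                            cds_gff = NULL, spurious_backend = NULL) {
  check_db_version(db$meta, config$supported_major)
  cds <- if (is.null(cds_gff)) {
    naive_orf_call(genome, min_aa = config$cds_min_aa)
  } else {
    ingest_cds(cds_gff, genome)
  }
  cds <- merge_edge_cds(cds, genome)
  sorfs <- extract_sorfs(genome, max_aa_exclusive = config$sorf_max_aa,
                         min_aa = config$sorf_min_aa)
  feats <- bind_rows(cds, sorfs)
  backend <- spurious_backend %||% blocklist_backend(db)
  feats <- filter_spurious(feats, backend)
  n_spurious <- nrow(attr(feats, "removed") %||% tibble())

  n <- nrow(feats)
  afsi <- identify_afsi(feats$aa, db)
  ann_rows <- vector("list", n)
  n_alignments <- integer(n)
  for (i in seq_len(n)) {
    ips_a <- NULL; psc_a <- NULL; pscc_a <- NULL
    cluster_hit <- NULL
    if (afsi$hit[i]) {
      ips_a <- afsi[i, c("gene", "product", "dbxrefs")] %>%
        mutate(tier = "ips", rule_rank = NA_integer_)
      # identified proteins inherit their cluster's preassigned annotation
      # by id lookup (no alignment): PSC via the IPS link, PSCC via the PSC
      u90 <- afsi$uniref90_id[i]
      if (!is.na(u90)) {
        psc_a <- .cluster_annotation(
          tibble(route = "psc", subject_id = u90), db
        )
        pscc_a <- .cluster_annotation(
          tibble(route = "pscc", subject_id = u90), db
        )
      }
    } else if (feats$feature_class[i] == "cds" && nzchar(feats$aa[i])) {
      hit <- search_clusters(feats$aa[i], db, config)
      n_alignments[i] <- hit$n_alignments
      ca <- .cluster_annotation(hit, db)
      if (!is.null(ca)) {
        if (ca$tier == "psc") psc_a <- ca else pscc_a <- ca
      }
    }
    exp_a <- if (nzchar(feats$aa[i])) apply_expert(feats$aa[i], db, config)
    ann_rows[[i]] <- conclude_annotation(
      expert = exp_a, ips = ips_a, psc = psc_a, pscc = pscc_a,
      tier_order = config$tier_order
    )
  }
  ann <- list_rbind(ann_rows)
  ann$product <- refine_product(ann$product)
  ann$product <- ifelse(
    tolower(ann$product) %in% .hypothetical_synonyms,
    "hypothetical protein", ann$product
  )
  feats <- bind_cols(feats, ann)
  feats$n_alignments <- n_alignments
  feats$afsi_hit <- afsi$hit

  # characterize hypothetical proteins
  feats$mass <- NA_real_
  feats$pi <- NA_real_
  hyp <- which(feats$product == "hypothetical protein" & nzchar(feats$aa))
  if (length(hyp) > 0L) {
    ch <- characterize_protein(feats$aa[hyp])
    feats$mass[hyp] <- ch$mass
    feats$pi[hyp] <- ch$pi
  }

  feats <- overlap_filter(feats, config$max_sorf_overlap)
  removed_overlap <- attr(feats, "removed")

  feats <- feats %>% arrange(.data$replicon_id, .data$start, .data$stop)
  feats$locus_tag <- sprintf("%s_%05d", config$locus_prefix,
                             seq_len(nrow(feats)))

  tier_counts <- table(factor(feats$tier,
                              levels = c(config$tier_order, "hypothetical")))
  summary <- list(
    db_schema = sprintf("%d.%d", db$meta$schema_major, db$meta$schema_minor),
    n_features = nrow(feats),
    n_cds = sum(feats$feature_class == "cds"),
    n_sorf = sum(feats$feature_class == "sorf"),
    tier_counts = as.list(tier_counts),
    n_hypothetical_product = sum(feats$product == "hypothetical protein"),
    resolved_without_alignment = sum(feats$afsi_hit),
    alignments_performed = sum(feats$n_alignments),
    n_spurious_removed = n_spurious,
    n_overlap_removed = nrow(removed_overlap %||% tibble()),
    pfam_domain_scan = NULL # hook point; domain screening not implemented
  )
  structure(
    list(genome = genome, features = feats, summary = summary),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<genome_annotation> %d features (%d CDS, %d sORF) | AFSI-resolved: %d | alignments: %d\n",
    s$n_features, s$n_cds, s$n_sorf, s$resolved_without_alignment,
    s$alignments_performed
  ))
  tc <- unlist(s$tier_counts)
  cat("tiers:", paste(sprintf("%s=%d", names(tc), tc), collapse = ", "), "\n")
  invisible(x)
}

## ---- broom-style accessors and plotting ----------------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the annotated feature table
#'
#' @param x A `genome_annotation`.
#' @param ... Unused.
#' @return The per-feature tibble (one row per retained feature).
#' @export
tidy.genome_annotation <- function(x, ...) {
  x$features
}

#' One-row summary of an annotation run
#'
#' @param x A `genome_annotation`.
#' @param ... Unused.
#' @return One-row tibble with feature counts, per-tier counts, the number
#'   of features resolved without alignment and alignments performed.
#' @export
glance.genome_annotation <- function(x, ...) {
  s <- x$summary
  tc <- unlist(s$tier_counts)
  names(tc) <- paste0("n_", names(tc))
  bind_cols(
    tibble(
      n_features = s$n_features, n_cds = s$n_cds, n_sorf = s$n_sorf,
      n_hypothetical_product = s$n_hypothetical_product,
      resolved_without_alignment = s$resolved_without_alignment,
      alignments_performed = s$alignments_performed,
      db_schema = s$db_schema
    ),
    as_tibble(as.list(tc))
  )
}

#' Plot annotation-tier composition per replicon
#'
#' @param object A `genome_annotation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.genome_annotation <- function(object, ...) {
  f <- object$features
  ggplot2::ggplot(f, ggplot2::aes(x = .data$replicon_id,
                                  fill = .data$tier)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::facet_wrap(~feature_class, scales = "free_y") +
    ggplot2::labs(x = "replicon", y = "features", fill = "annotation tier") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
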