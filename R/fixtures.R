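#' Deterministic synthetic-data generator
#'
#' Produces a toy reference proteome with known UniRef-style cluster
#' structure, the derived database build inputs, and a toy genome with
#' planted features whose coordinates, sequences and expected annotation
#' tiers are recorded in a ground-truth manifest. This is the test bed for
#' every stage of the pipeline: the background sequence is engineered so the
#' naive ORF caller cannot produce long false-positive CDS (stop codons are
#' injected in all six frames at least every ~60 bp), a property of these
#' fixtures, not of real genomes.
#'
#' @name fixtures
#' @keywords internal
NULL

.std_residues <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# codons per residue (table 11, stops excluded)
.codons_by_aa <- local({
  cod <- .codon_table_11[.codon_table_11 != "*"]
  split(names(cod), unname(cod))
})

# stop cassette: TAA at offsets 1/5/9 (forward frames) and TTA at 0/4/8
# (reverse-strand stops), i.e. stops in all six frames, no start codons
.stop_cassette <- "TTAATTAATTAA"

.random_protein <- function(len) {
  paste0("M", paste(sample(.std_residues, len - 1L, replace = TRUE),
                    collapse = ""))
}

# substitute round((1 - identity) * len) residues, never position 1
.mutate_protein <- function(seq, identity) {
  len <- nchar(seq)
  n_sub <- round((1 - identity) * len)
  if (n_sub == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(2:len, n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(.std_residues, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

.back_translate <- function(aa) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(r) {
    cods <- .codons_by_aa[[r]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

#' Generate a toy reference proteome with known cluster structure
#'
#' Each cluster gets a representative protein (uniform random residues,
#' starting with M) and `members_per_cluster` members derived by point
#' substitutions targeting the given identity levels (level 1.0 members are
#' identical to the representative and deduplicate at build time). Clusters
#' are paired into UniRef50-level superclusters. Per-source annotation
#' tables, expert rules (dedicated sequences outside the proteome), a
#' digest blocklist of decoy spurious proteins, and short sORF-sized
#' reference proteins are generated alongside; a ground-truth manifest
#' records every sequence's cluster, identity level and intended annotation.
#'
#' @param seed RNG seed.
#' @param n_clusters Number of UniRef90-level clusters.
#' @param members_per_cluster Members generated per cluster; member `j`
#'   targets `identity_levels[((j - 1) %% length(identity_levels)) + 1]`.
#' @param identity_levels Identity levels in (0, 1].
#' @param rep_len_range Representative length range (residues).
#' @param n_sorf_refs Number of short (8-29 aa) reference proteins stored as
#'   singleton records (AFSI-identifiable sORFs).
#' @param n_expert Number of expert rules (dedicated sequences).
#' @param n_spurious Number of blocklisted decoy proteins.
#' @return A `ref_fixture` list: `proteins`, `membership`, `annotations`
#'   (named list of per-source tibbles), `expert`, `blocklist`, `manifest`.
#' @export
gen_reference <- function(seed = 42L, n_clusters = 20L,
                          members_per_cluster = 3L,
                          identity_levels = c(1.0, 0.95, 0.70),
                          rep_len_range = c(60L, 400L),
                          n_sorf_refs = 5L, n_expert = 2L,
                          n_spurious = 2L) {
  stopifnot(all(identity_levels > 0 & identity_levels <= 1))
  set.seed(seed)
  rows <- list()
  pid <- 0L
  seen <- new.env(parent = emptyenv()) # digest -> uniref100 id
  for (ci in seq_len(n_clusters)) {
    rep_len <- sample(rep_len_range[1]:rep_len_range[2], 1L)
    rep_seq <- .random_protein(rep_len)
    u90 <- sprintf("UniRef90_C%03d", ci)
    u50 <- sprintf("UniRef50_S%03d", (ci + 1L) %/% 2L)
    for (j in seq_len(members_per_cluster)) {
      level <- identity_levels[((j - 1L) %% length(identity_levels)) + 1L]
      seq <- if (level >= 1) rep_seq else .mutate_protein(rep_seq, level)
      pid <- pid + 1L
      dg <- compute_digest(seq)
      u100 <- if (!is.null(seen[[dg]])) seen[[dg]] else {
        id <- sprintf("UniRef100_Q%05d", pid)
        seen[[dg]] <- id
        id
      }
      rows[[length(rows) + 1L]] <- tibble(
        protein_id = sprintf("P%05d", pid), seq = seq, digest = dg,
        uniref100_id = u100, uniref90_id = u90, uniref50_id = u50,
        level = level, is_rep = j == 1L, type = "cluster"
      )
    }
  }
  for (k in seq_len(n_sorf_refs)) {
    len <- sample(8:29, 1L)
    seq <- .random_protein(len)
    pid <- pid + 1L
    rows[[length(rows) + 1L]] <- tibble(
      protein_id = sprintf("P%05d", pid), seq = seq,
      digest = compute_digest(seq),
      uniref100_id = sprintf("UniRef100_Q%05d", pid),
      uniref90_id = NA_character_, uniref50_id = NA_character_,
      level = 1, is_rep = FALSE, type = "sorf_ref"
    )
  }
  manifest <- list_rbind(rows)

  proteins <- manifest %>% select("protein_id", "seq")
  membership <- manifest %>%
    select("protein_id", "uniref100_id", "uniref90_id", "uniref50_id")

  clusters <- manifest %>%
    filter(.data$type == "cluster") %>%
    distinct(.data$uniref90_id, .data$uniref50_id)
  u50s <- unique(clusters$uniref50_id)
  cl_i <- as.integer(sub("UniRef90_C", "", clusters$uniref90_id))
  annotations <- list(
    `cluster-derived` = bind_rows(
      tibble(key = u50s,
             product = sprintf("%s family protein", sub("UniRef50_", "",
                                                        u50s))),
      tibble(key = clusters$uniref90_id,
             product = sprintf("uncharacterised protein C%03d", cl_i))
    ),
    `model-organism` = bind_rows(
      tibble(
        key = clusters$uniref90_id,
        gene = sprintf("gen%03d", cl_i),
        product = sprintf("synthetic enzyme %03d", cl_i),
        cog_id = sprintf("COG%04d", cl_i),
        cog_category = rep_len_out(c("E", "F", "G", "H"), nrow(clusters)),
        ec = sprintf("1.1.1.%d", cl_i),
        go = sprintf("GO:%07d", cl_i)
      ),
      manifest %>%
        filter(.data$type == "sorf_ref") %>%
        mutate(key = .data$uniref100_id,
               gene = NA_character_,
               product = sprintf("small protein %s",
                                 sub("UniRef100_Q", "", .data$uniref100_id))) %>%
        select("key", "gene", "product"),
      manifest %>%
        filter(.data$type == "cluster", .data$is_rep) %>%
        mutate(key = .data$uniref100_id,
               gene = sprintf("gen%03d",
                              as.integer(sub("UniRef90_C", "",
                                             .data$uniref90_id))),
               product = sprintf(
                 "synthetic enzyme %03d, strain variant",
                 as.integer(sub("UniRef90_C", "", .data$uniref90_id))
               )) %>%
        select("key", "gene", "product")
    )
  )

  expert <- if (n_expert > 0L) {
    tibble(
      rule_id = sprintf("XR%03d", seq_len(n_expert)),
      source = "amr",
      rank = 10L * seq_len(n_expert),
      gene = paste0("amr", LETTERS[seq_len(n_expert)]),
      product = sprintf("curated resistance protein %d", seq_len(n_expert)),
      min_identity = 0.9, min_query_cov = 0.9, min_subject_cov = 0.9,
      seq = vapply(seq_len(n_expert), function(i) {
        .random_protein(sample(80:200, 1L))
      }, character(1)),
      dbxrefs = sprintf("ExpertDB:XR%03d", seq_len(n_expert))
    )
  } else NULL

  spurious <- if (n_spurious > 0L) {
    tibble(
      protein_id = sprintf("SPUR%02d", seq_len(n_spurious)),
      seq = vapply(seq_len(n_spurious), function(i) {
        .random_protein(sample(40:60, 1L))
      }, character(1))
    ) %>% mutate(digest = compute_digest(.data$seq))
  } else tibble(protein_id = character(0), seq = character(0),
                digest = character(0))

  structure(
    list(
      proteins = proteins, membership = membership,
      annotations = annotations, expert = expert,
      blocklist = spurious$digest, spurious = spurious,
      manifest = manifest
    ),
    class = "ref_fixture"
  )
}

# recycle a vector to length n
rep_len_out <- function(x, n) rep(x, length.out = n)

#' Build a `ref_db` directly from a fixture
#'
#' @param ref A `ref_fixture` from [gen_reference()].
#' @param version Schema version string.
#' @return A `ref_db`.
#' @export
build_fixture_db <- function(ref, version = "1.0") {
  build_ref_db(
    proteins = ref$proteins, membership = ref$membership,
    annotations = ref$annotations, expert = ref$expert,
    blocklist = ref$blocklist, version = version
  )
}

#' Write reference-database build inputs to disk
#'
#' Emits exactly the files the `build-db` command consumes: the protein
#' FASTA, membership TSV, one annotation TSV per source, the expert-rule TSV
#' plus rule-protein FASTA, and the digest blocklist.
#'
#' @param ref A `ref_fixture`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_inputs <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), showWarnings = FALSE)
  .write_fasta(ref$proteins$seq, ref$proteins$protein_id,
               file.path(dir, "proteins.faa"))
  readr::write_tsv(ref$membership, file.path(dir, "membership.tsv"))
  for (src in names(ref$annotations)) {
    readr::write_tsv(ref$annotations[[src]],
                     file.path(dir, "annotations", paste0(src, ".tsv")))
  }
  if (!is.null(ref$expert)) {
    readr::write_tsv(ref$expert %>% select(-"seq"),
                     file.path(dir, "expert.tsv"))
    .write_fasta(ref$expert$seq, ref$expert$rule_id,
                 file.path(dir, "expert.faa"))
  }
  writeLines(ref$blocklist, file.path(dir, "blocklist.txt"))
  invisible(dir)
}

## ---- genome fixture -------------------------------------------------------------

.random_chunk <- function(min_len = 20L, max_len = 40L) {
  paste(sample(c("A", "C", "G", "T"), sample(min_len:max_len, 1L),
               replace = TRUE), collapse = "")
}

#' Generate a toy genome with planted features
#'
#' Assembles a circular complete chromosome from stop-dense intergenic
#' background (stop codons in all six frames at least every ~60 bp, so the
#' naive ORF caller produces no long false positives) with planted genes
#' drawn from the reference fixture: exact copies (expected AFSI/ips tier),
#' fresh ~0.95-identity mutants of cluster representatives (expected psc
#' tier), fresh ~0.70-identity mutants (expected pscc tier), sORFs (some
#' copies of stored short proteins, some novel), optionally blocklisted
#' spurious proteins, and optionally a gene spanning the origin (last 99 bp
#' plus first 150 bp). Every planted feature's coordinates, strand, class
#' and expected tier are recorded in the truth table.
#'
#' @param ref A `ref_fixture`.
#' @param seed RNG seed.
#' @param n_exact Number of exact-copy genes.
#' @param n_mut_psc,n_mut_pscc Numbers of fresh representative mutants at
#'   identity ~0.95 / ~0.70.
#' @param n_sorfs Total planted sORFs; `n_sorf_known` of them are exact
#'   copies of stored short proteins.
#' @param n_sorf_known See `n_sorfs`.
#' @param n_spurious_planted Blocklisted decoys planted as genes.
#' @param with_edge_gene Plant an origin-spanning 82-aa gene.
#' @param replicon_id Chromosome id.
#' @return List: `genome` (a `cdsannot_genome`), `truth` tibble
#'   (`feature_id`, coordinates, strand, class, `edge`, `aa`,
#'   `expected_tier`, `target_identity`), and `replicon_meta` tibble.
#' @export
gen_genome <- function(ref, seed = 1L, n_exact = 50L, n_mut_psc = 20L,
                       n_mut_pscc = 20L, n_sorfs = 10L, n_sorf_known = 5L,
                       n_spurious_planted = 0L, with_edge_gene = TRUE,
                       replicon_id = "chr1") {
  set.seed(seed + 1L)
  manifest <- ref$manifest
  db_digests <- unique(manifest$digest)

  pool <- manifest %>%
    filter(.data$type == "cluster") %>%
    distinct(.data$seq, .keep_all = TRUE)
  stopifnot(n_exact <= nrow(pool))
  exact <- pool %>% dplyr::slice_sample(n = n_exact)

  reps <- manifest %>% filter(.data$type == "cluster", .data$is_rep)
  fresh_mutant <- function(level) {
    repeat {
      r <- reps[sample.int(nrow(reps), 1L), ]
      m <- .mutate_protein(r$seq, level)
      if (!compute_digest(m) %in% db_digests) {
        return(tibble(aa = m, source = r$uniref90_id))
      }
    }
  }
  mut_psc <- list_rbind(map(seq_len(n_mut_psc), ~fresh_mutant(0.95)))
  mut_pscc <- list_rbind(map(seq_len(n_mut_pscc), ~fresh_mutant(0.70)))

  sorf_refs <- manifest %>% filter(.data$type == "sorf_ref")
  n_sorf_known <- min(n_sorf_known, nrow(sorf_refs), n_sorfs)
  sorf_known <- if (n_sorf_known > 0L) {
    sorf_refs %>% dplyr::slice_sample(n = n_sorf_known)
  } else sorf_refs[0, ]
  n_sorf_novel <- n_sorfs - n_sorf_known
  sorf_novel <- vapply(seq_len(n_sorf_novel), function(i) {
    .random_protein(sample(8:29, 1L))
  }, character(1))

  spur <- if (n_spurious_planted > 0L) {
    head(ref$spurious, n_spurious_planted)
  } else ref$spurious[0, ]

  elements <- bind_rows(
    tibble(aa = exact$seq, feature_class = "cds", expected_tier = "ips",
           target_identity = 1, source = exact$uniref100_id),
    if (n_mut_psc > 0) tibble(aa = mut_psc$aa, feature_class = "cds",
                              expected_tier = "psc", target_identity = 0.95,
                              source = mut_psc$source),
    if (n_mut_pscc > 0) tibble(aa = mut_pscc$aa, feature_class = "cds",
                               expected_tier = "pscc", target_identity = 0.70,
                               source = mut_pscc$source),
    if (nrow(sorf_known) > 0) tibble(aa = sorf_known$seq,
                                     feature_class = "sorf",
                                     expected_tier = "ips",
                                     target_identity = 1,
                                     source = sorf_known$uniref100_id),
    if (n_sorf_novel > 0) tibble(aa = sorf_novel, feature_class = "sorf",
                                 expected_tier = "hypothetical",
                                 target_identity = NA_real_,
                                 source = NA_character_),
    if (nrow(spur) > 0) tibble(aa = spur$seq, feature_class = "spurious",
                               expected_tier = "removed",
                               target_identity = NA_real_,
                               source = spur$protein_id)
  )
  elements <- elements[sample.int(nrow(elements)), ]
  elements$strand <- sample(c("+", "-"), nrow(elements), replace = TRUE)

  edge_aa <- if (with_edge_gene) .random_protein(82L) else NULL
  edge_nt <- if (with_edge_gene) paste0(.back_translate(edge_aa), "TAA")
  # 249 nt: part A = first 99 nt (placed at the sequence end), part B =
  # remaining 150 nt (placed at the sequence start)
  part_a <- if (with_edge_gene) substr(edge_nt, 1L, 99L)
  part_b <- if (with_edge_gene) substr(edge_nt, 100L, 249L)

  parts <- character(0)
  pos <- 0L
  truth <- list()
  add <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  if (with_edge_gene) add(part_b)
  add(.stop_cassette)
  for (i in seq_len(nrow(elements))) {
    add(.random_chunk())
    add(.stop_cassette)
    el <- elements[i, ]
    nt <- paste0(.back_translate(el$aa), "TAA")
    ins <- if (el$strand == "+") nt else revcomp(nt)
    start <- pos
    add(ins)
    truth[[length(truth) + 1L]] <- tibble(
      feature_id = sprintf("planted_%03d", i),
      replicon_id = replicon_id,
      start = start, stop = pos, strand = el$strand, edge = FALSE,
      feature_class = el$feature_class, aa = el$aa,
      expected_tier = el$expected_tier,
      target_identity = el$target_identity, source = el$source
    )
    add(.stop_cassette)
  }
  add(.random_chunk())
  add(.stop_cassette)
  if (with_edge_gene) {
    start <- pos
    add(part_a)
    truth[[length(truth) + 1L]] <- tibble(
      feature_id = "planted_edge",
      replicon_id = replicon_id,
      start = start, stop = pos + nchar(part_b), strand = "+", edge = TRUE,
      feature_class = "cds", aa = edge_aa,
      expected_tier = "hypothetical", target_identity = NA_real_,
      source = NA_character_
    )
  }
  seq <- paste(parts, collapse = "")
  len <- nchar(seq)
  truth <- list_rbind(truth)
  replicons <- tibble(
    id = replicon_id, name = replicon_id, rep_type = "chromosome",
    topology = "circular", completeness = "complete", length = len
  )
  genome <- structure(
    list(replicons = replicons, seq = setNames(seq, replicon_id)),
    class = "cdsannot_genome"
  )
  list(genome = genome, truth = truth,
       replicon_meta = tibble(
         original_id = replicon_id, new_id = replicon_id,
         type = "chromosome", topology = "circular", name = replicon_id,
         completeness = "complete"
       ))
}

#' Write a genome fixture to disk (FASTA, replicon TSV, truth GFF3)
#'
#' The truth GFF3 writes origin-spanning genes as two partial CDS records
#' with distinct IDs and `partial5`/`partial3` attributes, the way an
#' external gene caller reports them; [merge_edge_cds()] re-joins them.
#'
#' @param gen Output of [gen_genome()].
#' @param dir Output directory.
#' @param gzip_fasta Also write a gzip-compressed copy of the FASTA.
#' @return Named character vector of the paths written.
#' @export
write_genome_fixture <- function(gen, dir, gzip_fasta = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "genome.fasta")
  .write_fasta(gen$genome$seq, names(gen$genome$seq), fasta)
  paths <- c(fasta = fasta)
  if (gzip_fasta) {
    gz <- paste0(fasta, ".gz")
    con <- gzfile(gz, "wb")
    writeLines(readLines(fasta), con)
    close(con)
    paths <- c(paths, fasta_gz = gz)
  }
  tsv <- file.path(dir, "replicons.tsv")
  readr::write_tsv(gen$replicon_meta, tsv)
  gff <- file.path(dir, "truth.gff3")
  .write_truth_gff3(gen, gff)
  c(paths, replicons = tsv, truth_gff = gff)
}

.write_truth_gff3 <- function(gen, path) {
  reps <- gen$genome$replicons
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", reps$id, reps$length))
  for (i in seq_len(nrow(gen$truth))) {
    r <- gen$truth[i, ]
    if (r$feature_class == "spurious") type <- "CDS"
    else type <- if (r$feature_class == "sorf") "sorf" else "CDS"
    len <- reps$length[reps$id == r$replicon_id]
    if (r$edge) {
      # two separate partial records, as an external caller would emit
      lines <- c(
        lines,
        paste(r$replicon_id, "fixture", type, r$start + 1L, len, ".",
              r$strand, "0",
              sprintf("ID=%s_5p;partial3=true", r$feature_id), sep = "\t"),
        paste(r$replicon_id, "fixture", type, 1L, r$stop - len, ".",
              r$strand, "0",
              sprintf("ID=%s_3p;partial5=true", r$feature_id), sep = "\t")
      )
    } else {
      lines <- c(
        lines,
        paste(r$replicon_id, "fixture", type, r$start + 1L, r$stop, ".",
              r$strand, "0", sprintf("ID=%s", r$feature_id), sep = "\t")
      )
    }
  }
  writeLines(lines, path)
  invisible(path)
}
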