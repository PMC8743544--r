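mk_genome <- function(seq, topology = "linear",
                      completeness = if (topology == "circular") "complete" else "incomplete",
                      id = "r1") {
  structure(
    list(
      replicons = tibble::tibble(
        id = id, name = id, rep_type = "contig", topology = topology,
        completeness = completeness, length = nchar(seq)
      ),
      seq = stats::setNames(seq, id)
    ),
    class = "cdsannot_genome"
  )
}

test_that("naive ORF caller finds a planted ORF and nothing in all-N sequence", {
  g <- mk_genome(paste0("TTAATTAATTAA", "ATGGGTAAATAA", "TTAATTAATTAA"))
  orfs <- naive_orf_call(g, min_aa = 3)
  expect_equal(nrow(orfs), 1L)
  expect_identical(orfs$aa, "MGK")
  expect_equal(orfs$start, 12L)
  expect_equal(orfs$stop, 24L)
  expect_identical(orfs$strand, "+")

  gN <- mk_genome(strrep("N", 500))
  expect_equal(nrow(naive_orf_call(gN, min_aa = 3)), 0L)
})

test_that("naive ORF caller matches the brute-force six-frame oracle on random sequences", {
  set.seed(21)
  for (i in 1:25) {
    topo <- if (i %% 2 == 0) "circular" else "linear"
    s <- random_dna(2000)
    g <- mk_genome(s, topology = topo)
    ours <- naive_orf_call(g, min_aa = 10)
    theirs <- oracle_orfs(s, min_aa = 10, circular = topo == "circular")
    expect_identical(orf_key(ours), orf_key(theirs),
                     label = sprintf("orf set, case %d (%s)", i, topo))
    m <- merge(as.data.frame(ours), theirs, by = c("start", "stop", "strand"))
    expect_identical(m$aa.x, m$aa.y)
  }
})

test_that("origin-spanning partial CDS pairs merge only on complete circular replicons", {
  ref <- test_ref()
  gen <- gen_genome(ref, seed = 5, n_exact = 3, n_mut_psc = 0,
                    n_mut_pscc = 0, n_sorfs = 0, with_edge_gene = TRUE)
  g <- gen$genome
  len <- g$replicons$length
  tr <- gen$truth[gen$truth$edge, ]
  dir <- withr::local_tempdir()
  paths <- write_genome_fixture(gen, dir)
  feats <- ingest_cds(paths[["truth_gff"]], g)
  parts <- feats[feats$partial5 | feats$partial3, ]
  expect_equal(nrow(parts), 2L)

  merged <- merge_edge_cds(feats, g)
  edge <- merged[merged$edge, ]
  expect_equal(nrow(edge), 1L)
  expect_equal(edge$start, tr$start)
  expect_equal(edge$stop, tr$stop)
  expect_equal(nchar(edge$aa), 82L)
  expect_identical(edge$aa, tr$aa)
  # total coding nucleotides conserved by the join
  expect_equal(nchar(edge$nt), sum(nchar(parts$nt)))

  # linear control: same features, linear topology -> no merge
  g_lin <- g
  g_lin$replicons$topology <- "linear"
  g_lin$replicons$completeness <- "incomplete"
  not_merged <- merge_edge_cds(feats, g_lin)
  expect_equal(sum(not_merged$edge), 0L)
  expect_equal(nrow(not_merged), nrow(feats))
})

test_that("partials on opposite strands are never merged", {
  # plant a fake pair: one partial at each edge, opposite strands
  s <- paste0(strrep("TTAATTAATTAA", 30))
  g <- mk_genome(s, topology = "circular")
  f <- new_feature_tbl(
    feature_id = c("a", "b"), replicon_id = "r1",
    start = c(0L, nchar(s) - 30L), stop = c(30L, nchar(s)),
    strand = c("+", "-"),
    partial5 = c(TRUE, FALSE), partial3 = c(FALSE, TRUE),
    edge = FALSE, feature_class = "cds",
    nt = c(substr(s, 1, 30), revcomp(substr(s, nchar(s) - 29, nchar(s)))),
    aa = ""
  )
  out <- merge_edge_cds(f, g)
  expect_equal(nrow(out), 2L)
  expect_equal(sum(out$edge), 0L)
})

test_that("sORF extraction respects the exclusive length bound", {
  cassette <- "TTAATTAATTAA"
  orf29 <- paste0("ATG", strrep("GGT", 28), "TAA") # 29 aa
  orf30 <- paste0("ATG", strrep("GGT", 29), "TAA") # 30 aa
  g <- mk_genome(paste0(cassette, orf29, cassette, orf30, cassette))
  sorfs <- extract_sorfs(g, max_aa_exclusive = 30, min_aa = 7)
  # the planted 29-aa ORF is included, the 30-aa one excluded
  expect_true(any(sorfs$start == 12L & sorfs$stop == 12L + nchar(orf29)))
  expect_false(any(sorfs$start == 24L + nchar(orf29)))
  expect_equal(sum(nchar(sorfs$aa) >= 30), 0L)
})

test_that("sORF extraction equals the brute-force oracle in the 7-29 aa window", {
  set.seed(33)
  for (i in 1:10) {
    topo <- if (i %% 2 == 0) "circular" else "linear"
    s <- random_dna(3000)
    g <- mk_genome(s, topology = topo)
    ours <- extract_sorfs(g)
    theirs <- oracle_orfs(s, min_aa = 7, max_aa_exclusive = 30,
                          circular = topo == "circular")
    expect_identical(orf_key(ours), orf_key(theirs),
                     label = sprintf("sorf set, case %d (%s)", i, topo))
  }
})

test_that("sORF protein set is invariant under rotation of a circular replicon", {
  set.seed(44)
  s <- random_dna(3000)
  g1 <- mk_genome(s, topology = "circular")
  for (k in c(1, 997, 1500)) {
    rot <- paste0(substr(s, k + 1, nchar(s)), substr(s, 1, k))
    g2 <- mk_genome(rot, topology = "circular")
    expect_identical(sort(extract_sorfs(g1)$aa), sort(extract_sorfs(g2)$aa),
                     label = sprintf("rotation by %d", k))
  }
})

test_that("spurious filtering removes exactly what the backend flags and aborts on failure", {
  ref <- test_ref()
  db <- test_db()
  feats <- new_feature_tbl(
    feature_id = c("f1", "f2", "f3"), replicon_id = "r1",
    start = c(0L, 100L, 200L), stop = c(60L, 160L, 260L), strand = "+",
    partial5 = FALSE, partial3 = FALSE, edge = FALSE, feature_class = "cds",
    nt = "", aa = c(ref$spurious$seq[1], "MAAAGH", "MWAAGH")
  )
  kept <- filter_spurious(feats, blocklist_backend(db))
  expect_setequal(kept$feature_id, c("f2", "f3"))
  expect_identical(attr(kept, "removed")$feature_id, "f1")

  # empty blocklist backend is the identity
  empty_db <- db
  empty_db$blocklist <- character(0)
  expect_equal(nrow(filter_spurious(feats, blocklist_backend(empty_db))), 3L)

  # pluggable stub: flag proteins containing W
  kept_w <- filter_spurious(feats, function(aa) grepl("W", aa))
  expect_setequal(kept_w$feature_id, c("f2"))

  # backend failure aborts rather than silently skipping
  expect_error(filter_spurious(feats, function(aa) NA), "backend failed")
})

test_that("GFF3 CDS ingestion converts coordinates, strands, and rejects broken records", {
  s <- paste0(strrep("A", 10), "ATGGGTAAATAA", strrep("A", 12))
  g <- mk_genome(s)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    sprintf("##sequence-region r1 1 %d", nchar(s)),
    "r1\tsrc\tCDS\t11\t22\t.\t+\t0\tID=ok",
    # reverse-strand record: nt must be the reverse complement of the slice
    "r1\tsrc\tCDS\t11\t22\t.\t-\t0\tID=minus",
    # internal stop (in-frame TAA early): rejected with report
    sprintf("r1\tsrc\tCDS\t11\t%d\t.\t+\t0\tID=bad", 10 + 12 + 9)
  ), gff)
  feats <- ingest_cds(gff, g)
  ok <- feats[feats$feature_id == "ok", ]
  expect_equal(ok$start, 10L)
  expect_equal(ok$stop, 22L)
  expect_identical(ok$aa, "MGK")
  minus <- feats[feats$feature_id == "minus", ]
  expect_identical(minus$nt, revcomp(substr(s, 11, 22)))
  expect_false("bad" %in% feats$feature_id)
  rej <- attr(feats, "rejected")
  expect_equal(nrow(rej), 1L)
  expect_match(rej$reason, "internal stop")

  writeLines(c("##gff-version 3",
               "nope\tsrc\tCDS\t1\t12\t.\t+\t0\tID=x"), gff)
  expect_error(ingest_cds(gff, g), "unknown replicon")
})
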