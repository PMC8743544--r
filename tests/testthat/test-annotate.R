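test_that("AFSI identifies stored proteins and misses mutants and absentees", {
  ref <- test_ref()
  db <- test_db()
  stored <- ref$manifest$seq[1]
  res <- identify_afsi(stored, db)
  expect_true(res$hit)
  expect_identical(res$tier, "ips")
  expect_true(any(grepl("^UniRef:UniRef100_", res$dbxrefs[[1]])))

  # one-residue, length-preserving mutant: digest miss
  chars <- strsplit(stored, "")[[1]]
  chars[5] <- setdiff(c("A", "G"), chars[5])[1]
  mut <- paste(chars, collapse = "")
  expect_false(identify_afsi(mut, db)$hit)

  expect_false(identify_afsi("MNOTINDBATALL", db)$hit)
})

test_that("AFSI equals brute-force exact string matching on a mixed query set", {
  ref <- test_ref()
  db <- test_db()
  seqs <- unique(ref$manifest$seq)
  set.seed(9)
  queries <- c(
    sample(seqs, 50, replace = TRUE),
    vapply(sample(seqs, 50, replace = TRUE), function(s) {
      chars <- strsplit(s, "")[[1]]
      i <- sample(seq_along(chars), 1)
      chars[i] <- sample(setdiff(c("A", "C", "D", "E"), chars[i]), 1)
      paste(chars, collapse = "")
    }, character(1)),
    vapply(1:50, function(i) random_aa(sample(10:100, 1)), character(1))
  )
  ours <- identify_afsi(queries, db)$hit
  oracle <- queries %in% seqs
  expect_identical(ours, oracle)
})

test_that("hit routing partitions by identity and requires mutual coverage", {
  grid <- expand.grid(identity = c(0.49, 0.50, 0.899, 0.90, 0.95),
                      cov = c(0.79, 0.80, 1.00))
  hits <- tibble::tibble(identity = grid$identity,
                         query_cov = grid$cov, subject_cov = grid$cov)
  routes <- route_hits(hits)
  expect_true(all(routes[hits$query_cov < 0.80] == "none"))
  accepted <- hits$query_cov >= 0.80
  expected <- c("none", "pscc", "pscc", "psc", "psc")
  for (cov in c(0.80, 1.00)) {
    sel <- accepted & hits$query_cov == cov
    expect_identical(routes[sel], expected)
  }
  # asymmetric coverage also rejects
  expect_identical(
    route_hits(tibble::tibble(identity = 0.95, query_cov = 0.79,
                              subject_cov = 1)),
    "none"
  )
})

test_that("cluster search routes mutants by measured identity and picks the best hit", {
  ref <- test_ref()
  db <- test_db()
  rep1 <- ref$manifest[ref$manifest$is_rep, ][1, ]
  set.seed(12)
  m95 <- cdsannot:::.mutate_protein(rep1$seq, 0.95)
  hit <- search_clusters(m95, db)
  expect_identical(hit$route, "psc")
  expect_identical(hit$subject_id, rep1$uniref90_id)
  expect_gte(hit$identity, 0.90)
  m70 <- cdsannot:::.mutate_protein(rep1$seq, 0.70)
  hit70 <- search_clusters(m70, db)
  expect_identical(hit70$route, "pscc")
  expect_lt(hit70$identity, 0.90)
  expect_gte(hit70$identity, 0.50)
  # unrelated protein: nothing
  expect_identical(search_clusters(random_aa(150, first_m = TRUE), db)$route,
                   "none")
})

test_that("expert rules apply their own thresholds and the highest rank wins", {
  db <- test_db()
  rules <- db$expert
  # exact sequence equality: eligible with identity 1.0, no alignment needed
  res <- apply_expert(rules$seq[1], db)
  expect_identical(res$tier, "expert")
  expect_identical(res$product, rules$product[1])
  expect_identical(res$rule_rank, rules$rank[1])

  # two eligible rules with equal sequence: higher rank wins
  db2 <- db
  db2$expert <- tibble::tibble(
    rule_id = c("r10", "r20"), source = "x", rank = c(10L, 20L),
    gene = c("g10", "g20"), product = c("p10", "p20"),
    min_identity = 0.9, min_query_cov = 0.9, min_subject_cov = 0.9,
    seq = rules$seq[1], dbxrefs = ""
  )
  res2 <- apply_expert(rules$seq[1], db2)
  expect_identical(res2$product, "p20")
  expect_identical(res2$rule_rank, 20L)

  # meeting identity but not subject coverage -> ineligible
  db3 <- db
  long_rule <- paste0(rules$seq[1], strrep("A", nchar(rules$seq[1])))
  db3$expert <- tibble::tibble(
    rule_id = "rcov", source = "x", rank = 1L, gene = "g", product = "p",
    min_identity = 0.9, min_query_cov = 0.9, min_subject_cov = 0.9,
    seq = long_rule, dbxrefs = ""
  )
  expect_null(apply_expert(rules$seq[1], db3))
})

ann_row <- function(tier, gene = NA_character_, product = NA_character_,
                    dbx = character(0), rank = NA_integer_) {
  tibble::tibble(gene = gene, product = product, dbxrefs = list(dbx),
                 tier = tier, rule_rank = rank)
}

test_that("concluding annotation enumerates all tier combinations correctly", {
  cands <- list(
    expert = ann_row("expert", gene = "gE", product = "expert product",
                     dbx = "ExpertDB:X", rank = 5L),
    ips = ann_row("ips", gene = "gI", product = "ips product",
                  dbx = "UniRef:UniRef100_A"),
    psc = ann_row("psc", gene = "gP", product = "psc product",
                  dbx = c("UniRef:UniRef90_B", "COG:COG0001")),
    pscc = ann_row("pscc", product = "pscc product",
                   dbx = "UniRef:UniRef50_C")
  )
  order4 <- c("expert", "ips", "psc", "pscc")
  for (mask in 0:15) {
    present <- order4[bitwAnd(mask, c(8L, 4L, 2L, 1L)) > 0]
    args <- lapply(order4, function(t) if (t %in% present) cands[[t]])
    names(args) <- order4
    out <- do.call(conclude_annotation, args)
    if (length(present) == 0) {
      expect_identical(out$tier, "hypothetical")
      expect_identical(out$product, "hypothetical protein")
    } else {
      expect_identical(out$tier, present[1],
                       label = sprintf("mask %d", mask))
      expect_identical(out$product, cands[[present[1]]]$product)
      expect_setequal(
        out$dbxrefs[[1]],
        unique(unlist(lapply(present, function(t) cands[[t]]$dbxrefs[[1]])))
      )
    }
  }
})

test_that("gaps are filled from lower tiers and uninformative products defer", {
  # ips present without product: tier stays ips, product from psc
  out <- conclude_annotation(
    ips = ann_row("ips", dbx = "UniRef:UniRef100_A"),
    psc = ann_row("psc", gene = "gP", product = "psc product")
  )
  expect_identical(out$tier, "ips")
  expect_identical(out$product, "psc product")
  expect_identical(out$gene, "gP")
  # hypothetical-synonym products are not informative
  out2 <- conclude_annotation(
    ips = ann_row("ips", product = "Uncharacterized protein"),
    pscc = ann_row("pscc", product = "real product")
  )
  expect_identical(out2$product, "real product")
  # evidence present but nothing informative -> hypothetical product, tier kept
  out3 <- conclude_annotation(ips = ann_row("ips", product = "putative protein"))
  expect_identical(out3$tier, "ips")
  expect_identical(out3$product, "hypothetical protein")
})

test_that("product refinement applies the deterministic rewrite chain", {
  expect_identical(refine_product("  DNA   polymerase III "),
                   "DNA polymerase III")
  expect_identical(refine_product("\"ATP synthase\""), "ATP synthase")
  expect_identical(refine_product("recA homolog"), "recA")
  expect_identical(refine_product("RecA-like protein"), "RecA")
  expect_identical(refine_product("uncharacterised kinase"),
                   "uncharacterized kinase")
  expect_identical(refine_product("Uncharacterised protein"),
                   "hypothetical protein")
  expect_identical(refine_product("Putative Protein"), "hypothetical protein")
  expect_identical(refine_product("conserved PREDICTED protein"),
                   "hypothetical protein")
})

test_that("molecular mass matches residue summation and pI behaves analytically", {
  ch <- characterize_protein("G")
  expect_equal(ch$mass, 75.07, tolerance = 0.001)
  # no ionizable side chains: pI is the midpoint of the terminal pKa values
  ch2 <- characterize_protein("GGAGG")
  expect_equal(ch2$pi, (pka_set[["nterm"]] + pka_set[["cterm"]]) / 2,
               tolerance = 1e-4)
  # net charge at the reported pI is ~0
  set.seed(5)
  peps <- vapply(1:50, function(i) random_aa(sample(5:200, 1)), character(1))
  ch3 <- characterize_protein(peps)
  expect_true(all(abs(peptide_charge(peps, ch3$pi)) < 1e-4))
  # appending R raises pI; appending D lowers it
  base_pi <- characterize_protein("GAGA")$pi
  expect_gt(characterize_protein("GAGAR")$pi, base_pi)
  expect_lt(characterize_protein("GAGAD")$pi, base_pi)
  # mass oracle: independent residue-mass summation
  oracle_mass <- vapply(peps, function(p) {
    sum(residue_masses[strsplit(p, "")[[1]]]) + 18.0153
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(ch3$mass, oracle_mass, tolerance = 1e-9)
})

test_that("overlap filter drops unidentified sORFs inside CDS and collapses duplicates", {
  f <- new_feature_tbl(
    feature_id = c("cds1", "cds1b", "s_hyp", "s_ips", "s_clear"),
    replicon_id = "r1",
    start = c(100L, 100L, 150L, 160L, 500L),
    stop = c(400L, 400L, 210L, 220L, 560L),
    strand = c("+", "+", "-", "+", "+"),
    partial5 = FALSE, partial3 = FALSE, edge = FALSE,
    feature_class = c("cds", "cds", "sorf", "sorf", "sorf"),
    nt = "", aa = ""
  )
  f$tier <- c("psc", "psc", "hypothetical", "ips", "hypothetical")
  out <- overlap_filter(f)
  expect_setequal(out$feature_id, c("cds1", "s_ips", "s_clear"))
  removed <- attr(out, "removed")
  expect_setequal(removed$feature_id, c("cds1b", "s_hyp"))
  expect_identical(removed$conflict_id[removed$feature_id == "s_hyp"], "cds1")
})

test_that("enriching the database with a query's sequence removes its alignments", {
  ref <- test_ref()
  db <- test_db()
  rep1 <- ref$manifest[ref$manifest$is_rep, ][1, ]
  set.seed(77)
  q <- cdsannot:::.mutate_protein(rep1$seq, 0.95)
  before <- search_clusters(q, db)
  expect_gt(before$n_alignments, 0)
  # add q itself to the store: AFSI resolves it, no cluster search needed
  ref2 <- gen_reference(seed = 42)
  prot2 <- dplyr::bind_rows(ref2$proteins,
                            tibble::tibble(protein_id = "NEW", seq = q))
  mem2 <- dplyr::bind_rows(
    ref2$membership,
    tibble::tibble(protein_id = "NEW", uniref100_id = "UniRef100_NEW",
                   uniref90_id = rep1$uniref90_id,
                   uniref50_id = rep1$uniref50_id)
  )
  db2 <- build_ref_db(prot2, mem2, ref2$annotations, ref2$expert,
                      ref2$blocklist)
  expect_true(identify_afsi(q, db2)$hit)
})
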