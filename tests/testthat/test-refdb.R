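test_that("MD5 digest matches an independent implementation and canonical inputs collide", {
  expect_identical(compute_digest("MGK"),
                   digest::digest("MGK", algo = "md5", serialize = FALSE))
  expect_identical(compute_digest(canonicalize_protein("mgk*")),
                   compute_digest("MGK"))
  set.seed(3)
  seqs <- unique(vapply(1:1000, function(i) random_aa(sample(10:500, 1)),
                        character(1)))
  expect_identical(length(unique(compute_digest(seqs))), length(seqs))
})

test_that("identifier prefix compression round-trips and leaves unknown prefixes verbatim", {
  cases <- c("UniRef100_ABC123", "UniRef90_Q99", "UniRef50_Z1",
             "WP_000000001.1")
  for (x in cases) {
    expect_identical(expand_id(shorten_id(x), id_namespace(x)), x)
  }
  expect_identical(shorten_id("UniRef100_ABC123"), "ABC123")
  expect_identical(shorten_id("WP_000000001.1"), "000000001.1")
  expect_identical(shorten_id("XY_1"), "XY_1")
  expect_true(is.na(id_namespace("XY_1")))
})

test_that("database build produces expected record counts and deduplicates by digest", {
  ref <- test_ref()
  db <- test_db()
  # fixture: 20 clusters x 3 members (one level-1.0 duplicate of the rep is
  # impossible here because member 1 IS the rep), plus 5 short proteins
  expect_equal(nrow(db$ups), length(unique(ref$manifest$digest)))
  expect_equal(nrow(db$ips), length(unique(ref$manifest$uniref100_id)))
  expect_equal(nrow(db$psc), 20L)
  expect_equal(nrow(db$pscc), 10L)
  expect_equal(db$meta$counts$ups, nrow(db$ups))

  # same sequence under two ids -> one UPS with both ids retrievable
  prot <- tibble::tibble(protein_id = c("A1", "A2"), seq = c("MGKH", "MGKH"))
  mem <- tibble::tibble(protein_id = c("A1", "A2"),
                        uniref100_id = c("UniRef100_X1", "UniRef100_X1"),
                        uniref90_id = NA_character_,
                        uniref50_id = NA_character_)
  db2 <- build_ref_db(prot, mem)
  expect_equal(nrow(db2$ups), 1L)
  expect_setequal(db2$ups$protein_ids[[1]], c("A1", "A2"))
  expect_true(any(db2$log$event == "dedup"))
})

test_that("forged digest collisions abort the build naming both records", {
  prot <- tibble::tibble(
    protein_id = c("B1", "B2"),
    seq = c("MGKH", "MAAA"),
    digest = rep("00ff00ff00ff00ff00ff00ff00ff00ff", 2)
  )
  mem <- tibble::tibble(protein_id = c("B1", "B2"),
                        uniref100_id = c("UniRef100_B1", "UniRef100_B2"),
                        uniref90_id = NA_character_,
                        uniref50_id = NA_character_)
  err <- tryCatch(build_ref_db(prot, mem), error = function(e) e)
  expect_s3_class(err, "cdsannot_digest_collision")
  expect_match(conditionMessage(err), "B1")
  expect_match(conditionMessage(err), "B2")
})

test_that("annotation sources supersede by declared specificity and events are logged", {
  prot <- tibble::tibble(protein_id = "C1", seq = "MGKHLLV")
  mem <- tibble::tibble(protein_id = "C1", uniref100_id = "UniRef100_C1",
                        uniref90_id = "UniRef90_C1",
                        uniref50_id = "UniRef50_C1")
  ann <- list(
    `cluster-derived` = tibble::tibble(key = "UniRef90_C1",
                                       product = "coarse protein"),
    `model-organism` = tibble::tibble(key = "UniRef90_C1",
                                      product = "specific enzyme")
  )
  db <- build_ref_db(prot, mem, ann)
  expect_identical(lookup_psc(db, "UniRef90_C1")$product, "specific enzyme")
  sup <- db$log[db$log$event == "supersede", ]
  expect_equal(nrow(sup), 1L)
  expect_identical(sup$old, "coarse protein")
  expect_identical(sup$new, "specific enzyme")
  expect_identical(sup$source, "model-organism")

  # within one source, later duplicate keys do not overwrite
  ann2 <- list(`model-organism` = tibble::tibble(
    key = c("UniRef90_C1", "UniRef90_C1"),
    product = c("first", "second")
  ))
  db2 <- build_ref_db(prot, mem, ann2)
  expect_identical(lookup_psc(db2, "UniRef90_C1")$product, "first")
  expect_true(any(db2$log$event == "skip-duplicate"))

  # annotation for an unknown cluster id is a hard failure
  ann3 <- list(`model-organism` = tibble::tibble(key = "UniRef90_NOPE",
                                                 product = "x"))
  expect_error(build_ref_db(prot, mem, ann3),
               class = "cdsannot_unknown_cluster")
})

test_that("UPS lookup requires both digest match and length equality", {
  db <- test_db()
  ref <- test_ref()
  aa <- ref$manifest$seq[1]
  hit <- lookup_ups(db, compute_digest(aa), nchar(aa))
  expect_true(hit$hit)
  expect_identical(hit$uniref100_id, ref$manifest$uniref100_id[1])
  # same digest, wrong length: no identification, collision reported
  expect_warning(
    miss <- lookup_ups(db, compute_digest(aa), nchar(aa) + 1L),
    "hash collision"
  )
  expect_false(miss$hit)
  expect_true(all(is.na(miss$uniref100_id)))
  expect_equal(nrow(attr(miss, "collisions")), 1L)
  # absent digest: nothing
  none <- lookup_ups(db, compute_digest("MNOTINDB"), 8L)
  expect_false(none$hit)
})

test_that("PSC/PSCC retrieval is exact-key", {
  db <- test_db()
  expect_equal(nrow(lookup_psc(db, "UniRef90_C001")), 1L)
  expect_equal(nrow(lookup_psc(db, "UniRef90_C999")), 0L)
  expect_equal(nrow(lookup_pscc(db, "UniRef50_S001")), 1L)
  expect_equal(nrow(lookup_pscc(db, "UniRef50_S999")), 0L)
})

test_that("schema version gate accepts any minor, rejects major mismatch", {
  expect_true(check_db_version(list(schema_major = 3, schema_minor = 0), 3))
  expect_true(check_db_version(list(schema_major = 3, schema_minor = 9), 3))
  err <- tryCatch(check_db_version(list(schema_major = 4, schema_minor = 0), 3),
                  error = function(e) e)
  expect_s3_class(err, "cdsannot_version_mismatch")
  expect_match(conditionMessage(err), "4\\.0")
  expect_match(conditionMessage(err), "3")
  expect_error(build_ref_db(tibble::tibble(protein_id = "X", seq = "MGK"),
                            tibble::tibble(protein_id = "X",
                                           uniref100_id = "UniRef100_X"),
                            version = "0.1"),
               "major")
})

test_that("SQLite persistence round-trips records through prefix compression", {
  db <- test_db()
  path <- withr::local_tempfile(fileext = ".db")
  write_ref_db(db, path)
  db2 <- read_ref_db(path)
  expect_equal(db2$meta$schema_major, db$meta$schema_major)
  expect_setequal(db2$ups$digest, db$ups$digest)
  expect_setequal(db2$ips$uniref100_id, db$ips$uniref100_id)
  # full public prefix queries resolve after the round-trip
  expect_equal(nrow(lookup_psc(db2, "UniRef90_C001")), 1L)
  expect_identical(
    sort(db2$psc$uniref50_id), sort(db$psc$uniref50_id)
  )
  expect_setequal(db2$blocklist, db$blocklist)
  # stored ids are actually compressed on disk
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  raw_ips <- DBI::dbReadTable(con, "ips")
  DBI::dbDisconnect(con)
  expect_false(any(grepl("^UniRef100_", raw_ips$uniref100_id)))
})

test_that("two builds from identical inputs are identical (records and log)", {
  ref <- test_ref()
  a <- build_fixture_db(ref)
  b <- build_fixture_db(ref)
  for (tb in c("ups", "ips", "psc", "pscc", "expert", "log")) {
    expect_equal(a[[tb]], b[[tb]], label = tb)
  }
  expect_identical(a$blocklist, b$blocklist)
})
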