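#' Reference-database compiler and query layer
#'
#' The annotation store is a four-tier hierarchy mirroring the UniRef cluster
#' levels:
#'
#' * **UPS** (unique protein sequence): one record per distinct full-length
#'   amino-acid sequence, keyed by its 16-byte MD5 digest, carrying the
#'   sequence length and the external identifiers it was imported under.
#' * **IPS** (identical protein sequence): UniRef100-level record linking a
#'   UPS to a gene symbol, product and the parent UniRef90 cluster.
#' * **PSC** (protein sequence cluster): UniRef90-level cluster with the
#'   representative sequence (used by the homology fallback), functional
#'   annotation (gene, product, COG, EC, GO) and the parent UniRef50 cluster.
#' * **PSCC** (protein sequence cluster of clusters): UniRef50-level cluster
#'   providing coarse product names.
#'
#' @name refdb
#' @keywords internal
NULL

#' MD5 digest of a canonical protein sequence
#'
#' Digests the ASCII bytes of the canonical amino-acid sequence; returned as
#' a lowercase 32-character hex string (16 bytes). Ambiguity residues
#' (X, B, Z, J, U, O) participate verbatim.
#'
#' @param aa Character vector of canonicalized amino-acid sequences.
#' @return Character vector of hex digests.
#' @export
#' @examples
#' compute_digest("MGK")
compute_digest <- function(aa) {
  if (length(aa) == 0) return(character(0))
  vapply(aa, function(s) as.character(openssl::md5(s)), character(1),
         USE.NAMES = FALSE)
}

## ---- identifier prefix compression -----------------------------------------

.id_prefixes <- c(
  uniref100 = "UniRef100_",
  uniref90 = "UniRef90_",
  uniref50 = "UniRef50_",
  refseq = "WP_"
)

#' Shorten / expand database identifiers
#'
#' Public identifiers are stored without their namespace prefix to keep the
#' persisted store compact; the transformation is reversed when reading.
#' Identifiers with an unregistered prefix are stored verbatim.
#'
#' @param public_id Character vector of public identifiers.
#' @param stored_id Character vector of stored (compressed) identifiers.
#' @param namespace One of `"uniref100"`, `"uniref90"`, `"uniref50"`,
#'   `"refseq"`.
#' @return `shorten_id()`: stored form; `expand_id()`: public form;
#'   `id_namespace()`: namespace name or `NA` for unregistered prefixes.
#' @export
shorten_id <- function(public_id) {
  out <- public_id
  for (p in .id_prefixes) {
    hit <- !is.na(out) & startsWith(out, p) & out == public_id # strip once
    out[hit] <- substring(out[hit], nchar(p) + 1L)
  }
  out
}

#' @rdname shorten_id
#' @export
expand_id <- function(stored_id, namespace) {
  pre <- unname(.id_prefixes[namespace])
  ifelse(is.na(stored_id) | is.na(pre), stored_id, paste0(pre, stored_id))
}

#' @rdname shorten_id
#' @export
id_namespace <- function(public_id) {
  ns <- rep(NA_character_, length(public_id))
  for (nm in names(.id_prefixes)) {
    ns[is.na(ns) & startsWith(public_id, .id_prefixes[[nm]])] <- nm
  }
  ns
}

## ---- audit log -------------------------------------------------------------

.new_log <- function() {
  tibble(
    event = character(0), record_type = character(0), key = character(0),
    source = character(0), field = character(0),
    old = character(0), new = character(0)
  )
}

.log_row <- function(event, record_type, key, source = NA_character_,
                     field = NA_character_, old = NA_character_,
                     new = NA_character_) {
  tibble(
    event = event, record_type = record_type, key = key,
    source = source, field = field, old = old, new = new
  )
}

## ---- build -----------------------------------------------------------------

#' Compile the reference annotation store
#'
#' Builds the UPS/IPS/PSC/PSCC hierarchy from a reference proteome plus
#' cluster-membership and per-source annotation tables. Digest uniqueness is
#' checked during the build: two distinct canonical sequences hashing to the
#' same digest abort the build naming both record ids. Annotation sources are
#' applied in increasing specificity; a more specific source supersedes
#' values from less specific ones, and every insert/supersession is appended
#' to the audit log.
#'
#' @param proteins Tibble with columns `protein_id`, `seq` (raw amino-acid
#'   sequences; canonicalized internally). An optional `digest` column of hex
#'   MD5 strings overrides internal computation (for externally hashed
#'   inputs); the uniqueness check applies either way.
#' @param membership Tibble with columns `protein_id`, `uniref100_id`,
#'   `uniref90_id`, `uniref50_id` (the latter two may be `NA`). The first row
#'   of each UniRef90 cluster names its representative sequence.
#' @param annotations Named list of per-source tibbles with columns `key`
#'   (a public UniRef100/UniRef90/UniRef50 identifier), `gene`, `product`,
#'   `cog_id`, `cog_category`, `ec`, `go` (multi-valued fields
#'   comma-separated; missing columns allowed).
#' @param expert Optional tibble of expert rules: `rule_id`, `source`,
#'   `rank`, `gene`, `product`, `min_identity`, `min_query_cov`,
#'   `min_subject_cov`, `seq`, `dbxrefs` (comma-separated).
#' @param blocklist Character vector of hex MD5 digests of known spurious
#'   sequences (the default spurious-filter backend).
#' @param version Schema version string `"<major>.<minor>"`; major must be
#'   at least 1.
#' @param specificity Character vector of source names ordered from most to
#'   least specific; sources absent from the list rank least specific, in
#'   input order.
#' @return A `ref_db` object: list of tibbles (`ups`, `ips`, `psc`, `pscc`,
#'   `expert`, `blocklist`), metadata (`meta`) and the audit `log`.
#' @export
build_ref_db <- function(proteins, membership, annotations = list(),
                         expert = NULL, blocklist = character(0),
                         version = "1.0",
                         specificity = c("expert-curated", "model-organism",
                                         "cluster-derived")) {
  stopifnot(
    all(c("protein_id", "seq") %in% names(proteins)),
    all(c("protein_id", "uniref100_id") %in% names(membership))
  )
  meta <- .parse_schema_version(version)
  log <- .new_log()

  prot <- proteins %>%
    mutate(seq = canonicalize_protein(.data$seq),
           aa_length = nchar(.data$seq))
  prot$digest <- if ("digest" %in% names(proteins)) {
    tolower(proteins$digest)
  } else {
    compute_digest(prot$seq)
  }

  # digest-uniqueness check: same digest must mean same sequence
  coll <- prot %>%
    group_by(.data$digest) %>%
    filter(dplyr::n_distinct(.data$seq) > 1L) %>%
    ungroup()
  if (nrow(coll) > 0L) {
    abort(sprintf(
      "MD5 digest collision between distinct sequences: %s",
      paste(coll$protein_id, collapse = ", ")
    ), class = "cdsannot_digest_collision")
  }

  if (!"uniref90_id" %in% names(membership)) membership$uniref90_id <- NA_character_
  if (!"uniref50_id" %in% names(membership)) membership$uniref50_id <- NA_character_
  missing_mem <- setdiff(prot$protein_id, membership$protein_id)
  if (length(missing_mem) > 0L) {
    abort(sprintf("proteins without membership rows: %s",
                  paste(missing_mem, collapse = ", ")))
  }

  pm <- prot %>% left_join(membership, by = "protein_id")
  bad100 <- pm %>% filter(is.na(.data$uniref100_id) | !nzchar(.data$uniref100_id))
  if (nrow(bad100) > 0L) {
    abort(sprintf("membership rows without a UniRef100 id: %s",
                  paste(bad100$protein_id, collapse = ", ")))
  }

  # one UPS per distinct canonical sequence; all source ids retained
  ups <- pm %>%
    group_by(.data$digest) %>%
    summarise(
      aa_length = .data$aa_length[1],
      uniref100_id = .data$uniref100_id[1],
      protein_ids = list(.data$protein_id),
      uniparc_id = .data$protein_id[1],
      .groups = "drop"
    )
  dup <- ups %>% filter(lengths(.data$protein_ids) > 1L)
  for (i in seq_len(nrow(dup))) {
    ids <- dup$protein_ids[[i]]
    log <- bind_rows(log, .log_row(
      "dedup", "ups", dup$digest[i], field = "protein_ids",
      new = paste(ids, collapse = ",")
    ))
  }
  log <- bind_rows(log, .log_row("insert", "ups", ups$digest))

  ips <- pm %>%
    distinct(.data$uniref100_id, .keep_all = TRUE) %>%
    select("uniref100_id", "uniref90_id") %>%
    mutate(gene = NA_character_, product = NA_character_)
  log <- bind_rows(log, .log_row("insert", "ips", ips$uniref100_id))

  psc <- pm %>%
    filter(!is.na(.data$uniref90_id)) %>%
    group_by(.data$uniref90_id) %>%
    summarise(
      uniref50_id = .data$uniref50_id[1],
      rep_seq = .data$seq[1], # first member listed is the representative
      .groups = "drop"
    ) %>%
    mutate(gene = NA_character_, product = NA_character_,
           cog_id = NA_character_, cog_category = NA_character_,
           ec = NA_character_, go = NA_character_)
  log <- bind_rows(log, .log_row("insert", "psc", psc$uniref90_id))

  pscc <- pm %>%
    filter(!is.na(.data$uniref50_id)) %>%
    distinct(.data$uniref50_id) %>%
    mutate(product = NA_character_)
  log <- bind_rows(log, .log_row("insert", "pscc", pscc$uniref50_id))

  db <- list(
    meta = meta, ups = ups, ips = ips, psc = psc, pscc = pscc,
    expert = .canon_expert(expert), blocklist = tolower(blocklist),
    log = log
  )

  # annotation sources, least specific applied first so that more specific
  # sources supersede (each supersession logged)
  src_names <- names(annotations) %||% character(0)
  order_apply <- c(setdiff(src_names, specificity),
                   rev(intersect(specificity, src_names)))
  for (src in order_apply) {
    db <- .apply_annotation_source(db, annotations[[src]], src)
  }

  db$meta$counts <- list(
    ups = nrow(db$ups), ips = nrow(db$ips), psc = nrow(db$psc),
    pscc = nrow(db$pscc), expert = nrow(db$expert),
    blocklist = length(db$blocklist)
  )
  structure(db, class = "ref_db",
            cache = new.env(parent = emptyenv()))
}

.parse_schema_version <- function(version) {
  parts <- strsplit(as.character(version), ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts)))) {
    abort(sprintf("schema version must be <major>.<minor>, got '%s'", version))
  }
  major <- as.integer(parts[1]); minor <- as.integer(parts[2])
  if (major < 1L) abort("schema major version must be >= 1")
  list(schema_major = major, schema_minor = minor, counts = list())
}

.canon_expert <- function(expert) {
  if (is.null(expert) || nrow(expert) == 0L) {
    return(tibble(
      rule_id = character(0), source = character(0), rank = integer(0),
      gene = character(0), product = character(0),
      min_identity = double(0), min_query_cov = double(0),
      min_subject_cov = double(0), seq = character(0), dbxrefs = character(0)
    ))
  }
  stopifnot(all(expert$min_identity >= 0 & expert$min_identity <= 1),
            all(expert$min_query_cov >= 0 & expert$min_query_cov <= 1),
            all(expert$min_subject_cov >= 0 & expert$min_subject_cov <= 1),
            all(expert$rank >= 0))
  expert %>%
    mutate(seq = canonicalize_protein(.data$seq),
           rank = as.integer(.data$rank)) %>%
    as_tibble()
}

.ann_fields <- c("gene", "product", "cog_id", "cog_category", "ec", "go")

.apply_annotation_source <- function(db, tbl, src) {
  if (is.null(tbl) || nrow(tbl) == 0L) return(db)
  for (f in setdiff(.ann_fields, names(tbl))) tbl[[f]] <- NA_character_
  # within one source, the first entry for a key wins
  dups <- duplicated(tbl$key)
  if (any(dups)) {
    db$log <- bind_rows(db$log, .log_row(
      "skip-duplicate", "annotation", tbl$key[dups], source = src
    ))
    tbl <- tbl[!dups, ]
  }
  ns <- id_namespace(tbl$key)
  if (anyNA(ns)) {
    abort(sprintf("annotation key(s) with unknown namespace: %s",
                  paste(tbl$key[is.na(ns)], collapse = ", ")))
  }
  for (i in seq_len(nrow(tbl))) {
    key <- tbl$key[i]
    target <- switch(ns[i],
      uniref100 = "ips", uniref90 = "psc", uniref50 = "pscc",
      abort(sprintf("annotation key '%s' is not a cluster identifier", key))
    )
    keycol <- switch(target, ips = "uniref100_id", psc = "uniref90_id",
                     pscc = "uniref50_id")
    idx <- which(db[[target]][[keycol]] == key)
    if (length(idx) == 0L) {
      abort(sprintf("annotation for unknown cluster id '%s' (source %s)",
                    key, src), class = "cdsannot_unknown_cluster")
    }
    fields <- intersect(.ann_fields, names(db[[target]]))
    for (f in fields) {
      val <- tbl[[f]][i]
      if (is.na(val) || !nzchar(val)) next
      old <- db[[target]][[f]][idx]
      if (!is.na(old) && old != val) {
        db$log <- bind_rows(db$log, .log_row(
          "supersede", target, key, source = src, field = f,
          old = old, new = val
        ))
      } else {
        db$log <- bind_rows(db$log, .log_row(
          "annotate", target, key, source = src, field = f, new = val
        ))
      }
      db[[target]][[f]][idx] <- val
    }
  }
  db
}

## ---- lookups ---------------------------------------------------------------

#' Alignment-free UPS lookup (digest + length check)
#'
#' Looks up protein digests in the UPS index. A record is returned only when
#' both the digest matches and the stored sequence length equals the query
#' length; a digest match with unequal length is treated as a potential hash
#' collision: nothing is returned and the event is reported in the
#' `collisions` attribute (and as a warning).
#'
#' @param db A `ref_db`.
#' @param digest Character vector of hex digests.
#' @param aa_length Integer vector of query protein lengths.
#' @return Tibble with one row per query (`digest`, `aa_length`, `hit`,
#'   UPS/IPS fields for hits); attribute `collisions` lists length-mismatch
#'   events.
#' @export
lookup_ups <- function(db, digest, aa_length) {
  q <- tibble(digest = digest, q_len = as.integer(aa_length))
  m <- q %>%
    left_join(
      db$ups %>% select("digest", ups_len = "aa_length", "uniref100_id",
                        "uniparc_id"),
      by = "digest"
    ) %>%
    left_join(db$ips, by = "uniref100_id")
  collisions <- m %>%
    filter(!is.na(.data$ups_len) & .data$ups_len != .data$q_len)
  if (nrow(collisions) > 0L) {
    warn(sprintf(
      "digest match with unequal sequence length for %d quer%s (possible hash collision); not identified",
      nrow(collisions), if (nrow(collisions) == 1L) "y" else "ies"
    ))
  }
  m <- m %>%
    mutate(hit = !is.na(.data$ups_len) & .data$ups_len == .data$q_len) %>%
    mutate(across(
      c("uniref100_id", "uniparc_id", "uniref90_id", "gene", "product"),
      ~ if_else(.data$hit, .x, NA_character_)
    ))
  attr(m, "collisions") <- collisions %>%
    select("digest", "q_len", "ups_len")
  m
}

#' Exact-key PSC / PSCC retrieval
#'
#' @param db A `ref_db`.
#' @param uniref90_id,uniref50_id Public cluster identifiers.
#' @return Tibble of matching records (zero rows when absent).
#' @export
lookup_psc <- function(db, uniref90_id) {
  db$psc %>% filter(.data$uniref90_id %in% .env$uniref90_id)
}

#' @rdname lookup_psc
#' @export
lookup_pscc <- function(db, uniref50_id) {
  db$pscc %>% filter(.data$uniref50_id %in% .env$uniref50_id)
}

#' Check schema compatibility of a database
#'
#' A database is compatible when its schema major version equals the
#' supported major version; any minor version is accepted.
#'
#' @param meta Database metadata (`db$meta`).
#' @param supported_major Integer major version the caller supports.
#' @return `TRUE` invisibly, or an error naming both versions.
#' @export
check_db_version <- function(meta, supported_major = 1L) {
  if (!identical(as.integer(meta$schema_major), as.integer(supported_major))) {
    abort(sprintf(
      "incompatible database schema: database is %d.%d, supported major is %d",
      meta$schema_major, meta$schema_minor, as.integer(supported_major)
    ), class = "cdsannot_version_mismatch")
  }
  invisible(TRUE)
}

## ---- persistence (single-file SQLite store) --------------------------------

.hex_to_raw <- function(hex) {
  lapply(hex, function(h) {
    as.raw(strtoi(substring(h, seq(1, nchar(h), 2), seq(2, nchar(h), 2)), 16L))
  })
}

.raw_to_hex <- function(blobs) {
  vapply(blobs, function(b) paste(sprintf("%02x", as.integer(b)), collapse = ""),
         character(1))
}

#' Persist / load the reference store as a single SQLite file
#'
#' Digests are stored as 16-byte BLOB keys and identifier prefixes are
#' compressed (`UniRef100_`/`UniRef90_`/`UniRef50_`/`WP_` stripped,
#' reconstructed on read). The store is read-only at annotation time. The
#' audit log is written alongside as TSV and the metadata as JSON.
#'
#' @param db A `ref_db`.
#' @param path Path of the database file to write/read.
#' @param supported_major Major schema version accepted by `read_ref_db()`.
#' @return `write_ref_db()`: `path` invisibly; `read_ref_db()`: a `ref_db`.
#' @export
write_ref_db <- function(db, path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  ups <- db$ups %>%
    mutate(
      uniref100_id = shorten_id(.data$uniref100_id),
      protein_ids = map_chr(.data$protein_ids, paste, collapse = ",")
    )
  ups$digest <- I(.hex_to_raw(db$ups$digest))
  ips <- db$ips %>%
    mutate(uniref100_id = shorten_id(.data$uniref100_id),
           uniref90_id = shorten_id(.data$uniref90_id))
  psc <- db$psc %>%
    mutate(uniref90_id = shorten_id(.data$uniref90_id),
           uniref50_id = shorten_id(.data$uniref50_id))
  pscc <- db$pscc %>% mutate(uniref50_id = shorten_id(.data$uniref50_id))
  DBI::dbWriteTable(con, "ups", as.data.frame(ups), overwrite = TRUE)
  DBI::dbWriteTable(con, "ips", as.data.frame(ips), overwrite = TRUE)
  DBI::dbWriteTable(con, "psc", as.data.frame(psc), overwrite = TRUE)
  DBI::dbWriteTable(con, "pscc", as.data.frame(pscc), overwrite = TRUE)
  DBI::dbWriteTable(con, "expert", as.data.frame(db$expert), overwrite = TRUE)
  DBI::dbWriteTable(con, "blocklist",
                    data.frame(digest = db$blocklist), overwrite = TRUE)
  DBI::dbWriteTable(con, "meta", data.frame(
    schema_major = db$meta$schema_major,
    schema_minor = db$meta$schema_minor
  ), overwrite = TRUE)
  DBI::dbWriteTable(con, "log", as.data.frame(db$log), overwrite = TRUE)
  DBI::dbExecute(con, "CREATE INDEX idx_ups_digest ON ups(digest)")
  DBI::dbExecute(con, "VACUUM")
  invisible(path)
}

#' @rdname write_ref_db
#' @export
read_ref_db <- function(path, supported_major = 1L) {
  if (!file.exists(path)) abort(sprintf("database file not found: %s", path))
  con <- DBI::dbConnect(RSQLite::SQLite(), path, flags = RSQLite::SQLITE_RO)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  meta_df <- DBI::dbReadTable(con, "meta")
  meta <- list(schema_major = meta_df$schema_major[1],
               schema_minor = meta_df$schema_minor[1], counts = list())
  check_db_version(meta, supported_major)
  ups <- as_tibble(DBI::dbReadTable(con, "ups")) %>%
    mutate(
      digest = .raw_to_hex(.data$digest),
      uniref100_id = expand_id(.data$uniref100_id, "uniref100"),
      protein_ids = str_split(.data$protein_ids, ",")
    )
  ips <- as_tibble(DBI::dbReadTable(con, "ips")) %>%
    mutate(uniref100_id = expand_id(.data$uniref100_id, "uniref100"),
           uniref90_id = expand_id(.data$uniref90_id, "uniref90"))
  psc <- as_tibble(DBI::dbReadTable(con, "psc")) %>%
    mutate(uniref90_id = expand_id(.data$uniref90_id, "uniref90"),
           uniref50_id = expand_id(.data$uniref50_id, "uniref50"))
  pscc <- as_tibble(DBI::dbReadTable(con, "pscc")) %>%
    mutate(uniref50_id = expand_id(.data$uniref50_id, "uniref50"))
  db <- list(
    meta = meta, ups = ups, ips = ips, psc = psc, pscc = pscc,
    expert = as_tibble(DBI::dbReadTable(con, "expert")),
    blocklist = DBI::dbReadTable(con, "blocklist")$digest,
    log = as_tibble(DBI::dbReadTable(con, "log"))
  )
  db$meta$counts <- list(
    ups = nrow(db$ups), ips = nrow(db$ips), psc = nrow(db$psc),
    pscc = nrow(db$pscc), expert = nrow(db$expert),
    blocklist = length(db$blocklist)
  )
  structure(db, class = "ref_db",
            cache = new.env(parent = emptyenv()))
}

#' Write the audit log as TSV and metadata as JSON
#'
#' @param db A `ref_db`.
#' @param log_path,meta_path Output paths.
#' @export
write_db_sidecars <- function(db, log_path, meta_path) {
  readr::write_tsv(db$log, log_path)
  jsonlite::write_json(
    list(schema_version = sprintf("%d.%d", db$meta$schema_major,
                                  db$meta$schema_minor),
         counts = db$meta$counts),
    meta_path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(NULL)
}

#' @export
print.ref_db <- function(x, ...) {
  cat(sprintf(
    "<ref_db> schema %d.%d | %d UPS, %d IPS, %d PSC, %d PSCC, %d expert rules, %d blocked digests\n",
    x$meta$schema_major, x$meta$schema_minor,
    nrow(x$ups), nrow(x$ips), nrow(x$psc), nrow(x$pscc),
    nrow(x$expert), length(x$blocklist)
  ))
  invisible(x)
}
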