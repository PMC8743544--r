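#' Readers and writers: FASTA genomes, replicon metadata, GFF3, JSON,
#' feature tables
#'
#' @name io
#' @keywords internal
NULL

.result_schema_version <- "1.0"

#' Read an assembled genome from FASTA with optional replicon metadata
#'
#' Reads a (optionally gzip-compressed) nucleotide FASTA and an optional
#' tab-separated replicon-metadata table with columns `original_id`,
#' `new_id`, `type` (chromosome/plasmid/contig), `topology`
#' (circular/linear), `name`, and optionally `completeness`
#' (complete/incomplete). Replicons without metadata default to
#' contig/linear/incomplete; completeness defaults to complete for circular
#' replicons. Sequences are uppercased and non-ACGT characters mapped to N.
#'
#' @param fasta_path Path to FASTA (`.gz` handled transparently).
#' @param replicon_tsv Optional path to the metadata TSV.
#' @return A `cdsannot_genome`: list with `replicons` tibble
#'   (`id`, `name`, `rep_type`, `topology`, `completeness`, `length`) and
#'   `seq` (named character vector).
#' @export
read_genome <- function(fasta_path, replicon_tsv = NULL) {
  set <- Biostrings::readDNAStringSet(fasta_path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sequence ids in FASTA: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- ids

  replicons <- tibble(
    id = ids, name = ids, rep_type = "contig",
    topology = "linear", completeness = "incomplete",
    length = unname(nchar(seqs))
  )
  if (!is.null(replicon_tsv)) {
    meta <- readr::read_tsv(replicon_tsv, show_col_types = FALSE,
                            col_types = readr::cols(.default = "c"))
    required <- c("original_id", "new_id", "type", "topology", "name")
    if (!all(required %in% names(meta))) {
      abort(sprintf("replicon TSV must have columns: %s",
                    paste(required, collapse = ", ")))
    }
    unknown <- setdiff(meta$original_id, ids)
    if (length(unknown) > 0L) {
      abort(sprintf("replicon TSV references unknown sequence id(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    for (i in seq_len(nrow(meta))) {
      j <- which(replicons$id == meta$original_id[i])
      new_id <- meta$new_id[i] %||% meta$original_id[i]
      if (!is.na(new_id) && nzchar(new_id)) {
        names(seqs)[j] <- new_id
        replicons$id[j] <- new_id
      }
      replicons$name[j] <- meta$name[i] %||% replicons$id[j]
      replicons$rep_type[j] <- meta$type[i]
      replicons$topology[j] <- meta$topology[i]
      replicons$completeness[j] <-
        if ("completeness" %in% names(meta) && !is.na(meta$completeness[i])) {
          meta$completeness[i]
        } else if (meta$topology[i] == "circular") "complete" else "incomplete"
    }
  }
  stopifnot(all(replicons$topology %in% c("circular", "linear")),
            all(replicons$rep_type %in% c("chromosome", "plasmid", "contig")),
            all(replicons$completeness %in% c("complete", "incomplete")))
  structure(list(replicons = replicons, seq = seqs),
            class = "cdsannot_genome")
}

#' @export
print.cdsannot_genome <- function(x, ...) {
  cat(sprintf("<genome> %d replicon(s), %d bp total\n",
              nrow(x$replicons), sum(x$replicons$length)))
  print(x$replicons)
  invisible(x)
}

## ---- GFF3 ------------------------------------------------------------------

.gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  gsub("\n", "%0A", x, fixed = TRUE)
}

.gff_attr_string <- function(row) {
  vals <- c(
    ID = row$feature_id,
    gene = if (!is.null(row$gene) && !is.na(row$gene)) row$gene,
    product = if (!is.null(row$product) && !is.na(row$product)) row$product,
    Dbxref = if (!is.null(row$dbxrefs[[1]]) && length(row$dbxrefs[[1]]) > 0) {
      paste(.gff_escape(row$dbxrefs[[1]]), collapse = ",")
    },
    partial5 = if (isTRUE(row$partial5)) "true",
    partial3 = if (isTRUE(row$partial3)) "true"
  )
  vals <- vals[!vapply(vals, is.null, logical(1))]
  esc <- ifelse(names(vals) == "Dbxref", vals, .gff_escape(unlist(vals)))
  paste(sprintf("%s=%s", names(vals), esc), collapse = ";")
}

#' Write annotated features as GFF3
#'
#' Emits a `##gff-version 3` header with `##sequence-region` pragmas,
#' 1-based inclusive coordinates, and per-feature attributes (`ID`, `gene`,
#' `product`, `Dbxref`, partial flags) with reserved characters
#' percent-encoded. Origin-spanning features are written as two lines sharing
#' one `ID` (the part at the sequence end first, then the part at the
#' sequence start), keeping files parseable by strict validators.
#'
#' @param features Feature tibble (annotation columns used when present).
#' @param genome A genome object.
#' @param path Output path.
#' @export
write_gff3 <- function(features, genome, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     genome$replicons$id, genome$replicons$length))
  if (!"dbxrefs" %in% names(features)) {
    features$dbxrefs <- vector("list", nrow(features))
  }
  if (!"gene" %in% names(features)) features$gene <- NA_character_
  if (!"product" %in% names(features)) features$product <- NA_character_
  for (i in seq_len(nrow(features))) {
    r <- features[i, ]
    len <- genome$replicons$length[genome$replicons$id == r$replicon_id]
    type <- if (r$feature_class == "sorf") "sorf" else "CDS"
    attrs <- .gff_attr_string(r)
    if (isTRUE(r$edge) && r$stop > len) {
      # two-part representation: 5' part (at sequence end) then 3' part
      lines <- c(
        lines,
        paste(r$replicon_id, "cdsannot", type, r$start + 1L, len, ".",
              r$strand, "0", attrs, sep = "\t"),
        paste(r$replicon_id, "cdsannot", type, 1L, r$stop - len, ".",
              r$strand, "0", attrs, sep = "\t")
      )
    } else {
      lines <- c(
        lines,
        paste(r$replicon_id, "cdsannot", type, r$start + 1L, r$stop, ".",
              r$strand, "0", attrs, sep = "\t")
      )
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- JSON result document ---------------------------------------------------

#' Write / read the full annotation result as JSON
#'
#' One versioned document carrying the genome metadata, per-replicon records,
#' per-feature records (coordinates, strand, class, sequences, annotation
#' with tier and dbxrefs, characterization) and run metadata (database
#' version, configuration, per-tier counts). `read_result_json()` restores a
#' model equal to the written one and rejects documents with an unsupported
#' schema major version.
#'
#' @param ann A `genome_annotation` from [annotate_genome()].
#' @param path Output/input path.
#' @return `read_result_json()`: a `genome_annotation`.
#' @export
write_result_json <- function(ann, path) {
  doc <- list(
    schema_version = .result_schema_version,
    genome = list(replicons = ann$genome$replicons,
                  seq = as.list(ann$genome$seq)),
    features = ann$features,
    summary = ann$summary
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_result_json
#' @export
read_result_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  ver <- doc$schema_version
  if (is.null(ver) ||
      strsplit(ver, ".", fixed = TRUE)[[1]][1] !=
      strsplit(.result_schema_version, ".", fixed = TRUE)[[1]][1]) {
    abort(sprintf("unsupported result schema version: %s",
                  ver %||% "<missing>"))
  }
  reps <- list_rbind(map(doc$genome$replicons, as_tibble)) %>%
    mutate(length = as.integer(.data$length))
  seqs <- unlist(doc$genome$seq)
  genome <- structure(list(replicons = reps, seq = seqs),
                      class = "cdsannot_genome")
  chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  dbl1 <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  int1 <- function(x) if (is.null(x)) NA_integer_ else as.integer(x)
  features <- list_rbind(map(doc$features, function(f) {
    tibble(
      feature_id = f$feature_id, replicon_id = f$replicon_id,
      start = as.integer(f$start), stop = as.integer(f$stop),
      strand = f$strand,
      partial5 = isTRUE(f$partial5), partial3 = isTRUE(f$partial3),
      edge = isTRUE(f$edge), feature_class = f$feature_class,
      nt = f$nt, aa = f$aa,
      locus_tag = chr1(f$locus_tag),
      gene = chr1(f$gene), product = chr1(f$product),
      tier = chr1(f$tier), rule_rank = int1(f$rule_rank),
      dbxrefs = list(as.character(unlist(f$dbxrefs))),
      mass = dbl1(f$mass), pi = dbl1(f$pi)
    )
  }))
  summary <- doc$summary
  summary$tier_counts <- unlist(summary$tier_counts)
  structure(list(genome = genome, features = features, summary = summary),
            class = "genome_annotation")
}

## ---- FASTA / TSV writers -----------------------------------------------------

.write_fasta <- function(seqs, ids, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(sprintf(">%s", ids[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write feature sequences as FASTA
#'
#' Writes `<prefix>.ffn` (nucleotide sequences of all features) and
#' `<prefix>.faa` (protein sequences of CDS/sORF features).
#'
#' @param features Feature tibble.
#' @param prefix Output path prefix.
#' @return Paths written, invisibly.
#' @export
write_feature_fastas <- function(features, prefix) {
  ids <- features$feature_id
  hdr <- if ("product" %in% names(features)) {
    ifelse(is.na(features$product), ids,
           paste(ids, features$product))
  } else ids
  ffn <- paste0(prefix, ".ffn")
  faa <- paste0(prefix, ".faa")
  .write_fasta(features$nt, hdr, ffn)
  coding <- features %>% filter(nzchar(.data$aa))
  hdr2 <- if ("product" %in% names(coding)) {
    ifelse(is.na(coding$product), coding$feature_id,
           paste(coding$feature_id, coding$product))
  } else coding$feature_id
  .write_fasta(coding$aa, hdr2, faa)
  invisible(c(ffn, faa))
}

#' Write the human-readable feature summary TSV
#'
#' One row per feature: replicon, class, 1-based coordinates, strand, gene,
#' product, number of database cross-references, annotation tier.
#'
#' @param features Feature tibble.
#' @param path Output path.
#' @export
write_summary_tsv <- function(features, path) {
  tbl <- tibble(
    replicon = features$replicon_id,
    class = features$feature_class,
    start = features$start + 1L,
    stop = features$stop,
    strand = features$strand,
    gene = if ("gene" %in% names(features)) features$gene else NA_character_,
    product = if ("product" %in% names(features)) features$product else NA_character_,
    n_dbxrefs = if ("dbxrefs" %in% names(features)) {
      lengths(features$dbxrefs)
    } else 0L,
    tier = if ("tier" %in% names(features)) features$tier else NA_character_
  )
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Write the hypothetical-protein table
#'
#' Rows for features whose concluding product is "hypothetical protein"
#' (including AFSI-identified proteins of unknown function), with their
#' sequence-based characterization: molecular mass (Da) and isoelectric
#' point, both to two decimals.
#'
#' @param features Feature tibble (annotated).
#' @param path Output path.
#' @export
write_hypotheticals_tsv <- function(features, path) {
  hyp <- features %>% filter(.data$product == "hypothetical protein")
  tbl <- tibble(
    feature_id = hyp$feature_id,
    replicon = hyp$replicon_id,
    start = hyp$start + 1L,
    stop = hyp$stop,
    strand = hyp$strand,
    length_aa = nchar(hyp$aa),
    mass_da = sprintf("%.2f", hyp$mass),
    pi = sprintf("%.2f", hyp$pi)
  )
  readr::write_tsv(tbl, path)
  invisible(path)
}
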