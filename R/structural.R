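#' Structural annotation: ORF calling, sORF extraction, origin-spanning
#' CDS merging, spurious filtering
#'
#' @name structural
#' @keywords internal
NULL

# Codon-level scan of one strand of one (possibly origin-extended) sequence.
# Returns maximal ORFs: for each in-frame stop codon, the ORF starting at the
# first start codon after the previous in-frame stop. Coordinates are 0-based
# half-open on the scanned string.
.scan_orfs <- function(s, min_aa) {
  n <- nchar(s)
  out <- list()
  for (frame in 0:2) {
    usable <- n - frame
    ncod <- usable %/% 3L
    if (ncod < 2L) next
    codons <- substring(s, frame + seq(1L, by = 3L, length.out = ncod),
                        frame + seq(3L, by = 3L, length.out = ncod))
    is_stop <- codons %in% .stop_codons
    is_start <- codons %in% .start_codons
    stops <- which(is_stop)
    starts <- which(is_start)
    if (length(stops) == 0L || length(starts) == 0L) next
    # previous in-frame stop for each start (0 = none)
    prev_stop <- findInterval(starts, stops)
    nxt <- prev_stop + 1L
    valid <- nxt <= length(stops)
    if (!any(valid)) next
    cand <- tibble(
      start_codon = starts[valid],
      stop_codon = stops[nxt[valid]]
    )
    # longest ORF per stop = earliest start after the previous stop
    cand <- cand %>%
      group_by(.data$stop_codon) %>%
      summarise(start_codon = min(.data$start_codon), .groups = "drop") %>%
      mutate(aa_len = .data$stop_codon - .data$start_codon) %>%
      filter(.data$aa_len >= min_aa)
    if (nrow(cand) == 0L) next
    out[[length(out) + 1L]] <- cand %>%
      mutate(start = frame + (.data$start_codon - 1L) * 3L,
             stop = frame + .data$stop_codon * 3L) %>%
      select("start", "stop", "aa_len")
  }
  if (length(out) == 0L) {
    return(tibble(start = integer(0), stop = integer(0), aa_len = integer(0)))
  }
  list_rbind(out)
}

#' Call open reading frames with a naive six-frame scanner
#'
#' Built-in fallback gene caller so the annotation engine runs without an
#' external predictor: reports all maximal ORFs (start codon ATG/GTG/TTG to
#' the nearest in-frame stop, longest ORF per stop) on both strands with a
#' protein of at least `min_aa` residues. On circular complete replicons the
#' scan continues across the origin; origin-spanning ORFs carry `edge = TRUE`
#' and a `stop` beyond the replicon length. This is a plain maximal-ORF
#' enumerator, not a statistical gene model.
#'
#' @param genome A genome object from [read_genome()].
#' @param min_aa Minimum protein length in residues.
#' @param feature_class Class label for the returned features.
#' @param max_aa_exclusive Optional exclusive upper bound on protein length.
#' @return Feature tibble (see [new_feature_tbl()]).
#' @export
naive_orf_call <- function(genome, min_aa = 30L, feature_class = "cds",
                           max_aa_exclusive = Inf) {
  res <- map(seq_len(nrow(genome$replicons)), function(i) {
    rep <- genome$replicons[i, ]
    s <- genome$seq[[rep$id]]
    len <- nchar(s)
    wrap <- rep$topology == "circular" && rep$completeness == "complete"
    # Circular replicons are scanned as three tandem copies and only ORFs
    # whose start codon falls in the middle copy are kept: every such ORF
    # sees its full upstream context (the previous in-frame stop, wherever
    # it sits on the circle), so the reported set is a function of the
    # circle, not of where the origin was drawn.
    scan_seq <- if (wrap) paste0(s, s, s) else s
    fwd <- .scan_orfs(scan_seq, min_aa) %>% mutate(strand = "+")
    rvs <- .scan_orfs(if (wrap) strrep(revcomp(s), 3L) else revcomp(s),
                      min_aa) %>% mutate(strand = "-")
    sl <- nchar(scan_seq)
    # map reverse-scan coordinates back to forward coordinates; the anchor
    # (start-codon position in scan orientation) rides along for filtering
    rvs <- rvs %>% mutate(anchor = .data$start,
                          tmp = sl - .data$stop, stop = sl - .data$start,
                          start = .data$tmp) %>% select(-"tmp")
    fwd <- fwd %>% mutate(anchor = .data$start)
    orfs <- bind_rows(fwd, rvs)
    if (wrap && nrow(orfs) > 0) {
      orfs <- orfs[orfs$anchor >= len & orfs$anchor < 2L * len &
                     (orfs$stop - orfs$start) <= len, ]
      orfs$start <- orfs$start - len
      orfs$stop <- orfs$stop - len
      neg <- orfs$start < 0L
      orfs$start[neg] <- orfs$start[neg] + len
      orfs$stop[neg] <- orfs$stop[neg] + len
    }
    orfs$anchor <- NULL
    if (nrow(orfs) == 0L) return(new_feature_tbl())
    orfs <- orfs %>% filter(.data$aa_len < max_aa_exclusive)
    if (nrow(orfs) == 0L) return(new_feature_tbl())
    nt <- pmap(list(orfs$start, orfs$stop, orfs$strand), function(a, b, st) {
      .extract_feature_nt(s, a, b, st, circular = wrap)
    })
    nt <- unlist(nt)
    aa <- vapply(nt, translate_cds, character(1), USE.NAMES = FALSE)
    new_feature_tbl(
      feature_id = sprintf("%s_orf_%s_%d_%d", rep$id,
                           ifelse(orfs$strand == "+", "f", "r"),
                           orfs$start, orfs$stop),
      replicon_id = rep$id,
      start = orfs$start, stop = orfs$stop, strand = orfs$strand,
      partial5 = FALSE, partial3 = FALSE,
      edge = orfs$stop > len,
      feature_class = feature_class, nt = nt, aa = aa
    )
  })
  list_rbind(res) %>% arrange(.data$replicon_id, .data$start, .data$stop)
}

#' Extract small-ORF (sORF) candidates
#'
#' Enumerates ORFs on both strands (six frames; across the origin on circular
#' complete replicons) encoding proteins of `min_aa` up to, but excluding,
#' `max_aa_exclusive` residues. Such small proteins fall below the length
#' cut-offs of de novo gene predictors and are recovered here by exhaustive
#' scanning; duplicates by (replicon, start, stop, strand) are removed.
#'
#' @param genome A genome object.
#' @param max_aa_exclusive Exclusive upper bound on protein length
#'   (default 30: "small" means shorter than 30 residues).
#' @param min_aa Minimum protein length (default 7).
#' @return Feature tibble with `feature_class = "sorf"`.
#' @export
extract_sorfs <- function(genome, max_aa_exclusive = 30L, min_aa = 7L) {
  naive_orf_call(genome, min_aa = min_aa, feature_class = "sorf",
                 max_aa_exclusive = max_aa_exclusive) %>%
    distinct(.data$replicon_id, .data$start, .data$stop, .data$strand,
             .keep_all = TRUE)
}

#' Merge origin-spanning partial CDS pairs on circular replicons
#'
#' On complete circular replicons, a gene spanning the artificial sequence
#' origin is predicted as two partial CDSs: one running off the end of the
#' sequence and one running off the start, on the same strand. Such pairs are
#' merged into a single feature (`edge = TRUE`) whose nucleotide sequence is
#' the concatenation across the origin, provided the merged sequence
#' translates cleanly (length a multiple of three, no internal stop);
#' otherwise the merge is abandoned and both partials retained. Only pairs
#' whose partial ends sit exactly at the sequence edges are merged.
#'
#' @param features Feature tibble.
#' @param genome A genome object.
#' @return Feature tibble with merged pairs replacing their parts.
#' @export
merge_edge_cds <- function(features, genome) {
  out <- features
  for (i in seq_len(nrow(genome$replicons))) {
    rep <- genome$replicons[i, ]
    if (rep$topology != "circular" || rep$completeness != "complete") next
    s <- genome$seq[[rep$id]]
    len <- nchar(s)
    f <- out %>% filter(.data$replicon_id == rep$id)
    for (st in c("+", "-")) {
      # partial at the end edge (runs off position len) / at the start edge
      at_end <- f %>% filter(.data$strand == st, .data$stop == len,
                             !.data$edge,
                             if (st == "+") .data$partial3 else .data$partial5)
      at_start <- f %>% filter(.data$strand == st, .data$start == 0L,
                               !.data$edge,
                               if (st == "+") .data$partial5 else .data$partial3)
      if (nrow(at_end) == 0L || nrow(at_start) == 0L) next
      if (nrow(at_end) > 1L || nrow(at_start) > 1L) {
        warn(sprintf(
          "multiple origin-flanking partial CDSs on %s strand of %s; merging the edge-adjacent pair only",
          st, rep$id
        ))
      }
      p_end <- at_end[1, ]; p_start <- at_start[1, ]
      m_start <- p_end$start
      m_stop <- len + p_start$stop
      nt <- .extract_feature_nt(s, m_start, m_stop, st, circular = TRUE)
      if (nchar(nt) %% 3L != 0L) next
      aa <- tryCatch(translate_cds(nt), error = function(e) NULL)
      if (is.null(aa)) next # does not translate cleanly; keep both partials
      merged <- new_feature_tbl(
        feature_id = p_end$feature_id,
        replicon_id = rep$id,
        start = m_start, stop = m_stop, strand = st,
        partial5 = FALSE, partial3 = FALSE, edge = TRUE,
        feature_class = "cds", nt = nt, aa = aa
      )
      out <- out %>%
        filter(!.data$feature_id %in% c(p_end$feature_id, p_start$feature_id)) %>%
        bind_rows(merged)
    }
  }
  out %>% arrange(.data$replicon_id, .data$start, .data$stop)
}

#' Filter spurious coding features through a pluggable backend
#'
#' Removes features whose protein a backend predicate flags as a known
#' false-positive sequence (e.g. shadow ORFs). The default backend,
#' [blocklist_backend()], flags proteins whose MD5 digest appears on the
#' reference database's blocklist; any function `aa -> logical` can be
#' supplied instead. Backend failures abort (filtering is never skipped
#' silently).
#'
#' @param features Feature tibble.
#' @param backend Function mapping a character vector of protein sequences
#'   to a logical vector (`TRUE` = spurious).
#' @return Retained features; removed rows in the `removed` attribute.
#' @export
filter_spurious <- function(features, backend) {
  if (nrow(features) == 0L) return(features)
  flagged <- backend(features$aa)
  if (!is.logical(flagged) || length(flagged) != nrow(features) ||
      anyNA(flagged)) {
    abort("spurious-filter backend failed: expected a complete logical vector")
  }
  removed <- features[flagged, ]
  kept <- features[!flagged, ]
  attr(kept, "removed") <- removed
  kept
}

#' @rdname filter_spurious
#' @param db A `ref_db` providing the digest blocklist.
#' @export
blocklist_backend <- function(db) {
  force(db)
  function(aa) compute_digest(aa) %in% db$blocklist
}

## ---- GFF3 ingest -----------------------------------------------------------

.gff_unescape <- function(x) {
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%26", "&", x, fixed = TRUE)
  x <- gsub("%2C", ",", x, fixed = TRUE)
  x <- gsub("%09", "\t", x, fixed = TRUE)
  x <- gsub("%0A", "\n", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

.parse_gff_attrs <- function(attr_str) {
  pairs <- strsplit(attr_str, ";", fixed = TRUE)[[1]]
  pairs <- pairs[nzchar(pairs)]
  kv <- strsplit(pairs, "=", fixed = TRUE)
  setNames(
    .gff_unescape(vapply(kv, function(p) paste(p[-1], collapse = "="),
                         character(1))),
    vapply(kv, `[[`, character(1), 1)
  )
}

#' Ingest pre-predicted CDS coordinates from GFF3
#'
#' Reads CDS records from a GFF3 file into the internal 0-based half-open
#' convention, extracts and translates their sequences, and rejects
#' non-partial records that fail the frame (length multiple of three) or
#' internal-stop checks; rejected records are reported, not fatal. Recognized
#' attributes: `ID`, `partial5`, `partial3` (`true`/`false`). Two CDS lines
#' sharing one `ID` on a circular replicon are re-joined into a single
#' origin-spanning feature.
#'
#' @param path GFF3 file path.
#' @param genome A genome object.
#' @return Feature tibble; rejected records in the `rejected` attribute
#'   (tibble with `line`, `reason`).
#' @export
ingest_cds <- function(path, genome) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  feats <- list()
  rejected <- tibble(line = character(0), reason = character(0))
  rows <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) {
      rejected <- bind_rows(rejected, tibble(line = ln, reason = "malformed"))
      next
    }
    if (!f[3] %in% c("CDS", "sorf", "sORF")) next
    attrs <- .parse_gff_attrs(f[9])
    rid <- f[1]
    if (!rid %in% genome$replicons$id) {
      abort(sprintf("GFF3 references unknown replicon '%s'", rid))
    }
    len <- genome$replicons$length[genome$replicons$id == rid]
    start1 <- as.integer(f[4]); end1 <- as.integer(f[5])
    if (is.na(start1) || is.na(end1) || start1 < 1L || end1 > len ||
        end1 < start1) {
      abort(sprintf("coordinates out of range in line: %s", ln))
    }
    rows[[length(rows) + 1L]] <- tibble(
      id = attrs[["ID"]] %||% sprintf("%s_%d_%d", rid, start1, end1),
      replicon_id = rid,
      start = start1 - 1L, stop = end1,
      strand = f[7],
      partial5 = isTRUE(unname(tolower(attrs["partial5"]) == "true")),
      partial3 = isTRUE(unname(tolower(attrs["partial3"]) == "true")),
      feature_class = if (f[3] == "CDS") "cds" else "sorf",
      line = ln
    )
  }
  if (length(rows) == 0L) {
    out <- new_feature_tbl()
    attr(out, "rejected") <- rejected
    return(out)
  }
  recs <- list_rbind(rows)

  # re-join two-line origin-spanning features sharing an ID
  joined <- list()
  for (id in unique(recs$id)) {
    g <- recs[recs$id == id, ]
    rep <- genome$replicons[genome$replicons$id == g$replicon_id[1], ]
    circ <- rep$topology == "circular" && rep$completeness == "complete"
    if (nrow(g) == 2L && circ && length(unique(g$strand)) == 1L &&
        any(g$stop == rep$length) && any(g$start == 0L)) {
      p_end <- g[g$stop == rep$length, ][1, ]
      p_start <- g[g$start == 0L, ][1, ]
      joined[[length(joined) + 1L]] <- tibble(
        id = id, replicon_id = p_end$replicon_id,
        start = p_end$start, stop = rep$length + p_start$stop,
        strand = p_end$strand, partial5 = FALSE, partial3 = FALSE,
        edge = TRUE, feature_class = p_end$feature_class, line = p_end$line
      )
    } else {
      joined[[length(joined) + 1L]] <- g %>% mutate(edge = FALSE)
    }
  }
  recs <- list_rbind(joined)

  keep <- rep(TRUE, nrow(recs))
  nt <- character(nrow(recs)); aa <- character(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    rep <- genome$replicons[genome$replicons$id == r$replicon_id, ]
    circ <- rep$topology == "circular" && rep$completeness == "complete"
    nt[i] <- .extract_feature_nt(genome$seq[[r$replicon_id]], r$start, r$stop,
                                 r$strand, circular = circ)
    partial <- r$partial5 || r$partial3
    if (!partial && nchar(nt[i]) %% 3L != 0L) {
      keep[i] <- FALSE
      rejected <- bind_rows(rejected,
                            tibble(line = r$line, reason = "length not a multiple of 3"))
      next
    }
    aa_i <- tryCatch(
      translate_cds(substr(nt[i], 1L, nchar(nt[i]) - nchar(nt[i]) %% 3L)),
      error = function(e) e
    )
    if (inherits(aa_i, "error")) {
      if (!partial) {
        keep[i] <- FALSE
        rejected <- bind_rows(rejected,
                              tibble(line = r$line, reason = "internal stop codon"))
        next
      }
      aa_i <- "" # partial fragments may lack a clean frame
    }
    aa[i] <- aa_i
  }
  out <- new_feature_tbl(
    feature_id = recs$id[keep], replicon_id = recs$replicon_id[keep],
    start = recs$start[keep], stop = recs$stop[keep],
    strand = recs$strand[keep],
    partial5 = recs$partial5[keep], partial3 = recs$partial3[keep],
    edge = recs$edge[keep], feature_class = recs$feature_class[keep],
    nt = nt[keep], aa = aa[keep]
  )
  attr(out, "rejected") <- rejected
  out
}
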