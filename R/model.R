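#' cdsannot: alignment-free identification and hierarchical annotation of
#' bacterial coding sequences
#'
#' Core conventions used throughout the package:
#'
#' * Coordinates are 0-based, half-open, on the forward strand. Conversion to
#'   the 1-based inclusive convention of GFF3 happens only in the writers.
#' * For features spanning the origin of a circular replicon (`edge = TRUE`),
#'   `stop` exceeds the replicon length; writers take it modulo the length.
#' * Protein sequences never carry a terminal stop symbol.
#' * Translation uses the bacterial/archaeal genetic code (table 11) with
#'   ATG/GTG/TTG accepted as initiators, all rendered as methionine.
#'
#' Feature tables are tibbles with columns `feature_id`, `replicon_id`,
#' `start`, `stop`, `strand`, `partial5`, `partial3`, `edge`,
#' `feature_class` (`"cds"` or `"sorf"`), `nt`, `aa`.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom dplyr %>% filter mutate select arrange bind_rows bind_cols left_join
#'   group_by ungroup summarise rename distinct n row_number anti_join
#'   semi_join slice pull across all_of first desc if_else coalesce
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data .env abort warn inform %||%
#' @importFrom purrr map map_chr map_int map_lgl map_dbl map2 pmap imap
#'   list_rbind keep compact
#' @importFrom stringr str_detect str_replace_all str_sub str_length
#'   str_split str_trim str_squish str_to_upper
#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

#' Canonicalize a protein sequence
#'
#' Uppercases, trims whitespace, and removes a single terminal stop symbol
#' (`*`). Sequences with internal stop symbols, characters outside the 20
#' standard residues plus X/B/Z/J/U/O, or that are empty after
#' canonicalization are rejected. Canonical form is the digest substrate:
#' two inputs identical up to case/terminal stop hash identically.
#'
#' @param raw Character vector of raw amino-acid sequences.
#' @return Character vector of canonical sequences.
#' @export
#' @examples
#' canonicalize_protein("mgk*")
canonicalize_protein <- function(raw) {
  if (length(raw) == 0) return(character(0))
  x <- str_to_upper(gsub("\\s+", "", raw))
  x <- sub("\\*$", "", x)
  if (any(!nzchar(x))) {
    abort("protein sequence empty after canonicalization")
  }
  bad_stop <- grepl("*", x, fixed = TRUE)
  if (any(bad_stop)) {
    abort(sprintf(
      "internal stop symbol in protein sequence(s): %s",
      paste(which(bad_stop), collapse = ", ")
    ))
  }
  bad_char <- grepl(sprintf("[^%s]", paste(.aa_alphabet, collapse = "")), x)
  if (any(bad_char)) {
    abort(sprintf(
      "invalid residue character in protein sequence(s): %s",
      paste(which(bad_char), collapse = ", ")
    ))
  }
  x
}

.split_codons <- function(nt) {
  n <- nchar(nt)
  if (n == 0L) return(character(0))
  substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate an in-frame coding sequence (genetic code table 11)
#'
#' Translates a nucleotide sequence whose length is a multiple of three.
#' The initiator codon (ATG/GTG/TTG at position 1) is rendered as M; a
#' terminal stop codon is dropped from the output. An internal stop codon is
#' an error carrying its 0-based nucleotide offset. Codons containing N
#' translate to X.
#'
#' @param nt Nucleotide string (ACGTN, uppercase).
#' @param table Genetic code table; only 11 is supported.
#' @return Amino-acid string without terminal stop.
#' @export
#' @examples
#' translate_cds("ATGGGTAAATAA")
translate_cds <- function(nt, table = 11L) {
  if (!identical(as.integer(table), 11L)) {
    abort("only translation table 11 is supported")
  }
  if (nchar(nt) %% 3L != 0L) {
    abort(sprintf("sequence length %d is not a multiple of 3", nchar(nt)))
  }
  codons <- .split_codons(nt)
  aa <- unname(.codon_table_11[codons])
  aa[is.na(aa)] <- "X" # ambiguous (N-containing) codons
  n <- length(aa)
  if (n == 0L) return("")
  if (aa[n] == "*") {
    aa <- aa[-n]
    codons <- codons[-n]
    n <- n - 1L
  }
  internal <- which(aa == "*")
  if (length(internal) > 0L) {
    abort(
      sprintf(
        "internal stop codon at nucleotide offset %d",
        (internal[1] - 1L) * 3L
      ),
      class = "cdsannot_internal_stop",
      offset = (internal[1] - 1L) * 3L
    )
  }
  if (n >= 1L && codons[1] %in% .start_codons) aa[1] <- "M"
  paste(aa, collapse = "")
}

#' Reverse complement of a nucleotide string
#'
#' @param nt Nucleotide string over ACGTN.
#' @return Reverse complement, same alphabet.
#' @export
revcomp <- function(nt) {
  vapply(
    nt,
    function(s) {
      chartr(
        "ACGTN", "TGCAN",
        paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
      )
    },
    character(1),
    USE.NAMES = FALSE
  )
}

#' Construct a feature table
#'
#' Standard constructor for the per-feature tibble used across the package;
#' validates coordinate conventions.
#'
#' @param feature_id,replicon_id Character.
#' @param start,stop Integers, 0-based half-open on the forward strand.
#' @param strand `"+"` or `"-"`.
#' @param partial5,partial3 Logical: feature runs off an edge.
#' @param edge Logical: spans the origin of a circular replicon.
#' @param feature_class `"cds"` or `"sorf"`.
#' @param nt,aa Sequences.
#' @return A feature tibble.
#' @export
new_feature_tbl <- function(feature_id = character(0),
                            replicon_id = character(0),
                            start = integer(0), stop = integer(0),
                            strand = character(0),
                            partial5 = logical(0), partial3 = logical(0),
                            edge = logical(0),
                            feature_class = character(0),
                            nt = character(0), aa = character(0)) {
  stopifnot(all(strand %in% c("+", "-")), all(start >= 0), all(stop >= start))
  tibble(
    feature_id = as.character(feature_id),
    replicon_id = as.character(replicon_id),
    start = as.integer(start), stop = as.integer(stop),
    strand = strand,
    partial5 = partial5, partial3 = partial3, edge = edge,
    feature_class = feature_class,
    nt = nt, aa = aa
  )
}

# Extract the nucleotide sequence of [start, stop) on `strand`; for edge
# features stop may exceed the replicon length and wraps around the origin.
.extract_feature_nt <- function(seq, start, stop, strand, circular = FALSE) {
  len <- nchar(seq)
  if (stop <= len) {
    s <- substr(seq, start + 1L, stop)
  } else {
    if (!circular) abort("feature overruns a linear replicon")
    s <- paste0(substr(seq, start + 1L, len), substr(seq, 1L, stop - len))
  }
  if (strand == "-") s <- revcomp(s) else s
}
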