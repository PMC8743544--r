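# Shared fixtures (built once per test run) and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

test_ref <- function() {
  if (is.null(.fixture_env$ref)) .fixture_env$ref <- gen_reference(seed = 42)
  .fixture_env$ref
}

test_db <- function() {
  if (is.null(.fixture_env$db)) .fixture_env$db <- build_fixture_db(test_ref())
  .fixture_env$db
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa <- function(n, first_m = FALSE) {
  res <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  s <- paste(sample(res, n, replace = TRUE), collapse = "")
  if (first_m) s <- paste0("M", substring(s, 2))
  s
}

# Independent codon-by-codon translation oracle backed by the Biostrings
# genetic-code table (not the package's own codon map).
oracle_translate <- function(nt) {
  gc11 <- Biostrings::getGeneticCode("11")
  n <- nchar(nt)
  codons <- substring(nt, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(gc11[codons])
  aa[is.na(aa)] <- "X"
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (length(aa) && codons[1] %in% c("ATG", "GTG", "TTG")) aa[1] <- "M"
  paste(aa, collapse = "")
}

# Independent brute-force ORF enumerator: explicit codon-walking state
# machine per frame and strand; circular sequences are scanned doubled and
# deduplicated by canonical anchor.
oracle_orfs <- function(seq, min_aa, max_aa_exclusive = Inf,
                        circular = FALSE) {
  gc11 <- Biostrings::getGeneticCode("11")
  starts3 <- c("ATG", "GTG", "TTG")
  scan_state_machine <- function(s) {
    out <- list()
    n <- nchar(s)
    for (fr in 0:2) {
      ncod <- (n - fr) %/% 3
      if (ncod < 2) next
      pos <- fr + seq(1, by = 3, length.out = ncod)
      codons <- substring(s, pos, pos + 2)
      cur <- NA_integer_
      for (c_i in seq_len(ncod)) {
        cd <- codons[c_i]
        if (!is.na(gc11[cd]) && gc11[cd] == "*") {
          if (!is.na(cur) && (c_i - cur) >= min_aa &&
              (c_i - cur) < max_aa_exclusive) {
            out[[length(out) + 1]] <- c(fr + (cur - 1L) * 3L, fr + c_i * 3L)
          }
          cur <- NA_integer_
        } else if (is.na(cur) && cd %in% starts3) {
          cur <- c_i
        }
      }
    }
    if (length(out) == 0) {
      return(data.frame(start = integer(0), stop = integer(0)))
    }
    m <- do.call(rbind, out)
    data.frame(start = m[, 1], stop = m[, 2])
  }
  L <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  # circular scan: three tandem copies, ORF anchored in the middle copy
  # (full upstream context regardless of where the origin is drawn)
  fwd_s <- if (circular) paste0(seq, seq, seq) else seq
  rev_s <- if (circular) paste0(rc, rc, rc) else rc
  sl <- nchar(fwd_s)
  fwd <- scan_state_machine(fwd_s)
  fwd$anchor <- fwd$start
  fwd$strand <- rep("+", nrow(fwd))
  rev <- scan_state_machine(rev_s)
  rev$anchor <- rev$start
  if (nrow(rev) > 0) {
    tmp <- sl - rev$stop
    rev$stop <- sl - rev$start
    rev$start <- tmp
  }
  rev$strand <- rep("-", nrow(rev))
  orfs <- rbind(fwd, rev)
  if (circular && nrow(orfs) > 0) {
    orfs <- orfs[orfs$anchor >= L & orfs$anchor < 2 * L &
                   (orfs$stop - orfs$start) <= L, ]
    orfs$start <- orfs$start - L
    orfs$stop <- orfs$stop - L
    neg <- orfs$start < 0
    orfs$start[neg] <- orfs$start[neg] + L
    orfs$stop[neg] <- orfs$stop[neg] + L
  }
  orfs$anchor <- NULL
  if (nrow(orfs) == 0) return(orfs)
  get_nt <- function(a, b, st) {
    s <- if (b <= L) substr(seq, a + 1, b) else {
      paste0(substr(seq, a + 1, L), substr(seq, 1, b - L))
    }
    if (st == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    } else s
  }
  orfs$aa <- mapply(function(a, b, st) {
    oracle_translate(get_nt(a, b, st))
  }, orfs$start, orfs$stop, orfs$strand)
  orfs[order(orfs$start, orfs$stop, orfs$strand), ]
}

orf_key <- function(df) {
  sort(sprintf("%d:%d:%s", df$start, df$stop, df$strand))
}
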