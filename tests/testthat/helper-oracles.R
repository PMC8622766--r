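# Independent oracles and small fixture builders used across tests.

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# deterministic filler sequence that leaves the caller's RNG untouched
random_dna_fixed <- function(n, seed = 1) {
  withr::with_seed(seed, random_dna(n))
}

# naive motif scan: test every offset by direct substring comparison
naive_motif_scan <- function(seq, motif) {
  n <- nchar(seq); m <- nchar(motif)
  if (m > n) return(integer())
  hits <- integer()
  for (o in 0:(n - m)) {
    if (substr(seq, o + 1, o + m) == motif) hits <- c(hits, o)
  }
  hits
}

# naive maximal exact tandem repeat finder: for every (start, unit
# length) pair, count exact copies by substring comparison and keep
# leftmost-maximal primitive-unit arrays
naive_tandem_repeats <- function(seq, unit_range, min_copies = 2) {
  n <- nchar(seq)
  recs <- list()
  for (u in unit_range[1]:min(unit_range[2], n %/% 2)) {
    for (s in 1:(n - 2 * u + 1)) {
      unit <- substr(seq, s, s + u - 1)
      # count whole copies rightwards
      k <- 1
      while (s + (k + 1) * u - 1 <= n &&
             substr(seq, s + k * u, s + (k + 1) * u - 1) == unit) k <- k + 1
      if (k < min_copies) next
      # partial trailing copy
      extra <- 0
      while (s + k * u + extra <= n &&
             substr(seq, s + k * u + extra, s + k * u + extra) ==
             substr(unit, extra + 1, extra + 1)) extra <- extra + 1
      # leftmost (not extendable by a full period to the left) and
      # not extendable leftwards within the same period phase
      if (s - 1 >= 1 &&
          substr(seq, s - 1, s - 1) == substr(seq, s + u - 1, s + u - 1)) next
      # primitive unit only (smallest-period convention)
      prim <- TRUE
      for (d in seq_len(u %/% 2)) {
        if (u %% d == 0 &&
            strrep(substr(unit, 1, d), u / d) == unit) prim <- FALSE
      }
      if (!prim) next
      recs[[length(recs) + 1]] <- data.frame(
        unit_length = u, copy_number = (k * u + extra) / u,
        start = s, unit_sequence = unit, stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) return(data.frame(unit_length = integer(),
                                       copy_number = numeric(),
                                       start = integer(),
                                       unit_sequence = character()))
  out <- unique(do.call(rbind, recs))
  out[order(out$start, out$unit_length), , drop = FALSE]
}

# Independent single-TDRL oracle: the set of all orders reachable from
# `source` by duplicating one contiguous block in tandem and deleting
# exactly one copy of each duplicated element. Works on collapsed
# strings via expand.grid, a different code path from the package's
# index-based enumerator.
oracle_tdrl_targets <- function(source) {
  n <- length(source)
  seen <- character()
  for (i in seq_len(n)) for (j in i:n) {
    block <- source[i:j]
    m <- length(block)
    choices <- expand.grid(rep(list(c(TRUE, FALSE)), m))
    for (r in seq_len(nrow(choices))) {
      keep_first <- as.logical(choices[r, ])
      res <- c(if (i > 1) source[1:(i - 1)],
               block[keep_first], block[!keep_first],
               if (j < n) source[(j + 1):n])
      seen <- c(seen, paste(res, collapse = ","))
    }
  }
  unique(seen)
}

# a random signed order over k fake labels
random_signed_order <- function(k) {
  labs <- paste0("g", seq_len(k))
  paste0(sample(c("", "-"), k, replace = TRUE), sample(labs))
}

# minimal hand-written GenBank text for parser tests
genbank_text_fixture <- function() {
  c("LOCUS       TEST01 60 bp    DNA     circular MIT 01-JAN-2026",
    "DEFINITION  Test record.",
    "ACCESSION   TEST01",
    "SOURCE      mitochondrion",
    "  ORGANISM  Testus fixtureus",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             3..11",
    '                     /product="cytochrome c oxidase subunit I"',
    "     tRNA            complement(12..25)",
    '                     /product="tRNA-Gln"',
    "     tRNA            26..39",
    '                     /product="tRNA-Ser"',
    '                     /note="anticodon:tga"',
    "     rRNA            join(55..60,1..2)",
    '                     /product="16S ribosomal RNA"',
    "ORIGIN",
    "        1 atgaaaccct aagggtttaa acccgggttt aaacccgggt ttaaacccgg gtttaaaccc",
    "//")
}
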