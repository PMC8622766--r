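#' Construct an annotated mitogenome record
#'
#' The basic container of the package: a (usually circular) DNA sequence
#' plus an ordered feature table. Internally all coordinates are 0-based
#' half-open; an origin-spanning feature on a circular genome is encoded
#' with `end > length(genome)` and interpreted modulo the genome length,
#' so one feature always corresponds to one biological gene. User-facing
#' reports convert back to 1-based inclusive GenBank coordinates.
#'
#' @param sequence DNA string over A,C,G,T,N (upper-cased on input).
#' @param features A data frame with columns `label`, `strand` (`"J"` or
#'   `"N"`), `start` (0-based inclusive) and `end` (exclusive; may exceed
#'   the genome length for origin-spanning features). An optional
#'   `category` column is filled from the canonical vocabulary when absent.
#' @param accession,organism Identifier and organism name.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `mitogenome`.
#' @export
#' @examples
#' g <- mitogenome("ATGAAACCCTAA",
#'                 tibble::tibble(label = "ND2", strand = "J",
#'                                start = 0, end = 12))
#' g
mitogenome <- function(sequence, features,
                       accession = "unknown", organism = "unknown organism",
                       topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  sequence <- toupper(as.character(sequence))
  stopifnot(nchar(sequence) > 0)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains letters outside {A,C,G,T,N}")
  features <- as_tibble(features)
  if (!nrow(features)) {
    features <- tibble(label = character(), category = character(),
                       strand = character(), start = integer(),
                       end = integer(), flagged = logical())
  } else {
    if (is.null(features[["category"]]))
      features$category <- gene_category(features$label)
    if (is.null(features[["flagged"]]))
      features$flagged <- startsWith(features$label, "unknown:")
    features <- features[, c("label", "category", "strand", "start", "end", "flagged")]
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
    len <- nchar(sequence)
    if (any(features$end <= features$start)) stop("feature with end <= start")
    if (any(features$start < 0 | features$start >= len))
      stop("feature start outside [0, genome length)")
    if (any(features$end - features$start > len))
      stop("feature span exceeds genome length")
    if (any(features$end > len) && topology == "linear")
      stop("origin-spanning feature on a linear genome")
    features <- features[order(features$start, features$end), ]
  }
  g <- structure(
    list(accession = accession, organism = organism, topology = topology,
         sequence = sequence, features = features),
    class = "mitogenome"
  )
  dup <- canonical_duplicates(g)
  if (length(dup))
    warning("duplicate canonical labels (flagged, not dropped): ",
            paste(dup, collapse = ", "))
  g
}

canonical_duplicates <- function(g) {
  lab <- g$features$label[!g$features$flagged & !(g$features$category %in% c("NCR"))]
  unique(lab[duplicated(lab)])
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s | %s | %s, %d bp, %d features\n",
              x$accession, x$organism, x$topology, nchar(x$sequence),
              nrow(x$features)))
  print(feature_table(x), n = 8)
  invisible(x)
}

#' @export
length.mitogenome <- function(x) nchar(x$sequence)

#' Extract a gene's sequence in reading orientation
#'
#' Returns the sub-sequence of the feature, reverse-complemented for
#' N-strand genes so that the result reads 5' to 3' of the encoded gene.
#' Origin-spanning features (end beyond the genome length) concatenate
#' the tail and head of the circular sequence.
#'
#' @param g A [mitogenome].
#' @param feature A feature: one row of `g$features`, a canonical label,
#'   or a row index.
#' @param orientation `"reading"` (default) or `"forward"` to keep the
#'   forward-strand slice regardless of the feature's strand.
#' @return A DNA string.
#' @export
#' @examples
#' g <- mitogenome("ATGCCC", tibble::tibble(label = "trnI", strand = "N",
#'                                          start = 0, end = 3))
#' extract_gene_sequence(g, "trnI")
extract_gene_sequence <- function(g, feature,
                                  orientation = c("reading", "forward")) {
  orientation <- match.arg(orientation)
  f <- resolve_feature(g, feature)
  s <- forward_slice(g, f$start, f$end)
  if (orientation == "reading" && f$strand == "N") s <- revcomp(s)
  s
}

resolve_feature <- function(g, feature) {
  if (is.character(feature)) {
    i <- which(g$features$label == feature)
    if (!length(i)) stop("no feature labeled ", feature)
    return(g$features[i[1], ])
  }
  if (is.numeric(feature)) return(g$features[feature, ])
  as_tibble(feature)[1, ]
}

# forward-strand slice of [start, end) with modular wrap
forward_slice <- function(g, start, end) {
  len <- nchar(g$sequence)
  if (start < 0 || end <= start || end - start > len)
    stop("coordinates outside modular range")
  if (end <= len) return(substr(g$sequence, start + 1, end))
  if (g$topology != "circular") stop("coordinates beyond a linear genome")
  paste0(substr(g$sequence, start + 1, len), substr(g$sequence, 1, end - len))
}

#' Feature table in GenBank-style coordinates
#'
#' One row per feature with 1-based inclusive coordinates (ends of
#' origin-spanning features keep counting past the genome length) and the
#' feature length, ordered by start.
#'
#' @param g A [mitogenome].
#' @return A tibble with columns `label`, `category`, `strand`, `start`,
#'   `end`, `length`.
#' @export
feature_table <- function(g) {
  f <- g$features
  tibble(label = f$label, category = f$category, strand = f$strand,
         start = f$start + 1L, end = f$end,
         length = f$end - f$start)
}

#' Write / read the TSV feature table
#'
#' @param g A [mitogenome].
#' @param path Output (input) file path.
#' @return `write_feature_table` invisibly returns the tibble it wrote;
#'   `read_feature_table` returns a features tibble in internal 0-based
#'   half-open coordinates suitable for [mitogenome()].
#' @export
write_feature_table <- function(g, path) {
  tab <- feature_table(g)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character",
                                          "character", "integer", "integer",
                                          "integer"))
  tibble(label = tab$label, category = tab$category, strand = tab$strand,
         start = tab$start - 1L, end = tab$end)
}

# ---- GenBank flat files -----------------------------------------------

#' Read annotated mitogenomes from a GenBank flat file
#'
#' A reader for the subset of the GenBank format that mitochondrial
#' records use: LOCUS topology, ACCESSION, ORGANISM, the feature table
#' (CDS, tRNA, rRNA, misc_feature, D-loop) and ORIGIN sequence. Gene
#' names are canonicalized via [canonical_gene_name()]; 1-based inclusive
#' coordinates become 0-based half-open; `join(x..L,1..y)` origin spans
#' become single wrap-encoded features. Unmappable names are kept as
#' flagged `unknown:` features with a warning, never dropped.
#'
#' @param path Path to a GenBank flat file (one or more records).
#' @return A list of [mitogenome] objects.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines)))
    stop("not a GenBank flat file: ", path)
  starts <- grep("^LOCUS", lines)
  ends <- c(starts[-1] - 1, length(lines))
  purrr::map2(starts, ends, function(s, e) parse_genbank_record(lines[s:e]))
}

parse_genbank_record <- function(lines) {
  locus <- lines[1]
  topology <- if (grepl("\\bcircular\\b", locus)) "circular" else "linear"
  accession <- "unknown"
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line)) {
    acc <- strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]]
    if (length(acc) && nzchar(acc[1])) accession <- acc[1]
  }
  organism <- "unknown organism"
  org_line <- grep("^\\s+ORGANISM", lines, value = TRUE)
  if (length(org_line)) organism <- trimws(sub("^\\s+ORGANISM", "", org_line[1]))

  ftab_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (!length(ftab_i) || !length(orig_i))
    stop("GenBank record missing FEATURES or ORIGIN section")
  seq_lines <- lines[(orig_i[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  len <- nchar(sequence)

  feat_lines <- lines[(ftab_i[1] + 1):(orig_i[1] - 1)]
  feats <- parse_genbank_features(feat_lines, len)
  mitogenome(sequence, feats, accession = accession, organism = organism,
             topology = topology)
}

parse_genbank_features <- function(feat_lines, len) {
  key_i <- grep("^ {5}\\S", feat_lines)
  out <- list()
  for (k in seq_along(key_i)) {
    i0 <- key_i[k]
    i1 <- if (k < length(key_i)) key_i[k + 1] - 1 else length(feat_lines)
    block <- feat_lines[i0:i1]
    key <- sub("^ {5}(\\S+).*", "\\1", block[1])
    if (!key %in% c("CDS", "tRNA", "rRNA", "misc_feature", "D-loop", "gene"))
      next
    if (key == "gene") next  # gene features duplicate CDS/tRNA/rRNA entries
    loc <- sub("^ {5}\\S+\\s+", "", block[1])
    # location may continue on following lines until a qualifier starts
    j <- 2
    while (j <= length(block) && !grepl("^\\s+/", block[j])) {
      loc <- paste0(loc, trimws(block[j])); j <- j + 1
    }
    quals <- parse_qualifiers(block[seq_len(length(block)) >= j])
    coords <- parse_genbank_location(loc, len)
    raw <- quals[["gene"]] %||% quals[["product"]] %||% quals[["note"]] %||%
      (if (key == "D-loop") "D-loop" else "unnamed")
    anticodon <- extract_anticodon_hint(quals)
    label <- canonical_gene_name(raw, anticodon = anticodon)
    if (startsWith(label, "unknown:"))
      warning("unmappable feature name: ", raw)
    out[[length(out) + 1]] <- tibble(
      label = label, strand = coords$strand,
      start = coords$start, end = coords$end
    )
  }
  if (!length(out)) return(tibble(label = character(), strand = character(),
                                  start = integer(), end = integer()))
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_qualifiers <- function(lines) {
  lines <- trimws(lines)
  starts <- grepl("^/", lines)
  if (!any(starts)) return(list())
  idx <- cumsum(starts)
  pieces <- split(lines[idx > 0], idx[idx > 0])
  quals <- list()
  for (p in pieces) {
    q <- paste(p, collapse = " ")
    m <- regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', q)[[1]]
    if (m[1] == -1) next
    name <- regmatches(q, regexec('^/([A-Za-z_]+)', q))[[1]][2]
    val <- sub('^/[A-Za-z_]+=?', "", q)
    val <- gsub('^"|"$', "", val)
    quals[[name]] <- val
  }
  quals
}

extract_anticodon_hint <- function(quals) {
  for (field in c("note", "product", "anticodon")) {
    v <- quals[[field]]
    if (is.null(v)) next
    m <- regmatches(v, regexec("anticodon[:= ]+([A-Za-z]{3})", v,
                               ignore.case = TRUE))[[1]]
    if (length(m) == 2) return(m[2])
    m <- regmatches(v, regexec("seq:([a-z]{3})", v))[[1]]
    if (length(m) == 2) return(m[2])
  }
  NULL
}

parse_genbank_location <- function(loc, len) {
  strand <- "J"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    rng <- lapply(parts, parse_simple_range)
    if (length(rng) == 2 && rng[[1]]$to == len && rng[[2]]$from == 1) {
      # origin-spanning: encode as end > genome length
      return(list(strand = strand, start = rng[[1]]$from - 1L,
                  end = as.integer(len + rng[[2]]$to)))
    }
    stop("unsupported join() location: ", loc)
  }
  r <- parse_simple_range(loc)
  list(strand = strand, start = r$from - 1L, end = as.integer(r$to))
}

parse_simple_range <- function(x) {
  m <- regmatches(x, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", x))[[1]]
  if (length(m) != 3) stop("unparseable location: ", x)
  list(from = as.integer(m[2]), to = as.integer(m[3]))
}

# ---- GenBank writing ---------------------------------------------------

#' Write mitogenomes as a GenBank flat file
#'
#' Emits the minimal GenBank dialect that [read_genbank()] parses, so the
#' two functions round-trip: LOCUS (with topology), ACCESSION, ORGANISM,
#' a feature table with CDS/tRNA/rRNA/D-loop/misc_feature keys, and the
#' ORIGIN sequence in 60-base lines.
#'
#' @param genomes A [mitogenome] or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genbank <- function(genomes, path) {
  if (inherits(genomes, "mitogenome")) genomes <- list(genomes)
  txt <- unlist(lapply(genomes, format_genbank_record))
  writeLines(txt, path)
  invisible(path)
}

format_genbank_record <- function(g) {
  len <- nchar(g$sequence)
  out <- c(
    sprintf("LOCUS       %s %d bp    DNA     %s MIT %s",
            g$accession, len, g$topology, format(Sys.Date(), "%d-%b-%Y")),
    sprintf("DEFINITION  %s mitochondrion, complete genome.", g$organism),
    sprintf("ACCESSION   %s", g$accession),
    "SOURCE      mitochondrion",
    sprintf("  ORGANISM  %s", g$organism),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", len)
  )
  for (i in seq_len(nrow(g$features))) {
    f <- g$features[i, ]
    out <- c(out, format_genbank_feature(f, len))
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1, len, by = 60)
  for (p in pos) {
    chunk <- substr(g$sequence, p, min(p + 59, len))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))))
  }
  c(out, "//")
}

format_genbank_feature <- function(f, len) {
  key <- switch(f$category, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                CR = "D-loop", NCR = "misc_feature", "misc_feature")
  loc <- if (f$end <= len) sprintf("%d..%d", f$start + 1, f$end)
  else sprintf("join(%d..%d,1..%d)", f$start + 1, len, f$end - len)
  if (f$strand == "N") loc <- sprintf("complement(%s)", loc)
  head <- sprintf("     %-16s%s", key, loc)
  quals <- sprintf('                     /gene="%s"', f$label)
  prod <- switch(f$category,
                 PCG = sprintf('                     /product="%s protein"', f$label),
                 tRNA = sprintf('                     /product="tRNA-%s"', f$label),
                 NULL)
  note <- if (f$category == "NCR")
    '                     /note="non-coding region"' else NULL
  c(head, quals, prod, note)
}
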