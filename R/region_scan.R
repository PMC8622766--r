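# Overlaps, intergenic spacers, motifs, homopolymers, exact tandem
# repeats and control-region characterization on the circular genome.

#' Spacers and overlaps between circularly adjacent features
#'
#' One record per adjacent feature pair, including the pair that spans
#' the origin. Negative lengths are overlaps, zero means abutting, and
#' positive lengths are intergenic spacers (IGS) whose sequence is
#' returned. Features nested entirely inside another feature break the
#' adjacency chain and are excluded with a warning (and listed in the
#' `nested` attribute), which keeps the circular conservation identity
#' `sum(feature lengths) + sum(spacer lengths) == genome length` exact.
#'
#' @param g A [mitogenome] with at least two features.
#' @param motifs Optional character vector of IUPAC motifs to scan for in
#'   each positive spacer (forward strand; set `both_strands = TRUE` to
#'   scan the reverse complement too).
#' @param both_strands Scan motifs on both strands (default FALSE).
#' @return A tibble: `upstream`, `downstream`, `length`, `sequence`
#'   (empty unless `length > 0`), and if `motifs` were given a list
#'   column `motif_hits` of tibbles (`motif`, `offset` 0-based, `strand`).
#' @export
adjacent_spacers <- function(g, motifs = NULL, both_strands = FALSE) {
  f <- g$features
  if (nrow(f) < 2) stop("need at least two features")
  len <- nchar(g$sequence)
  nested <- rep(FALSE, nrow(f))
  # features sorted by start; a feature is nested if it ends within the
  # running maximum end of earlier features
  run_end <- f$end[1]
  for (i in seq_len(nrow(f))[-1]) {
    if (f$end[i] <= run_end) nested[i] <- TRUE
    run_end <- max(run_end, f$end[i])
  }
  if (any(nested))
    warning("nested features excluded from the adjacency chain: ",
            paste(f$label[nested], collapse = ", "))
  fc <- f[!nested, ]
  n <- nrow(fc)
  nxt <- c(2:n, 1)
  gap <- integer(n)
  for (i in seq_len(n)) {
    d <- if (i < n) fc$start[nxt[i]] - fc$end[i]
    else (fc$start[1] + len) - fc$end[n]
    gap[i] <- as.integer(d)
  }
  seqs <- purrr::map_chr(seq_len(n), function(i) {
    if (gap[i] <= 0) return("")
    s <- fc$end[i] %% len
    forward_slice(g, s, s + gap[i])
  })
  out <- tibble(upstream = fc$label, downstream = fc$label[nxt],
                length = gap, sequence = seqs)
  if (!is.null(motifs)) {
    out$motif_hits <- purrr::map(out$sequence, function(s)
      scan_motifs(s, motifs, both_strands))
  }
  attr(out, "nested") <- f$label[nested]
  out
}

scan_motifs <- function(s, motifs, both_strands = FALSE) {
  hits <- purrr::map_dfr(motifs, function(m) {
    fw <- tibble(motif = m, offset = find_motif(s, m), strand = "+")
    if (!both_strands) return(fw)
    rv <- tibble(motif = m, offset = find_motif(revcomp(s), m), strand = "-")
    dplyr::bind_rows(fw, rv)
  })
  hits
}

#' Find all occurrences of an IUPAC motif
#'
#' Overlapping occurrences are reported; IUPAC degeneracy letters
#' (N, R, Y, W, S, K, M, B, D, H, V) are honored.
#'
#' @param seq DNA string.
#' @param motif IUPAC pattern.
#' @return Integer vector of 0-based offsets (possibly empty).
#' @export
#' @examples
#' find_motif("TACTACTA", "TACTA")  # overlapping: 0, 3
find_motif <- function(seq, motif) {
  seq <- toupper(seq); motif <- toupper(motif)
  map <- Biostrings::IUPAC_CODE_MAP
  letters <- strsplit(motif, "")[[1]]
  if (!all(letters %in% names(map)))
    stop("invalid IUPAC letter in motif: ",
         paste(setdiff(letters, names(map)), collapse = ""))
  rex <- paste0(vapply(letters, function(l) {
    opts <- map[[l]]
    if (nchar(opts) == 1) opts else paste0("[", opts, "]")
  }, character(1)), collapse = "")
  m <- gregexpr(paste0("(?=", rex, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer())
  as.integer(m) - 1L
}

#' Maximal homopolymer runs
#'
#' @param seq DNA string.
#' @param min_len Minimum run length reported (>= 2).
#' @return A tibble `base`, `start` (1-based), `length`; maximal runs
#'   only.
#' @export
#' @examples
#' homopolymer_runs("AACCCCCCCCCCCA", 11)
homopolymer_runs <- function(seq, min_len = 6) {
  stopifnot(min_len >= 2)
  if (!nchar(seq))
    return(tibble(base = character(), start = integer(), length = integer()))
  r <- rle(seq_chars(toupper(seq)))
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  keep <- r$lengths >= min_len
  tibble(base = r$values[keep], start = start[keep],
         length = r$lengths[keep])
}

#' Exact tandem repeats
#'
#' Finds maximal arrays of an exactly repeated unit by brute-force period
#' scanning (no mismatches; mismatch-tolerant detection is deliberately
#' out of scope). Each array is reported once, under its smallest period:
#' units that are themselves repetitions of a shorter unit are dropped,
#' so e.g. `"AAAA"` is not reported as a 2 bp unit when unit lengths
#' start at 2. Copy number may be fractional when a partial copy trails
#' the last full unit.
#'
#' @param seq DNA string.
#' @param unit_range Length-2 integer vector: smallest and largest unit
#'   length considered (bounded by `floor(nchar(seq)/2)`).
#' @param min_copies Minimum copy number (default 2).
#' @return A tibble `unit_length`, `copy_number`, `start` (1-based),
#'   `unit_sequence`.
#' @export
#' @examples
#' exact_tandem_repeats("ATGATGATG", c(2, 5))
exact_tandem_repeats <- function(seq, unit_range = c(2, 200),
                                 min_copies = 2) {
  seq <- toupper(seq)
  n <- nchar(seq)
  umin <- max(2L, as.integer(unit_range[1]))
  umax <- min(as.integer(unit_range[2]), n %/% 2)
  out <- list()
  if (umax >= umin && n >= 2 * umin) {
    x <- seq_chars(seq)
    for (u in umin:umax) {
      same <- x[seq_len(n - u)] == x[(u + 1):n]
      r <- rle(same)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        arr_start <- starts[k]
        arr_len <- r$lengths[k] + u   # array spans matched region + one unit
        if (arr_len < u * min_copies) next
        unit <- substr(seq, arr_start, arr_start + u - 1)
        if (!is_primitive_unit(unit)) next
        out[[length(out) + 1]] <- tibble(
          unit_length = u,
          copy_number = arr_len / u,
          start = arr_start,
          unit_sequence = unit)
      }
    }
  }
  if (!length(out))
    return(tibble(unit_length = integer(), copy_number = numeric(),
                  start = integer(), unit_sequence = character()))
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$unit_length)
}

is_primitive_unit <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(u %/% 2)) {
    if (u %% d != 0) next
    if (identical(strrep(substr(unit, 1, d), u %/% d), unit)) return(FALSE)
  }
  TRUE
}

#' Locate and characterize the control region
#'
#' The control region (A+T-rich region) of the insect mitogenome lies
#' between rrnS (12S) and the next annotated gene: trnI in the ancestral
#' arrangement, trnQ in the rearranged dynastine arrangement. The span
#' is computed circularly from the end of rrnS to the start of the next
#' non-CR/NCR feature; an annotated CR feature is not required (and is
#' ignored for the boundary computation).
#'
#' @param g A [mitogenome] with rrnS annotated.
#' @return A list: `feature` (one-row tibble with label `"CR"` and the
#'   computed span), `length`, `at_fraction`, `next_gene`, and
#'   `zero_length` flag when rrnS abuts the next gene.
#' @export
locate_control_region <- function(g) {
  f <- g$features
  i <- which(f$label == "rrnS")
  if (!length(i)) stop("rrnS is not annotated; cannot locate control region")
  len <- nchar(g$sequence)
  rr_end <- f$end[i[1]] %% len
  cand <- f[!(f$category %in% c("CR", "NCR")) & !f$flagged, ]
  dist <- (cand$start - rr_end) %% len
  dist[cand$label == "rrnS"] <- NA
  j <- which.min(dist)
  gap <- dist[j]
  if (gap == 0) {
    return(list(feature = NULL, length = 0L, at_fraction = NA_real_,
                next_gene = cand$label[j], zero_length = TRUE))
  }
  cr_seq <- forward_slice(g, rr_end, rr_end + gap)
  feature <- tibble(label = "CR", category = "CR", strand = "J",
                    start = rr_end, end = rr_end + gap, flagged = FALSE)
  list(feature = feature, length = as.integer(gap),
       at_fraction = composition_stats(cr_seq)$at_fraction,
       next_gene = cand$label[j], zero_length = FALSE)
}
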