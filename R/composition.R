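#' Base counts of a DNA string
#'
#' Counts A, C, G, T; every other letter (N and IUPAC ambiguity codes) is
#' tallied as `n_ambiguous` and excluded from all derived denominators.
#'
#' @param seq DNA string.
#' @return One-row tibble: `n_a`, `n_c`, `n_g`, `n_t`, `n_ambiguous`.
#' @export
#' @examples
#' base_counts("ATGCN")
base_counts <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  cnt <- function(b) stringr::str_count(seq, stringr::fixed(b))
  a <- cnt("A"); c <- cnt("C"); g <- cnt("G"); t <- cnt("T")
  tibble(n_a = a, n_c = c, n_g = g, n_t = t,
         n_ambiguous = n - a - c - g - t)
}

#' AT and GC strand skew
#'
#' `at_skew` = (A - T) / (A + T), `gc_skew` = (G - C) / (G + C). When the
#' denominator is zero the skew is undefined and `NA` is returned rather
#' than an error.
#'
#' @param seq DNA string.
#' @return A single value in \[-1, 1\], or `NA` when undefined.
#' @export
#' @examples
#' at_skew("AAAT")  # 0.5
#' gc_skew("CCCG")  # -0.5
at_skew <- function(seq) {
  b <- base_counts(seq)
  skew_of(b$n_a, b$n_t)
}

#' @rdname at_skew
#' @export
gc_skew <- function(seq) {
  b <- base_counts(seq)
  skew_of(b$n_g, b$n_c)
}

skew_of <- function(x, y) if ((x + y) > 0) (x - y) / (x + y) else NA_real_

#' Full composition statistics for a DNA string
#'
#' @param seq DNA string.
#' @return One-row tibble with the base counts plus `at_fraction`,
#'   `at_skew` and `gc_skew` (ambiguity codes excluded from denominators).
#' @export
composition_stats <- function(seq) {
  b <- base_counts(seq)
  tot <- b$n_a + b$n_c + b$n_g + b$n_t
  dplyr::mutate(b,
    at_fraction = if (tot > 0) (.data$n_a + .data$n_t) / tot else NA_real_,
    at_skew = skew_of(.data$n_a, .data$n_t),
    gc_skew = skew_of(.data$n_g, .data$n_c))
}

#' Composition of a set of genome regions
#'
#' Concatenates the selected features and computes composition statistics.
#' By default regions are read in genome forward-strand orientation (not
#' reading orientation), which is what makes strand asymmetry between
#' J- and N-strand gene sets measurable; `orientation = "reading"`
#' reverse-complements N-strand features before concatenation.
#'
#' @param g A [mitogenome].
#' @param selector Which features to use: `"genome"` for the whole
#'   sequence, a character vector of labels, a predicate function taking
#'   the features tibble and returning a logical vector, or a logical
#'   vector. Common selections: `pcg_selector("J")`, `pcg_selector("N")`.
#' @param orientation `"forward"` (default) or `"reading"`.
#' @return One-row tibble as [composition_stats()], plus `n_features` and
#'   `total_length`.
#' @export
#' @examples
#' g <- generate_mitogenome(synthetic_spec(seed = 1))$genome
#' region_composition(g, "genome")
#' region_composition(g, pcg_selector("N"))
region_composition <- function(g, selector = "genome",
                               orientation = c("forward", "reading")) {
  orientation <- match.arg(orientation)
  if (is.character(selector) && length(selector) == 1 && selector == "genome") {
    stats <- composition_stats(g$sequence)
    return(dplyr::mutate(stats, n_features = nrow(g$features),
                         total_length = nchar(g$sequence)))
  }
  f <- g$features
  keep <- if (is.function(selector)) selector(f)
  else if (is.logical(selector)) selector
  else f$label %in% selector
  f <- f[keep, , drop = FALSE]
  if (!nrow(f)) stop("selector picked no features")
  seqs <- purrr::map_chr(seq_len(nrow(f)), function(i)
    extract_gene_sequence(g, f[i, ],
                          orientation = if (orientation == "forward") "forward" else "reading"))
  stats <- composition_stats(paste(seqs, collapse = ""))
  dplyr::mutate(stats, n_features = nrow(f),
                total_length = sum(f$end - f$start))
}

#' Feature selectors for composition reports
#'
#' `pcg_selector(strand)` selects protein-coding genes, optionally on one
#' strand; returned as a predicate usable in [region_composition()].
#'
#' @param strand `"J"`, `"N"`, or `NULL` for both.
#' @return A function of the features tibble returning a logical vector.
#' @export
pcg_selector <- function(strand = NULL) {
  function(f) f$category == "PCG" & (if (is.null(strand)) TRUE else f$strand == strand)
}

#' Per-genome composition report
#'
#' One row per (genome, region set): whole genome, PCGs on each strand,
#' all PCGs, and the control region if annotated. AT fraction is also
#' given in percent at the conventional reporting precision (one decimal
#' for genome-scale rows, two for the control region); raw values are
#' retained in `at_fraction`.
#'
#' @param genomes A list of [mitogenome] objects (or a single one).
#' @return A tibble, one row per genome x region.
#' @export
composition_report <- function(genomes) {
  if (inherits(genomes, "mitogenome")) genomes <- list(genomes)
  purrr::map_dfr(genomes, function(g) {
    sel <- list(
      genome = "genome",
      PCG_all = pcg_selector(),
      PCG_J = pcg_selector("J"),
      PCG_N = pcg_selector("N")
    )
    if ("CR" %in% g$features$label) sel$CR <- "CR"
    purrr::imap_dfr(sel, function(s, nm) {
      row <- region_composition(g, s)
      digits <- if (nm == "CR") 2 else 1
      dplyr::mutate(row,
        accession = g$accession, organism = g$organism, region = nm,
        at_percent = round(100 * .data$at_fraction, digits),
        .before = 1)
    })
  })
}
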