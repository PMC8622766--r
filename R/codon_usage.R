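# Codon usage and start/stop codon calling under the invertebrate
# mitochondrial genetic code (NCBI translation table 5).

CANONICAL_STARTS <- c("ATA", "ATT", "ATC", "ATG")
AAN_STARTS <- c("AAC", "AAT")
OTHER_STARTS <- c("GTC", "GTG", "TTG", "CAA", "CGA", "AAA", "CTA")
STOP_CODONS <- c("TAA", "TAG")

#' Codon families of the invertebrate mitochondrial code
#'
#' All 64 codons with their amino acid under translation table 5 and the
#' synonymous family used for RSCU. Leucine and serine are split into the
#' conventional mitochondrial sub-families Leu1 (CUN), Leu2 (UUR),
#' Ser1 (AGN) and Ser2 (UCN); stop codons form family `"*"`.
#'
#' @return A tibble with columns `codon`, `aa` (one-letter), `family`
#'   and `family_size`.
#' @export
codon_families <- function() {
  gc5 <- Biostrings::getGeneticCode("5")
  codon <- names(gc5)
  aa <- unname(gc5)
  three <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
             Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
             L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
             S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
             `*` = "*")
  family <- unname(three[aa])
  first2 <- substr(codon, 1, 2)
  family[aa == "L"] <- ifelse(first2[aa == "L"] == "CT", "Leu1", "Leu2")
  family[aa == "S"] <- ifelse(first2[aa == "S"] == "AG", "Ser1", "Ser2")
  fam_size <- table(family)
  tibble(codon = codon, aa = aa, family = family,
         family_size = as.integer(fam_size[family]))
}

#' Count codons across coding sequences
#'
#' Each sequence (already in reading orientation, starting at its first
#' codon) is cut into triplets; the incomplete remainder, if any, is
#' dropped, and a terminal complete TAA/TAG stop codon is excluded from
#' the usable total, following the convention that codon totals are
#' reported "except for the stop codon". Codons containing N or other
#' ambiguity letters are skipped and tallied separately.
#'
#' @param cds_seqs Character vector (or list) of CDS sequences in reading
#'   orientation.
#' @return A `codon_usage` tibble: `codon`, `aa`, `family`, `family_size`,
#'   `count`, with attributes `total_codons` (stops and incomplete
#'   terminal codons excluded), `total_codons_incl_incomplete` (incomplete
#'   terminal codon counted as one) and `ambiguous_codons`.
#' @export
#' @examples
#' count_codons("ATGTTTTAA")   # 2 usable codons
count_codons <- function(cds_seqs) {
  cds_seqs <- toupper(unlist(cds_seqs, use.names = FALSE))
  fam <- codon_families()
  counts <- setNames(integer(64), fam$codon)
  ambiguous <- 0L
  n_incomplete <- 0L
  for (s in cds_seqs) {
    n <- nchar(s)
    ncod <- n %/% 3
    if (n %% 3 > 0) n_incomplete <- n_incomplete + 1L
    if (!ncod) next
    cods <- substring(s, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
    # terminal complete stop codon excluded from the tally
    if (n %% 3 == 0 && cods[ncod] %in% STOP_CODONS) cods <- cods[-ncod]
    ok <- cods %in% fam$codon
    ambiguous <- ambiguous + sum(!ok)
    tab <- table(cods[ok])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  out <- dplyr::mutate(fam, count = as.integer(counts[fam$codon]))
  total <- sum(out$count[out$family != "*"])
  structure(out,
            class = c("codon_usage", class(out)),
            total_codons = total,
            total_codons_incl_incomplete = total + n_incomplete,
            ambiguous_codons = ambiguous)
}

#' Relative synonymous codon usage
#'
#' For each codon, RSCU = count x family size / total family count, so a
#' uniformly used family has RSCU 1 for each member and the family mean
#' is exactly 1 whenever the family is observed at all. Stop codons are
#' excluded (RSCU `NA`); a codon in an unobserved family gets RSCU 0.
#'
#' @param x A `codon_usage` table from [count_codons()], or anything with
#'   `codon`, `family`, `family_size`, `count` columns.
#' @return The table with an `rscu` column added.
#' @export
#' @examples
#' rscu(count_codons("ATGTTTTTCTAA"))
rscu <- function(x) {
  at <- attributes(x)
  out <- x |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(rscu = {
      tot <- sum(.data$count)
      if (.data$family[1] == "*") rep(NA_real_, dplyr::n())
      else if (tot > 0) .data$count * .data$family_size / tot
      else rep(0, dplyr::n())
    }) |>
    dplyr::ungroup()
  for (a in c("total_codons", "total_codons_incl_incomplete",
              "ambiguous_codons"))
    attr(out, a) <- at[[a]]
  class(out) <- unique(c("codon_usage", class(out)))
  out
}

#' Amino-acid composition from a codon table
#'
#' Sums codon counts per amino acid, keeping the mitochondrial convention
#' of splitting Leu into Leu1 (CUN) / Leu2 (UUR) and Ser into Ser1 (AGN)
#' / Ser2 (UCN). Stop codons are excluded.
#'
#' @param x A `codon_usage` table.
#' @return A tibble `family`, `count`.
#' @export
amino_acid_composition <- function(x) {
  x |>
    dplyr::filter(.data$family != "*") |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}

#' RSCU bar chart
#'
#' @param x A `codon_usage` table with an `rscu` column (see [rscu()]).
#' @return A ggplot object: stacked RSCU per codon family.
#' @export
plot_rscu <- function(x) {
  if (!"rscu" %in% names(x)) x <- rscu(x)
  dat <- dplyr::filter(x, .data$family != "*")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$family, y = .data$rscu,
                                    fill = .data$codon)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2,
                      show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "RSCU") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

# ---- start / stop codon identification --------------------------------

# Reading-orientation neighbours of a feature on the circular genome:
# the gene immediately 5' (upstream) or 3' (downstream) of `f` in f's
# reading direction.
reading_neighbor <- function(g, f, side = c("upstream", "downstream")) {
  side <- match.arg(side)
  feats <- g$features
  i <- which(feats$label == f$label & feats$start == f$start)[1]
  n <- nrow(feats)
  prev_i <- if (i == 1) n else i - 1
  next_i <- if (i == n) 1 else i + 1
  want_prev <- (f$strand == "J") == (side == "upstream")
  feats[if (want_prev) prev_i else next_i, ]
}

#' Identify a protein-coding gene's start codon
#'
#' Implements the minimize-intergenic-space rule used to call atypical
#' starts: candidate start codons are scanned at every offset 0..`window`
#' downstream (in reading orientation) of the upstream gene's end, so a
#' candidate can never overlap the upstream gene. The call minimizes the
#' offset; at equal offset a canonical ATN start (ATA/ATT/ATC/ATG) beats
#' an atypical AAN start (AAC/AAT), which beats the rarer atypical set
#' (GTC, GTG, TTG, CAA, CGA, AAA, CTA). Consequently, when the nearest
#' canonical ATN lies farther from the upstream gene than an atypical
#' candidate, the atypical codon is called - e.g. an AAC one base after
#' the upstream tRNA wins over an ATN 34 bp downstream.
#'
#' @param g A [mitogenome].
#' @param pcg The protein-coding feature (label, index, or row).
#' @param upstream The upstream feature; by default the reading-orientation
#'   neighbour of `pcg`.
#' @param window Search window in bp downstream of the upstream gene's end
#'   (default 60).
#' @return One-row tibble: `gene`, `start_codon`, `start_class`
#'   (`canonical-ATN` / `atypical-AAN` / `atypical-other`), `start_offset`
#'   (bp from the end of the upstream gene), `no_call` flag.
#' @export
identify_start_codon <- function(g, pcg, upstream = NULL, window = 60) {
  f <- resolve_feature(g, pcg)
  up <- if (is.null(upstream)) reading_neighbor(g, f, "upstream")
  else resolve_feature(g, upstream)
  region <- start_scan_region(g, f, up, window)
  best <- NULL
  for (o in 0:window) {
    codon <- substr(region, o + 1, o + 3)
    if (nchar(codon) < 3) break
    cls <- start_class(codon)
    if (is.na(cls)) next
    best <- tibble(gene = f$label, start_codon = codon, start_class = cls,
                   start_offset = o, no_call = FALSE)
    break  # offsets scanned in increasing order; class ranks break ties
  }
  if (is.null(best))
    best <- tibble(gene = f$label, start_codon = NA_character_,
                   start_class = NA_character_, start_offset = NA_integer_,
                   no_call = TRUE)
  best
}

# All candidate codons at one offset are a single trinucleotide, so the
# tie-break between classes only matters conceptually; rank anyway.
start_class <- function(codon) {
  if (codon %in% CANONICAL_STARTS) return("canonical-ATN")
  if (codon %in% AAN_STARTS) return("atypical-AAN")
  if (codon %in% OTHER_STARTS) return("atypical-other")
  NA_character_
}

# the genome segment from the upstream gene's 3' end, read in the pcg's
# reading orientation, long enough for `window` candidate offsets
start_scan_region <- function(g, f, up, window) {
  len <- nchar(g$sequence)
  if (f$strand == "J") {
    s <- up$end %% len
    forward_slice(g, s, s + window + 3)
  } else {
    e <- up$start %% len
    s <- (e - window - 3) %% len
    revcomp(forward_slice(g, s, s + window + 3))
  }
}

#' Identify a protein-coding gene's stop codon
#'
#' Uses the annotated reading frame: if the gene ends on a complete
#' in-frame TAA/TAG the stop is complete; otherwise a trailing in-frame
#' `T` or `TA` immediately before the downstream gene is called as an
#' incomplete stop, assumed completed to TAA by post-transcriptional
#' polyadenylation. An in-frame TAA/TAG strictly before the annotated
#' end raises a premature-stop flag.
#'
#' @param g A [mitogenome].
#' @param pcg The protein-coding feature (label, index, or row).
#' @return One-row tibble: `gene`, `stop_codon` (`TAA`/`TAG`/`TA`/`T` or
#'   `NA`), `stop_class` (`complete`/`incomplete`), `premature` flag,
#'   `no_call` flag.
#' @export
identify_stop_codon <- function(g, pcg) {
  f <- resolve_feature(g, pcg)
  s <- extract_gene_sequence(g, f)
  n <- nchar(s)
  ncod <- n %/% 3
  rem <- n %% 3
  cods <- substring(s, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
  internal <- if (rem == 0) cods[-length(cods)] else cods
  premature <- any(internal %in% STOP_CODONS)
  if (rem == 0 && ncod > 0 && cods[ncod] %in% STOP_CODONS) {
    return(tibble(gene = f$label, stop_codon = cods[ncod],
                  stop_class = "complete", premature = premature,
                  no_call = FALSE))
  }
  tailseq <- substr(s, 3 * ncod + 1, n)
  if (rem > 0 && tailseq %in% c("T", "TA")) {
    return(tibble(gene = f$label, stop_codon = tailseq,
                  stop_class = "incomplete", premature = premature,
                  no_call = FALSE))
  }
  tibble(gene = f$label, stop_codon = NA_character_,
         stop_class = NA_character_, premature = premature, no_call = TRUE)
}

#' Start/stop codon table for all protein-coding genes
#'
#' @param g A [mitogenome].
#' @param window Start-search window in bp (default 60).
#' @return A tibble, one row per PCG, joining [identify_start_codon()]
#'   and [identify_stop_codon()] output plus the conventional
#'   `"start/stop"` display string.
#' @export
start_stop_table <- function(g, window = 60) {
  pcgs <- g$features[g$features$category == "PCG", ]
  purrr::map_dfr(seq_len(nrow(pcgs)), function(i) {
    st <- dplyr::rename(identify_start_codon(g, pcgs[i, ], window = window),
                        start_no_call = "no_call")
    sp <- dplyr::rename(identify_stop_codon(g, pcgs[i, ]),
                        stop_no_call = "no_call")
    dplyr::bind_cols(st, sp[, setdiff(names(sp), "gene")]) |>
      dplyr::mutate(display = paste0(.data$start_codon, "/", .data$stop_codon))
  })
}
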