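# Synthetic annotated mitogenomes with known ground truth. Every
# observable the analysis modules measure (gene order, composition and
# skews, start/stop codons, spacers and overlaps, motifs, homopolymers,
# control-region repeats, NCR length) is planted by construction and
# returned alongside the genome.

#' Specification of a synthetic mitogenome
#'
#' Builds the parameter set consumed by [generate_mitogenome()]. The two
#' presets mirror the gene-level observables of phytophagous scarab
#' mitogenomes: `"cetoniinae"` uses the ancestral insect gene order, an
#' atypical AAC start for COX1 one base downstream of trnY, and a TACTAA
#' hexanucleotide motif in the trnS2-ND1 spacer; `"dynastinae"` uses the
#' rearranged trnQ-NCR-trnI-trnM order with a short NCR (56 bp by
#' default; set `ncr_length = 412` for the long class), the TACTA
#' pentanucleotide motif, and an 11 bp cytosine homopolymer in the
#' trnK-trnD spacer. Both presets share an 8 bp trnW/trnC overlap, an
#' ATP8 of 156 bp, an ND5 of 1716 bp, 65 bp tRNAs, a control region with
#' an exact tandem-repeat array, and an incomplete T stop on COX2.
#'
#' @param template `"cetoniinae"` (ancestral order) or `"dynastinae"`
#'   (rearranged order).
#' @param seed Integer seed; all randomness derives from it.
#' @param at,skew_at,skew_gc Composition targets for non-coding
#'   background sequence on the forward strand (PCG codon pools are
#'   calibrated to the same targets in each gene's reading orientation,
#'   sign-flipped for N-strand genes so forward-strand skews stay
#'   coherent).
#' @param cr_length Control-region length in bp.
#' @param cr_at Control-region AT target.
#' @param cr_repeat `list(unit_length=, copies=)` or `NULL` for no
#'   planted repeat array.
#' @param ncr_length NCR length in bp (rearranged template only).
#' @param trna_length,rrns_length,rrnl_length RNA gene lengths in bp.
#' @param pcg_lengths Named integer vector of PCG lengths in bp
#'   (including start and stop; a length not divisible by 3 implies an
#'   incomplete stop).
#' @param start_codons,stop_codons Named character vectors overriding the
#'   per-gene defaults.
#' @param spacers Named integer vector `"up|down" = bp` of planted
#'   intergenic spacers (all other adjacencies abut).
#' @param motif_insertions Named character vector `"up|down" = motif`.
#' @param homopolymers Named list `"up|down" = list(base=, length=)`.
#' @param overlaps Named integer vector `"up|down" = bp` of planted
#'   overlaps.
#' @return A `synthetic_spec` list.
#' @export
#' @examples
#' spec <- synthetic_spec("dynastinae", seed = 7, ncr_length = 412)
#' g <- generate_mitogenome(spec)$genome
synthetic_spec <- function(template = c("cetoniinae", "dynastinae"),
                           seed = 1L,
                           at = 0.75, skew_at = 0.05, skew_gc = -0.20,
                           cr_length = 1776, cr_at = 0.80,
                           cr_repeat = list(unit_length = 12, copies = 3),
                           ncr_length = 56,
                           trna_length = 65, rrns_length = 780,
                           rrnl_length = 1280,
                           pcg_lengths = NULL,
                           start_codons = NULL, stop_codons = NULL,
                           spacers = NULL, motif_insertions = NULL,
                           homopolymers = NULL,
                           overlaps = c("trnW|trnC" = 8)) {
  template <- match.arg(template)
  def_pcg <- c(ND2 = 1020, COX1 = 1536, COX2 = 688, ATP8 = 156,
               ATP6 = 672, COX3 = 786, ND3 = 354, ND5 = 1716,
               ND4 = 1344, ND4L = 288, ND6 = 504, CYTB = 1137, ND1 = 945)
  if (!is.null(pcg_lengths)) def_pcg[names(pcg_lengths)] <- pcg_lengths
  def_start <- c(ND2 = "ATA", COX1 = "ATG", COX2 = "ATG", ATP8 = "ATT",
                 ATP6 = "ATG", COX3 = "ATG", ND3 = "ATT", ND5 = "ATA",
                 ND4 = "ATG", ND4L = "ATA", ND6 = "ATT", CYTB = "ATG",
                 ND1 = "ATA")
  def_stop <- c(ND2 = "TAA", COX1 = "TAA", COX2 = "T", ATP8 = "TAA",
                ATP6 = "TAA", COX3 = "TAA", ND3 = "TAG", ND5 = "TAA",
                ND4 = "TAA", ND4L = "TAA", ND6 = "TAA", CYTB = "TAA",
                ND1 = "TAG")
  if (template == "cetoniinae") {
    order <- ancestral_insect_order()
    def_start[["COX1"]] <- "AAC"
    def_spacers <- c("trnY|COX1" = 1, "trnS2|ND1" = 18, "trnE|trnF" = 3)
    def_motifs <- c("trnS2|ND1" = "TACTAA")
    def_homo <- list()
  } else {
    order <- dynastine_gene_order()
    def_spacers <- c("trnS2|ND1" = 20, "trnK|trnD" = 20, "trnE|trnF" = 3)
    def_motifs <- c("trnS2|ND1" = "TACTA")
    def_homo <- list("trnK|trnD" = list(base = "C", length = 11))
  }
  if (!is.null(start_codons)) def_start[names(start_codons)] <- start_codons
  if (!is.null(stop_codons)) def_stop[names(stop_codons)] <- stop_codons
  if (!is.null(spacers)) def_spacers[names(spacers)] <- spacers
  if (!is.null(motif_insertions)) def_motifs[names(motif_insertions)] <- motif_insertions
  if (!is.null(homopolymers)) def_homo[names(homopolymers)] <- homopolymers
  spec <- structure(list(
    template = template, order = order, seed = as.integer(seed),
    at = at, skew_at = skew_at, skew_gc = skew_gc,
    cr_length = as.integer(cr_length), cr_at = cr_at, cr_repeat = cr_repeat,
    ncr_length = as.integer(ncr_length),
    trna_length = as.integer(trna_length),
    rrns_length = as.integer(rrns_length),
    rrnl_length = as.integer(rrnl_length),
    pcg_lengths = def_pcg, start_codons = def_start, stop_codons = def_stop,
    spacers = def_spacers, motifs = def_motifs, homopolymers = def_homo,
    overlaps = overlaps
  ), class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  lens <- c(spec$pcg_lengths, spec$trna_length, spec$rrns_length,
            spec$rrnl_length, spec$cr_length)
  if (any(lens <= 0)) stop("all lengths must be positive")
  if (abs(spec$skew_at) >= 1 || abs(spec$skew_gc) >= 1)
    stop("infeasible skew targets (|skew| must be < 1)")
  if (spec$at < 0 || spec$at > 1) stop("AT fraction must be in [0, 1]")
  for (g in names(spec$pcg_lengths)) {
    stopv <- spec$stop_codons[[g]]
    n <- spec$pcg_lengths[[g]]
    if (!stopv %in% c("TAA", "TAG", "TA", "T"))
      stop("unsupported stop codon for ", g, ": ", stopv)
    if ((n - nchar(stopv)) %% 3 != 0)
      stop("PCG length inconsistent with stop codon length for ", g)
  }
  for (p in names(spec$overlaps)) {
    if (spec$overlaps[[p]] >= spec$trna_length)
      stop("overlap longer than the overlapping genes: ", p)
  }
  invisible(spec)
}

#' Sample a background DNA sequence with target composition
#'
#' Per-base sampling with `p(A) = at(1+skew_at)/2`,
#' `p(T) = at(1-skew_at)/2`, `p(G) = (1-at)(1+skew_gc)/2`,
#' `p(C) = (1-at)(1-skew_gc)/2`.
#'
#' @param length Number of bases.
#' @param at AT fraction target in \[0, 1\].
#' @param skew_at,skew_gc Skew targets in (-1, 1); the degenerate
#'   boundary values 1/-1 are allowed and give deterministic sequence.
#' @param seed Optional integer seed (local to this call).
#' @return A DNA string.
#' @export
#' @examples
#' compose_region_sequence(10, at = 1, skew_at = 1)  # "AAAAAAAAAA"
compose_region_sequence <- function(length, at, skew_at = 0, skew_gc = 0,
                                    seed = NULL) {
  if (abs(skew_at) > 1 || abs(skew_gc) > 1 || at < 0 || at > 1)
    stop("infeasible composition targets")
  if (length == 0) return("")
  p <- base_probs(at, skew_at, skew_gc)
  with_local_seed(seed,
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = ""))
}

base_probs <- function(at, skew_at, skew_gc) {
  c(A = at * (1 + skew_at) / 2, T = at * (1 - skew_at) / 2,
    G = (1 - at) * (1 + skew_gc) / 2, C = (1 - at) * (1 - skew_gc) / 2)
}

#' Build a protein-coding gene sequence
#'
#' First codon is the requested start; body codons are drawn from the
#' non-stop codons by weight (so the body is guaranteed free of in-frame
#' stops); the terminal stop, possibly incomplete (`"TA"` or `"T"`), is
#' appended.
#'
#' @param body_codons Number of body codons between start and stop.
#' @param start_codon Start codon (canonical ATN, AAN, or the atypical
#'   set GTC/GTG/TTG/CAA/CGA/AAA/CTA).
#' @param stop_codon `"TAA"`, `"TAG"`, `"TA"` or `"T"`.
#' @param codon_weights Named non-negative weights over the 62 non-stop
#'   codons (defaults to uniform); all-zero weights are an error.
#' @param seed Optional local seed.
#' @return A DNA string of length `3 + 3*body_codons + nchar(stop_codon)`.
#' @export
#' @examples
#' nchar(build_pcg(2, "AAC", "T", seed = 1))  # 10
build_pcg <- function(body_codons, start_codon, stop_codon,
                      codon_weights = NULL, seed = NULL) {
  start_codon <- toupper(start_codon)
  stop_codon <- toupper(stop_codon)
  if (!start_codon %in% c(CANONICAL_STARTS, AAN_STARTS, OTHER_STARTS))
    stop("unsupported start codon: ", start_codon)
  if (!stop_codon %in% c("TAA", "TAG", "TA", "T"))
    stop("unsupported stop codon: ", stop_codon)
  pool <- setdiff(codon_families()$codon, STOP_CODONS)
  if (is.null(codon_weights)) codon_weights <- setNames(rep(1, 62), pool)
  w <- codon_weights[pool]
  w[is.na(w)] <- 0
  if (all(w == 0)) stop("codon weights are all zero")
  body <- if (body_codons > 0)
    with_local_seed(seed,
      paste(sample(pool, body_codons, replace = TRUE, prob = w),
            collapse = ""))
  else ""
  paste0(start_codon, body, stop_codon)
}

# Codon weights whose *conditional* (non-stop) base composition hits the
# target at/skews: independent-base weights, iteratively recalibrated to
# undo the bias introduced by excluding the two stop codons.
codon_weights_for_targets <- function(at, skew_at, skew_gc, iters = 40) {
  target <- base_probs(at, skew_at, skew_gc)
  target <- pmax(target, 1e-12)
  fam <- codon_families()
  pool <- fam$codon[fam$family != "*"]
  mat <- t(vapply(pool, function(cd) {
    b <- strsplit(cd, "")[[1]]
    vapply(c("A", "T", "G", "C"), function(x) sum(b == x), numeric(1))
  }, numeric(4)))
  q <- target
  for (i in seq_len(iters)) {
    w <- exp(mat %*% log(q[c("A", "T", "G", "C")]))[, 1]
    w <- w / sum(w)
    realized <- colSums(w * mat) / 3
    q <- q * (target / pmax(realized, 1e-12))[names(q)]
    q <- q / sum(q)
  }
  w <- exp(mat %*% log(q[c("A", "T", "G", "C")]))[, 1]
  setNames(w / sum(w), pool)
}

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' Deterministic for a fixed spec and seed. The genome is assembled gene
#' by gene in the spec's order: PCGs are built codon-wise in reading
#' orientation (reverse-complemented onto the forward strand for
#' N-strand genes), RNA genes and non-coding regions are background
#' sequence at the spec's composition targets, planted spacers carry
#' their motif or homopolymer insertions, the control region carries an
#' exact tandem-repeat array, and the trnW/trnC pair overlaps by the
#' requested amount. Spacer sequence upstream of each PCG start is
#' resampled until no spurious earlier start-codon candidate exists, so
#' start-codon calls recover the planted truth exactly.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `genome` (a [mitogenome]) and `truth` (a list:
#'   `order`, `features`, `spacers`, `start_stop`, `cr`, `repeat_record`,
#'   `motif_hits`, `homopolymers`, `ncr_length`, `composition_targets`).
#' @export
generate_mitogenome <- function(spec) {
  validate_synthetic_spec(spec)
  with_local_seed(spec$seed, generate_mitogenome_impl(spec))
}

generate_mitogenome_impl <- function(spec) {
  ord <- unclass(spec$order)
  bare <- strip_sign(ord)
  strands <- ifelse(startsWith(ord, "-"), "N", "J")
  n <- length(ord)
  cw_fwd <- codon_weights_for_targets(spec$at, spec$skew_at, spec$skew_gc)
  cw_rev <- codon_weights_for_targets(spec$at, -spec$skew_at, -spec$skew_gc)

  # planted spacer AFTER element i (between ord[i] and ord[i+1]); the
  # adjacency name uses the flanking labels
  pair_name <- function(i) paste(bare[i], bare[(i %% n) + 1], sep = "|")
  spacer_len <- vapply(seq_len(n), function(i) {
    v <- unname(spec$spacers[pair_name(i)])
    if (!length(v) || is.na(v)) 0L else as.integer(v)
  }, integer(1))
  overlap_len <- vapply(seq_len(n), function(i) {
    v <- unname(spec$overlaps[pair_name(i)])
    if (!length(v) || is.na(v)) 0L else as.integer(v)
  }, integer(1))

  # per-element sequences (forward strand)
  elem_seq <- character(n)
  truth_start_stop <- list()
  cr_repeat_truth <- NULL
  for (i in seq_len(n)) {
    lab <- bare[i]
    cat_i <- gene_category(lab)
    if (cat_i == "PCG") {
      st <- spec$start_codons[[lab]]
      sp <- spec$stop_codons[[lab]]
      len <- spec$pcg_lengths[[lab]]
      body <- (len - 3 - nchar(sp)) / 3
      cw <- if (strands[i] == "J") cw_fwd else cw_rev
      reading <- build_pcg(body, st, sp, codon_weights = cw)
      elem_seq[i] <- if (strands[i] == "J") reading else revcomp(reading)
      truth_start_stop[[lab]] <- tibble(
        gene = lab, start_codon = st,
        start_class = start_class(st),
        stop_codon = sp,
        stop_class = if (sp %in% c("T", "TA")) "incomplete" else "complete")
    } else if (cat_i == "tRNA") {
      elem_seq[i] <- compose_bg(spec, spec$trna_length)
    } else if (cat_i == "rRNA") {
      len <- if (lab == "rrnS") spec$rrns_length else spec$rrnl_length
      elem_seq[i] <- compose_bg(spec, len)
    } else if (cat_i == "CR") {
      cr <- build_control_region(spec)
      elem_seq[i] <- cr$seq
      cr_repeat_truth <- cr$repeat_record
    } else { # NCR
      elem_seq[i] <- compose_region_sequence(spec$ncr_length, spec$cr_at,
                                             spec$skew_at, spec$skew_gc)
    }
  }

  # spacer sequences, with motif/homopolymer plants and start-candidate
  # hygiene for the downstream PCG
  spacer_seq <- character(n)
  motif_truth <- list()
  homo_truth <- list()
  for (i in seq_len(n)) {
    if (spacer_len[i] == 0) next
    nm <- pair_name(i)
    motif <- chr_lookup(spec$motifs, nm)
    homo <- spec$homopolymers[[nm]]
    made <- build_spacer(spec, spacer_len[i], motif, homo)
    spacer_seq[i] <- made$seq
    if (!is.null(motif))
      motif_truth[[nm]] <- tibble(pair = nm, motif = motif,
                                  offset = made$motif_offset)
    if (!is.null(homo))
      homo_truth[[nm]] <- tibble(pair = nm, base = homo$base,
                                 length = homo$length,
                                 offset = made$homo_offset)
  }

  # start-candidate hygiene: the scan window upstream of each PCG start
  # must not contain a candidate codon at an offset below the true one
  for (i in seq_len(n)) {
    if (gene_category(bare[i]) != "PCG") next
    prev_i <- if (i == 1) n else i - 1
    if (strands[i] == "J") {
      # upstream (reading) gap is the spacer before this element
      gi <- prev_i
      true_off <- spacer_len[gi]
      if (true_off == 0) next
      for (tries in 1:200) {
        ctx <- paste0(spacer_seq[gi], substr(elem_seq[i], 1, 2))
        if (earliest_candidate_offset(ctx) >= true_off) break
        made <- build_spacer(spec, spacer_len[gi], chr_lookup(spec$motifs, pair_name(gi)),
                             spec$homopolymers[[pair_name(gi)]])
        spacer_seq[gi] <- made$seq
        nm <- pair_name(gi)
        if (!is.null(chr_lookup(spec$motifs, nm)))
          motif_truth[[nm]]$offset <- made$motif_offset
        if (!is.null(spec$homopolymers[[nm]]))
          homo_truth[[nm]]$offset <- made$homo_offset
      }
    } else {
      # reading upstream gap is the spacer after this element
      gi <- i
      true_off <- spacer_len[gi]
      if (true_off == 0) next
      for (tries in 1:200) {
        ctx <- paste0(revcomp(spacer_seq[gi]),
                      substr(revcomp(elem_seq[i]), 1, 2))
        if (earliest_candidate_offset(ctx) >= true_off) break
        made <- build_spacer(spec, spacer_len[gi], chr_lookup(spec$motifs, pair_name(gi)),
                             spec$homopolymers[[pair_name(gi)]])
        spacer_seq[gi] <- made$seq
        nm <- pair_name(gi)
        if (!is.null(chr_lookup(spec$motifs, nm)))
          motif_truth[[nm]]$offset <- made$motif_offset
        if (!is.null(spec$homopolymers[[nm]]))
          homo_truth[[nm]]$offset <- made$homo_offset
      }
    }
  }

  # assemble: element i, then its spacer; an overlap after element i
  # trims the start of element i+1 (the shared bases are element i's)
  chunks <- character(0)
  starts <- integer(n); ends <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    ov <- if (i > 1) overlap_len[i - 1] else 0L
    s <- elem_seq[i]
    starts[i] <- pos - ov
    ends[i] <- starts[i] + nchar(s)
    chunks <- c(chunks, substr(s, ov + 1, nchar(s)))
    pos <- ends[i]
    if (spacer_len[i] > 0) {
      chunks <- c(chunks, spacer_seq[i])
      pos <- pos + spacer_len[i]
    }
  }
  sequence <- paste(chunks, collapse = "")
  feats <- tibble(label = bare, strand = strands,
                  start = starts, end = ends)
  genome <- mitogenome(sequence, feats,
                       accession = paste0("SYN_", spec$template, "_",
                                          spec$seed),
                       organism = paste0("Synthetica ",
                                         spec$template, " (synthetic)"),
                       topology = "circular")

  spacer_truth <- tibble(
    upstream = bare, downstream = bare[c(2:n, 1)],
    length = as.integer(spacer_len - c(overlap_len))
  )
  truth <- list(
    order = spec$order,
    features = feature_table(genome),
    spacers = spacer_truth,
    start_stop = dplyr::bind_rows(truth_start_stop),
    start_offsets = pcg_start_offsets(spec, bare, strands, spacer_len, n),
    cr = list(length = spec$cr_length, at = spec$cr_at,
              upstream = "rrnS",
              downstream = bare[(which(bare == "CR") %% n) + 1]),
    repeat_record = cr_repeat_truth,
    motif_hits = dplyr::bind_rows(motif_truth),
    homopolymers = dplyr::bind_rows(homo_truth),
    ncr_length = if ("NCR" %in% bare) spec$ncr_length else NA_integer_,
    composition_targets = local({
      # whole-genome AT expectation is a mixture: the CR (and NCR) are
      # generated at their own, richer AT target
      total <- nchar(sequence)
      rich <- spec$cr_length + if ("NCR" %in% bare) spec$ncr_length else 0L
      list(at = spec$at, skew_at = spec$skew_at, skew_gc = spec$skew_gc,
           cr_at = spec$cr_at,
           expected_genome_at =
             ((total - rich) * spec$at + rich * spec$cr_at) / total)
    })
  )
  list(genome = genome, truth = truth)
}

compose_bg <- function(spec, len) {
  compose_region_sequence(len, spec$at, spec$skew_at, spec$skew_gc)
}

# true start offset of each PCG = the planted spacer on its reading-
# upstream side (overlaps never involve PCGs in the default specs)
pcg_start_offsets <- function(spec, bare, strands, spacer_len, n) {
  idx <- which(gene_category(bare) == "PCG")
  purrr::map_dfr(idx, function(i) {
    off <- if (strands[i] == "J") {
      spacer_len[if (i == 1) n else i - 1]
    } else spacer_len[i]
    tibble(gene = bare[i], start_offset = as.integer(off))
  })
}

# earliest offset in `ctx` at which a start-codon candidate begins
# (Inf when none); ctx covers the gap plus the gene's first two bases
earliest_candidate_offset <- function(ctx) {
  cands <- c(CANONICAL_STARTS, AAN_STARTS, OTHER_STARTS)
  n <- nchar(ctx)
  if (n < 3) return(Inf)
  for (o in 0:(n - 3)) {
    if (substr(ctx, o + 1, o + 3) %in% cands) return(o)
  }
  Inf
}

# spacer with optional planted motif (exactly one occurrence) or
# homopolymer (exactly one maximal run >= 6, flanked by non-matching
# bases so genomic context cannot extend it)
build_spacer <- function(spec, len, motif = NULL, homo = NULL,
                         max_tries = 500) {
  for (t in seq_len(max_tries)) {
    s <- compose_bg(spec, len)
    m_off <- NA_integer_
    h_off <- NA_integer_
    if (!is.null(homo)) {
      run <- strrep(homo$base, homo$length)
      room <- len - homo$length - 2
      if (room < 0) stop("spacer too short for homopolymer insertion")
      at0 <- sample.int(room + 1, 1)  # 1-based position of left flank
      flank <- setdiff(c("A", "C", "G", "T"), homo$base)
      s <- paste0(substr(s, 1, at0 - 1),
                  sample(flank, 1), run, sample(flank, 1),
                  substr(s, at0 + homo$length + 2, len))
      h_off <- at0  # 0-based offset of the run within the spacer
      runs <- homopolymer_runs(s, min_len = 6)
      if (!(nrow(runs) == 1 && runs$base == homo$base &&
            runs$length == homo$length && runs$start == h_off + 1)) next
    }
    if (!is.null(motif)) {
      ml <- nchar(motif)
      if (len < ml) stop("spacer too short for motif insertion")
      pos <- sample.int(len - ml + 1, 1)
      # keep the motif clear of the pinned homopolymer block (run + flanks)
      if (!is.null(homo) &&
          pos + ml - 1 >= h_off && pos <= h_off + homo$length + 2) next
      s <- paste0(substr(s, 1, pos - 1), motif, substr(s, pos + ml, len))
      hits <- find_motif(s, motif)
      if (!identical(hits, as.integer(pos - 1))) next
      if (!is.null(homo)) {
        runs <- homopolymer_runs(s, min_len = 6)
        if (!(nrow(runs) == 1 && runs$length == homo$length)) next
      }
      m_off <- pos - 1L
    }
    return(list(seq = s, motif_offset = m_off, homo_offset = h_off))
  }
  stop("could not build spacer satisfying constraints")
}

# control region: random prefix, exact tandem-repeat array (primitive
# unit, integer copies, boundaries pinned so the array is maximal), then
# AT-rich background
build_control_region <- function(spec) {
  len <- spec$cr_length
  make_bg <- function(k) compose_region_sequence(k, spec$cr_at,
                                                 spec$skew_at, spec$skew_gc)
  if (is.null(spec$cr_repeat)) {
    return(list(seq = make_bg(len), repeat_record = NULL))
  }
  u <- spec$cr_repeat$unit_length
  k <- spec$cr_repeat$copies
  arr_len <- u * k
  prefix_len <- min(20L, max(1L, len - arr_len - 1L))
  suffix_len <- len - prefix_len - arr_len
  if (suffix_len < 1) stop("control region too short for its repeat array")
  for (t in 1:500) {
    unit <- make_bg(u)
    if (!is_primitive_unit(unit)) next
    prefix <- make_bg(prefix_len)
    suffix <- make_bg(suffix_len)
    # pin boundaries: array must not extend left or right at period u
    if (substr(prefix, prefix_len, prefix_len) == substr(unit, u, u)) next
    if (substr(suffix, 1, 1) == substr(unit, 1, 1)) next
    s <- paste0(prefix, strrep(unit, k), suffix)
    found <- exact_tandem_repeats(s, unit_range = c(u, u), min_copies = k)
    hit <- found[found$start == prefix_len + 1 & found$unit_length == u, ]
    if (nrow(hit) == 1 && hit$copy_number == k) {
      return(list(seq = s, repeat_record = tibble(
        unit_length = u, copy_number = as.numeric(k),
        start = prefix_len + 1L, unit_sequence = unit)))
    }
  }
  stop("could not build control-region repeat array")
}
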