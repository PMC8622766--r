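#' Run the full comparative mitogenomic analysis
#'
#' Orchestrates every analysis stage over a set of annotated mitogenomes
#' and writes the report bundle: a per-genome summary table (length, AT%,
#' skews, gene counts, control-region length and AT%), the per-gene
#' start/stop codon table, the codon-usage/RSCU long table, the
#' spacer/overlap table (with motif scan), the control-region tandem
#' repeat table, and a JSON rearrangement report against the reference
#' order including any single-TDRL scenarios. Percentages are printed at
#' the conventional precision (1 decimal genome-level, 2 decimals for
#' the control region); the JSON twin keeps full precision. A run log
#' records the configuration and per-genome warnings.
#'
#' @param inputs Character vector of GenBank file paths, and/or a list of
#'   [mitogenome] objects.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing and just returns the tables.
#' @param reference Reference [gene_order] (default the ancestral insect
#'   order).
#' @param ncr_breaks Two NCR class bounds in bp (default `c(100, 400)`:
#'   below the first is NCR1, above the second NCR2).
#' @param homopolymer_min Minimum homopolymer run length (default 6).
#' @param repeat_unit_range,repeat_min_copies Tandem-repeat search
#'   parameters for the control region (defaults 2-200 bp, 2 copies).
#' @param start_window Start-codon search window in bp (default 60).
#' @param igs_min Minimum spacer length counted as an IGS in the summary
#'   (default 1); a second count at threshold 5 is always reported.
#' @param motifs Motifs scanned in spacers (default TACTAA and TACTA).
#' @return Invisibly, a list of tibbles (`summary`, `start_stop`,
#'   `codon_rscu`, `spacers`, `repeats`), a list of
#'   `rearrangement_report`s, and `failures` (named character vector of
#'   parse errors); attribute `status` is 1 if any input failed to
#'   parse, else 0.
#' @export
#' @examples
#' gens <- list(generate_mitogenome(synthetic_spec("cetoniinae", seed = 1))$genome,
#'              generate_mitogenome(synthetic_spec("dynastinae", seed = 2))$genome)
#' res <- run_comparative(gens, out_dir = NULL)
#' res$summary
run_comparative <- function(inputs, out_dir = NULL,
                            reference = ancestral_insect_order(),
                            ncr_breaks = c(100, 400),
                            homopolymer_min = 6,
                            repeat_unit_range = c(2, 200),
                            repeat_min_copies = 2,
                            start_window = 60,
                            igs_min = 1,
                            motifs = c("TACTAA", "TACTA")) {
  if (inherits(inputs, "mitogenome")) inputs <- list(inputs)
  if (!length(inputs)) stop("no input genomes given")
  genomes <- list()
  failures <- character()
  log_lines <- c(sprintf("mitocomp %s | run_comparative | %s",
                         as.character(utils::packageVersion("mitocomp")),
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("config: start_window=%d igs_min=%d ncr_breaks=%d/%d homopolymer_min=%d repeat_unit=%d-%d min_copies=%s",
                         start_window, igs_min, ncr_breaks[1], ncr_breaks[2],
                         homopolymer_min, repeat_unit_range[1],
                         repeat_unit_range[2], repeat_min_copies))
  for (inp in inputs) {
    if (inherits(inp, "mitogenome")) {
      genomes[[inp$accession]] <- inp
      next
    }
    res <- tryCatch(read_genbank(inp), error = function(e) e)
    if (inherits(res, "error")) {
      failures[inp] <- conditionMessage(res)
      log_lines <- c(log_lines, sprintf("ERROR %s: %s", inp, failures[inp]))
    } else {
      for (g in res) genomes[[g$accession]] <- g
      log_lines <- c(log_lines, sprintf("read %s: %d record(s)", inp,
                                        length(res)))
    }
  }
  if (!length(genomes)) stop("no genome could be read")

  per <- purrr::imap(genomes, function(g, acc) {
    withCallingHandlers(
      analyse_one_genome(g, reference, homopolymer_min, repeat_unit_range,
                         repeat_min_copies, start_window, igs_min, motifs),
      warning = function(w) {
        log_lines <<- c(log_lines,
                        sprintf("WARN %s: %s", acc, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  })

  out <- list(
    summary = purrr::map_dfr(per, "summary"),
    start_stop = purrr::map_dfr(per, "start_stop"),
    codon_rscu = purrr::map_dfr(per, "codon_rscu"),
    spacers = purrr::map_dfr(per, "spacers"),
    repeats = purrr::map_dfr(per, "repeats"),
    rearrangements = purrr::map(per, "rearrangement"),
    failures = failures
  )
  attr(out, "status") <- if (length(failures)) 1L else 0L

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wr(out$summary, "genome_summary.tsv")
    wr(out$start_stop, "start_stop_codons.tsv")
    wr(out$codon_rscu, "codon_rscu.tsv")
    wr(dplyr::select(out$spacers, -dplyr::any_of("motif_hits")),
       "spacers_overlaps.tsv")
    wr(spacer_motif_long(out$spacers), "spacer_motifs.tsv")
    wr(out$repeats, "cr_repeats.tsv")
    jsonlite::write_json(
      purrr::map(out$rearrangements, rearrangement_report_json),
      file.path(out_dir, "rearrangements.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(out$summary, file.path(out_dir, "genome_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(out)
}

spacer_motif_long <- function(spacers) {
  if (!"motif_hits" %in% names(spacers) || !nrow(spacers))
    return(tibble(accession = character(), upstream = character(),
                  downstream = character(), motif = character(),
                  offset = integer()))
  spacers |>
    dplyr::select(dplyr::any_of(c("accession", "upstream", "downstream",
                                  "motif_hits"))) |>
    tidyr::unnest("motif_hits")
}

analyse_one_genome <- function(g, reference, homopolymer_min,
                               repeat_unit_range, repeat_min_copies,
                               start_window, igs_min, motifs) {
  comp <- region_composition(g, "genome")
  cr <- tryCatch(locate_control_region(g), error = function(e) NULL)
  spacers <- adjacent_spacers(g, motifs = motifs)
  sp <- dplyr::mutate(spacers, accession = g$accession, .before = 1)

  sstab <- start_stop_table(g, window = start_window) |>
    dplyr::mutate(accession = g$accession, .before = 1)

  pcgs <- g$features[g$features$category == "PCG", ]
  cds <- purrr::map_chr(seq_len(nrow(pcgs)), function(i)
    extract_gene_sequence(g, pcgs[i, ]))
  cu <- rscu(count_codons(cds))
  codon_rscu <- cu |>
    dplyr::mutate(accession = g$accession, .before = 1)

  reps <- if (!is.null(cr) && !cr$zero_length) {
    crseq <- forward_slice(g, cr$feature$start, cr$feature$end)
    exact_tandem_repeats(crseq, unit_range = repeat_unit_range,
                         min_copies = repeat_min_copies) |>
      dplyr::mutate(accession = g$accession, region = "CR", .before = 1)
  } else {
    tibble(accession = character(), region = character(),
           unit_length = integer(), copy_number = numeric(),
           start = integer(), unit_sequence = character())
  }

  obs <- extract_gene_order(g)
  ncr_f <- g$features[g$features$category == "NCR", ]
  ncr_lengths <- if (nrow(ncr_f))
    setNames(ncr_f$end - ncr_f$start, ncr_f$label) else NULL
  rear <- classify_rearrangement(reference, obs, ncr_lengths = ncr_lengths)

  n_overlap <- sum(sp$length < 0)
  summary <- tibble(
    accession = g$accession, organism = g$organism,
    length_bp = nchar(g$sequence),
    n_genes = sum(!g$features$flagged &
                    !g$features$category %in% c("CR", "NCR")),
    at_percent = round(100 * comp$at_fraction, 1),
    at_skew = comp$at_skew, gc_skew = comp$gc_skew,
    n_overlaps = n_overlap,
    max_overlap_bp = if (n_overlap) -min(sp$length) else 0L,
    n_igs = sum(sp$length >= igs_min),
    n_igs_ge5 = sum(sp$length >= 5),
    cr_length = if (!is.null(cr)) cr$length else NA_integer_,
    cr_at_percent = if (!is.null(cr) && !cr$zero_length)
      round(100 * cr$at_fraction, 2) else NA_real_,
    total_codons = attr(cu, "total_codons"),
    event_class = rear$event_class,
    tdrl_compatible = rear$tdrl_compatible
  )
  list(summary = summary, start_stop = sstab, codon_rscu = codon_rscu,
       spacers = sp, repeats = reps, rearrangement = rear)
}
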