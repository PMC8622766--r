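# Signed circular gene orders, breakpoint distance, rearrangement
# classification and single-TDRL scenario enumeration.

#' Signed circular gene order
#'
#' A gene order is a character vector of canonical labels, each optionally
#' prefixed with `-` for the minority (N) strand, interpreted circularly.
#' Two orders are equal iff one is a rotation of the other; reflections
#' are *not* identified, because reading the circular chromosome on a
#' fixed strand has a fixed direction.
#'
#' @param labels Character vector of signed labels (e.g. `"-trnQ"`).
#' @param anchor Optional label used by [normalize_rotation()].
#' @return A `gene_order` object.
#' @export
#' @examples
#' gene_order(c("trnI", "-trnQ", "trnM"))
gene_order <- function(labels, anchor = NULL) {
  labels <- as.character(labels)
  bare <- strip_sign(labels)
  if (anyDuplicated(bare))
    stop("duplicate labels in gene order: ",
         paste(unique(bare[duplicated(bare)]), collapse = ", "))
  structure(labels, class = "gene_order", anchor = anchor)
}

#' @export
print.gene_order <- function(x, ...) {
  cat("<gene_order>", paste(unclass(x), collapse = ","), "\n")
  invisible(x)
}

#' @method format gene_order
#' @export
format.gene_order <- function(x, ...) paste(unclass(x), collapse = ",")

#' Read/write a gene order as a comma-separated string
#'
#' The plain-text exchange format: signed labels joined by commas,
#' `-trnQ` marking the minority strand.
#'
#' @param x A `gene_order` (for writing) or a string/path (for reading).
#' @return `gene_order_string()` returns a string; `parse_gene_order()`
#'   a `gene_order`.
#' @export
gene_order_string <- function(x) format(x)

#' @rdname gene_order_string
#' @export
parse_gene_order <- function(x) {
  gene_order(trimws(strsplit(x, ",", fixed = TRUE)[[1]]))
}

#' Extract the signed gene order of an annotated mitogenome
#'
#' Features are taken circularly in order of start coordinate; NCR
#' features are included as labeled elements, flagged unknown features
#' are excluded. Duplicated canonical labels are an error; a genome
#' missing some of the 37 genes yields a warning but still returns the
#' order.
#'
#' @param g A [mitogenome].
#' @return A [gene_order].
#' @export
extract_gene_order <- function(g) {
  f <- g$features[!g$features$flagged, ]
  dup <- canonical_duplicates(g)
  if (length(dup))
    stop("duplicate canonical labels: ", paste(dup, collapse = ", "))
  expected <- mito_gene_table()$label
  expected <- expected[!expected %in% c("NCR")]
  missing <- setdiff(expected, f$label)
  if (length(missing))
    warning("genome missing ", length(missing), " canonical genes: ",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
  gene_order(paste0(ifelse(f$strand == "N", "-", ""), f$label))
}

#' Rotate a gene order so an anchor label comes first
#'
#' Deterministic and idempotent; the anchor is matched by bare label
#' (sign ignored).
#'
#' @param o A [gene_order].
#' @param anchor A canonical label present in `o`.
#' @return The rotated [gene_order].
#' @export
#' @examples
#' normalize_rotation(ancestral_insect_order(), "CR")
normalize_rotation <- function(o, anchor) {
  x <- unclass(o)
  i <- which(strip_sign(x) == strip_sign(anchor))
  if (!length(i)) stop("anchor not present: ", anchor)
  i <- i[1]
  gene_order(c(x[i:length(x)], x[seq_len(i - 1)]), anchor = anchor)
}

# rotation equality of signed circular sequences (labels unique)
rotation_equal <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (length(a) != length(b)) return(FALSE)
  if (!length(a)) return(TRUE)
  i <- which(strip_sign(b) == strip_sign(a[1]))
  if (!length(i)) return(FALSE)
  identical(a, c(b[i:length(b)], b[seq_len(i - 1)]))
}

drop_ncr <- function(o) {
  x <- unclass(o)
  x[!grepl("^NCR", strip_sign(x))]
}

check_same_labels <- function(ref, obs) {
  if (!setequal(strip_sign(ref), strip_sign(obs)))
    stop("gene orders have different label sets")
}

# one maximum circular common subsequence (elements, signed)
circular_lcs <- function(a, b) {
  n <- length(a)
  if (!n) return(character())
  best <- character()
  for (i in seq_len(n)) {
    ai <- c(a[i:n], a[seq_len(i - 1)])
    for (j in seq_len(n)) {
      bj <- c(b[j:n], b[seq_len(j - 1)])
      cand <- lcs_traceback(ai, bj)
      if (length(cand) > length(best)) best <- cand
      if (length(best) == n) return(best)
    }
  }
  best
}

lcs_traceback <- function(a, b) {
  n <- length(a); m <- length(b)
  L <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m))
    L[i + 1, j + 1] <- if (a[i] == b[j]) L[i, j] + 1L
    else max(L[i, j + 1], L[i + 1, j])
  out <- character(L[n + 1, m + 1])
  k <- length(out); i <- n; j <- m
  while (i > 0 && j > 0) {
    if (a[i] == b[j]) { out[k] <- a[i]; k <- k - 1; i <- i - 1; j <- j - 1 }
    else if (L[i, j + 1] >= L[i + 1, j]) i <- i - 1
    else j <- j - 1
  }
  out
}

# circular unsigned adjacency set, as "x|y" with sorted endpoints
adjacency_set <- function(x) {
  lab <- strip_sign(x)
  n <- length(lab)
  if (n < 2) return(character())
  nxt <- c(lab[-1], lab[1])
  unique(paste(pmin(lab, nxt), pmax(lab, nxt), sep = "|"))
}

#' Breakpoint distance between two circular gene orders
#'
#' The number of unsigned circular adjacencies of `ref` absent from
#' `obs`. NCR elements are ignored (they are products of rearrangement,
#' not markers). The distance is symmetric for permutations, rotation
#' invariant, and zero iff the orders are rotation-equal up to sign.
#'
#' @param ref,obs [gene_order] objects over the same label set
#'   (after NCR removal).
#' @return A non-negative integer.
#' @export
#' @examples
#' breakpoint_distance(ancestral_insect_order(), dynastine_gene_order())
breakpoint_distance <- function(ref, obs) {
  r <- drop_ncr(ref); o <- drop_ncr(obs)
  check_same_labels(r, o)
  sum(!adjacency_set(r) %in% adjacency_set(o))
}

#' Minimal sets of genes whose removal reconciles two orders
#'
#' The moved genes between `ref` and `obs`: the complement of a
#' maximum-length circular common subsequence (signs respected). All
#' optimal sets are reported when their number is tractable - e.g. the
#' ancestral vs dynastine comparison returns both `{trnI}` and `{trnQ}`,
#' either of which restores rotation equality. NCR elements are ignored.
#'
#' @param ref,obs [gene_order] objects over the same label set.
#' @param max_k Largest removal-set size searched exhaustively (all
#'   optima reported up to here); larger events fall back to a single
#'   optimum recovered from a maximum circular common subsequence.
#' @return A list of character vectors (bare labels), each a minimal
#'   removal set; empty-set singleton when the orders already agree.
#' @export
moved_genes <- function(ref, obs, max_k = 3) {
  r <- drop_ncr(ref); o <- drop_ncr(obs)
  check_same_labels(r, o)
  labels <- strip_sign(r)
  n <- length(r)
  for (k in 0:min(max_k, n)) {
    sets <- if (k == 0) list(character())
    else combn(labels, k, simplify = FALSE)
    keep <- purrr::keep(sets, function(s) {
      rotation_equal(r[!labels %in% s], o[!strip_sign(o) %in% s])
    })
    if (length(keep)) return(keep)
  }
  # larger event: one optimum via a maximum circular common subsequence
  best <- circular_lcs(r, o)
  list(sort(setdiff(labels, strip_sign(best))))
}

#' Classify a non-coding region by length
#'
#' The two NCR classes observed between trnQ and trnI: NCR1 below 100 bp
#' and NCR2 above 400 bp; lengths of 100-400 bp fall outside that
#' dichotomy and are flagged `intermediate`.
#'
#' @param length NCR length(s) in bp, positive.
#' @return Character vector: `"NCR1"`, `"NCR2"` or `"intermediate"`.
#' @export
#' @examples
#' classify_ncr(c(56, 412, 250))
classify_ncr <- function(length) {
  if (any(length <= 0)) stop("NCR length must be positive")
  dplyr::case_when(length < 100 ~ "NCR1",
                   length > 400 ~ "NCR2",
                   TRUE ~ "intermediate")
}

# ---- single-TDRL enumeration ------------------------------------------

#' Enumerate single tandem-duplication-random-loss scenarios
#'
#' A single TDRL event duplicates one contiguous block of the source
#' order in tandem and then loses exactly one of the two copies of every
#' duplicated gene. This routine exhaustively tries every block and every
#' copy-loss assignment on a (linear) window of at most 12 elements and
#' returns the scenarios whose surviving gene sequence equals the target
#' window. NCR elements in the target are not part of the gene match;
#' instead, every lost copy whose flanking surviving genes bracket a
#' target NCR is recorded as a candidate origin of that NCR (the
#' degenerate remnant of the lost copy).
#'
#' @param source,target [gene_order] windows (or plain character vectors)
#'   sharing a gene set; `target` may additionally contain NCR elements.
#' @return A list of class `tdrl_scenarios`; each element has `block`
#'   (index range in `source`), `block_genes`, `kept_copy` (named
#'   `"copy1"`/`"copy2"` per duplicated gene), `result` (signed labels)
#'   and `remnant_slots` (tibble of lost copies adjacent to target NCRs:
#'   `lost_gene`, `lost_copy`, `left_gene`, `right_gene`, `ncr`).
#' @export
#' @examples
#' sc <- enumerate_single_tdrl(c("CR", "trnI", "-trnQ", "trnM"),
#'                             c("CR", "-trnQ", "NCR", "trnI", "trnM"))
#' length(sc) > 0
enumerate_single_tdrl <- function(source, target) {
  src <- as.character(source)
  tgt <- as.character(target)
  tgt_genes <- tgt[!grepl("^NCR", strip_sign(tgt))]
  if (!setequal(strip_sign(src), strip_sign(tgt_genes)))
    stop("source and target windows must share a gene set")
  if (length(src) > 12)
    stop("window too large for exhaustive TDRL enumeration (max 12)")
  # a TDRL never inverts: any sign change rules out a single-TDRL origin
  if (!setequal(src, tgt_genes))
    return(structure(list(), class = "tdrl_scenarios"))
  ncr_slots <- target_ncr_slots(tgt)
  n <- length(src)
  out <- list()
  for (i in seq_len(n)) for (j in i:n) {
    block <- src[i:j]
    m <- length(block)
    for (mask in 0:(2^m - 1)) {
      keep1 <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0  # TRUE: keep copy1
      kept <- c(if (i > 1) src[1:(i - 1)],
                block[keep1], block[!keep1],
                if (j < n) src[(j + 1):n])
      if (!identical(kept, tgt_genes)) next
      out[[length(out) + 1]] <- build_tdrl_scenario(
        src, i, j, keep1, tgt_genes, ncr_slots)
    }
  }
  structure(out, class = "tdrl_scenarios")
}

# NCRs in the target, keyed by the bare labels of the flanking genes
# (NA at a window boundary)
target_ncr_slots <- function(tgt) {
  is_ncr <- grepl("^NCR", strip_sign(tgt))
  if (!any(is_ncr)) return(tibble(ncr = character(), left_gene = character(),
                                  right_gene = character()))
  purrr::map_dfr(which(is_ncr), function(k) {
    left <- if (k > 1 && !is_ncr[k - 1]) strip_sign(tgt[k - 1]) else NA_character_
    right <- if (k < length(tgt) && !is_ncr[k + 1]) strip_sign(tgt[k + 1]) else NA_character_
    tibble(ncr = tgt[k], left_gene = left, right_gene = right)
  })
}

build_tdrl_scenario <- function(src, i, j, keep1, tgt_genes, ncr_slots) {
  block <- src[i:j]
  m <- length(block)
  # intermediate token sequence after duplication
  tokens <- tibble(
    gene = c(if (i > 1) src[1:(i - 1)], block, block,
             if (j < length(src)) src[(j + 1):length(src)]),
    copy = c(rep("single", i - 1), rep("copy1", m), rep("copy2", m),
             rep("single", length(src) - j)),
    kept = c(rep(TRUE, i - 1), keep1, !keep1, rep(TRUE, length(src) - j))
  )
  remnants <- lost_copy_slots(tokens, ncr_slots)
  kc <- ifelse(keep1, "copy1", "copy2")
  list(
    block = c(from = i, to = j),
    block_genes = block,
    kept_copy = setNames(kc, block),
    result = tokens$gene[tokens$kept],
    remnant_slots = remnants
  )
}

# lost copies whose flanking kept genes bracket a target NCR slot
lost_copy_slots <- function(tokens, ncr_slots) {
  lost <- which(!tokens$kept)
  if (!length(lost) || !nrow(ncr_slots))
    return(tibble(lost_gene = character(), lost_copy = character(),
                  left_gene = character(), right_gene = character(),
                  ncr = character()))
  purrr::map_dfr(lost, function(p) {
    lk <- which(tokens$kept[seq_len(p - 1)])
    rk <- which(tokens$kept) ; rk <- rk[rk > p]
    left <- if (length(lk)) strip_sign(tokens$gene[max(lk)]) else NA_character_
    right <- if (length(rk)) strip_sign(tokens$gene[min(rk)]) else NA_character_
    hit <- ncr_slots[
      (is.na(ncr_slots$left_gene) | (!is.na(left) & ncr_slots$left_gene == left)) &
      (is.na(ncr_slots$right_gene) | (!is.na(right) & ncr_slots$right_gene == right)), ]
    if (!nrow(hit)) return(NULL)
    tibble(lost_gene = tokens$gene[p], lost_copy = tokens$copy[p],
           left_gene = left, right_gene = right, ncr = hit$ncr[1])
  })
}

#' Re-apply a TDRL scenario mechanically
#'
#' Duplicates the scenario's block in the source window and applies its
#' copy-loss assignment; used to verify that every returned scenario
#' reproduces the target exactly.
#'
#' @param source The source window given to [enumerate_single_tdrl()].
#' @param scenario One element of its result.
#' @return The surviving signed gene sequence.
#' @export
apply_tdrl <- function(source, scenario) {
  src <- as.character(source)
  i <- scenario$block[["from"]]; j <- scenario$block[["to"]]
  block <- src[i:j]
  keep1 <- unname(scenario$kept_copy[block]) == "copy1"
  c(if (i > 1) src[1:(i - 1)], block[keep1], block[!keep1],
    if (j < length(src)) src[(j + 1):length(src)])
}

# ---- rearrangement classification -------------------------------------

#' Compare a genome's gene order against a reference order
#'
#' Computes the breakpoint distance and moved genes, classifies the event
#' (`none`, `inversion` when every moved gene only changed strand,
#' `translocation` when strands are preserved, `complex` otherwise),
#' tests single-TDRL compatibility by exhaustive enumeration over the
#' minimal window spanning the moved genes and their neighbours, and
#' classifies any NCR elements by length.
#'
#' @param ref Reference [gene_order] (default the ancestral insect order).
#' @param obs Observed [gene_order].
#' @param ncr_lengths Optional named numeric vector of NCR lengths (bp),
#'   names matching the NCR labels in `obs`.
#' @return A `rearrangement_report` object; see [tidy()] and [glance()]
#'   methods.
#' @export
#' @examples
#' rep <- classify_rearrangement(ancestral_insect_order(),
#'                               dynastine_gene_order(),
#'                               ncr_lengths = c(NCR = 412))
#' glance(rep)
classify_rearrangement <- function(ref = ancestral_insect_order(), obs,
                                   ncr_lengths = NULL) {
  bd <- breakpoint_distance(ref, obs)
  ncrs <- ncr_report(obs, ncr_lengths)
  r <- drop_ncr(ref); o <- drop_ncr(obs)
  sign_ref <- setNames(sign_of(r), strip_sign(r))
  sign_obs <- setNames(sign_of(o), strip_sign(o))
  flipped <- names(sign_ref)[sign_ref != sign_obs[names(sign_ref)]]
  if (bd == 0 && !length(flipped)) {
    return(new_rearrangement_report(
      breakpoint_count = 0L, moved = list(character()),
      event_class = "none", tdrl_compatible = FALSE,
      scenarios = structure(list(), class = "tdrl_scenarios"), ncrs = ncrs))
  }
  mg <- moved_genes(ref, obs)
  moved_union <- sort(unique(unlist(mg)))
  event <- if (length(flipped) == 0) "translocation"
  else if (setequal(flipped, moved_union)) "inversion"
  else "complex"
  scen <- structure(list(), class = "tdrl_scenarios")
  tdrl_ok <- FALSE
  if (event == "translocation") {
    win <- tdrl_window(ref, obs, moved_union)
    if (!is.null(win)) {
      scen <- enumerate_single_tdrl(win$source, win$target)
      tdrl_ok <- length(scen) > 0
    }
  }
  new_rearrangement_report(breakpoint_count = bd, moved = mg,
                           event_class = event, tdrl_compatible = tdrl_ok,
                           scenarios = scen, ncrs = ncrs)
}

ncr_report <- function(obs, ncr_lengths) {
  x <- unclass(obs)
  idx <- which(grepl("^NCR", strip_sign(x)))
  if (!length(idx))
    return(tibble(ncr = character(), position = integer(),
                  length = numeric(), class = character()))
  len <- rep(NA_real_, length(idx))
  if (!is.null(ncr_lengths)) {
    nm <- strip_sign(x[idx])
    len <- unname(ncr_lengths[nm])
  }
  tibble(ncr = strip_sign(x[idx]), position = idx, length = len,
         class = ifelse(is.na(len), NA_character_, classify_ncr(pmax(len, 1))))
}

# Minimal circular window in ref covering the moved genes and their
# neighbours in both orders, with the matching window of obs (NCRs kept
# in the target so remnant slots can be assigned).
tdrl_window <- function(ref, obs, moved_union, max_window = 12) {
  r <- drop_ncr(ref); o_full <- unclass(obs); o <- drop_ncr(obs)
  if (!length(moved_union)) return(NULL)
  want <- moved_union
  repeat {
    want <- unique(c(want,
                     circular_neighbors(r, want),
                     circular_neighbors(o, want)))
    ri <- which(strip_sign(r) %in% want)
    oi <- which(strip_sign(o) %in% want)
    rwin <- minimal_circular_window(r, ri)
    owin <- minimal_circular_window(o, oi)
    genes_r <- strip_sign(rwin); genes_o <- strip_sign(owin)
    if (setequal(genes_r, genes_o)) break
    want <- unique(c(genes_r, genes_o))
    if (length(want) > max_window) return(NULL)
  }
  if (length(rwin) > max_window) return(NULL)
  # re-cut the obs window from the full order so NCRs inside it survive
  owin_full <- minimal_circular_window(
    o_full, which(strip_sign(o_full) %in% strip_sign(owin)))
  list(source = rwin, target = owin_full)
}

circular_neighbors <- function(x, labels) {
  lab <- strip_sign(x)
  n <- length(lab)
  idx <- which(lab %in% labels)
  unique(lab[c((idx %% n) + 1, ((idx - 2) %% n) + 1)])
}

# shortest circular interval of x containing all idx positions
minimal_circular_window <- function(x, idx) {
  n <- length(x)
  idx <- sort(idx)
  if (!length(idx)) return(character())
  # the complement of the largest gap between consecutive hits
  gaps <- diff(c(idx, idx[1] + n))
  gi <- which.max(gaps)
  from <- idx[(gi %% length(idx)) + 1]
  span <- n - max(gaps) + 1
  pos <- ((from - 1 + seq_len(span) - 1) %% n) + 1
  x[pos]
}

new_rearrangement_report <- function(breakpoint_count, moved, event_class,
                                     tdrl_compatible, scenarios, ncrs) {
  structure(list(breakpoint_count = breakpoint_count,
                 moved_genes = moved,
                 moved_union = sort(unique(unlist(moved))),
                 event_class = event_class,
                 tdrl_compatible = tdrl_compatible,
                 scenarios = scenarios,
                 ncrs = ncrs),
            class = "rearrangement_report")
}

#' @export
print.rearrangement_report <- function(x, ...) {
  cat(sprintf("<rearrangement_report> %s | breakpoints: %d | moved: {%s}%s\n",
              x$event_class, x$breakpoint_count,
              paste(x$moved_union, collapse = ", "),
              if (x$tdrl_compatible)
                sprintf(" | tdrl-compatible (%d scenarios)",
                        length(x$scenarios)) else ""))
  if (nrow(x$ncrs)) print(x$ncrs)
  invisible(x)
}

#' Tidy a rearrangement report
#'
#' @param x A `rearrangement_report`.
#' @param ... Unused.
#' @return `tidy()`: one row per detected NCR (with the event context);
#'   `glance()`: a one-row summary (`event_class`, `breakpoint_count`,
#'   `n_moved`, `moved_genes`, `tdrl_compatible`, `n_scenarios`, `n_ncr`).
#' @export
tidy.rearrangement_report <- function(x, ...) {
  base <- tibble(event_class = x$event_class,
                 breakpoint_count = x$breakpoint_count,
                 tdrl_compatible = x$tdrl_compatible)
  if (!nrow(x$ncrs)) return(base)
  dplyr::bind_cols(x$ncrs, base[rep(1, nrow(x$ncrs)), ])
}

#' @rdname tidy.rearrangement_report
#' @export
glance.rearrangement_report <- function(x, ...) {
  tibble(event_class = x$event_class,
         breakpoint_count = x$breakpoint_count,
         n_moved = length(x$moved_union),
         moved_genes = paste(x$moved_union, collapse = ","),
         tdrl_compatible = x$tdrl_compatible,
         n_scenarios = length(x$scenarios),
         n_ncr = nrow(x$ncrs))
}

# JSON-friendly representation of a report (used by run_comparative)
rearrangement_report_json <- function(x) {
  list(
    event_class = x$event_class,
    breakpoint_count = x$breakpoint_count,
    moved_gene_sets = x$moved_genes,
    tdrl_compatible = x$tdrl_compatible,
    n_scenarios = length(x$scenarios),
    scenarios = lapply(x$scenarios, function(s) {
      list(block = unname(s$block), block_genes = s$block_genes,
           kept_copy = as.list(s$kept_copy), result = s$result,
           remnant_slots = s$remnant_slots)
    }),
    ncrs = x$ncrs
  )
}
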