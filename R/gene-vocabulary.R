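#' Canonical mitochondrial gene vocabulary
#'
#' The 37 genes of the insect mitochondrial genome (13 protein-coding genes,
#' 22 tRNAs, 2 rRNAs) plus the control region (CR) and the generic
#' non-coding-region label (NCR), with the strand each gene occupies in the
#' ancestral insect arrangement. Strands follow the J/N convention:
#' J is the majority (forward) strand of the deposited sequence, N the
#' minority strand.
#'
#' @return A tibble with columns `label`, `category`
#'   (`PCG`/`tRNA`/`rRNA`/`CR`/`NCR`) and `ancestral_strand` (`J`/`N`;
#'   `NA` for CR/NCR).
#' @export
#' @examples
#' mito_gene_table()
mito_gene_table <- function() {
  ord <- ancestral_insect_order()
  strands <- setNames(ifelse(startsWith(ord, "-"), "N", "J"), strip_sign(ord))
  pcg <- c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
           "COX1", "COX2", "COX3", "ATP6", "ATP8", "CYTB")
  trn <- paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L1",
                         "L2", "M", "N", "P", "Q", "R", "S1", "S2", "T",
                         "V", "W", "Y"))
  lab <- c(pcg, trn, "rrnS", "rrnL", "CR", "NCR")
  tibble(
    label = lab,
    category = c(rep("PCG", 13), rep("tRNA", 22), "rRNA", "rRNA", "CR", "NCR"),
    ancestral_strand = unname(strands[lab])
  )
}

#' The ancestral insect mitochondrial gene order
#'
#' The plesiomorphic pancrustacean arrangement of the 37 genes plus the
#' control region, as a signed circular gene order (a leading `-` marks the
#' minority N strand). The order begins, by convention, with the
#' trnI-trnQ-trnM cluster that follows the control region.
#'
#' @return A [gene_order] vector of 38 signed labels.
#' @seealso [dynastine_gene_order()] for the rearranged
#'   trnQ-NCR-trnI-trnM variant.
#' @export
#' @examples
#' ancestral_insect_order()
ancestral_insect_order <- function() {
  gene_order(c(
    "trnI", "-trnQ", "trnM", "ND2", "trnW", "-trnC", "-trnY", "COX1",
    "trnL2", "COX2", "trnK", "trnD", "ATP8", "ATP6", "COX3", "trnG",
    "ND3", "trnA", "trnR", "trnN", "trnS1", "trnE", "-trnF", "-ND5",
    "-trnH", "-ND4", "-ND4L", "trnT", "-trnP", "ND6", "CYTB", "trnS2",
    "-ND1", "-trnL1", "-rrnL", "-trnV", "-rrnS", "CR"
  ))
}

#' The rearranged gene order of dynastine scarab beetles
#'
#' Identical to [ancestral_insect_order()] except that trnI and trnQ have
#' swapped positions and a non-coding region (NCR) sits between them,
#' giving the CR-trnQ-NCR-trnI-trnM cluster characteristic of the
#' subfamily Dynastinae.
#'
#' @return A [gene_order] vector of 39 signed labels (38 genes/CR + NCR).
#' @export
#' @examples
#' dynastine_gene_order()
dynastine_gene_order <- function() {
  anc <- unclass(ancestral_insect_order())
  gene_order(c("-trnQ", "NCR", "trnI", "trnM", anc[4:38]))
}

strip_sign <- function(x) sub("^-", "", x)
sign_of <- function(x) ifelse(startsWith(x, "-"), "-", "+")

gene_category <- function(labels) {
  tab <- mito_gene_table()
  cat <- tab$category[match(strip_sign(labels), tab$label)]
  cat[is.na(cat) & grepl("^NCR", strip_sign(labels))] <- "NCR"
  cat[is.na(cat)] <- "unknown"
  cat
}

# anticodon (DNA alphabet, lowercase ok) -> Leu/Ser paralog label
ANTICODON_PARALOG <- c(
  tag = "trnL1", taa = "trnL2",   # Leu(CUN) vs Leu(UUR)
  gct = "trnS1", tct = "trnS1",   # Ser(AGN)
  tga = "trnS2"                   # Ser(UCN)
)

#' Map a raw gene name to the canonical label
#'
#' Performs a case- and punctuation-insensitive lookup of common GenBank
#' aliases ("nad2", "COI", "16S ribosomal RNA", "tRNA-Gln", "D-loop", ...)
#' onto the canonical vocabulary of [mito_gene_table()]. The Leu and Ser
#' tRNA paralogs are disambiguated by an explicit family tag in the name
#' (e.g. "trnL-uag", "tRNA-Ser (UCN)") or by the `anticodon` argument.
#' Names that cannot be mapped are never dropped: they come back as
#' `"unknown:<raw>"` so downstream 37-gene logic can exclude them.
#'
#' @param raw Character vector of raw names (from `/gene`, `/product`, ...).
#' @param anticodon Optional character vector (recycled) of anticodon
#'   triplets, DNA or RNA alphabet, used to split trnL1/trnL2 and
#'   trnS1/trnS2.
#' @return Character vector of canonical labels; unmappable entries are
#'   flagged as `"unknown:<raw>"`.
#' @export
#' @examples
#' canonical_gene_name(c("nad5", "COI", "l-rRNA", "tRNA-Gln"))
#' canonical_gene_name("tRNA-Leu", anticodon = "tag")
canonical_gene_name <- function(raw, anticodon = NULL) {
  if (!length(raw)) return(character())
  if (is.null(anticodon)) anticodon <- NA_character_
  anticodon <- rep_len(tolower(chartr("uU", "tT", as.character(anticodon))),
                       length(raw))
  mapply(canonical_one, as.character(raw), anticodon, USE.NAMES = FALSE)
}

canonical_one <- function(raw, anticodon) {
  key <- gsub("[^a-z0-9]", "", tolower(raw))
  hit <- GENE_ALIASES[[key]]
  if (!is.null(hit)) return(hit)
  # tRNAs named by amino acid, with optional codon-family tag in the raw name
  aa <- trna_amino_acid(key)
  if (!is.na(aa)) {
    if (aa %in% c("L", "S")) {
      fam <- trna_family_tag(raw, aa)
      if (!is.na(fam)) return(fam)
      if (!is.na(anticodon) && anticodon %in% names(ANTICODON_PARALOG)) {
        lab <- ANTICODON_PARALOG[[anticodon]]
        if (substr(lab, 4, 4) == aa) return(lab)
      }
      return(paste0("unknown:", raw))
    }
    return(paste0("trn", aa))
  }
  paste0("unknown:", raw)
}

trna_amino_acid <- function(key) {
  m <- regmatches(key, regexec(
    "^trna?(ala|arg|asn|asp|cys|gln|glu|gly|his|ile|leu|lys|met|phe|pro|ser|thr|trp|tyr|val|[acdefghiklmnpqrstvwy])",
    key))[[1]]
  if (length(m) < 2) return(NA_character_)
  three <- c(ala = "A", arg = "R", asn = "N", asp = "D", cys = "C",
             gln = "Q", glu = "E", gly = "G", his = "H", ile = "I",
             leu = "L", lys = "K", met = "M", phe = "F", pro = "P",
             ser = "S", thr = "T", trp = "W", tyr = "Y", val = "V")
  code <- m[2]
  if (nchar(code) == 3) unname(three[code]) else toupper(code)
}

trna_family_tag <- function(raw, aa) {
  key <- tolower(raw)
  if (aa == "L") {
    if (grepl("cun|uag|tag|l1", key)) return("trnL1")
    if (grepl("uur|uaa|taa|l2", key)) return("trnL2")
  } else {
    if (grepl("agn|gcu|gct|ucu|tct|s1", key)) return("trnS1")
    if (grepl("ucn|uga|tga|s2", key)) return("trnS2")
  }
  NA_character_
}

# alias key (lowercase, alnum only) -> canonical label
GENE_ALIASES <- local({
  al <- list()
  add <- function(label, ...) for (a in c(...)) al[[gsub("[^a-z0-9]", "", tolower(a))]] <<- label
  for (i in 1:6) {
    add(paste0("ND", i), paste0("nd", i), paste0("nad", i),
        paste0("nadh dehydrogenase subunit ", i),
        paste0("nadhdehydrogenasesubunit", c("i","ii","iii","iv","v","vi")[i]))
  }
  add("ND4L", "nd4l", "nad4l", "nadh dehydrogenase subunit 4l")
  for (i in 1:3) {
    add(paste0("COX", i), paste0("cox", i), paste0("co", i),
        paste0("co", c("i", "ii", "iii")[i]),
        paste0("cytochrome c oxidase subunit ", i),
        paste0("cytochromecoxidasesubunit", c("i", "ii", "iii")[i]),
        paste0("cytochromeoxidasesubunit", i))
  }
  add("ATP6", "atp6", "atpase6", "atp synthase f0 subunit 6",
      "atpsynthasesubunit6")
  add("ATP8", "atp8", "atpase8", "atp synthase f0 subunit 8",
      "atpsynthasesubunit8")
  add("CYTB", "cytb", "cob", "cytb gene", "cytochrome b", "cytochromeb")
  add("rrnS", "rrns", "12s", "srrna", "12srrna", "12sribosomalrna",
      "smallsubunitribosomalrna", "ssurrna", "rns")
  add("rrnL", "rrnl", "16s", "lrrna", "16srrna", "16sribosomalrna",
      "largesubunitribosomalrna", "lsurrna", "rnl")
  add("CR", "cr", "dloop", "controlregion", "atrichregion",
      "atrichregion", "putativecontrolregion")
  add("NCR", "ncr", "noncodingregion")
  for (t in c("A","C","D","E","F","G","H","I","K","M","N","P","Q","R","T","V","W","Y"))
    add(paste0("trn", t), paste0("trn", tolower(t)))
  for (t in c("L1", "L2", "S1", "S2"))
    add(paste0("trn", t), paste0("trn", tolower(t)))
  al
})
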