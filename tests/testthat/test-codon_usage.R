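counts_for <- function(tbl, codons) {
  tbl$count[match(codons, tbl$codon)]
}

test_that("codon counting excludes stops and incomplete remainders", {
  t1 <- count_codons("ATGTTTTAA")
  expect_equal(attr(t1, "total_codons"), 2)        # ATG, TTT; TAA excluded
  expect_equal(counts_for(t1, c("ATG", "TTT", "TAA")), c(1L, 1L, 0L))

  t2 <- count_codons("ATGT")                        # incomplete stop T
  expect_equal(attr(t2, "total_codons"), 1)
  expect_equal(attr(t2, "total_codons_incl_incomplete"), 2)

  t3 <- count_codons(c("ATGTTTTAA", "ATGTTTTAA"))   # additivity
  expect_equal(counts_for(t3, c("ATG", "TTT")), c(2L, 2L))

  t4 <- count_codons("ATGNNNTTT")                   # ambiguous codon skipped
  expect_equal(attr(t4, "ambiguous_codons"), 1)
  expect_equal(attr(t4, "total_codons"), 2)
})

test_that("RSCU follows the family-size formula and normalizes to mean 1", {
  # Lys family AAA/AAG (size 2): counts (10, 10) and (20, 0)
  tab <- count_codons(c(strrep("AAA", 10), strrep("AAG", 10)))
  r <- rscu(tab)
  expect_equal(r$rscu[match(c("AAA", "AAG"), r$codon)], c(1, 1))
  tab2 <- count_codons(strrep("AAA", 20))
  r2 <- rscu(tab2)
  expect_equal(r2$rscu[match(c("AAA", "AAG"), r2$codon)], c(2, 0))
  # Val family GTN (size 4): counts 4,2,1,1 -> RSCU 2,1,0.5,0.5
  tab3 <- count_codons(paste0(strrep("GTA", 4), strrep("GTC", 2),
                              "GTG", "GTT"))
  r3 <- rscu(tab3)
  expect_equal(r3$rscu[match(c("GTA", "GTC", "GTG", "GTT"), r3$codon)],
               c(2, 1, 0.5, 0.5))
  # stop codons carry no RSCU; unused family is all zero
  expect_true(all(is.na(r3$rscu[r3$family == "*"])))
  expect_true(all(r3$rscu[r3$family == "Pro"] == 0))
})

test_that("amino-acid composition splits Leu1/Leu2 and Ser1/Ser2", {
  fam <- codon_families()
  expect_equal(sort(unique(fam$family[fam$aa == "L"])), c("Leu1", "Leu2"))
  expect_equal(sort(unique(fam$family[fam$aa == "S"])), c("Ser1", "Ser2"))
  expect_equal(fam$family_size[fam$codon == "CTA"], 4)  # Leu1 = CUN
  expect_equal(fam$family_size[fam$codon == "TTA"], 2)  # Leu2 = UUR
  expect_equal(fam$family_size[fam$codon == "AGA"], 4)  # Ser1 = AGN (table 5)

  aa <- amino_acid_composition(count_codons(strrep("AAA", 20)))
  expect_equal(aa$count[aa$family == "Lys"], 20)
  empty <- amino_acid_composition(count_codons(character()))
  expect_true(all(empty$count == 0))
})

test_that("codon counts recover a PCG built from known draws", {
  s <- build_pcg(50, "ATG", "TAA", seed = 5)
  # oracle: direct substring codon tally
  cods <- substring(s, seq(1, nchar(s) - 3, 3), seq(3, nchar(s), 3))
  cods <- cods[-length(cods)]  # drop the stop (already excluded by rule)
  tab <- count_codons(s)
  oracle <- table(cods)
  for (cd in names(oracle))
    expect_equal(tab$count[tab$codon == cd], as.integer(oracle[[cd]]))
  expect_equal(attr(tab, "total_codons"), 51)
  expect_equal(sum(tab$count), 51)  # conservation
})

test_that("start-codon rule prefers the nearest candidate over a distant ATN", {
  # upstream tRNA ends at 20; AAC begins 1 bp later; the nearest
  # canonical ATN sits 34 bp downstream of the tRNA end
  gap <- "G"                                       # offset 0 codon = GAA: no candidate
  filler <- strrep("CG", 15)                       # offsets 4..33 free of candidates
  cds <- paste0("AAC", filler, "ATGTTTTTC", strrep("GGC", 20), "TAA")
  seqs <- paste0(random_dna_fixed(20), gap, cds, random_dna_fixed(30))
  g <- mitogenome(seqs, tibble::tibble(
    label = c("trnY", "COX1"), strand = c("J", "J"),
    start = c(0, 21), end = c(20, 21 + nchar(cds))))
  call <- identify_start_codon(g, "COX1")
  expect_equal(call$start_codon, "AAC")
  expect_equal(call$start_class, "atypical-AAN")
  expect_equal(call$start_offset, 1)
  # and the distant canonical really is at offset 34
  region <- substr(seqs, 21, 21 + 60)
  expect_equal(substr(region, 35, 37), "ATG")
})

test_that("start-codon search respects the window and reports no-call", {
  s <- paste0(strrep("G", 20), strrep("GC", 40))
  g <- mitogenome(s, tibble::tibble(
    label = c("trnY", "COX1"), strand = c("J", "J"),
    start = c(0, 20), end = c(20, 80)))
  call <- identify_start_codon(g, "COX1")
  expect_true(call$no_call)
})

test_that("canonical start at offset zero is called for both strands", {
  res <- generate_mitogenome(synthetic_spec("dynastinae", seed = 19))
  g <- res$genome
  nd1 <- identify_start_codon(g, "ND1")  # N strand
  expect_equal(nd1$start_codon, "ATA")
  expect_equal(nd1$start_offset, 0)
})

test_that("stop codons: complete, incomplete, and premature flags", {
  # CDS ending ...T| immediately followed by a tRNA: incomplete T
  cds <- paste0("ATG", strrep("GGC", 5), "T")
  s <- paste0(cds, random_dna_fixed(20))
  g <- mitogenome(s, tibble::tibble(
    label = c("COX2", "trnK"), strand = c("J", "J"),
    start = c(0, nchar(cds)), end = c(nchar(cds), nchar(cds) + 20)))
  call <- identify_stop_codon(g, "COX2")
  expect_equal(call$stop_codon, "T")
  expect_equal(call$stop_class, "incomplete")
  expect_false(call$premature)

  cds2 <- paste0("ATT", strrep("GGC", 5), "TAG")
  g2 <- mitogenome(paste0(cds2, "AAAA"), tibble::tibble(
    label = "ND3", strand = "J", start = 0, end = nchar(cds2)))
  call2 <- identify_stop_codon(g2, "ND3")
  expect_equal(call2$stop_codon, "TAG")
  expect_equal(call2$stop_class, "complete")

  cds3 <- paste0("ATG", strrep("GGC", 3), "TAA", strrep("GGC", 4), "TAA")
  g3 <- mitogenome(paste0(cds3, "AAAA"), tibble::tibble(
    label = "ND2", strand = "J", start = 0, end = nchar(cds3)))
  expect_true(identify_stop_codon(g3, "ND2")$premature)
})

test_that("start/stop calls recover generator truth for every PCG", {
  for (template in c("cetoniinae", "dynastinae")) {
    res <- generate_mitogenome(synthetic_spec(template, seed = 23))
    tab <- start_stop_table(res$genome)
    truth <- dplyr::inner_join(res$truth$start_stop,
                               res$truth$start_offsets, by = "gene")
    m <- dplyr::inner_join(tab, truth, by = "gene",
                           suffix = c("", ".truth"))
    expect_equal(nrow(m), 13)
    expect_equal(m$start_codon, m$start_codon.truth)
    expect_equal(m$start_offset, m$start_offset.truth)
    expect_equal(m$stop_codon, m$stop_codon.truth)
    expect_equal(m$stop_class, m$stop_class.truth)
    expect_false(any(m$premature))
  }
})
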