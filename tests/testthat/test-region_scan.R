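test_that("adjacent spacers report overlaps, gaps, and the origin pair", {
  res <- generate_mitogenome(synthetic_spec("cetoniinae", seed = 2))
  g <- res$genome
  sp <- adjacent_spacers(g)
  wc <- sp[sp$upstream == "trnW", ]
  expect_equal(wc$downstream, "trnC")
  expect_equal(wc$length, -8L)
  expect_equal(wc$sequence, "")
  # abutting pairs: zero length, empty sequence
  ab <- sp[sp$upstream == "trnM", ]
  expect_equal(ab$length, 0L)
  # circular conservation of lengths
  expect_equal(sum(g$features$end - g$features$start) + sum(sp$length),
               length(g))
})

test_that("an origin-spanning gap is measured circularly", {
  s <- paste0(strrep("A", 5), strrep("G", 10), strrep("C", 25),
              strrep("G", 10), strrep("T", 30))
  g <- mitogenome(s, tibble::tibble(
    label = c("trnI", "trnM"), strand = "J",
    start = c(5, 40), end = c(15, 50)))
  sp <- adjacent_spacers(g)
  expect_equal(sp$length, c(25L, 35L))  # trnI->trnM, then the wrap pair
  expect_equal(sp$sequence[2], paste0(strrep("T", 30), strrep("A", 5)))
})

test_that("nested features are excluded from the chain with a warning", {
  g <- mitogenome(strrep("ACGT", 20), tibble::tibble(
    label = c("rrnL", "trnV", "trnM"), strand = "J",
    start = c(0, 10, 40), end = c(30, 20, 60)))
  expect_warning(sp <- adjacent_spacers(g), "nested")
  expect_equal(attr(sp, "nested"), "trnV")
  expect_equal(nrow(sp), 2)
  expect_equal(sum(sp$length) + (30 - 0) + (60 - 40), 80)
})

test_that("motif search honors overlaps and IUPAC degeneracy", {
  expect_equal(find_motif("xxTACTAAxx", "TACTAA"), 2L)
  expect_equal(find_motif("GGGG", "TACTA"), integer())
  expect_equal(find_motif("TACTACTA", "TACTA"), c(0L, 3L))
  expect_equal(find_motif("TAGTACTA", "TASTA"), c(0L, 3L))  # S = C/G
  expect_equal(find_motif("ACGT", "NNNN"), 0L)
  expect_error(find_motif("ACGT", "TAXTA"), "IUPAC")
  # oracle comparison on random sequences
  set.seed(11)
  for (i in 1:25) {
    s <- random_dna(80, bases = c("A", "T", "C"))
    m <- random_dna(3, bases = c("A", "T"))
    expect_equal(find_motif(s, m), naive_motif_scan(s, m))
  }
})

test_that("homopolymer runs are maximal and respect boundaries", {
  r <- homopolymer_runs("AACCCCCCCCCCCA", 11)
  expect_equal(as.data.frame(r),
               data.frame(base = "C", start = 3L, length = 11L))
  expect_equal(nrow(homopolymer_runs("ACGT", 2)), 0)
  rend <- homopolymer_runs("ACGTTTT", 4)  # run touching the end
  expect_equal(rend$start, 4L)
  expect_equal(rend$length, 4L)
  expect_error(homopolymer_runs("AAAA", 1))
})

test_that("exact tandem repeats match the brute-force oracle", {
  r <- exact_tandem_repeats("ATGATGATG", c(2, 5))
  expect_equal(r$unit_sequence, "ATG")
  expect_equal(r$copy_number, 3)
  expect_equal(r$start, 1L)
  # smallest-period rule: AAAA is not a 2 bp-unit repeat
  expect_equal(nrow(exact_tandem_repeats("AAAA", c(2, 2))), 0)
  # random sequences against the oracle
  set.seed(21)
  for (i in 1:15) {
    s <- random_dna(100, bases = c("A", "T"))  # repeat-prone alphabet
    mine <- as.data.frame(exact_tandem_repeats(s, c(2, 10)))
    oracle <- naive_tandem_repeats(s, c(2, 10))
    rownames(mine) <- rownames(oracle) <- NULL
    expect_equal(mine, oracle)
  }
})

test_that("control region is located between rrnS and the next gene", {
  res <- generate_mitogenome(synthetic_spec("cetoniinae", seed = 6))
  cr <- locate_control_region(res$genome)
  expect_equal(cr$next_gene, "trnI")
  expect_equal(cr$length, res$truth$cr$length)
  expect_equal(cr$at_fraction, 0.80, tolerance = 0.03)

  dyn <- generate_mitogenome(synthetic_spec("dynastinae", seed = 6))
  crd <- locate_control_region(dyn$genome)
  expect_equal(crd$next_gene, "trnQ")
  expect_equal(crd$length, dyn$truth$cr$length)

  # rrnS abutting the next gene: zero-length CR flag
  g0 <- mitogenome(strrep("ACGT", 10), tibble::tibble(
    label = c("rrnS", "trnI"), strand = c("N", "J"),
    start = c(0, 20), end = c(20, 40)))
  expect_true(locate_control_region(g0)$zero_length)
  g1 <- mitogenome("ACGTACGT", tibble::tibble(
    label = "trnI", strand = "J", start = 0, end = 4))
  expect_error(locate_control_region(g1), "rrnS")
})

test_that("planted CR repeat arrays are recovered exactly", {
  for (seed in c(3, 13)) {
    res <- generate_mitogenome(synthetic_spec("dynastinae", seed = seed))
    g <- res$genome
    f <- g$features[g$features$label == "CR", ]
    crseq <- extract_gene_sequence(g, f, orientation = "forward")
    found <- exact_tandem_repeats(crseq, c(2, 200), min_copies = 2)
    tr <- res$truth$repeat_record
    hit <- found[found$start == tr$start & found$unit_length == tr$unit_length, ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$unit_sequence, tr$unit_sequence)
    expect_equal(hit$copy_number, tr$copy_number)
  }
})
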