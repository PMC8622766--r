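test_that("canonical_gene_name maps common aliases and flags unknowns", {
  expect_equal(canonical_gene_name("nad5"), "ND5")
  expect_equal(canonical_gene_name("COI"), "COX1")
  expect_equal(canonical_gene_name("cytochrome c oxidase subunit I"), "COX1")
  expect_equal(canonical_gene_name("l-rRNA"), "rrnL")
  expect_equal(canonical_gene_name("16S ribosomal RNA"), "rrnL")
  expect_equal(canonical_gene_name("tRNA-Gln"), "trnQ")
  expect_equal(canonical_gene_name("trnL-uag"), "trnL1")
  expect_equal(canonical_gene_name("tRNA-Leu (UUR)"), "trnL2")
  expect_equal(canonical_gene_name("D-loop"), "CR")
  expect_equal(canonical_gene_name("hypothetical"), "unknown:hypothetical")
  # Leu/Ser paralogs split by anticodon: GCU decodes AGN (Ser1),
  # UGA decodes UCN (Ser2), UAG decodes CUN (Leu1)
  expect_equal(canonical_gene_name("tRNA-Ser", anticodon = "gct"), "trnS1")
  expect_equal(canonical_gene_name("tRNA-Ser", anticodon = "tga"), "trnS2")
  expect_equal(canonical_gene_name("tRNA-Leu", anticodon = "uag"), "trnL1")
  # a Ser anticodon cannot resolve a Leu name
  expect_match(canonical_gene_name("tRNA-Leu", anticodon = "tga"), "^unknown:")
})

test_that("extract_gene_sequence honors strand and origin wrap", {
  g <- mitogenome("ATGCCC",
                  tibble::tibble(label = c("trnI", "trnM"),
                                 strand = c("J", "J"),
                                 start = c(0, 3), end = c(3, 6)))
  expect_equal(extract_gene_sequence(g, g$features[1, ]), "ATG")
  gN <- mitogenome("ATGCCC",
                   tibble::tibble(label = "trnQ", strand = "N",
                                  start = 0, end = 3))
  expect_equal(extract_gene_sequence(gN, "trnQ"), "CAT")
  # wrap feature [5, 8) on a 6 bp genome reads positions 5,0,1
  gw <- mitogenome("ATGCCC",
                   tibble::tibble(label = "trnW", strand = "J",
                                  start = 5, end = 8))
  expect_equal(extract_gene_sequence(gw, "trnW"), "CAT")
  expect_error(extract_gene_sequence(g, tibble::tibble(
    label = "x", category = "tRNA", strand = "J", start = -1, end = 2,
    flagged = FALSE)), "modular")
})

test_that("GenBank reader parses keys, strands, wraps, and aliases", {
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(genbank_text_fixture(), tf)
  g <- suppressWarnings(read_genbank(tf))[[1]]
  expect_equal(g$accession, "TEST01")
  expect_equal(g$organism, "Testus fixtureus")
  expect_equal(g$topology, "circular")
  expect_equal(nchar(g$sequence), 60)
  ft <- g$features
  expect_equal(ft$label[ft$start == 2], "COX1")
  expect_equal(ft$category[ft$label == "COX1"], "PCG")
  expect_equal(ft$strand[ft$label == "trnQ"], "N")
  expect_equal(ft$label[ft$start == 25], "trnS2")  # anticodon tga
  wrap <- ft[ft$label == "rrnL", ]
  expect_equal(c(wrap$start, wrap$end), c(54, 62))  # join(55..60,1..2)
})

test_that("GenBank write -> read round-trips generator output exactly", {
  for (template in c("cetoniinae", "dynastinae")) {
    g <- generate_mitogenome(synthetic_spec(template, seed = 42))$genome
    tf <- withr::local_tempfile(fileext = ".gb")
    write_genbank(g, tf)
    g2 <- read_genbank(tf)[[1]]
    expect_identical(g2$sequence, g$sequence)
    expect_identical(as.data.frame(g2$features), as.data.frame(g$features))
    expect_identical(g2$topology, g$topology)
  }
})

test_that("feature table TSV round-trips and handles empty genomes", {
  g <- generate_mitogenome(synthetic_spec("cetoniinae", seed = 8))$genome
  tf <- withr::local_tempfile(fileext = ".tsv")
  tab <- write_feature_table(g, tf)
  expect_equal(nrow(tab), 38)  # 37 genes + CR
  back <- read_feature_table(tf)
  expect_equal(back$label, g$features$label)
  expect_equal(back$start, g$features$start)
  expect_equal(back$end, g$features$end)

  g0 <- mitogenome("ACGT", tibble::tibble(label = character(),
                                          strand = character(),
                                          start = integer(),
                                          end = integer()))
  tf0 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(g0, tf0)
  expect_equal(length(readLines(tf0)), 1)  # header only
})

test_that("duplicate canonical labels are flagged, not dropped", {
  expect_warning(
    g <- mitogenome("ACGTACGTACGT",
                    tibble::tibble(label = c("trnI", "trnI"),
                                   strand = c("J", "J"),
                                   start = c(0, 6), end = c(4, 10))),
    "duplicate")
  expect_equal(nrow(g$features), 2)
})
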