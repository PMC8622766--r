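test_that("the ancestral order constant has the expected strand partition", {
  o <- ancestral_insect_order()
  expect_length(o, 38)
  bare <- sub("^-", "", unclass(o))
  minus <- startsWith(unclass(o), "-")
  cat_of <- mito_gene_table()$category[match(bare, mito_gene_table()$label)]
  expect_equal(sum(cat_of == "tRNA" & !minus), 14)
  expect_equal(sum(cat_of == "PCG" & !minus), 9)
  expect_equal(sum(cat_of == "tRNA" & minus), 8)
  expect_equal(sum(cat_of == "PCG" & minus), 4)
  expect_equal(sum(cat_of == "rRNA" & minus), 2)
})

test_that("extract_gene_order reproduces templates and rejects duplicates", {
  anc <- generate_mitogenome(synthetic_spec("cetoniinae", seed = 4))$genome
  o <- extract_gene_order(anc)
  expect_true(mitocomp:::rotation_equal(o, ancestral_insect_order()))

  dyn <- generate_mitogenome(synthetic_spec("dynastinae", seed = 4))$genome
  od <- unclass(extract_gene_order(dyn))
  i <- which(od == "CR")
  run <- od[((i - 1 + 0:4) %% length(od)) + 1]
  expect_equal(run, c("CR", "-trnQ", "NCR", "trnI", "trnM"))

  g <- suppressWarnings(mitogenome("ACGTACGTACGT",
    tibble::tibble(label = c("trnI", "trnI"), strand = "J",
                   start = c(0, 6), end = c(4, 10))))
  expect_error(extract_gene_order(g), "duplicate")
})

test_that("rotation normalization is idempotent and rotation-invariant", {
  o <- ancestral_insect_order()
  n1 <- normalize_rotation(o, "CR")
  expect_equal(unclass(normalize_rotation(n1, "CR")), unclass(n1))
  expect_equal(unclass(n1)[1:2], c("CR", "trnI"))
  x <- unclass(o)
  for (k in c(5, 17, 30)) {
    rot <- gene_order(c(x[k:length(x)], x[seq_len(k - 1)]))
    expect_equal(unclass(normalize_rotation(rot, "CR")), unclass(n1))
  }
  expect_error(normalize_rotation(o, "nope"), "anchor")
})

test_that("breakpoint distance counts lost adjacencies, rotation-invariantly", {
  expect_equal(breakpoint_distance(ancestral_insect_order(),
                                   ancestral_insect_order()), 0)
  # trnI/trnQ swap: adjacencies {CR,I} and {Q,M} lost; {I,Q} survives unsigned
  expect_equal(breakpoint_distance(ancestral_insect_order(),
                                   dynastine_gene_order()), 2)
  x <- unclass(ancestral_insect_order())
  rot <- gene_order(c(x[10:length(x)], x[1:9]))
  expect_equal(breakpoint_distance(ancestral_insect_order(), rot), 0)
  expect_error(breakpoint_distance(gene_order(c("a", "b")),
                                   gene_order(c("a", "c"))),
               "label set")
  # symmetry on random signed permutations
  set.seed(7)
  for (i in 1:20) {
    a <- gene_order(random_signed_order(8))
    b <- gene_order(sample(unclass(a)))
    expect_equal(breakpoint_distance(a, b), breakpoint_distance(b, a))
  }
})

test_that("moved_genes finds all minimal removal sets", {
  o <- ancestral_insect_order()
  expect_equal(moved_genes(o, o), list(character()))
  mg <- moved_genes(o, dynastine_gene_order())
  expect_setequal(purrr::map_chr(mg, paste, collapse = "+"),
                  c("trnI", "trnQ"))
  # fully reversed 4-gene order needs two removals
  a <- gene_order(c("w", "x", "y", "z"))
  b <- gene_order(c("z", "y", "x", "w"))
  mg2 <- moved_genes(a, b)
  expect_true(all(lengths(mg2) == 2))
  # brute-force check: no single removal reconciles them
  for (s in c("w", "x", "y", "z")) {
    expect_false(mitocomp:::rotation_equal(
      unclass(a)[unclass(a) != s], unclass(b)[unclass(b) != s]))
  }
})

test_that("rearrangement classification covers none/translocation/inversion", {
  o <- ancestral_insect_order()
  expect_equal(classify_rearrangement(o, o)$event_class, "none")

  rep <- classify_rearrangement(o, dynastine_gene_order(),
                                ncr_lengths = c(NCR = 56))
  expect_equal(rep$event_class, "translocation")
  expect_true(rep$tdrl_compatible)
  expect_true(all(rep$moved_union %in% c("trnI", "trnQ")))
  expect_equal(rep$ncrs$class, "NCR1")
  expect_gt(length(rep$scenarios), 0)

  flipped <- unclass(o)
  flipped[flipped == "trnI"] <- "-trnI"
  rep2 <- classify_rearrangement(o, gene_order(flipped))
  expect_equal(rep2$event_class, "inversion")

  gl <- glance(rep)
  expect_equal(gl$event_class, "translocation")
  expect_true(gl$tdrl_compatible)
  td <- tidy(rep)
  expect_equal(td$ncr, "NCR")
})

test_that("NCR length classes follow the 100/400 bp dichotomy", {
  expect_equal(classify_ncr(56), "NCR1")
  expect_equal(classify_ncr(412), "NCR2")
  expect_equal(classify_ncr(250), "intermediate")
  expect_equal(classify_ncr(c(99, 100, 400, 401)),
               c("NCR1", "intermediate", "intermediate", "NCR2"))
  expect_error(classify_ncr(0), "positive")
})

test_that("gene-order strings round-trip", {
  o <- dynastine_gene_order()
  expect_equal(unclass(parse_gene_order(gene_order_string(o))), unclass(o))
})
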