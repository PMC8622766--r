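test_that("generation is deterministic in the seed and geometry-stable", {
  spec <- synthetic_spec("dynastinae", seed = 55)
  a <- generate_mitogenome(spec)
  b <- generate_mitogenome(spec)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(as.data.frame(a$genome$features),
                   as.data.frame(b$genome$features))
  expect_identical(a$truth, b$truth)
  # a different seed changes sequence content but not annotation geometry
  c <- generate_mitogenome(synthetic_spec("dynastinae", seed = 56))
  expect_false(identical(a$genome$sequence, c$genome$sequence))
  expect_identical(as.data.frame(a$genome$features[, c("label", "strand",
                                                       "start", "end")]),
                   as.data.frame(c$genome$features[, c("label", "strand",
                                                       "start", "end")]))
})

test_that("background sampling hits degenerate and measured targets", {
  expect_equal(compose_region_sequence(10, at = 1, skew_at = 1), strrep("A", 10))
  expect_equal(compose_region_sequence(0, at = 0.5), "")
  expect_error(compose_region_sequence(10, at = 1.2), "infeasible")
  s <- compose_region_sequence(20000, at = 0.5, seed = 3)
  b <- base_counts(s)
  for (x in unlist(b[1, 1:4])) expect_equal(x / 20000, 0.25, tolerance = 0.02)
})

test_that("build_pcg honors start, stop, length, and stop-free bodies", {
  s <- build_pcg(2, "AAC", "T", seed = 1)
  expect_equal(nchar(s), 10)
  expect_equal(substr(s, 1, 3), "AAC")
  expect_equal(substr(s, 10, 10), "T")
  s2 <- build_pcg(200, "GTC", "TAA", seed = 2)
  expect_equal(substr(s2, 1, 3), "GTC")
  cods <- substring(s2, seq(4, 600, 3), seq(6, 602, 3))
  expect_false(any(cods %in% c("TAA", "TAG")))
  expect_error(build_pcg(2, "CCC", "TAA"), "start")
  expect_error(build_pcg(2, "ATG", "TGA"), "stop")
  w <- stats::setNames(rep(0, 62),
                       setdiff(codon_families()$codon, c("TAA", "TAG")))
  expect_error(build_pcg(2, "ATG", "TAA", codon_weights = w), "zero")
})

test_that("whole-genome AT fraction lands within the sampling bound", {
  res <- generate_mitogenome(synthetic_spec("cetoniinae", seed = 91,
                                            at = 0.75))
  g <- res$genome
  expect_gt(length(g), 16000)
  measured <- region_composition(g, "genome")$at_fraction
  expect_lt(abs(measured -
                  res$truth$composition_targets$expected_genome_at), 0.01)
  # a pure-background region sits at the background target itself
  rr <- region_composition(g, "rrnL")
  expect_lt(abs(rr$at_fraction - 0.75), 0.04)  # 1.28 kb sampling bound
})

test_that("the rearranged template plants the NCR with its class", {
  res <- generate_mitogenome(synthetic_spec("dynastinae", seed = 14,
                                            ncr_length = 412))
  g <- res$genome
  ncr <- g$features[g$features$category == "NCR", ]
  expect_equal(ncr$end - ncr$start, 412L)
  expect_equal(classify_ncr(ncr$end - ncr$start), "NCR2")
  od <- unclass(extract_gene_order(g))
  i <- which(od == "-trnQ")
  expect_equal(od[((i - 1 + 0:3) %% length(od)) + 1],
               c("-trnQ", "NCR", "trnI", "trnM"))
})

test_that("inconsistent specs are rejected", {
  expect_error(synthetic_spec("cetoniinae", overlaps = c("trnW|trnC" = 70)),
               "overlap")
  expect_error(synthetic_spec("cetoniinae", skew_at = 1), "skew")
  expect_error(synthetic_spec("cetoniinae",
                              pcg_lengths = c(ND2 = 1021)), "stop codon")
})

test_that("planted homopolymers survive assembly with exact geometry", {
  res <- generate_mitogenome(synthetic_spec("dynastinae", seed = 44))
  g <- res$genome
  truth <- res$truth$homopolymers
  expect_equal(truth$pair, "trnK|trnD")
  runs <- homopolymer_runs(g$sequence, min_len = 11)
  cs <- runs[runs$base == "C", ]
  expect_equal(nrow(cs), 1)
  expect_equal(cs$length, 11L)
  # located inside the trnK-trnD spacer
  k_end <- g$features$end[g$features$label == "trnK"]
  d_start <- g$features$start[g$features$label == "trnD"]
  expect_true(cs$start > k_end & cs$start + 10 <= d_start)
})
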