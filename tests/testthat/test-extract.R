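# Read demultiplexing, gene location, and the two library filters.

test_that("demultiplexing partitions reads by exact barcode match", {
  tpl <- demoTemplate()
  gene <- geneSeq(tpl)
  reads <- c(paste0("ACGTAC", "AAAA", gene),     # s1
             paste0("GGTTCC", "AAAAA", gene),    # s2
             paste0("ACGTAA", "AAAA", gene),     # 1 mismatch -> unmatched
             paste0("TTTTTT", "AAAA", gene))     # unmatched
  dm <- demultiplexReads(reads, tpl)
  expect_equal(lengths(dm$samples), c(s1 = 1L, s2 = 1L))
  expect_equal(dm$unmatched, 2L)
  expect_equal(sum(lengths(dm$samples)) + dm$unmatched, length(reads))
  # empty input
  dm0 <- demultiplexReads(character(), tpl)
  expect_equal(dm0$unmatched, 0L)
  expect_true(all(lengths(dm0$samples) == 0L))
})

test_that("parseReads applies filters in order and accepts synonymous changes", {
  tpl <- demoTemplate()
  gene <- geneSeq(tpl)
  rp <- codonPositions(tpl)
  setCodon <- function(g, codonIdx, codon) {
    substr(g, (codonIdx - 1) * 3 + 1, codonIdx * 3) <- codon
    g
  }
  wtRead <- paste0("CCCCC", gene)  # 5-nt spacer
  # identity read
  p <- parseReads(wtRead, tpl)
  expect_equal(p$accepted$aa_triplet, "DKE")
  expect_true(is.na(p$reason))
  # filter (a): non-NNK codon (third base A) at a randomised position
  g <- setCodon(gene, rp[1], "ATA")
  expect_equal(parseReads(paste0("CCCC", g), tpl)$reason, "filter_a_non_nnk")
  # filter (b): non-synonymous change in an off-target codon (codon 10
  # sits beyond the 12-nt anchor; it is AAG = Lys in the template)
  g <- setCodon(gene, 10L, "GGG")  # Lys -> Gly
  expect_equal(parseReads(paste0("CCCC", g), tpl)$reason,
               "filter_b_nonsynonymous_offtarget")
  # synonymous off-target change passes: AAG -> AAA (both Lys)
  g <- setCodon(gene, 10L, "AAA")
  p <- parseReads(paste0("CCCCCC", g), tpl)
  expect_equal(p$accepted$aa_triplet, "DKE")
  # order: a read failing both reports the first ((a) before (b))
  g <- setCodon(setCodon(gene, rp[1], "ATA"), 10L, "GGG")
  expect_equal(parseReads(paste0("CCCC", g), tpl)$reason, "filter_a_non_nnk")
  # anchor not found / length error
  expect_equal(parseReads(paste0("CCCC", substr(gene, 2, nchar(gene)), "AA"),
                          tpl)$reason, "anchor_not_found")
  expect_equal(parseReads("CCCCACGT", tpl)$reason, "length_error")
  # ambiguity base in a randomised codon rejects via filter (a)
  g <- setCodon(gene, rp[2], "ANG")
  expect_equal(parseReads(paste0("CCCC", g), tpl)$reason, "filter_a_non_nnk")
})

test_that("stop-codon variants are parsed and counted", {
  tpl <- demoTemplate()
  counts <- setNames(4L, firstSpelling("D*E"))
  reads <- synthesizeReads(counts, tpl, "ACGTAC", seed = 1)
  sc <- extractVariants(reads, tpl, prePostInfo(ids = c("s1", "s2")))
  rd <- SummarizedExperiment::rowData(sc)
  expect_equal(unname(readCountMatrix(sc)[rd$aa_triplet == "D*E", "s1"]), 4L)
})

test_that("counting keeps codon spellings distinct until aggregation", {
  tpl <- demoTemplate()
  # three NNK spellings of L at position 2, same codons elsewhere
  spellings <- paste0("GAT", c("CTG", "CTT", "TTG"), "GAG")
  counts <- setNames(c(5L, 3L, 2L), spellings)
  reads <- synthesizeReads(counts, tpl, "ACGTAC", seed = 2)
  sc <- extractVariants(reads, tpl, prePostInfo(ids = c("s1", "s2")))
  m <- readCountMatrix(sc)
  expect_equal(unname(m[spellings, "s1"]), c(5L, 3L, 2L))
  pr <- aggregateToProtein(sc)
  expect_equal(unname(readCountMatrix(pr)["DLE", "s1"]), 10L)
  expect_equal(sum(readCountMatrix(pr)), sum(m))  # totals conserved
})

test_that("synthesized reads round-trip to the originating count table", {
  tpl <- demoTemplate()
  set.seed(42)
  lib <- enumerateLibrary()
  picks <- sample(lib$aa_triplet, 40)
  counts1 <- setNames(sample(1:20, 40, replace = TRUE), picks)
  reads <- c(synthesizeReads(counts1, tpl, "ACGTAC", seed = 7),
             synthesizeReads(setNames(9L, "ILK"), tpl, "GGTTCC", seed = 8))
  fq <- tempfile(fileext = ".fastq")
  writeFastq(reads, fq)
  sc <- extractVariants(fq, tpl, prePostInfo(ids = c("s1", "s2")),
                        level = "protein")
  m <- readCountMatrix(sc)
  expect_equal(m[names(counts1), "s1"], counts1 + 0L,
               ignore_attr = "names")
  expect_equal(unname(m["ILK", "s2"]), 9L)
  # partition property: accepted + per-reason rejections = input
  rej <- S4Vectors::metadata(sc)$rejections
  tot <- vapply(rej, function(r) sum(unlist(r)), 0)
  expect_equal(sum(tot) + S4Vectors::metadata(sc)$unmatched, length(reads))
})

test_that("count tables survive a TSV round trip", {
  sim <- smallSim()
  sub <- sim$counts[1:200, ]
  sub <- SelectionCounts(readCountMatrix(sub),
                         as.data.frame(SummarizedExperiment::colData(sub)),
                         level = "protein")
  f <- tempfile(fileext = ".tsv")
  writeCountsTsv(sub, f)
  back <- readCountsTsv(f)
  keep <- rowSums(readCountMatrix(sub)) > 0
  expect_equal(readCountMatrix(back),
               readCountMatrix(sub)[keep, , drop = FALSE])
})

test_that("template YAML round trip preserves the specification", {
  tpl <- demoTemplate()
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(gene_nt = geneSeq(tpl),
                        randomized_codon_positions = codonPositions(tpl),
                        barcode_map = as.list(barcodeMap(tpl)),
                        spacer_range = c(4L, 6L)), f)
  tpl2 <- readTemplateYaml(f)
  expect_equal(geneSeq(tpl2), geneSeq(tpl))
  expect_equal(wtTriplet(tpl2), "DKE")
  expect_equal(barcodeMap(tpl2), barcodeMap(tpl))
})
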