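test_that("FASTA parsing preserves records, order and bytes", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a first", "ACGT", ">b", "GGGTTTAA"), f)
  seqs <- parse_fasta(f)
  expect_length(seqs, 2)
  expect_equal(seqs[[1]]$id, "a")
  expect_equal(seqs[[1]]$seq, "ACGT")
  expect_equal(seqs[[2]]$seq, "GGGTTTAA")

  # round trip preserves sequence bytes exactly
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f2)
  again <- parse_fasta(f2)
  expect_identical(lapply(again, `[[`, "seq"), lapply(seqs, `[[`, "seq"))
})

test_that("FASTA errors name the offence", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), f)
  expect_error(parse_fasta(f), "duplicate.*a", class = "haplozein_format_error")
  writeLines(c("ACGT"), f)
  expect_error(parse_fasta(f), "line 1", class = "haplozein_format_error")
  writeLines(character(), f)
  expect_error(parse_fasta(f), "empty", class = "haplozein_format_error")
})

test_that("GFF3 import converts to 0-based half-open and resolves parents", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr", paste(rep("ACGTT", 20), collapse = "")), fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tzein_gene\t1\t10\t.\t+\t.\tID=g1",
               "chr\tsrc\tretroelement\t21\t80\t.\t+\t.\tID=re1",
               "chr\tsrc\tltr\t21\t30\t.\t+\t.\tID=l1;Parent=re1"), gff)
  haps <- parse_gff3(gff, parse_fasta(fa), inbred = "B73", locus = "z1A1")
  f <- haps[[1]]$features
  expect_equal(f$start[f$feature_id == "g1"], 0)
  expect_equal(f$end[f$feature_id == "g1"], 10)
  expect_equal(f$parent[f$feature_id == "l1"], "re1")

  # child span outside its parent is a validation error
  writeLines(c("##gff-version 3",
               "chr\tsrc\tretroelement\t21\t80\t.\t+\t.\tID=re1",
               "chr\tsrc\tltr\t21\t90\t.\t+\t.\tID=l1;Parent=re1"), gff)
  expect_error(parse_gff3(gff, parse_fasta(fa)),
               class = "haplozein_validation_error")

  # unknown seqid
  writeLines(c("##gff-version 3",
               "nope\tsrc\tzein_gene\t1\t10\t.\t+\t.\tID=g1"), gff)
  expect_error(parse_gff3(gff, parse_fasta(fa)),
               class = "haplozein_format_error")
})

test_that("GFF3 write/parse round trip reproduces the feature table", {
  sim <- simulate_locus_pair(simulation_config(
    seed = 5, re_insertions = list(re_insertion(1, 200, 400),
                                   re_insertion(0.2, 200, 400, nested_in = 1))))
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_fasta(list(sim$hapA$contig), fa)
  write_gff3(sim$hapA, gff)
  back <- parse_gff3(gff, parse_fasta(fa), inbred = sim$hapA$inbred)[[1]]
  cols <- c("feature_id", "kind", "start", "end", "strand", "parent")
  expect_identical(back$features[, cols], sim$hapA$features[, cols])
})

test_that("feature extraction honours strand and span", {
  hap <- annotated_haplotype(
    "B73", "custom", genomic_sequence("c", "AACGT"),
    feature_table(feature_id = c("f", "r"), kind = "other",
                  start = c(1, 1), end = c(4, 4), strand = c("+", "-")))
  expect_equal(extract_feature_sequence(hap, "f")$seq, "ACG")
  expect_equal(extract_feature_sequence(hap, "r")$seq, "CGT")
  expect_equal(extract_feature_sequence(hap, "r")$seq, oracle_revcomp("ACG"))
  expect_error(extract_feature_sequence(hap, "zz"),
               class = "haplozein_lookup_error")
})

test_that("extracted length always equals end - start", {
  set.seed(42)
  hap <- annotated_haplotype(
    "x", "custom", genomic_sequence("c", oracle_random_dna(500)),
    feature_table(feature_id = sprintf("f%d", 1:20), kind = "other",
                  start = s <- sample(0:400, 20),
                  end = s + sample(1:100, 20),
                  strand = sample(c("+", "-"), 20, replace = TRUE)))
  for (id in hap$features$feature_id) {
    f <- hap$features[hap$features$feature_id == id, ]
    expect_equal(nchar(extract_feature_sequence(hap, id)$seq), f$end - f$start)
  }
})

test_that("haplotype validation enforces the parent contract", {
  ctg <- genomic_sequence("c", strrep("ACGT", 30))
  expect_error(annotated_haplotype("x", "custom", ctg,
    feature_table("l1", "ltr", 0, 10)),
    class = "haplozein_validation_error")
  expect_error(annotated_haplotype("x", "custom", ctg,
    feature_table(c("g1", "l1"), c("zein_gene", "ltr"), c(0, 2), c(20, 10),
                  parent = c(NA, "g1"))),
    class = "haplozein_validation_error")
  expect_error(annotated_haplotype("x", "nope", ctg, feature_table()))
})
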