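make_orf <- function(n_codons = 250) {
  set.seed(123)
  body <- sample(setdiff(names(Biostrings::GENETIC_CODE)
                         [Biostrings::GENETIC_CODE != "*"], "ATG"),
                 n_codons - 2, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

test_that("copy status classification covers every category with precedence", {
  orf <- make_orf()          # 750 bp, intact
  expect_equal(classify_copy_status(orf, 750)$status, "intact")

  premature <- paste0(substr(orf, 1, 297), "TAG", substr(orf, 301, 750))
  st <- classify_copy_status(premature, 750)
  expect_equal(st$status, "premature_stop")
  expect_match(st$detail, "codon 100")

  startless <- substr(orf, 2, 750)   # lost the A of ATG
  expect_equal(classify_copy_status(startless, 750)$status, "start_loss")

  expect_equal(classify_copy_status(substr(orf, 1, 332), 750)$status,
               "truncated")
  nostop <- paste0(substr(orf, 1, 747), "GGG")
  expect_equal(classify_copy_status(nostop, 750)$status, "truncated")

  # an overlapping insertion dominates any point defect
  ins <- feature_table("solo1", "retroelement", 10, 500,
                       parent = NA)
  expect_equal(classify_copy_status(premature, 750, ins)$status,
               "re_disrupted")
  expect_error(classify_copy_status("", 750))
})

test_that("promoter motif scanning reports offsets from the ATG", {
  set.seed(5)
  L <- 500
  prom <- strsplit(oracle_random_dna(L), "")[[1]]
  # P-box with first base 300 bp upstream (so last base 293 bp upstream)
  prom[(L - 300 + 1):(L - 300 + 8)] <- strsplit("GTGTAAAG", "")[[1]]
  # O2 site on the lower strand, upstream-most base 171 bp upstream
  o2 <- default_motif_set()$pattern[2]
  prom[(L - 171 + 1):(L - 171 + nchar(o2))] <-
    strsplit(oracle_revcomp(o2), "")[[1]]
  hits <- scan_promoter_motifs(paste(prom, collapse = ""))
  pbox <- hits[hits$motif_name == "P-box" & hits$strand == "+", ]
  expect_equal(pbox$offset_upstream[1], 300)
  o2hit <- hits[hits$motif_name == "O2-box", ]
  expect_equal(o2hit$strand[1], "-")
  expect_equal(o2hit$offset_upstream[1], 171)

  none <- scan_promoter_motifs(strrep("AT", 250),
                               data.frame(name = "x", pattern = "GGGGGG"))
  expect_equal(nrow(none), 0)
  expect_warning(scan_promoter_motifs("ACGT"), "shorter")
})

test_that("IUPAC degeneracies in motifs are honoured", {
  hits <- scan_promoter_motifs(paste0(strrep("A", 92), "TGACGTGA"),
                               data.frame(name = "bzip", pattern = "TGACGTRA"))
  expect_equal(nrow(hits[hits$strand == "+", ]), 1)
})

test_that("composition partitions every base exactly once", {
  ctg <- genomic_sequence("c", strrep("ACGTT", 20000))  # 100 kb
  ft <- feature_table(
    feature_id = c("re1", "re2", "te1", "g1"),
    kind = c("retroelement", "retroelement", "dna_transposon", "zein_gene"),
    start = c(0, 10000, 50000, 55000),
    end = c(50000, 20000, 55000, 58000),
    parent = c(NA, "re1", NA, NA))
  cs <- composition_summary(annotated_haplotype("x", "custom", ctg, ft))
  # nested RE counted once
  expect_equal(cs$re_pct, 50)
  expect_equal(cs$dna_te_pct, 5)
  expect_equal(cs$genic_pct, 3)
  expect_equal(cs$intergenic_pct, 42)
  expect_equal(cs$re_pct + cs$dna_te_pct + cs$genic_pct + cs$intergenic_pct,
               100, tolerance = 0.5)

  empty <- composition_summary(
    annotated_haplotype("x", "custom", ctg, feature_table()))
  expect_equal(empty$intergenic_pct, 100)
})

test_that("partition sums to 100 on arbitrary annotations", {
  set.seed(31)
  ctg <- genomic_sequence("c", oracle_random_dna(20000))
  for (i in 1:10) {
    n <- sample(3:12, 1)
    s <- sample(0:19000, n)
    ft <- feature_table(
      feature_id = sprintf("f%d", seq_len(n)),
      kind = sample(c("retroelement", "dna_transposon", "zein_gene",
                      "helitron", "other"), n, replace = TRUE),
      start = s, end = pmin(s + sample(100:5000, n), 20000))
    cs <- composition_summary(annotated_haplotype("x", "custom", ctg, ft))
    expect_equal(cs$re_pct + cs$dna_te_pct + cs$genic_pct + cs$intergenic_pct,
                 100, tolerance = 0.5)
  }
})

test_that("conserved coverage finds identical, diverged and inserted regions", {
  set.seed(77)
  a <- oracle_random_dna(30000)
  hapA <- genomic_sequence("a", a)
  expect_equal(as.numeric(conserved_coverage(hapA, genomic_sequence("b", a))),
               100)
  unrel <- genomic_sequence("u", oracle_random_dna(30000))
  expect_lt(as.numeric(conserved_coverage(hapA, unrel)), 1)

  # haplotype-specific 3-kb insertion: ~90% of the longer haplotype
  longer <- genomic_sequence("l", paste0(substr(a, 1, 15000),
                                         oracle_random_dna(3000),
                                         substr(a, 15001, 30000)))
  cov <- conserved_coverage(longer, hapA)
  expect_equal(as.numeric(cov), 100 * 30000 / 33000, tolerance = 0.02)

  # symmetry within one percentage point on equal-length diverged inputs
  b <- evolve_sequence(a, 0.01, seed = 3)
  hapB <- genomic_sequence("b2", b)
  expect_lt(abs(as.numeric(conserved_coverage(hapA, hapB)) -
                as.numeric(conserved_coverage(hapB, hapA))), 1)
})

test_that("chronologies order events and flag nesting violations", {
  ev <- data.frame(event_id = c("prem2", "zeon2", "young"),
                   age_mya = c(2.04, 1.19, 0))
  rep <- insertion_chronology(ev, data.frame(nested = "zeon2", host = "prem2"))
  expect_identical(rep$events$event_id, c("prem2", "zeon2", "young"))
  expect_equal(nrow(rep$violations), 0)

  bad <- insertion_chronology(
    data.frame(event_id = c("h", "n"), age_mya = c(1, 3)),
    data.frame(nested = "n", host = "h"))
  expect_equal(bad$violations$nested, "n")
  expect_error(insertion_chronology(ev, data.frame(nested = "zz", host = "prem2")))
})

test_that("helitron detection needs termini plus subterminal hairpin", {
  set.seed(6)
  stem <- "GATCCGGA"
  hair <- paste0(stem, "TTTT", oracle_revcomp(stem))
  cand <- paste0("TC", oracle_random_dna(150), hair,
                 oracle_random_dna(20), "CTAG")
  expect_true(detect_helitron(cand)$is_candidate)

  noterm <- paste0("TC", oracle_random_dna(150), hair, "CTTT")
  expect_false(detect_helitron(noterm)$is_candidate)

  nohair <- paste0("TC", strrep("ACAAT", 40), "CTAG")
  res <- detect_helitron(nohair)
  expect_false(res$is_candidate)
  expect_match(res$detail, "no hairpin")
})
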