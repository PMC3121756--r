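test_that("sequence evolution is exact at zero divergence and deterministic", {
  s <- "ACGTACGTACGTNNACGT"
  expect_identical(evolve_sequence(s, 0, seed = 3), s)
  e1 <- evolve_sequence(strrep("ACGT", 250), 0.1, seed = 9)
  e2 <- evolve_sequence(strrep("ACGT", 250), 0.1, seed = 9)
  expect_identical(e1, e2)
  expect_error(evolve_sequence(s, -0.1), class = "haplozein_parameter_error")
})

test_that("the K2P estimator recovers the generator's divergence", {
  set.seed(7)
  s <- oracle_random_dna(100000)
  e <- evolve_sequence(s, 0.1702, kappa = 2, seed = 11)
  est <- k2p(pairwise_site_counts(s, e, prealigned = TRUE))
  expect_lt(abs(est$K - 0.1702), 0.01)
})

test_that("simulated locus pairs honour the configured structure", {
  cfg <- simulation_config(
    seed = 21,
    re_insertions = list(re_insertion(2, 300, 600, family = "Prem2"),
                         re_insertion(0.5, 300, 600, nested_in = 1),
                         re_insertion(0, 300, 600, haplotype = "B")))
  sim <- simulate_locus_pair(cfg)
  fA <- sim$hapA$features
  fB <- sim$hapB$features

  expect_equal(sum(fA$kind == "zein_gene"), 5)
  expect_equal(sum(fB$kind == "zein_gene"), 5)

  # haplotype-specific element present in exactly one haplotype
  expect_false("re3" %in% fA$feature_id)
  expect_true("re3" %in% fB$feature_id)

  # age-0 element has byte-identical LTRs
  ltrs <- fB$feature_id[fB$kind == "ltr" & fB$parent == "re3"]
  expect_identical(extract_feature_sequence(sim$hapB, ltrs[1])$seq,
                   extract_feature_sequence(sim$hapB, ltrs[2])$seq)

  # every element is flanked by an identical TSD pair
  for (rid in fA$feature_id[fA$kind == "retroelement"]) {
    tsds <- fA$feature_id[fA$kind == "tsd" & fA$parent == rid]
    expect_identical(extract_feature_sequence(sim$hapA, tsds[1])$seq,
                     extract_feature_sequence(sim$hapA, tsds[2])$seq)
  }

  # nested element wholly inside its host, and recorded as its child
  re2 <- fA[fA$feature_id == "re2", ]
  re1 <- fA[fA$feature_id == "re1", ]
  expect_equal(re2$parent, "re1")
  expect_gte(re2$start, re1$start)
  expect_lte(re2$end, re1$end)

  # determinism: same seed, byte-identical output
  sim2 <- simulate_locus_pair(cfg)
  expect_identical(sim2$hapA$contig$seq, sim$hapA$contig$seq)
  expect_identical(sim2$hapB$features, sim$hapB$features)
  expect_identical(sim2$truth, sim$truth)
})

test_that("truth ledger and haplotypes agree element for element", {
  sim <- simulate_locus_pair(simulation_config(seed = 8))
  fA <- sim$hapA$features; fB <- sim$hapB$features
  tr <- sim$truth
  in_haps <- union(fA$feature_id[fA$kind == "retroelement"],
                   fB$feature_id[fB$kind == "retroelement"])
  expect_setequal(in_haps, tr$true_ages$event_id)
  expect_setequal(fA$feature_id[fA$kind == "zein_gene"],
                  tr$copy_provenance$copy_id)
  # nesting chronology in the ledger
  nested <- tr$true_ages[!is.na(tr$true_ages$nested_in), ]
  host_age <- setNames(tr$true_ages$age_mya, tr$true_ages$event_id)
  expect_true(all(nested$age_mya <= host_age[nested$nested_in]))
  # insertion order is oldest first
  expect_identical(order(-tr$true_ages$age_mya),
                   seq_len(nrow(tr$true_ages)))
})

test_that("a nested insertion older than its host is rejected", {
  expect_error(simulation_config(
    seed = 1, re_insertions = list(re_insertion(1), re_insertion(3, nested_in = 1))),
    class = "haplozein_config_error")
})

test_that("clone libraries follow the configured mixture", {
  db <- c(a = strrep("ACGGTTCA", 40), b = strrep("TTGACCGT", 40))
  pure <- simulate_clone_library(db, c(1, 0), 25, error_rate = 0, seed = 2)
  expect_length(pure, 25)
  expect_true(all(vapply(pure, `[[`, "", "seq") == db[["a"]]))
  expect_identical(unique(attr(pure, "truth")$true_copy), "a")

  expect_error(simulate_clone_library(db, c(0.5, 0.4), 10),
               class = "haplozein_parameter_error")

  # multinomial counts within 3 sigma of expectation
  lib <- simulate_clone_library(db, c(0.9, 0.1), 10000, error_rate = 0, seed = 4)
  n_a <- sum(attr(lib, "truth")$true_copy == "a")
  expect_lt(abs(n_a - 9000), 3 * sqrt(10000 * 0.9 * 0.1))
})

test_that("bisulfite conversion follows per-cytosine probabilities", {
  prom <- "ACGTCCATGCA"
  ncs <- sum(strsplit(prom, "")[[1]] == "C")
  all0 <- simulate_bisulfite_reads(prom, rep(0, ncs), 0, n_reads = 5, seed = 1)
  expect_true(all(!grepl("C", vapply(all0, `[[`, "", "seq"))))
  all1 <- simulate_bisulfite_reads(prom, rep(1, ncs), 0, n_reads = 5, seed = 1)
  expect_true(all(vapply(all1, `[[`, "", "seq") == prom))
  expect_error(simulate_bisulfite_reads(prom, rep(0.5, ncs + 1), 0, 5),
               class = "haplozein_parameter_error")

  # per-site retention within the exact binomial interval at p = 0.3
  set.seed(10)
  prom2 <- oracle_random_dna(400)
  ncs2 <- sum(strsplit(prom2, "")[[1]] == "C")
  reads <- simulate_bisulfite_reads(prom2, rep(0.3, ncs2), 0, n_reads = 96,
                                    seed = 12)
  cpos <- which(strsplit(prom2, "")[[1]] == "C")
  mat <- do.call(rbind, lapply(reads, function(r) strsplit(r$seq, "")[[1]][cpos]))
  retained <- colSums(mat == "C")
  ci <- oracle_binom_ci(96, 0.3)
  expect_gte(mean(retained >= ci[1] & retained <= ci[2]), 0.95)
})
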