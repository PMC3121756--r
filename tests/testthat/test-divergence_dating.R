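test_that("site counting distinguishes transitions, transversions and gaps", {
  sc <- pairwise_site_counts("ACGT", "ACGT", prealigned = TRUE)
  expect_equal(unclass(sc)[c("n", "P", "Q")], list(n = 4, P = 0, Q = 0))
  sc <- pairwise_site_counts("ACGT", "ACGA", prealigned = TRUE)
  expect_equal(sc$Q, 0.25)
  expect_equal(sc$P, 0)
  sc <- pairwise_site_counts("ACGT", "GCGT", prealigned = TRUE)  # A<->G
  expect_equal(sc$P, 0.25)
  # gap and N columns are removed before counting
  sc <- pairwise_site_counts("AC-GT", "ACCGT", prealigned = TRUE)
  expect_equal(unclass(sc)[c("n", "P", "Q")], list(n = 4, P = 0, Q = 0))
  sc <- pairwise_site_counts("ANGT", "ACGT", prealigned = TRUE)
  expect_equal(sc$n, 3)
  expect_error(pairwise_site_counts("NNN", "NNN", prealigned = TRUE),
               class = "haplozein_degenerate_error")
})

test_that("unaligned pairs are globally aligned before counting", {
  a <- "ACGTACGTACGTACGTACGT"
  b <- "ACGTACGTCGTACGTACGT"  # one deletion
  sc <- pairwise_site_counts(a, b)
  expect_equal(sc$n, 19)
  expect_equal(sc$P + sc$Q, 0)
})

test_that("K2P matches its closed form and flags saturation", {
  expect_equal(k2p(pairwise_site_counts("ACGT", "ACGT", prealigned = TRUE))$K, 0)
  sc <- structure(list(n = 1000, P = 0.1, Q = 0.05), class = "site_counts")
  est <- k2p(sc)
  expect_equal(est$K, -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)))
  expect_lt(abs(est$K - 0.1702), 1e-4)
  # delta-method variance, recomputed by hand
  c1 <- 1 / 0.75; c2 <- 1 / 0.9; c3 <- (c1 + c2) / 2
  expect_equal(est$variance,
               (c1^2 * 0.1 + c3^2 * 0.05 - (c1 * 0.1 + c3 * 0.05)^2) / 1000)
  expect_error(k2p(structure(list(n = 10, P = 0.5, Q = 0), class = "site_counts")),
               class = "haplozein_saturation_error")
})

test_that("K2P is symmetric, monotone in P, and linear at small distance", {
  set.seed(1)
  a <- oracle_random_dna(2000)
  b <- evolve_sequence(a, 0.05, seed = 2)
  expect_equal(k2p(pairwise_site_counts(a, b, prealigned = TRUE))$K,
               k2p(pairwise_site_counts(b, a, prealigned = TRUE))$K)
  # small-distance limit: K ~ P + Q within 1% when P + Q <= 0.01
  for (pq in list(c(0.004, 0.004), c(0.005, 0.002), c(0, 0.008))) {
    sc <- structure(list(n = 1e5, P = pq[1], Q = pq[2]), class = "site_counts")
    if (sum(pq) > 0)
      expect_lt(abs(k2p(sc)$K - sum(pq)) / sum(pq), 0.01)
  }
  # strict monotonicity in P at fixed Q
  ks <- vapply(seq(0, 0.3, by = 0.02), function(P)
    k2p(structure(list(n = 100, P = P, Q = 0.1), class = "site_counts"))$K, 0)
  expect_true(all(diff(ks) > 0))
})

test_that("insertion ages follow the LTR clock", {
  clk <- clock_params()
  expect_equal(clk$ltr_rate, 1.3e-8)
  # identical LTRs date to zero
  ev <- date_ltr_pair(strrep("ACGT", 100), strrep("ACGT", 100), clk)
  expect_equal(ev$age, 0)
  expect_equal(ev$kind, "re_insertion")
  # age = K / (2 * ltr_rate): the reported 6.2 and 0.12 mya elements
  expect_equal(0.1612 / (2 * clk$ltr_rate) / 1e6, 6.2, tolerance = 1e-3)
  expect_equal(0.00312 / (2 * clk$ltr_rate) / 1e6, 0.12, tolerance = 1e-3)
  # SE propagates as sqrt(var) through the same constant
  set.seed(3)
  a <- oracle_random_dna(1000)
  b <- evolve_sequence(a, 0.05, seed = 5)
  ev <- date_ltr_pair(a, b, clk, prealigned = TRUE)
  d <- k2p(pairwise_site_counts(a, b, prealigned = TRUE))
  expect_equal(ev$age_se, sqrt(d$variance) / (2 * clk$ltr_rate) / 1e6)
})

test_that("NG86 Ks reproduces hand-counted codon examples", {
  expect_equal(ks_ng86("ATGGCT", "ATGGCT")$K, 0)
  # 9x GGG + TTT vs TTC: S = 28/3, Sd = 1, ps = 3/28, Ks = 0.1156
  a <- paste(c(rep("GGG", 9), "TTT"), collapse = "")
  b <- paste(c(rep("GGG", 9), "TTC"), collapse = "")
  ks <- ks_ng86(a, b)
  expect_equal(ks$n, 28 / 3)
  expect_equal(ks$ps, 3 / 28, tolerance = 1e-12)
  expect_lt(abs(ks$K - 0.1156), 1e-4)
  expect_equal(ks$K, -0.75 * log(1 - 4 * (3 / 28) / 3))
  # single codon TTT vs TTC: ps = 1 / (1/3) = 3 -> saturated
  expect_error(ks_ng86("TTT", "TTC"), class = "haplozein_saturation_error")
  expect_error(ks_ng86("ATGC", "ATGC"), class = "haplozein_frame_error")
  # symmetry
  expect_equal(ks_ng86(a, b)$K, ks_ng86(b, a)$K)
})

test_that("duplication ages follow the genic clock", {
  clk <- clock_params()
  mk <- function(K) structure(list(K = K, variance = 0, n = 100),
                              class = "distance_estimate")
  expect_equal(date_duplication(mk(0), clk)$age, 0)
  expect_equal(date_duplication(mk(0.0078), clk)$age, 0.6, tolerance = 1e-6)
  expect_equal(date_duplication(mk(0.0286), clk)$age, 2.2, tolerance = 1e-6)
  expect_equal(date_duplication(mk(0.0286), clk)$kind, "gene_duplication")
})

test_that("breaking the 2:1 LTR/gene rate convention warns", {
  expect_warning(clock_params(gene_rate = 6.5e-9, ltr_rate = 1e-8), "2 x")
  expect_silent(clock_params())
})
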