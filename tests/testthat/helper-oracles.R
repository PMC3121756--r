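# Independent oracles used across the suite; deliberately implemented
# with different machinery than the package functions they check.

# reverse complement by character table, no Biostrings
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

oracle_random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force triplet scan for cytosine contexts
oracle_contexts <- function(ref) {
  cs <- strsplit(ref, "")[[1]]
  pos <- which(cs == "C")
  vapply(pos, function(p) {
    trip <- cs[p:min(p + 2, length(cs))]
    if (length(trip) >= 2 && trip[2] == "G") "CG"
    else if (length(trip) == 3 && trip[3] == "G") "CHG"
    else "CHH"
  }, "")
}

# exhaustive least-squares topology search over all unrooted topologies
oracle_ls_topology <- function(dm) {
  labs <- rownames(dm)
  topos <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  ss <- vapply(topos, function(tp) {
    ft <- suppressWarnings(phangorn::nnls.tree(dm, tp, method = "unrooted"))
    sum((stats::cophenetic(ft)[labs, labs] - dm)^2)
  }, 0)
  topos[[which.min(ss)]]
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# exact binomial central interval for a count
oracle_binom_ci <- function(n, p, level = 0.95) {
  a <- (1 - level) / 2
  c(qbinom(a, n, p), qbinom(1 - a, n, p))
}
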