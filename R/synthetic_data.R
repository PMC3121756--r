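#' Synthetic haplotype pairs with known truth
#'
#' The generator emulates the structures seen in alpha-zein cluster
#' haplotypes: a tandem array of gene copies descending from one
#' ancestral unit, retroelement insertions (shared, haplotype-specific
#' and nested) whose paired LTRs have diverged according to a neutral
#' K2P clock, 5-bp target-site duplications, multinomially sampled cDNA
#' clone libraries with sequencing error, and bisulfite reads with
#' per-cytosine methylation probabilities and imperfect conversion.
#' Every stochastic choice is recorded in a truth ledger so downstream
#' estimators can be scored by parameter recovery.
#'
#' @name synthetic_data
NULL

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*" & names(gc) != "ATG"]
})

# expected observed transition (P) and transversion (Q) proportions of a
# K2P process at distance d with ts/tv rate ratio kappa
k2p_event_probs <- function(d, kappa) {
  bT <- d / (kappa + 2)
  aT <- kappa * bT
  Q <- 0.5 * (1 - exp(-4 * bT))
  P <- 0.25 * (1 - 2 * exp(-2 * (aT + bT)) + exp(-4 * bT))
  c(P = P, Q = Q)
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

#' Evolve a sequence under the K2P substitution model
#'
#' Applies per-site independent substitutions such that the K2P distance
#' estimated between input and output converges to `expected_divergence`
#' as length grows: sites change by a transition with probability `P(d)`
#' and by each transversion with probability `Q(d)/2`, the exact
#' time-`d` event probabilities of the Kimura model (multiple hits are
#' thereby built in, so the estimator's correction is consistent with
#' the generator). `N` bases are left untouched.
#'
#' @param seq DNA string.
#' @param expected_divergence Target substitutions/site (>= 0).
#' @param kappa Transition/transversion rate ratio.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return The evolved DNA string, same length as the input.
#' @export
evolve_sequence <- function(seq, expected_divergence, kappa = 2, seed = 1) {
  hz_assert(is.numeric(expected_divergence) && expected_divergence >= 0,
            "expected_divergence must be >= 0",
            class = "haplozein_parameter_error")
  seq <- check_dna(seq)
  if (expected_divergence == 0) return(seq)
  pq <- k2p_event_probs(expected_divergence, kappa)
  with_seed(seed, {
    cs <- chars(seq)
    mut <- cs %in% c("A", "C", "G", "T")
    u <- runif(length(cs))
    ts <- mut & u < pq[["P"]]
    tv1 <- mut & u >= pq[["P"]] & u < pq[["P"]] + pq[["Q"]] / 2
    tv2 <- mut & u >= pq[["P"]] + pq[["Q"]] / 2 & u < pq[["P"]] + pq[["Q"]]
    cs[ts] <- TRANSITION[cs[ts]]
    cs[tv1] <- vapply(cs[tv1], function(b) TRANSVERSIONS[[b]][1], "")
    cs[tv2] <- vapply(cs[tv2], function(b) TRANSVERSIONS[[b]][2], "")
    paste(cs, collapse = "")
  })
}

#' Describe one retroelement insertion for the simulator
#'
#' @param age Insertion age in mya.
#' @param ltr_len,body_len Lengths (bp) of each LTR and the internal
#'   region.
#' @param nested_in Index (into the insertion list) of the host element
#'   this one inserted into, or `NA` for a top-level insertion.
#' @param haplotype Which haplotype carries the element: "both", "A" or
#'   "B" (an element absent from one haplotype is haplotype-specific).
#' @param family Optional family label stored in the annotation.
#' @export
re_insertion <- function(age, ltr_len = 1000, body_len = 4000,
                         nested_in = NA, haplotype = "both", family = NULL) {
  hz_assert(age >= 0, "insertion age must be >= 0",
            class = "haplozein_parameter_error")
  hz_assert(haplotype %in% c("both", "A", "B"),
            "haplotype must be 'both', 'A' or 'B'")
  list(age = age, ltr_len = as.integer(ltr_len),
       body_len = as.integer(body_len), nested_in = nested_in,
       haplotype = haplotype, family = family)
}

#' Simulation configuration
#'
#' Defaults reproduce the study conditions the package is designed
#' around: five tandem gene copies with duplication ages spanning the
#' locus chronology, five retroelement insertions covering the shared /
#' haplotype-specific / nested / identical-LTR cases at the reported
#' ages (6.2, 2.04, 1.19 nested, 0.12 and 0 mya), 5-bp TSDs, a
#' 288-clone cDNA library (three 96-well plates) dominated by one copy,
#' and one 96-read bisulfite plate per tissue.
#'
#' @param seed Master integer seed; every stream is derived from it.
#' @param n_zein_copies Number of tandem gene copies per haplotype.
#' @param copy_ages Duplication age (mya) of each copy relative to its
#'   parent in the amplification chain; the first entry is the locus
#'   founding age and dates no pair.
#' @param re_insertions List of [re_insertion()] descriptions.
#' @param tsd_len Target-site duplication length (bp).
#' @param expression_fractions Per-copy transcript fractions, summing
#'   to 1.
#' @param clone_error_rate Per-base substitution error of clone
#'   consensus sequences.
#' @param n_clones Clones per library.
#' @param methylation_probs Optional per-cytosine methylation
#'   probabilities for the assayed promoter (`NULL`: filled in by
#'   context when the pipeline builds the reference).
#' @param conversion_failure_rate Probability an unmethylated C escapes
#'   bisulfite conversion.
#' @param n_bs_reads Bisulfite reads per sample.
#' @param clock A [clock_params()].
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_zein_copies = 5,
                              copy_ages = c(11.9, 2.2, 1.4, 0.6, 0.5),
                              re_insertions = list(
                                re_insertion(6.2, family = "Gypsy35"),
                                re_insertion(2.04, family = "Prem2"),
                                re_insertion(1.19, nested_in = 2, family = "Zeon2"),
                                re_insertion(0.12, haplotype = "A", family = "Zeon2"),
                                re_insertion(0, haplotype = "B", family = "Gypsy73")),
                              tsd_len = 5,
                              expression_fractions = c(0.90, 0.05, 0.03, 0.02, 0),
                              clone_error_rate = 0.005,
                              n_clones = 288,
                              methylation_probs = NULL,
                              conversion_failure_rate = 0.005,
                              n_bs_reads = 96,
                              clock = clock_params()) {
  hz_assert(!missing(seed), "seed is required", "haplozein_parameter_error")
  hz_assert(n_zein_copies >= 1 && length(copy_ages) == n_zein_copies,
            "copy_ages must have one entry per gene copy",
            class = "haplozein_parameter_error")
  hz_assert(all(copy_ages >= 0), "ages must be >= 0",
            class = "haplozein_parameter_error")
  hz_assert(length(expression_fractions) == n_zein_copies &&
            all(expression_fractions >= 0 & expression_fractions <= 1) &&
            abs(sum(expression_fractions) - 1) <= 1e-9,
            "expression_fractions must lie in [0,1] and sum to 1",
            class = "haplozein_parameter_error")
  for (frac in c(clone_error_rate, conversion_failure_rate))
    hz_assert(frac >= 0 && frac <= 1, "rates must lie in [0,1]",
              class = "haplozein_parameter_error")
  for (i in seq_along(re_insertions)) {
    host <- re_insertions[[i]]$nested_in
    if (!is.na(host)) {
      hz_assert(host >= 1 && host <= length(re_insertions) && host != i,
                sprintf("insertion %d: nested_in out of range", i),
                class = "haplozein_config_error")
      hz_assert(re_insertions[[i]]$age <= re_insertions[[host]]$age,
                sprintf("insertion %d is older than its host %d", i, host),
                class = "haplozein_config_error")
    }
  }
  structure(list(seed = as.integer(seed), n_zein_copies = n_zein_copies,
                 copy_ages = copy_ages, re_insertions = re_insertions,
                 tsd_len = as.integer(tsd_len),
                 expression_fractions = expression_fractions,
                 clone_error_rate = clone_error_rate, n_clones = n_clones,
                 methylation_probs = methylation_probs,
                 conversion_failure_rate = conversion_failure_rate,
                 n_bs_reads = n_bs_reads, clock = clock),
            class = "simulation_config")
}

# insert block_seq at 0-based position pos, shifting/growing features
insert_block <- function(state, pos, block_seq) {
  len <- nchar(block_seq)
  n <- nchar(state$seq)
  state$seq <- paste0(substr(state$seq, 1, pos), block_seq,
                      substr(state$seq, pos + 1, n))
  f <- state$feats
  if (nrow(f) > 0) {
    shift <- f$start >= pos
    grow <- f$start < pos & f$end > pos
    f$start[shift] <- f$start[shift] + len
    f$end[shift] <- f$end[shift] + len
    f$end[grow] <- f$end[grow] + len
    state$feats <- f
  }
  state
}

add_feats <- function(state, ft) {
  state$feats <- rbind(state$feats, ft)
  state
}

#' Simulate a pair of annotated haplotypes with truth ledger
#'
#' Builds an ancestral tandem array (each unit = 500-bp promoter
#' carrying the P-box and O2-site motifs + 750-bp CDS), derives the gene
#' copies along the duplication chain at `2 * age * gene_rate` expected
#' divergence per duplication, and applies the configured retroelement
#' insertions oldest-first. Each element is flanked by an identical TSD,
#' and each of its two LTRs is evolved independently from the ancestral
#' LTR by `age * ltr_rate * 1e6` substitutions/site, so the LTR-LTR
#' expected divergence is `2 * age * ltr_rate * 1e6` and the K2P clock
#' recovers the configured age. Nested elements are placed wholly inside
#' their host's internal region (the host span grows accordingly).
#'
#' @param config A [simulation_config()].
#' @param inbreds Labels for the two haplotypes.
#' @return A list with elements `hapA`, `hapB`
#'   ([annotated_haplotype()]) and `truth` (class `synthetic_truth`):
#'   `true_ages` (per-element ages and carriers), `copy_provenance`
#'   (duplication chain), `true_expression`, `true_methylation`,
#'   `insertion_order` (oldest first).
#' @export
simulate_locus_pair <- function(config, inbreds = c("inbredA", "inbredB")) {
  hz_assert(inherits(config, "simulation_config"),
            "config must come from simulation_config()")
  seed <- config$seed
  clk <- config$clock
  n_cp <- config$n_zein_copies
  prom_len <- 500L; cds_len <- 750L
  spacer <- 2000L

  anc <- with_seed(derive_seed(seed, "ancestor"), {
    prom <- chars(random_dna(prom_len))
    # plant P-box with its 5'-most base 300 bp upstream of the ATG and
    # the O2 site on the lower strand 171 bp upstream
    prom[(prom_len - 300 + 1):(prom_len - 300 + 8)] <- chars("GTGTAAAG")
    o2rc <- chars(revcomp(default_motif_set()$pattern[2]))
    prom[(prom_len - 171 + 1):(prom_len - 171 + length(o2rc))] <- o2rc
    cds <- paste0("ATG",
                  paste(sample(SENSE_CODONS, (cds_len - 6) / 3, replace = TRUE),
                        collapse = ""), "TAA")
    list(prom = paste(prom, collapse = ""), cds = cds,
         spacers = replicate(n_cp + 1, random_dna(spacer)),
         ltrs = lapply(config$re_insertions, function(r) random_dna(r$ltr_len)),
         bodies = lapply(config$re_insertions, function(r) random_dna(r$body_len)))
  })

  # duplication chain: copy i evolves from copy i-1 at 2 * age * gene_rate
  units <- vector("list", n_cp)
  units[[1]] <- paste0(anc$prom, anc$cds)
  for (i in seq_len(n_cp)[-1])
    units[[i]] <- evolve_sequence(units[[i - 1]],
                                  2 * config$copy_ages[i] * 1e6 * clk$gene_rate,
                                  clk$kappa, derive_seed(seed, paste0("copy", i)))

  base <- list(seq = "", feats = feature_table())
  pos <- 0L
  base$seq <- anc$spacers[[1]]
  pos <- nchar(base$seq)
  for (i in seq_len(n_cp)) {
    cid <- sprintf("zg%d", i)
    ft <- feature_table(
      feature_id = c(paste0(cid, "_prom"), cid),
      kind = c("promoter", "zein_gene"),
      start = c(pos, pos + prom_len),
      end = c(pos + prom_len, pos + prom_len + cds_len),
      strand = "+",
      attributes = list(c(gene = cid),
                        c(copy = cid, age_mya = format(config$copy_ages[i]))))
    base$seq <- paste0(base$seq, units[[i]], anc$spacers[[i + 1]])
    base <- add_feats(base, ft)
    pos <- nchar(base$seq)
  }

  states <- list(A = base, B = base)
  order_idx <- order(-vapply(config$re_insertions, `[[`, 0, "age"),
                     seq_along(config$re_insertions))
  true_ages <- data.frame(event_id = character(), kind = character(),
                          age_mya = numeric(), haplotype = character(),
                          nested_in = character(), stringsAsFactors = FALSE)
  for (i in order_idx) {
    r <- config$re_insertions[[i]]
    rid <- sprintf("re%d", i)
    host_id <- if (is.na(r$nested_in)) NA_character_
               else sprintf("re%d", r$nested_in)
    carriers <- switch(r$haplotype, both = c("A", "B"), A = "A", B = "B")
    if (!is.na(host_id)) {
      host_hap <- config$re_insertions[[r$nested_in]]$haplotype
      ok <- switch(host_hap, both = carriers, A = "A", B = "B")
      hz_assert(all(carriers %in% ok),
                sprintf("insertion %d nests in a host absent from its haplotype", i),
                class = "haplozein_config_error")
    }
    for (hap in carriers) {
      st <- states[[hap]]
      ltr5 <- evolve_sequence(anc$ltrs[[i]], r$age * 1e6 * clk$ltr_rate,
                              clk$kappa, derive_seed(seed, paste0(rid, hap, "L")))
      ltr3 <- evolve_sequence(anc$ltrs[[i]], r$age * 1e6 * clk$ltr_rate,
                              clk$kappa, derive_seed(seed, paste0(rid, hap, "R")))
      element <- paste0(ltr5, anc$bodies[[i]], ltr3)
      if (is.na(host_id)) {
        g <- ((i - 1) %% n_cp) + 1
        gi <- match(sprintf("zg%d", g), st$feats$feature_id)
        p <- st$feats$end[gi] + 500L
      } else {
        hi <- match(host_id, st$feats$feature_id)
        hz_assert(!is.na(hi), sprintf("host %s missing in haplotype %s",
                                      host_id, hap))
        # inside the host's internal region, clear of its LTRs and TSDs
        host <- config$re_insertions[[r$nested_in]]
        p <- st$feats$start[hi] + config$tsd_len + host$ltr_len +
          as.integer(host$body_len / 3)
      }
      tsd_len <- config$tsd_len
      elen <- nchar(element)
      st <- insert_block(st, p + tsd_len, paste0(element, substr(st$seq, p + 1, p + tsd_len)))
      ft <- feature_table(
        feature_id = paste0(rid, c("", "_tsd5", "_ltr5", "_ltr3", "_tsd3")),
        kind = c("retroelement", "tsd", "ltr", "ltr", "tsd"),
        start = c(p, p, p + tsd_len, p + tsd_len + r$ltr_len + r$body_len,
                  p + tsd_len + elen),
        end = c(p + elen + 2 * tsd_len, p + tsd_len,
                p + tsd_len + r$ltr_len, p + tsd_len + elen,
                p + 2 * tsd_len + elen),
        strand = "+",
        parent = c(host_id, rid, rid, rid, rid),
        attributes = list(c(family = r$family %||% rid,
                            age_mya = format(r$age)),
                          character(), character(), character(), character()))
      st <- add_feats(st, ft)
      states[[hap]] <- st
    }
    true_ages <- rbind(true_ages, data.frame(
      event_id = rid, kind = "re_insertion", age_mya = r$age,
      haplotype = r$haplotype, nested_in = host_id %||% NA_character_,
      stringsAsFactors = FALSE))
  }

  haps <- lapply(c("A", "B"), function(h) {
    annotated_haplotype(
      inbreds[match(h, c("A", "B"))], "custom",
      genomic_sequence(sprintf("%s_locus", inbreds[match(h, c("A", "B"))]),
                       states[[h]]$seq),
      states[[h]]$feats)
  })

  copy_ids <- sprintf("zg%d", seq_len(n_cp))
  truth <- structure(list(
    true_ages = true_ages,
    copy_provenance = data.frame(
      copy_id = copy_ids,
      parent_id = c(NA_character_, copy_ids[-n_cp]),
      age_mya = config$copy_ages, stringsAsFactors = FALSE),
    true_expression = setNames(config$expression_fractions, copy_ids),
    true_methylation = config$methylation_probs,
    insertion_order = true_ages$event_id),
    class = "synthetic_truth")
  list(hapA = haps[[1]], hapB = haps[[2]], truth = truth)
}

#' Simulate a cDNA clone library by multinomial sampling
#'
#' @param refdb Reference copies: a [copy_reference_db()], a named
#'   character vector, or a list of [genomic_sequence()].
#' @param fractions Per-copy transcript fractions summing to 1.
#' @param n_clones Number of clones to draw.
#' @param error_rate Per-base substitution error applied to each clone.
#' @param seed Integer seed.
#' @param sample Sample label stored on each clone.
#' @return A list of [clone_record()]; the true source copy of every
#'   clone is attached as `attr(, "truth")` (a data.frame).
#' @export
simulate_clone_library <- function(refdb, fractions, n_clones,
                                   error_rate = 0, seed = 1, sample = "S1") {
  seqs <- normalize_refdb(refdb)
  hz_assert(length(seqs) > 0, "refdb must be non-empty")
  hz_assert(length(fractions) == length(seqs) &&
            abs(sum(fractions) - 1) <= 1e-9 && all(fractions >= 0),
            "fractions must be non-negative and sum to 1",
            class = "haplozein_parameter_error")
  with_seed(seed, {
    counts <- as.vector(rmultinom(1, n_clones, fractions))
    src <- base::sample(rep(names(seqs), counts))
    clones <- lapply(seq_along(src), function(j) {
      cs <- chars(seqs[[src[j]]])
      if (error_rate > 0) {
        hit <- which(runif(length(cs)) < error_rate & cs %in% BASES)
        for (h in hit) cs[h] <- base::sample(setdiff(BASES, cs[h]), 1)
      }
      clone_record(sprintf("%s_clone%04d", sample, j),
                   paste(cs, collapse = ""), sample)
    })
    attr(clones, "truth") <- data.frame(
      clone_id = vapply(clones, `[[`, "", "clone_id"),
      true_copy = src, stringsAsFactors = FALSE)
    clones
  })
}

#' Simulate bisulfite clone reads from a promoter
#'
#' Reads are generated from the top strand only (single amplicon primer
#' design). Each top-strand cytosine is retained as `C` with probability
#' `p_meth + (1 - p_meth) * conversion_failure_rate` and written as `T`
#' otherwise; all other bases are copied unchanged.
#'
#' @param promoter Top-strand promoter reference.
#' @param methylation_probs One methylation probability per top-strand
#'   C, in reference order.
#' @param conversion_failure_rate Probability an unmethylated C escapes
#'   conversion.
#' @param n_reads Number of reads.
#' @param seed Integer seed.
#' @param locus,tissue Labels stored on each read.
#' @return List of [bisulfite_read()].
#' @export
simulate_bisulfite_reads <- function(promoter, methylation_probs,
                                     conversion_failure_rate = 0,
                                     n_reads = 96, seed = 1,
                                     locus = "z1A", tissue = "endosperm") {
  promoter <- check_dna(promoter, "promoter")
  cpos <- which(chars(promoter) == "C")
  hz_assert(length(methylation_probs) == length(cpos),
            sprintf("methylation_probs must have one entry per top-strand C (%d)",
                    length(cpos)),
            class = "haplozein_parameter_error")
  hz_assert(all(methylation_probs >= 0 & methylation_probs <= 1),
            "methylation probabilities must lie in [0,1]",
            class = "haplozein_parameter_error")
  p_keep <- methylation_probs + (1 - methylation_probs) * conversion_failure_rate
  with_seed(seed, {
    lapply(seq_len(n_reads), function(j) {
      cs <- chars(promoter)
      conv <- runif(length(cpos)) >= p_keep
      cs[cpos[conv]] <- "T"
      bisulfite_read(sprintf("%s_%s_read%03d", locus, tissue, j),
                     paste(cs, collapse = ""), locus, tissue)
    })
  })
}
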