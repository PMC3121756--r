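#' Molecular-clock dating of insertions and duplications
#'
#' LTR retroelements carry two long terminal repeats that are identical
#' at insertion and then diverge neutrally; the Kimura two-parameter
#' (K2P) distance between the paired LTRs, divided by twice the LTR
#' substitution rate, dates the insertion. Tandem gene duplications are
#' dated the same way from the synonymous-site distance (Nei-Gojobori
#' 1986 counting with Jukes-Cantor correction) between the duplicates,
#' using the (two-fold lower) genic rate.
#'
#' @name divergence_dating
NULL

#' Molecular-clock parameters
#'
#' @param gene_rate Substitutions/site/year at synonymous sites of genes.
#' @param ltr_rate Substitutions/site/year in LTRs; conventionally twice
#'   the genic rate (a warning is issued when the 2:1 ratio is broken,
#'   but the values are honoured).
#' @param kappa Transition/transversion rate ratio.
#' @return A list of class `clock_params`.
#' @export
clock_params <- function(gene_rate = 6.5e-9, ltr_rate = 2 * gene_rate,
                         kappa = 2) {
  hz_assert(gene_rate > 0 && ltr_rate > 0 && kappa > 0,
            "clock rates and kappa must be positive")
  if (abs(ltr_rate - 2 * gene_rate) > 1e-12 * ltr_rate)
    warning("ltr_rate is not 2 x gene_rate; the conventional 2:1 ratio is broken",
            call. = FALSE)
  structure(list(gene_rate = gene_rate, ltr_rate = ltr_rate, kappa = kappa),
            class = "clock_params")
}

PURINES <- c("A", "G")

is_transition <- function(x, y) {
  (x %in% PURINES) == (y %in% PURINES)  # called only when x != y
}

#' Count transition/transversion site proportions for a sequence pair
#'
#' Columns containing a gap (`-`) or an ambiguous base (`N`, IUPAC
#' degeneracies) in either sequence are removed before counting
#' (pairwise deletion), mirroring the indel-removal rule used for LTR
#' comparison. Unaligned pairs are first globally aligned with an
#' affine-gap Needleman-Wunsch (match +1, mismatch -1, gap open 5,
#' extend 1).
#'
#' @param a,b DNA strings (aligned, possibly with `-`, when
#'   `prealigned = TRUE`).
#' @param prealigned If `TRUE` the inputs must be equal length and are
#'   compared column-wise as given.
#' @return A list of class `site_counts` with fields `n` (comparable
#'   sites), `P` (transition proportion), `Q` (transversion proportion).
#' @export
pairwise_site_counts <- function(a, b, prealigned = FALSE) {
  hz_assert(nzchar(a) && nzchar(b), "sequences must be non-empty")
  a <- toupper(a); b <- toupper(b)
  if (prealigned) {
    hz_assert(nchar(a) == nchar(b),
              "prealigned sequences must have equal length")
  } else if (nchar(gsub("-", "", a)) != nchar(a) ||
             nchar(gsub("-", "", b)) != nchar(b) || nchar(a) != nchar(b)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(gsub("-", "", a)),
      Biostrings::DNAString(gsub("-", "", b)),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 1)
    a <- as.character(Biostrings::alignedPattern(al))
    b <- as.character(Biostrings::alignedSubject(al))
  }
  ca <- chars(a); cb <- chars(b)
  keep <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  ca <- ca[keep]; cb <- cb[keep]
  n <- length(ca)
  if (n == 0)
    hz_stop("no comparable sites after removing gaps and ambiguous bases",
            "haplozein_degenerate_error")
  diff <- ca != cb
  ts <- sum(diff & (ca %in% PURINES) == (cb %in% PURINES))
  tv <- sum(diff) - ts
  structure(list(n = n, P = ts / n, Q = tv / n), class = "site_counts")
}

#' Kimura two-parameter distance
#'
#' `K = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))` with the delta-method
#' sampling variance
#' `[c1^2 P + c3^2 Q - (c1 P + c3 Q)^2] / n`,
#' where `c1 = 1/(1-2P-Q)`, `c2 = 1/(1-2Q)`, `c3 = (c1 + c2)/2`.
#'
#' @param counts A `site_counts` object from [pairwise_site_counts()].
#' @return A list of class `distance_estimate`: `K`, `variance`, `n`,
#'   plus the input `P`, `Q`.
#' @export
k2p <- function(counts) {
  P <- counts$P; Q <- counts$Q; n <- counts$n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    hz_stop(sprintf(
      "K2P distance inestimable (saturation): 1-2P-Q = %.4g, 1-2Q = %.4g",
      w1, w2), "haplozein_saturation_error")
  K <- -0.5 * log(w1 * sqrt(w2))
  c1 <- 1 / w1; c2 <- 1 / w2; c3 <- (c1 + c2) / 2
  v <- (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n
  structure(list(K = max(K, 0), variance = max(v, 0), n = n, P = P, Q = Q),
            class = "distance_estimate")
}

new_dated_event <- function(event_id, kind, K, variance, n, rate,
                            P = NA_real_, Q = NA_real_) {
  structure(list(event_id = event_id, kind = kind, K_or_Ks = K,
                 age = K / (2 * rate) / 1e6,
                 age_se = sqrt(variance) / (2 * rate) / 1e6,
                 n = n, P = P, Q = Q, variance = variance, rate_used = rate),
            class = "dated_event")
}

#' @export
print.dated_event <- function(x, ...) {
  cat(sprintf("<dated_event> %s (%s): K = %.5f, age = %.3f +/- %.3f mya\n",
              x$event_id, x$kind, x$K_or_Ks, x$age, x$age_se))
  invisible(x)
}

#' Date a retroelement insertion from its two LTRs
#'
#' The LTRs were identical at insertion, so their K2P distance `K`
#' converts to an age `K / (2 * ltr_rate)` years (each LTR accumulates
#' substitutions independently). The standard error is the delta-method
#' `sqrt(variance)` propagated through the same constant.
#'
#' @param ltr5,ltr3 The element's left and right LTR sequences.
#' @param clock A [clock_params()].
#' @param event_id Identifier recorded in the result.
#' @param prealigned Passed to [pairwise_site_counts()].
#' @return A `dated_event` with `kind = "re_insertion"` and `age` in mya.
#' @export
date_ltr_pair <- function(ltr5, ltr3, clock = clock_params(),
                          event_id = "re", prealigned = FALSE) {
  sc <- pairwise_site_counts(ltr5, ltr3, prealigned = prealigned)
  d <- k2p(sc)
  new_dated_event(event_id, "re_insertion", d$K, d$variance, d$n,
                  clock$ltr_rate, d$P, d$Q)
}

# --- NG86 synonymous-site machinery ------------------------------------

BASES <- c("T", "C", "A", "G")

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# fraction of the three possible changes at each codon position that are
# synonymous; changes to stop codons count as nonsynonymous
codon_syn_sites <- function(codon, gc) {
  aa <- gc[[codon]]
  s <- 0
  cc <- chars(codon)
  for (pos in 1:3) {
    for (b in setdiff(BASES, cc[pos])) {
      mut <- cc; mut[pos] <- b
      maa <- gc[[paste(mut, collapse = "")]]
      if (maa != "*" && maa == aa) s <- s + 1 / 3
    }
  }
  s
}

# average synonymous/nonsynonymous difference counts over all mutational
# pathways between two codons, skipping pathways through stop codons
codon_diff_counts <- function(c1, c2, gc) {
  pos <- which(chars(c1) != chars(c2))
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(pos) else
    if (k == 2) list(pos, rev(pos)) else
    lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
           function(o) pos[o])
  tally <- matrix(0, nrow = 0, ncol = 2)
  for (ord in perms) {
    cur <- chars(c1); sdd <- 0; ndd <- 0; ok <- TRUE
    for (p in ord) {
      prev <- paste(cur, collapse = "")
      cur[p] <- chars(c2)[p]
      nxt <- paste(cur, collapse = "")
      if (gc[[nxt]] == "*" || gc[[prev]] == "*") { ok <- FALSE; break }
      if (gc[[prev]] == gc[[nxt]]) sdd <- sdd + 1 else ndd <- ndd + 1
    }
    if (ok) tally <- rbind(tally, c(sdd, ndd))
  }
  if (nrow(tally) == 0) {
    # all pathways pass through a stop; fall back to counting stop steps
    # as nonsynonymous so the pair still contributes
    return(c(sd = 0, nd = k))
  }
  c(sd = mean(tally[, 1]), nd = mean(tally[, 2]))
}

#' Synonymous-site distance (Nei-Gojobori 1986)
#'
#' Counts potential synonymous sites per codon (fractional, changes to
#' stop codons treated as nonsynonymous), averages observed synonymous
#' differences over all mutational pathways (pathways through stops
#' excluded), and applies the Jukes-Cantor correction
#' `Ks = -3/4 ln(1 - 4 ps / 3)`. Codon pairs where either codon is a
#' stop are excluded from both site and difference counts.
#'
#' @param cds_a,cds_b In-frame coding sequences of equal length,
#'   divisible by 3.
#' @return A `distance_estimate` with `K` = Ks, `n` = mean number of
#'   synonymous sites, and the Nei-Gojobori large-sample `variance`.
#' @export
ks_ng86 <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b) || nchar(cds_a) %% 3 != 0)
    hz_stop("coding sequences must be equal length and divisible by 3",
            "haplozein_frame_error")
  gc <- codon_table()
  n_codon <- nchar(cds_a) / 3
  S <- 0; Sd <- 0
  used <- 0
  for (i in seq_len(n_codon)) {
    c1 <- substr(cds_a, 3 * i - 2, 3 * i)
    c2 <- substr(cds_b, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (gc[[c1]] == "*" || gc[[c2]] == "*") next
    S <- S + (codon_syn_sites(c1, gc) + codon_syn_sites(c2, gc)) / 2
    Sd <- Sd + codon_diff_counts(c1, c2, gc)[["sd"]]
    used <- used + 1
  }
  if (used == 0 || S <= 0)
    hz_stop("no usable codons for synonymous-site counting",
            "haplozein_degenerate_error")
  ps <- Sd / S
  if (ps >= 0.75)
    hz_stop(sprintf("synonymous sites saturated (ps = %.4f >= 0.75)", ps),
            "haplozein_saturation_error")
  Ks <- -0.75 * log(1 - 4 * ps / 3)
  v <- 9 * ps * (1 - ps) / ((3 - 4 * ps)^2 * S)
  structure(list(K = max(Ks, 0), variance = max(v, 0), n = S,
                 P = NA_real_, Q = NA_real_, ps = ps),
            class = "distance_estimate")
}

#' Date a tandem gene duplication from a Ks estimate
#'
#' @param ks A `distance_estimate` (typically from [ks_ng86()]).
#' @param clock A [clock_params()]; the genic rate applies.
#' @param event_id Identifier recorded in the result.
#' @return A `dated_event` with `kind = "gene_duplication"`,
#'   `age = Ks / (2 * gene_rate)` in mya.
#' @export
date_duplication <- function(ks, clock = clock_params(), event_id = "dup") {
  hz_assert(is.finite(ks$K), "Ks must be finite")
  new_dated_event(event_id, "gene_duplication", ks$K, ks$variance, ks$n,
                  clock$gene_rate)
}

#' Tabulate dated events
#'
#' @param events List of `dated_event` objects.
#' @return A `data.frame` with one row per event: event_id, kind, n, P,
#'   Q, K, variance, age_mya, age_se_mya, rate_used.
#' @export
dating_report <- function(events) {
  if (inherits(events, "dated_event")) events <- list(events)
  do.call(rbind, lapply(events, function(e)
    data.frame(event_id = e$event_id, kind = e$kind, n = e$n,
               P = e$P, Q = e$Q, K = e$K_or_Ks, variance = e$variance,
               age_mya = e$age, age_se_mya = e$age_se,
               rate_used = e$rate_used, stringsAsFactors = FALSE)))
}
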