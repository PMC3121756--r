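#' Gene-copy status, promoter motifs, composition and chronology
#'
#' Utilities that turn an annotated haplotype into the summary tables a
#' cluster comparison needs: per-copy coding status (intact, premature
#' stop, truncated, start loss, retroelement-disrupted), promoter
#' cis-element positions (prolamin box, Opaque2 site), base-composition
#' partitions (retroelement / DNA transposon / genic / intergenic),
#' cross-haplotype conserved coverage, nested-insertion chronologies and
#' a helitron terminal-structure check.
#'
#' @name locus_annotation
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Classify the coding status of a gene copy
#'
#' Precedence (a physical insertion dominates point defects):
#' `re_disrupted` > `start_loss` > `truncated` > `premature_stop` >
#' `intact`. A copy is truncated when shorter than
#' `truncation_frac * model_len` or when it contains no in-frame stop at
#' all; it has a premature stop when an in-frame stop occurs before the
#' model's stop codon position.
#'
#' @param gene_seq Coding-strand sequence of the copy.
#' @param model_len Length (bp) of an intact family member's CDS
#'   (including the stop codon).
#' @param overlapping_insertions Optional feature table rows (e.g.
#'   retroelements or solo LTRs) overlapping the copy's span.
#' @param truncation_frac Truncation threshold as a fraction of
#'   `model_len`.
#' @return A list of class `copy_status` with `status` and `detail`.
#' @export
classify_copy_status <- function(gene_seq, model_len,
                                 overlapping_insertions = NULL,
                                 truncation_frac = 0.8) {
  hz_assert(is.character(gene_seq) && length(gene_seq) == 1 && nzchar(gene_seq),
            "gene_seq must be a non-empty string")
  hz_assert(model_len > 0, "model_len must be positive")
  gene_seq <- toupper(gene_seq)
  n <- nchar(gene_seq)
  status <- function(s, d) structure(list(status = s, detail = d),
                                     class = "copy_status")
  if (!is.null(overlapping_insertions) &&
      ((is.data.frame(overlapping_insertions) && nrow(overlapping_insertions) > 0) ||
       (!is.data.frame(overlapping_insertions) && length(overlapping_insertions) > 0))) {
    what <- if (is.data.frame(overlapping_insertions))
      paste(overlapping_insertions$feature_id, collapse = ",")
    else paste(unlist(overlapping_insertions), collapse = ",")
    return(status("re_disrupted", sprintf("disrupted by insertion(s): %s", what)))
  }
  if (substr(gene_seq, 1, 3) != "ATG")
    return(status("start_loss",
                  sprintf("first codon is %s, not ATG", substr(gene_seq, 1, 3))))
  n_codons <- n %/% 3
  codons <- substring(gene_seq, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
  stops <- which(codons %in% STOP_CODONS)
  if (n < truncation_frac * model_len)
    return(status("truncated",
                  sprintf("length %d bp < %.0f%% of the %d bp model",
                          n, 100 * truncation_frac, model_len)))
  if (length(stops) == 0)
    return(status("truncated", "no in-frame stop codon in the sequence"))
  model_stop <- model_len %/% 3
  early <- stops[stops < model_stop]
  if (length(early) > 0)
    return(status("premature_stop",
                  sprintf("stop codon %s at codon %d (model stop at %d)",
                          codons[early[1]], early[1], model_stop)))
  status("intact", sprintf("ORF of %d codons ending in %s", n_codons,
                           codons[stops[1]]))
}

#' Default promoter motif set
#'
#' The prolamin box core is as printed in the zein literature; the
#' Opaque2 bZIP site consensus varies between studies, so the shipped
#' ACGT-core pattern is a configurable default rather than a fixed
#' constant.
#'
#' @return data.frame with columns `name`, `pattern` (IUPAC).
#' @export
default_motif_set <- function() {
  data.frame(name = c("P-box", "O2-box"),
             pattern = c("GTGTAAAG", "TCCACGTAGA"),
             stringsAsFactors = FALSE)
}

#' Scan a promoter window for cis-element motifs
#'
#' Scans both strands of the window (the 500 bp immediately upstream of
#' the ATG, coding-strand orientation, 3' end adjacent to the A) for
#' IUPAC patterns. `offset_upstream` is the distance from the A of the
#' ATG to the hit's upstream-most base on the coding strand, so a P-box
#' whose first base sits 300 bp upstream reports offset 300.
#'
#' @param promoter Promoter window (coding strand).
#' @param motifs data.frame with `name` and `pattern` columns; defaults
#'   to [default_motif_set()].
#' @return data.frame of hits: `motif_name`, `pattern`,
#'   `offset_upstream`, `strand`.
#' @export
scan_promoter_motifs <- function(promoter, motifs = default_motif_set()) {
  promoter <- check_dna(promoter, "promoter")
  L <- nchar(promoter)
  if (L < max(nchar(motifs$pattern)))
    warning("promoter window shorter than the longest motif; scanning what exists",
            call. = FALSE)
  subj <- Biostrings::DNAString(promoter)
  hits <- list()
  for (i in seq_len(nrow(motifs))) {
    pat <- motifs$pattern[i]
    if (nchar(pat) > L) next
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else revcomp(pat)
      m <- Biostrings::matchPattern(Biostrings::DNAString(p), subj,
                                    fixed = FALSE)
      if (length(m) == 0) next
      hits[[length(hits) + 1]] <- data.frame(
        motif_name = motifs$name[i], pattern = pat,
        offset_upstream = L - Biostrings::start(m) + 1L,
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(motif_name = character(), pattern = character(),
                      offset_upstream = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(-out$offset_upstream), , drop = FALSE]
}

kind_ranges <- function(hap, kinds) {
  f <- hap$features[hap$features$kind %in% kinds, , drop = FALSE]
  if (nrow(f) == 0) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(start = f$start + 1L, end = f$end))
}

#' Base-composition summary of a haplotype
#'
#' Every base is assigned to exactly one of retroelement, DNA
#' transposon, genic or intergenic, with precedence RE > DNA-TE > genic
#' > intergenic for overlapping annotation (nested elements are counted
#' once). Conserved coverage is computed independently from the
#' supplied blocks.
#'
#' @param hap An [annotated_haplotype()].
#' @param conserved_blocks Optional data.frame/matrix with `start`,
#'   `end` columns (0-based half-open) of conserved blocks, e.g. from
#'   [conserved_coverage()].
#' @return A list of class `composition_summary`: `total_len`, `re_pct`,
#'   `dna_te_pct`, `genic_pct`, `intergenic_pct`, `conserved_pct`.
#' @export
composition_summary <- function(hap, conserved_blocks = NULL) {
  total <- nchar(hap$contig$seq)
  re <- kind_ranges(hap, "retroelement")
  te <- IRanges::setdiff(kind_ranges(hap, c("dna_transposon", "helitron")), re)
  genic <- IRanges::setdiff(kind_ranges(hap, "zein_gene"),
                            IRanges::union(re, te))
  re_b <- sum(IRanges::width(re))
  te_b <- sum(IRanges::width(te))
  g_b <- sum(IRanges::width(genic))
  cons <- NA_real_
  if (!is.null(conserved_blocks) && NROW(conserved_blocks) > 0) {
    cb <- IRanges::reduce(IRanges::IRanges(
      start = conserved_blocks[, "start"] + 1L,
      end = conserved_blocks[, "end"]))
    cons <- 100 * sum(IRanges::width(cb)) / total
  } else if (!is.null(conserved_blocks)) cons <- 0
  structure(list(total_len = total,
                 re_pct = 100 * re_b / total,
                 dna_te_pct = 100 * te_b / total,
                 genic_pct = 100 * g_b / total,
                 intergenic_pct = 100 * (total - re_b - te_b - g_b) / total,
                 conserved_pct = cons),
            class = "composition_summary")
}

#' Conserved coverage between two haplotypes
#'
#' Finds shared blocks by exact k-mer seeding: every k-mer of haplotype
#' A found anywhere in haplotype B marks its A-span as seeded; seeds on
#' a common alignment diagonal are merged across small gaps (point
#' substitutions interrupt seeds for at most k-1 bp), each merged block
#' is verified base-by-base at its diagonal, and blocks are retained if
#' identity >= `min_identity` and length >= `min_block`. Reported as the
#' percentage of haplotype A covered by retained blocks.
#'
#' @param hapA,hapB [annotated_haplotype()] objects (or
#'   [genomic_sequence()]s).
#' @param min_identity Minimum block identity (default 0.95, the
#'   conventional homology threshold for haplotype comparison).
#' @param min_block Minimum block length in bp.
#' @param k Seed length.
#' @return The coverage percentage, with the retained blocks (0-based
#'   half-open, columns `start`, `end`, `identity`) as `attr(, "blocks")`.
#' @export
conserved_coverage <- function(hapA, hapB, min_identity = 0.95,
                               min_block = 1000, k = 50) {
  a <- if (inherits(hapA, "annotated_haplotype")) hapA$contig$seq else hapA$seq
  b <- if (inherits(hapB, "annotated_haplotype")) hapB$contig$seq else hapB$seq
  hz_assert(nzchar(a) && nzchar(b), "both contigs must be non-empty")
  nA <- nchar(a)
  if (nA < k || nchar(b) < k) return(structure(0, blocks = NULL))
  startsA <- seq_len(nA - k + 1)
  kmersA <- substring(a, startsA, startsA + k - 1)
  startsB <- seq_len(nchar(b) - k + 1)
  kmersB <- substring(b, startsB, startsB + k - 1)
  hitB <- match(kmersA, kmersB)
  sel <- which(!is.na(hitB))
  if (length(sel) == 0) return(structure(0, blocks = NULL))
  diag <- hitB[sel] - sel
  ca <- chars(a); cb <- chars(b)
  blocks <- list()
  for (dg in unique(diag)) {
    posA <- sel[diag == dg]
    ir <- IRanges::reduce(IRanges::IRanges(posA, posA + k - 1),
                          min.gapwidth = 3 * k)
    for (j in seq_along(ir)) {
      s <- IRanges::start(ir)[j]; e <- IRanges::end(ir)[j]
      if (e - s + 1 < min_block) next
      idx <- s:e
      ident <- mean(ca[idx] == cb[idx + dg])
      if (ident >= min_identity)
        blocks[[length(blocks) + 1]] <- c(start = s - 1, end = e,
                                          identity = ident)
    }
  }
  if (length(blocks) == 0) return(structure(0, blocks = NULL))
  bm <- do.call(rbind, blocks)
  cov <- IRanges::reduce(IRanges::IRanges(bm[, "start"] + 1, bm[, "end"]))
  structure(100 * sum(IRanges::width(cov)) / nA,
            blocks = as.data.frame(bm))
}

#' Order dated events and flag nesting violations
#'
#' @param events List of `dated_event`s or a data.frame with `event_id`
#'   and `age_mya` (e.g. from [dating_report()]).
#' @param containment Optional data.frame with columns `nested`, `host`
#'   naming event ids; each pair is checked for age(nested) <=
#'   age(host).
#' @return A list of class `chronology_report`: `events` (sorted oldest
#'   to youngest) and `violations`.
#' @export
insertion_chronology <- function(events, containment = NULL) {
  df <- if (is.data.frame(events)) events else dating_report(events)
  df <- df[order(-df$age_mya), , drop = FALSE]
  rownames(df) <- NULL
  viol <- data.frame(nested = character(), host = character(),
                     nested_age = numeric(), host_age = numeric(),
                     stringsAsFactors = FALSE)
  if (!is.null(containment) && nrow(containment) > 0) {
    unknown <- setdiff(c(containment$nested, containment$host), df$event_id)
    hz_assert(length(unknown) == 0,
              sprintf("containment references unknown event(s): %s",
                      paste(unknown, collapse = ", ")))
    age <- setNames(df$age_mya, df$event_id)
    bad <- which(age[containment$nested] > age[containment$host])
    if (length(bad) > 0)
      viol <- data.frame(nested = containment$nested[bad],
                         host = containment$host[bad],
                         nested_age = unname(age[containment$nested[bad]]),
                         host_age = unname(age[containment$host[bad]]),
                         stringsAsFactors = FALSE)
  }
  structure(list(events = df, violations = viol), class = "chronology_report")
}

has_hairpin <- function(w, stem_min = 8, loop_max = 12) {
  n <- nchar(w)
  if (n < 2 * stem_min) return(FALSE)
  cs <- chars(w)
  for (i in seq_len(n - 2 * stem_min + 1)) {
    stem <- substr(w, i, i + stem_min - 1)
    rc <- revcomp(stem)
    jmax <- min(n - stem_min + 1, i + stem_min + loop_max)
    j <- i + stem_min
    while (j <= jmax) {
      if (substr(w, j, j + stem_min - 1) == rc) return(TRUE)
      j <- j + 1
    }
  }
  FALSE
}

#' Check a window for helitron terminal structure
#'
#' A candidate window starts with 5'-TC, ends with CTAG-3', and carries
#' a hairpin (a >= 8 bp stem whose reverse complement recurs within a
#' <= 12 bp loop) within 100 bp of the 3' end.
#'
#' @param window DNA string, >= 100 bp.
#' @return list(is_candidate, detail).
#' @export
detect_helitron <- function(window) {
  window <- check_dna(window, "window")
  hz_assert(nchar(window) >= 100, "window must be >= 100 bp")
  n <- nchar(window)
  if (substr(window, 1, 2) != "TC")
    return(list(is_candidate = FALSE, detail = "no 5'-TC terminus"))
  if (substr(window, n - 3, n) != "CTAG")
    return(list(is_candidate = FALSE, detail = "no CTAG-3' terminus"))
  tail_w <- substr(window, n - 99, n)
  if (!has_hairpin(tail_w))
    return(list(is_candidate = FALSE,
                detail = "termini present, but no hairpin within 100 bp of the 3' end"))
  list(is_candidate = TRUE,
       detail = "TC...CTAG termini with subterminal hairpin")
}
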