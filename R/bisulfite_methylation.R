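#' Per-cytosine bisulfite methylation profiling
#'
#' Bisulfite converts unmethylated cytosines to uracil (read as T);
#' methylated cytosines are protected. Comparing clone-sequenced
#' amplicon reads with the untreated reference therefore reveals, for
#' every top-strand cytosine of a promoter, the fraction of chromosomes
#' methylated at that position. Sites are classified by the two
#' reference bases 3' of the C: CG, CHG or CHH (H = A, C or T).
#' Analysis is top-strand only, matching a single-amplicon primer
#' design.
#'
#' @name bisulfite_methylation
NULL

#' Classify every top-strand cytosine of a reference
#'
#' Context: CG when the next base is G; CHG when the next is A/C/T and
#' the base after is G; CHH otherwise. Trailing cytosines with fewer
#' than two 3' bases default to CHH and are flagged.
#'
#' @param reference Coding-strand promoter reference (conventionally
#'   the 500 bp upstream of the ATG).
#' @return data.frame with one row per C: `pos` (1-based position in
#'   the reference), `offset_upstream` (bp upstream of the ATG),
#'   `context`, `trailing` flag, and zeroed `n_methylated`, `n_total`,
#'   `pct` columns.
#' @export
cytosine_contexts <- function(reference) {
  reference <- check_dna(reference, "reference")
  cs <- chars(reference)
  L <- length(cs)
  pos <- which(cs == "C")
  ctx <- character(length(pos))
  trailing <- logical(length(pos))
  for (i in seq_along(pos)) {
    p <- pos[i]
    n1 <- if (p + 1 <= L) cs[p + 1] else NA
    n2 <- if (p + 2 <= L) cs[p + 2] else NA
    if (is.na(n1)) { ctx[i] <- "CHH"; trailing[i] <- TRUE }
    else if (n1 == "G") ctx[i] <- "CG"
    else if (is.na(n2)) { ctx[i] <- "CHH"; trailing[i] <- TRUE }
    else if (n2 == "G") ctx[i] <- "CHG"
    else ctx[i] <- "CHH"
  }
  data.frame(pos = pos, offset_upstream = L - pos + 1L, context = ctx,
             trailing = trailing, n_methylated = 0L, n_total = 0L,
             pct = NA_real_, stringsAsFactors = FALSE)
}

# conversion-aware per-position comparison of one read to the reference
conversion_aware_identity <- function(read_cs, ref_cs) {
  mean(read_cs == ref_cs | (ref_cs == "C" & read_cs == "T"))
}

#' Call per-cytosine methylation from bisulfite reads
#'
#' Reads are matched to the reference with conversion-aware identity
#' (a reference C matches read C or T); reads below `min_identity` are
#' dropped and counted. At each reference C, reads showing C count as
#' methylated and reads showing T as unmethylated; any other base at
#' that position (sequencing error) is excluded from the site's
#' denominator. No conversion-efficiency correction is applied; the
#' overall converted fraction is recorded as a crude QC note.
#'
#' @param reads List of [bisulfite_read()] covering the full reference
#'   (equal length; reads of other lengths are globally aligned first).
#' @param reference The untreated top-strand reference.
#' @param min_identity Conversion-aware identity below which a read is
#'   dropped.
#' @return A list of class `methylation_profile`: `locus`, `tissue`,
#'   `sites` (as [cytosine_contexts()] with counts filled),
#'   `n_reads_used`, `n_reads_dropped`, `conversion_note`, `reference`.
#' @export
call_site_methylation <- function(reads, reference, min_identity = 0.90) {
  reference <- check_dna(reference, "reference")
  hz_assert(length(reads) > 0, "no reads supplied",
            class = "haplozein_degenerate_error")
  sites <- cytosine_contexts(reference)
  ref_cs <- chars(reference)
  used <- 0L; dropped <- 0L
  meth <- integer(nrow(sites)); tot <- integer(nrow(sites))
  conv_c <- 0; conv_t <- 0
  for (rd in reads) {
    s <- rd$seq
    if (nchar(s) != nchar(reference)) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(s), Biostrings::DNAString(reference),
        type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1, baseOnly = FALSE),
        gapOpening = 5, gapExtension = 1)
      pat <- chars(as.character(Biostrings::alignedPattern(al)))
      sub <- chars(as.character(Biostrings::alignedSubject(al)))
      keep <- sub != "-"
      read_cs <- pat[keep]
      read_cs[read_cs == "-"] <- "N"
    } else read_cs <- chars(s)
    if (conversion_aware_identity(read_cs, ref_cs) < min_identity) {
      dropped <- dropped + 1L
      next
    }
    used <- used + 1L
    obs <- read_cs[sites$pos]
    meth <- meth + (obs == "C")
    tot <- tot + (obs %in% c("C", "T"))
    conv_c <- conv_c + sum(obs == "C")
    conv_t <- conv_t + sum(obs == "T")
  }
  if (used == 0)
    hz_stop("no usable reads after identity filtering",
            "haplozein_degenerate_error")
  sites$n_methylated <- meth
  sites$n_total <- tot
  sites$pct <- ifelse(tot > 0, 100 * meth / tot, NA_real_)
  structure(list(
    locus = reads[[1]]$locus, tissue = reads[[1]]$tissue, sites = sites,
    n_reads_used = used, n_reads_dropped = dropped,
    conversion_note = sprintf(
      "%.1f%% of cytosine calls converted (crude QC; no correction applied)",
      100 * conv_t / max(conv_c + conv_t, 1)),
    reference = reference),
    class = "methylation_profile")
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat(sprintf("<methylation_profile> %s %s: %d sites, %d reads (%d dropped)\n",
              x$locus, x$tissue, nrow(x$sites), x$n_reads_used,
              x$n_reads_dropped))
  print(context_averages(x))
  invisible(x)
}

#' Average methylation per sequence context
#'
#' Arithmetic mean of per-site percentages within each of CG, CHG, CHH;
#' contexts absent from the reference (e.g. a promoter whose cytosines
#' are all CHH) are reported as `NA`.
#'
#' @param profile A `methylation_profile`.
#' @return Named numeric vector with entries CG, CHG, CHH.
#' @export
context_averages <- function(profile) {
  s <- profile$sites[profile$sites$n_total > 0, , drop = FALSE]
  vapply(c(CG = "CG", CHG = "CHG", CHH = "CHH"), function(ctx) {
    v <- s$pct[s$context == ctx]
    if (length(v) == 0) NA_real_ else mean(v)
  }, 0)
}

#' Compare methylation profiles across tissues
#'
#' Takes the first profile as reference and reports per-site and
#' per-context differences (alt - ref) for each of the others. Sites
#' with coverage below `min_coverage` in either profile are masked
#' (`NA` delta) and excluded from context averages.
#'
#' @param profiles List of `methylation_profile`s over the same
#'   reference; the first is the reference tissue.
#' @param min_coverage Minimum per-site read coverage.
#' @return A list of class `methylation_comparison` with `per_site`
#'   (data.frame: pos, offset_upstream, context, one delta column per
#'   alternative tissue) and `per_context`.
#' @export
compare_tissue_profiles <- function(profiles, min_coverage = 10) {
  hz_assert(length(profiles) >= 2, "need at least two profiles")
  ref <- profiles[[1]]
  for (p in profiles[-1])
    hz_assert(identical(p$reference, ref$reference) &&
              identical(p$sites$pos, ref$sites$pos),
              "all profiles must be called against the same reference")
  per_site <- ref$sites[, c("pos", "offset_upstream", "context")]
  per_ctx <- list()
  for (p in profiles[-1]) {
    lab <- paste0("delta_", p$tissue)
    ok <- ref$sites$n_total >= min_coverage & p$sites$n_total >= min_coverage
    delta <- ifelse(ok, p$sites$pct - ref$sites$pct, NA_real_)
    per_site[[lab]] <- delta
    per_ctx[[lab]] <- vapply(c(CG = "CG", CHG = "CHG", CHH = "CHH"),
                             function(ctx) {
      v <- delta[ref$sites$context == ctx & !is.na(delta)]
      if (length(v) == 0) NA_real_ else mean(v)
    }, 0)
  }
  structure(list(per_site = per_site,
                 per_context = do.call(rbind, per_ctx)),
            class = "methylation_comparison")
}
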