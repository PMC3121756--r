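#' Paralog-specific transcript attribution from cDNA clones
#'
#' Randomly sequenced cDNA clones are assigned to near-identical
#' paralogous gene copies by best local-alignment score against a
#' reference database of all copies; counts per copy convert to percent
#' of total transcripts. A deterministic scorer with fixed parameters
#' replaces the original database search so results are platform-stable;
#' ties go to "ambiguous" and are excluded from the percent denominator.
#'
#' @name expression_attribution
NULL

#' Build a reference database of gene copies
#'
#' @param copy_id,locus,inbred,sequence Parallel vectors, one entry per
#'   copy; `copy_id` unique, sequences non-empty.
#' @return A data.frame of class `copy_reference_db`.
#' @export
copy_reference_db <- function(copy_id, locus = "custom", inbred = "unknown",
                              sequence = character()) {
  hz_assert(length(copy_id) > 0 && !anyDuplicated(copy_id),
            "copy_ids must be non-empty and unique")
  hz_assert(all(nzchar(sequence)) && length(sequence) == length(copy_id),
            "one non-empty sequence per copy is required")
  structure(data.frame(copy_id = as.character(copy_id),
                       locus = rep_len(locus, length(copy_id)),
                       inbred = rep_len(inbred, length(copy_id)),
                       sequence = toupper(sequence),
                       stringsAsFactors = FALSE),
            class = c("copy_reference_db", "data.frame"))
}

normalize_refdb <- function(refdb) {
  if (inherits(refdb, "copy_reference_db"))
    return(setNames(refdb$sequence, refdb$copy_id))
  if (is.character(refdb)) {
    hz_assert(!is.null(names(refdb)), "refdb vector must be named")
    return(refdb)
  }
  if (is.list(refdb) && all(vapply(refdb, inherits, TRUE, "genomic_sequence")))
    return(setNames(vapply(refdb, `[[`, "", "seq"),
                    vapply(refdb, `[[`, "", "id")))
  hz_stop("refdb must be a copy_reference_db, named character vector, or list of genomic_sequence",
          "haplozein_input_error")
}

local_scores <- function(clone_seqs, ref_seqs) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  pats <- Biostrings::DNAStringSet(clone_seqs)
  vapply(ref_seqs, function(r)
    Biostrings::pairwiseAlignment(pats, Biostrings::DNAString(r),
                                  type = "local", substitutionMatrix = mat,
                                  gapOpening = 5, gapExtension = 2,
                                  scoreOnly = TRUE),
    numeric(length(clone_seqs)))
}

#' Assign cDNA clones to their best-matching gene copy
#'
#' Scores every clone against every reference copy by local alignment
#' (match +1, mismatch -2, gap open 5, extend 2) and records the
#' best-scoring copy. A clone is `unassigned` when its best score falls
#' below `score_min` (default: 80% of the clone's self-alignment score,
#' i.e. its length), `ambiguous` when the margin to the runner-up is
#' below `margin_min`, otherwise `assigned`.
#'
#' @param clones List of [clone_record()] (or a single one).
#' @param db Reference copies (see [copy_reference_db()]).
#' @param score_min Absolute score threshold, or `NULL` for the 80%
#'   self-score default.
#' @param margin_min Minimum score gap to the runner-up.
#' @return A data.frame with one row per clone: `clone_id`, `best_copy`,
#'   `score`, `margin`, `status`.
#' @export
assign_clones <- function(clones, db, score_min = NULL, margin_min = 2) {
  if (inherits(clones, "clone_record")) clones <- list(clones)
  hz_assert(length(clones) > 0, "no clones supplied")
  refs <- normalize_refdb(db)
  seqs <- vapply(clones, `[[`, "", "seq")
  hz_assert(all(nzchar(seqs)), "clone sequences must be non-empty")
  sc <- local_scores(seqs, refs)
  if (!is.matrix(sc))
    sc <- matrix(sc, nrow = length(seqs), dimnames = list(NULL, names(refs)))
  best_i <- max.col(sc, ties.method = "first")
  best <- sc[cbind(seq_len(nrow(sc)), best_i)]
  runner <- apply(sc, 1, function(r) if (length(r) > 1) max(r[-which.max(r)]) else -Inf)
  margin <- ifelse(is.finite(runner), best - runner, Inf)
  smin <- if (is.null(score_min)) 0.8 * nchar(seqs) else score_min
  status <- ifelse(best < smin, "unassigned",
                   ifelse(margin < margin_min, "ambiguous", "assigned"))
  data.frame(clone_id = vapply(clones, `[[`, "", "clone_id"),
             best_copy = ifelse(status == "unassigned", NA_character_,
                                colnames(sc)[best_i]),
             score = best, margin = margin, status = status,
             stringsAsFactors = FALSE)
}

#' @rdname assign_clones
#' @param clone A single [clone_record()].
#' @export
assign_clone <- function(clone, db, score_min = NULL, margin_min = 2) {
  assign_clones(list(clone), db, score_min, margin_min)[1, ]
}

#' Convert clone assignments to an expression profile
#'
#' Percent of total transcripts per copy is `100 * count / n_assigned`;
#' ambiguous and unassigned clones are excluded from the denominator but
#' reported.
#'
#' @param assignments data.frame from [assign_clones()].
#' @param sample Sample label.
#' @param copy_ids Copy set to tabulate over (so unobserved copies
#'   report 0); defaults to the copies seen among assignments.
#' @return A list of class `expression_profile` with `sample`, `counts`,
#'   `percents`, `n_assigned`, `n_ambiguous`, `n_unassigned`.
#' @export
expression_profile <- function(assignments, sample = "S1", copy_ids = NULL) {
  asg <- assignments[assignments$status == "assigned", , drop = FALSE]
  if (nrow(asg) == 0)
    hz_stop("no assigned clones: cannot form an expression profile",
            "haplozein_degenerate_error")
  if (is.null(copy_ids)) copy_ids <- sort(unique(asg$best_copy))
  counts <- setNames(integer(length(copy_ids)), copy_ids)
  tab <- table(asg$best_copy)
  counts[names(tab)] <- as.integer(tab)
  structure(list(sample = sample, counts = counts,
                 percents = 100 * counts / nrow(asg),
                 n_assigned = nrow(asg),
                 n_ambiguous = sum(assignments$status == "ambiguous"),
                 n_unassigned = sum(assignments$status == "unassigned")),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %s: %d assigned, %d ambiguous, %d unassigned\n",
              x$sample, x$n_assigned, x$n_ambiguous, x$n_unassigned))
  print(round(x$percents, 2))
  invisible(x)
}

#' Smallest expression fraction detectable from a clone library
#'
#' With `n` random clones, a copy expressed at fraction `p` is seen at
#' least once with probability `1 - (1-p)^n`; the detection threshold at
#' the stated confidence is `p_min = 1 - (1 - confidence)^(1/n)`.
#'
#' @param n_clones Number of clones sequenced.
#' @param confidence Detection confidence.
#' @return The detection threshold as a fraction.
#' @export
detection_threshold <- function(n_clones, confidence = 0.95) {
  hz_assert(n_clones >= 1, "n_clones must be >= 1")
  hz_assert(confidence > 0 && confidence < 1, "confidence must lie in (0,1)")
  1 - (1 - confidence)^(1 / n_clones)
}

#' Compare two expression profiles copy by copy
#'
#' Classifies each copy as `reactivated` (zero in the reference, at or
#' above the alternative library's detection threshold in the
#' alternative), `silenced` (the reverse), `enhanced`/`reduced`
#' (fold-change >= `fold_min` and two-proportion exact test
#' p < `alpha`), else `unchanged`.
#'
#' @param p_ref,p_alt [expression_profile()]s over the same copy set
#'   (reference first, e.g. normal endosperm vs tissue-cultured).
#' @param alpha Significance level for the exact test.
#' @param fold_min Minimum fold-change for enhanced/reduced calls.
#' @param confidence Confidence used for the detection threshold.
#' @return data.frame: `copy_id`, counts and percents in both profiles,
#'   `fold`, `p_value`, `class`.
#' @export
compare_profiles <- function(p_ref, p_alt, alpha = 0.05, fold_min = 2,
                             confidence = 0.95) {
  hz_assert(identical(sort(names(p_ref$counts)), sort(names(p_alt$counts))),
            "profiles must cover the same copy set")
  ids <- names(p_ref$counts)
  thr_alt <- 100 * detection_threshold(p_alt$n_assigned, confidence)
  thr_ref <- 100 * detection_threshold(p_ref$n_assigned, confidence)
  rows <- lapply(ids, function(id) {
    cr <- p_ref$counts[[id]]; ca <- p_alt$counts[[id]]
    pr <- p_ref$percents[[id]]; pa <- p_alt$percents[[id]]
    fold <- if (pr > 0 && pa > 0) max(pa / pr, pr / pa) else NA_real_
    pv <- fisher.test(matrix(c(ca, p_alt$n_assigned - ca,
                               cr, p_ref$n_assigned - cr), nrow = 2))$p.value
    cls <- if (cr == 0 && ca > 0 && pa >= thr_alt) "reactivated"
      else if (ca == 0 && cr > 0 && pr >= thr_ref) "silenced"
      else if (!is.na(fold) && fold >= fold_min && pv < alpha)
        if (pa > pr) "enhanced" else "reduced"
      else "unchanged"
    data.frame(copy_id = id, count_ref = cr, count_alt = ca,
               pct_ref = pr, pct_alt = pa, fold = fold, p_value = pv,
               class = cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
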