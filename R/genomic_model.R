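#' Domain containers for annotated haplotypes
#'
#' The package represents a haplotype as a contig sequence plus a flat,
#' ordered table of typed features. Internal coordinates are 0-based
#' half-open (arithmetic-safe); all file I/O converts at the boundary
#' (GFF3 is 1-based inclusive). Minus-strand feature sequences are
#' returned reverse-complemented.
#'
#' @name genomic_model
NULL

FEATURE_KINDS <- c("zein_gene", "retroelement", "dna_transposon", "helitron",
                   "ltr", "tsd", "promoter", "other")
LOCUS_LABELS <- c("z1A1", "z1A2", "z1B", "z1C1", "z1C2", "z1D", "custom")

#' Create a genomic sequence record
#'
#' @param id Unique sequence identifier.
#' @param seq DNA string over the IUPAC nucleotide alphabet.
#' @param description Free-text description (FASTA header remainder).
#' @return An object of class `genomic_sequence` with fields `id`, `seq`
#'   (uppercased), `description`.
#' @export
genomic_sequence <- function(id, seq, description = "") {
  hz_assert(is.character(id) && length(id) == 1 && nzchar(id),
            "id must be a non-empty string")
  structure(list(id = id, seq = check_dna(seq, sprintf("sequence '%s'", id)),
                 description = description),
            class = "genomic_sequence")
}

#' @export
print.genomic_sequence <- function(x, ...) {
  cat(sprintf("<genomic_sequence> %s (%d bp) %s\n", x$id, nchar(x$seq),
              x$description))
  invisible(x)
}

#' Build a feature table
#'
#' Columns use 0-based half-open coordinates on the contig. `ltr` and
#' `tsd` features require a `retroelement` parent; the parent span of a
#' retroelement includes its two flanking target-site duplications so
#' that every child lies within its parent.
#'
#' @param feature_id,kind,start,end,strand,parent Vectors, recycled to a
#'   common length. `kind` must be one of the controlled kinds.
#' @param attributes Optional list (one element per feature) of named
#'   character vectors with free-form annotation (family, locus label,
#'   copy status, ...).
#' @return A `data.frame` with one row per feature and a list column
#'   `attributes`.
#' @export
feature_table <- function(feature_id = character(), kind = character(),
                          start = integer(), end = integer(),
                          strand = "+", parent = NA_character_,
                          attributes = NULL) {
  n <- length(feature_id)
  hz_assert(all(kind %in% FEATURE_KINDS),
            sprintf("unknown feature kind(s): %s",
                    paste(setdiff(kind, FEATURE_KINDS), collapse = ", ")))
  df <- data.frame(feature_id = as.character(feature_id),
                   kind = as.character(kind),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   parent = rep_len(as.character(parent), n),
                   stringsAsFactors = FALSE)
  df$attributes <- if (is.null(attributes)) rep(list(character()), n)
                   else attributes
  hz_assert(all(df$strand %in% c("+", "-")), "strand must be '+' or '-'")
  df
}

#' Assemble an annotated haplotype
#'
#' @param inbred Inbred line label (e.g. "B73").
#' @param locus Locus label; one of the six alpha-zein loci or "custom".
#' @param contig A [genomic_sequence()].
#' @param features A [feature_table()]; sorted by `start` on creation.
#' @return An object of class `annotated_haplotype`.
#' @export
annotated_haplotype <- function(inbred, locus, contig, features) {
  hz_assert(inherits(contig, "genomic_sequence"), "contig must be a genomic_sequence")
  hz_assert(locus %in% LOCUS_LABELS,
            sprintf("locus must be one of: %s", paste(LOCUS_LABELS, collapse = ", ")))
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  len <- nchar(contig$seq)
  hz_assert(all(features$start >= 0 & features$start < features$end &
                features$end <= len),
            "feature spans must satisfy 0 <= start < end <= contig length")
  hz_assert(!anyDuplicated(features$feature_id),
            "feature_id values must be unique")
  idx <- setNames(seq_len(nrow(features)), features$feature_id)
  for (i in seq_len(nrow(features))) {
    p <- features$parent[i]
    if (!is.na(p)) {
      hz_assert(p %in% names(idx), sprintf("unknown parent '%s'", p))
      j <- idx[[p]]
      hz_assert(features$start[i] >= features$start[j] &&
                features$end[i] <= features$end[j],
                sprintf("feature '%s' extends outside its parent '%s'",
                        features$feature_id[i], p),
                class = "haplozein_validation_error")
      if (features$kind[i] %in% c("ltr", "tsd"))
        hz_assert(features$kind[j] == "retroelement",
                  sprintf("%s feature '%s' must have a retroelement parent",
                          features$kind[i], features$feature_id[i]),
                  class = "haplozein_validation_error")
    } else if (features$kind[i] %in% c("ltr", "tsd")) {
      hz_stop(sprintf("%s feature '%s' requires a retroelement parent",
                      features$kind[i], features$feature_id[i]),
              class = "haplozein_validation_error")
    }
  }
  structure(list(inbred = inbred, locus = locus, contig = contig,
                 features = features),
            class = "annotated_haplotype")
}

#' @export
print.annotated_haplotype <- function(x, ...) {
  cat(sprintf("<annotated_haplotype> %s %s: %d bp, %d features\n",
              x$inbred, x$locus, nchar(x$contig$seq), nrow(x$features)))
  print(table(x$features$kind))
  invisible(x)
}

#' Read a multi-record FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A list of [genomic_sequence()] records in file order.
#' @export
parse_fasta <- function(path) {
  hz_assert(file.exists(path), sprintf("file not found: %s", path),
            class = "haplozein_format_error")
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0)
    hz_stop(sprintf("empty FASTA file: %s", path), "haplozein_format_error")
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    hz_stop(sprintf("malformed FASTA: line %d of %s does not start a record",
                    nonblank[1], path), "haplozein_format_error")
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    hz_stop(sprintf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", ")),
            "haplozein_format_error")
  desc <- sub("^\\S+\\s*", "", names(ss))
  lapply(seq_along(ss), function(i)
    genomic_sequence(ids[i], toupper(as.character(ss[[i]])), desc[i]))
}

#' Write genomic sequences to FASTA
#'
#' @param seqs List of [genomic_sequence()].
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "genomic_sequence")) seqs <- list(seqs)
  ss <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "seq"))
  names(ss) <- vapply(seqs, function(s)
    trimws(paste(s$id, s$description)), "")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

hap_to_granges <- function(hap) {
  f <- hap$features
  keys <- unique(unlist(lapply(f$attributes, names)))
  gr <- GenomicRanges::GRanges(
    seqnames = hap$contig$id,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand)
  S4Vectors::mcols(gr)$type <- f$kind
  S4Vectors::mcols(gr)$ID <- f$feature_id
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(f$parent, function(p) if (is.na(p)) character() else p))
  for (k in keys)
    S4Vectors::mcols(gr)[[k]] <- vapply(f$attributes, function(a)
      if (k %in% names(a)) a[[k]] else NA_character_, "")
  gr
}

#' Write annotated haplotypes to GFF3
#'
#' Converts internal 0-based half-open coordinates to GFF3 1-based
#' inclusive; `Parent` attributes encode the retroelement/LTR/TSD
#' hierarchy.
#'
#' @param haps An [annotated_haplotype()] or list of them.
#' @param path Output path.
#' @export
write_gff3 <- function(haps, path) {
  if (inherits(haps, "annotated_haplotype")) haps <- list(haps)
  grl <- lapply(haps, hap_to_granges)
  gr <- do.call(c, grl)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation against known contigs
#'
#' @param path GFF3 file; `seqid` values must name a contig.
#' @param contigs List of [genomic_sequence()] (e.g. from [parse_fasta()]).
#' @param inbred,locus Metadata labels recycled across contigs (GFF3
#'   itself carries neither).
#' @return A list of [annotated_haplotype()], one per contig with
#'   features, in `contigs` order.
#' @export
parse_gff3 <- function(path, contigs, inbred = "unknown", locus = "custom") {
  gr <- rtracklayer::import(path, format = "gff3")
  ids <- vapply(contigs, `[[`, "", "id")
  inbred <- rep_len(inbred, length(contigs))
  locus <- rep_len(locus, length(contigs))
  seqids <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(seqids), ids)
  if (length(unknown) > 0)
    hz_stop(sprintf("GFF3 seqid(s) with no matching contig: %s",
                    paste(unknown, collapse = ", ")), "haplozein_format_error")
  mc <- S4Vectors::mcols(gr)
  reserved <- c("source", "type", "score", "phase", "ID", "Name", "Parent")
  extra <- setdiff(colnames(mc), reserved)
  out <- list()
  for (ci in seq_along(contigs)) {
    sel <- which(seqids == ids[ci])
    if (length(sel) == 0) next
    sub <- gr[sel]
    m <- S4Vectors::mcols(sub)
    par <- vapply(seq_along(sub), function(i) {
      p <- m$Parent[[i]]
      if (length(p) == 0) NA_character_ else as.character(p[1])
    }, "")
    attrs <- lapply(seq_along(sub), function(i) {
      a <- character()
      for (k in extra) {
        v <- m[[k]][i]
        if (is.list(v) || methods::is(v, "List")) v <- unlist(v)
        if (length(v) == 1 && !is.na(v)) a[[k]] <- as.character(v)
      }
      a
    })
    fid <- if ("ID" %in% colnames(m)) as.character(m$ID) else
      sprintf("f%03d", seq_along(sub))
    ft <- feature_table(
      feature_id = fid, kind = as.character(m$type),
      start = GenomicRanges::start(sub) - 1L, end = GenomicRanges::end(sub),
      strand = ifelse(as.character(GenomicRanges::strand(sub)) == "-", "-", "+"),
      parent = par, attributes = attrs)
    out[[length(out) + 1]] <- annotated_haplotype(inbred[ci], locus[ci],
                                                  contigs[[ci]], ft)
  }
  out
}

#' Extract the sequence of one feature
#'
#' @param hap An [annotated_haplotype()].
#' @param feature_id Feature to extract.
#' @return A [genomic_sequence()]: the `[start, end)` substring,
#'   reverse-complemented for minus-strand features.
#' @export
extract_feature_sequence <- function(hap, feature_id) {
  i <- match(feature_id, hap$features$feature_id)
  if (is.na(i))
    hz_stop(sprintf("unknown feature_id '%s'", feature_id), "haplozein_lookup_error")
  f <- hap$features[i, ]
  s <- substr(hap$contig$seq, f$start + 1L, f$end)
  if (f$strand == "-") s <- revcomp(s)
  genomic_sequence(feature_id, s,
                   sprintf("%s %s:%d-%d(%s)", f$kind, hap$contig$id,
                           f$start, f$end, f$strand))
}

#' Create a cDNA clone record
#'
#' @param clone_id Clone identifier.
#' @param seq Consensus sequence of the paired end reads.
#' @param sample Genotype/tissue label the clone came from.
#' @export
clone_record <- function(clone_id, seq, sample) {
  hz_assert(nzchar(sample), "sample label must be present")
  structure(list(clone_id = clone_id, seq = check_dna(seq, "clone sequence"),
                 sample = sample), class = "clone_record")
}

#' Create a bisulfite clone read
#'
#' @param read_id Read identifier.
#' @param seq Bisulfite-converted sequence (top strand of the amplicon).
#' @param locus One of "z1A", "z1B", "z1C".
#' @param tissue One of "leaf", "endosperm", "cultured_endosperm".
#' @export
bisulfite_read <- function(read_id, seq, locus, tissue) {
  hz_assert(locus %in% c("z1A", "z1B", "z1C"),
            "locus must be one of z1A, z1B, z1C")
  hz_assert(tissue %in% c("leaf", "endosperm", "cultured_endosperm"),
            "tissue must be leaf, endosperm or cultured_endosperm")
  structure(list(read_id = read_id, seq = check_dna(seq, "read sequence"),
                 locus = locus, tissue = tissue), class = "bisulfite_read")
}
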