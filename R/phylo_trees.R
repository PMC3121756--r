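#' Distance-matrix phylogenetics for paralog chronology
#'
#' Neighbor-joining and UPGMA trees from aligned paralog sequences, with
#' nonparametric bootstrap support (column resampling) and Newick
#' output. Trees are `ape::phylo` objects throughout, so the whole ape
#' toolkit applies downstream.
#'
#' @name phylo_trees
NULL

#' Pairwise distance matrix from an alignment
#'
#' Distances are computed per pair with pairwise deletion (columns with
#' a gap or ambiguous base in either member are dropped for that pair),
#' under the K2P model or as raw p-distance.
#'
#' @param seqs Named character vector (or list) of equal-length aligned
#'   DNA strings, length >= 2, unique names.
#' @param model "k2p" or "p_distance".
#' @return A symmetric numeric matrix with sequence names as dimnames.
#' @export
distance_matrix <- function(seqs, model = c("k2p", "p_distance")) {
  model <- match.arg(model)
  seqs <- unlist(seqs)
  hz_assert(length(seqs) >= 2, "need at least two sequences")
  hz_assert(!is.null(names(seqs)) && !anyDuplicated(names(seqs)),
            "sequences must carry unique names")
  hz_assert(length(unique(nchar(seqs))) == 1,
            "aligned sequences must all have the same length")
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sc <- pairwise_site_counts(seqs[[i]], seqs[[j]], prealigned = TRUE)
    dij <- if (model == "k2p") {
      est <- tryCatch(k2p(sc), haplozein_saturation_error = function(e)
        hz_stop(sprintf("pair (%s, %s) is saturated: %s",
                        names(seqs)[i], names(seqs)[j], conditionMessage(e)),
                "haplozein_saturation_error"))
      est$K
    } else sc$P + sc$Q
    d[i, j] <- d[j, i] <- dij
  }
  d
}

# clamp negative branch lengths to zero, moving the deficit to the
# sibling branch so path lengths are approximately preserved
clamp_negative_edges <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1]
    sib <- which(tree$edge[, 1] == parent & seq_along(tree$edge[, 2]) != e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sib) > 0)
      tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] + deficit
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix; exact on additive
#' matrices. Negative branch lengths (possible on noisy input) are
#' clamped to zero with the deficit shifted to the sibling branch.
#'
#' @param m Symmetric distance matrix with dimnames (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(m) {
  hz_assert(nrow(m) >= 3, "neighbor joining needs at least 3 taxa",
            class = "haplozein_size_error")
  clamp_negative_edges(ape::nj(stats::as.dist(m)))
}

#' UPGMA tree
#'
#' Average-linkage clustering; the height of each merge is the average
#' inter-cluster distance and node depth is half that height, so the
#' result is ultrametric.
#'
#' @param m Symmetric distance matrix with dimnames (>= 2 taxa).
#' @return A rooted ultrametric `ape::phylo` tree.
#' @export
upgma_tree <- function(m) {
  hz_assert(nrow(m) >= 2, "UPGMA needs at least 2 taxa",
            class = "haplozein_size_error")
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  ape::as.phylo(hc)
}

#' Bootstrap support for a distance tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the tree for each replicate, and reports for every internal edge of
#' the full-data tree the percentage of replicates containing the same
#' bipartition (stored in `node.label` as integer percents). Replicates
#' in which some pair saturates are skipped, counted, and reported via a
#' warning and `attr(, "replicates_used")`.
#'
#' @param seqs Named aligned DNA strings as for [distance_matrix()].
#' @param method "nj" or "upgma".
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed (column resampling is the only randomness).
#' @param model Distance model passed to [distance_matrix()].
#' @return The full-data `phylo` tree with `node.label` support values.
#' @export
bootstrap_tree <- function(seqs, method = c("nj", "upgma"), n_reps = 1000,
                           seed = 1, model = "k2p") {
  method <- match.arg(method)
  hz_assert(n_reps >= 1, "n_reps must be >= 1")
  seqs <- unlist(seqs)
  build <- function(s) {
    m <- distance_matrix(s, model = model)
    if (method == "nj") nj_tree(m) else upgma_tree(m)
  }
  full <- build(seqs)
  len <- nchar(seqs[[1]])
  mats <- lapply(seqs, function(s) chars(s))
  boots <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- base::sample.int(len, len, replace = TRUE)
      rs <- vapply(mats, function(cs) paste(cs[cols], collapse = ""), "")
      tryCatch(build(rs), haplozein_saturation_error = function(e) NULL)
    })
  })
  used <- Filter(Negate(is.null), boots)
  skipped <- n_reps - length(used)
  if (skipped > 0)
    warning(sprintf("%d bootstrap replicate(s) skipped due to saturation",
                    skipped), call. = FALSE)
  counts <- ape::prop.clades(full, used, rooted = (method == "upgma"))
  counts[is.na(counts)] <- 0
  full$node.label <- as.character(as.integer(round(100 * counts / length(used))))
  attr(full, "replicates_used") <- length(used)
  full
}
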