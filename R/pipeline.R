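#' End-to-end reproducible runs
#'
#' `validate_config()` normalises a raw key/value configuration into a
#' run configuration with defaults filled in; `run_pipeline()` executes
#' the full analysis — simulate (synthetic mode), date insertions and
#' duplications, build paralog trees, summarise composition and copy
#' status, scan promoters, attribute expression, profile methylation —
#' and returns (optionally writes) a report bundle. Synthetic-mode
#' bundles are a pure function of (config, seed): one master seed
#' deterministically spawns every per-stage stream.
#'
#' @name pipeline_cli
NULL

#' Validate a raw configuration
#'
#' All violations are collected and reported at once. Defaults: clock
#' gene_rate 6.5e-9, ltr_rate 1.3e-8, kappa 2; confidence 0.95; score
#' margin 2; min identity 0.95; min coverage 10; alpha 0.05; fold_min 2.
#' An `ltr_rate` differing from `2 * gene_rate` is a warning, not an
#' error.
#'
#' @param raw Named list of settings. Required: `mode` ("synthetic" or
#'   "user_data"); `seed` in synthetic mode; input paths in user_data
#'   mode.
#' @return A validated list of class `run_config`.
#' @export
validate_config <- function(raw = list()) {
  problems <- character()
  mode <- raw$mode %||% "synthetic"
  if (!mode %in% c("synthetic", "user_data"))
    problems <- c(problems, "mode must be 'synthetic' or 'user_data'")
  if (mode == "synthetic" && is.null(raw$seed))
    problems <- c(problems, "missing required field: seed")
  if (mode == "user_data")
    for (p in c("fasta", "gff3"))
      if (is.null(raw[[p]]))
        problems <- c(problems, sprintf("missing required field: %s", p))
      else if (!file.exists(raw[[p]]))
        problems <- c(problems, sprintf("%s path does not exist: %s", p, raw[[p]]))
  num_in <- function(name, lo, hi, default) {
    v <- raw[[name]] %||% default
    if (!is.numeric(v) || length(v) != 1 || v < lo || v > hi)
      problems <<- c(problems, sprintf("%s must be a number in [%g, %g]",
                                       name, lo, hi))
    v
  }
  alpha <- num_in("alpha", 0, 1, 0.05)
  confidence <- num_in("confidence", 1e-9, 1 - 1e-9, 0.95)
  min_identity <- num_in("min_identity", 0, 1, 0.95)
  fold_min <- num_in("fold_min", 1, Inf, 2)
  min_coverage <- num_in("min_coverage", 0, Inf, 10)
  margin_min <- num_in("margin_min", 0, Inf, 2)
  gene_rate <- raw$gene_rate %||% 6.5e-9
  ltr_rate <- raw$ltr_rate %||% (2 * gene_rate)
  kappa <- raw$kappa %||% 2
  if (length(problems) > 0)
    hz_stop(paste0("invalid configuration:\n  - ",
                   paste(problems, collapse = "\n  - ")),
            "haplozein_config_error")
  clock <- clock_params(gene_rate = gene_rate, ltr_rate = ltr_rate,
                        kappa = kappa)
  structure(list(mode = mode, seed = raw$seed,
                 fasta = raw$fasta, gff3 = raw$gff3,
                 clones_fasta = raw$clones_fasta,
                 bisulfite_fasta = raw$bisulfite_fasta,
                 sim = raw$sim,
                 clock = clock, alpha = alpha, confidence = confidence,
                 min_identity = min_identity, fold_min = fold_min,
                 min_coverage = min_coverage, margin_min = margin_min,
                 score_min = raw$score_min, n_boot = raw$n_boot %||% 1000,
                 output_dir = raw$output_dir),
            class = "run_config")
}

# tissue-level methylation scenarios used by the synthetic run: leaf
# heavily methylated, endosperm hypomethylated, cultured endosperm
# re-methylated above its normal counterpart
METH_SCENARIO <- list(
  leaf = c(CG = 0.90, CHG = 0.70, CHH = 0.10),
  endosperm = c(CG = 0.50, CHG = 0.30, CHH = 0.05),
  cultured_endosperm = c(CG = 0.80, CHG = 0.60, CHH = 0.10))

# expression fractions after tissue-culture resetting used by the
# synthetic run: dominant copy reduced, a weak copy enhanced, a silent
# copy reactivated
reset_fractions <- function(fr) {
  n <- length(fr)
  alt <- fr
  if (n >= 5) {
    alt[1] <- fr[1] - 0.50
    alt[3] <- fr[3] + 0.32
    alt[5] <- fr[5] + 0.18
  } else {
    alt <- rev(fr)
  }
  alt / sum(alt)
}

#' Run the full analysis pipeline
#'
#' In synthetic mode the stages are: generate haplotype pair, date
#' every retroelement from its LTR pair and every duplication from the
#' parent/child Ks, order the chronology against the nesting relations,
#' build NJ and UPGMA paralog trees with bootstrap support, summarise
#' composition and conserved coverage, classify copy status, scan
#' promoters, simulate and attribute a normal and a tissue-cultured
#' clone library, and call leaf/endosperm/cultured methylation profiles
#' on the first copy's promoter. Identical config and seed give an
#' identical bundle.
#'
#' @param config A [validate_config()] result (or raw list, validated
#'   on entry).
#' @return A list of class `report_bundle`: `dating`, `chronology`,
#'   `trees`, `composition`, `copy_status`, `motifs`, `expression`,
#'   `expression_comparison`, `methylation`, `methylation_comparison`,
#'   `conserved`, `truth`, `manifest`. When `config$output_dir` is set
#'   the tables are also written there as TSV/Newick/JSON.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  hz_assert(config$mode == "synthetic",
            "user_data mode requires externally supplied annotations; see vignette")
  seed <- config$seed
  sim_cfg <- config$sim %||% simulation_config(seed = seed, clock = config$clock)
  sim <- simulate_locus_pair(sim_cfg)
  hapA <- sim$hapA; hapB <- sim$hapB; truth <- sim$truth

  # --- dating -----------------------------------------------------------
  events <- list()
  containment <- data.frame(nested = character(), host = character(),
                            stringsAsFactors = FALSE)
  fA <- hapA$features
  for (rid in fA$feature_id[fA$kind == "retroelement"]) {
    ltrs <- fA$feature_id[fA$kind == "ltr" & fA$parent == rid]
    ev <- date_ltr_pair(extract_feature_sequence(hapA, ltrs[1])$seq,
                        extract_feature_sequence(hapA, ltrs[2])$seq,
                        clock = config$clock, event_id = rid,
                        prealigned = FALSE)
    events[[rid]] <- ev
    host <- fA$parent[fA$feature_id == rid]
    if (!is.na(host))
      containment <- rbind(containment,
                           data.frame(nested = rid, host = host,
                                      stringsAsFactors = FALSE))
  }
  prov <- truth$copy_provenance
  gene_cds <- setNames(
    lapply(prov$copy_id, function(id) extract_feature_sequence(hapA, id)$seq),
    prov$copy_id)
  for (i in seq_len(nrow(prov))[-1]) {
    ks <- tryCatch(ks_ng86(gene_cds[[prov$parent_id[i]]],
                           gene_cds[[prov$copy_id[i]]]),
                   haplozein_saturation_error = function(e) NULL)
    if (!is.null(ks))
      events[[prov$copy_id[i]]] <- date_duplication(
        ks, clock = config$clock, event_id = prov$copy_id[i])
  }
  dating <- dating_report(events)
  chron <- insertion_chronology(
    dating[dating$kind == "re_insertion", , drop = FALSE], containment)

  # --- paralog trees ----------------------------------------------------
  aln <- unlist(gene_cds)  # duplication chain evolves without indels
  trees <- list(
    nj = bootstrap_tree(aln, "nj", n_reps = config$n_boot,
                        seed = derive_seed(seed, "boot_nj")),
    upgma = bootstrap_tree(aln, "upgma", n_reps = config$n_boot,
                           seed = derive_seed(seed, "boot_upgma")))

  # --- composition / conservation / status / motifs ---------------------
  consAB <- conserved_coverage(hapA, hapB, min_identity = config$min_identity)
  composition <- do.call(rbind, lapply(list(hapA, hapB), function(h) {
    cs <- composition_summary(
      h, if (identical(h, hapA)) attr(consAB, "blocks") else NULL)
    data.frame(inbred = h$inbred, total_len = cs$total_len,
               re_pct = cs$re_pct, dna_te_pct = cs$dna_te_pct,
               genic_pct = cs$genic_pct, intergenic_pct = cs$intergenic_pct,
               conserved_pct = cs$conserved_pct, stringsAsFactors = FALSE)
  }))
  status <- do.call(rbind, lapply(prov$copy_id, function(id) {
    f <- fA[fA$feature_id == id, ]
    over <- fA[fA$kind %in% c("retroelement", "ltr") & is.na(fA$parent) &
               fA$start < f$end & fA$end > f$start &
               fA$feature_id != id, , drop = FALSE]
    st <- classify_copy_status(gene_cds[[id]], model_len = 750,
                               overlapping_insertions =
                                 if (nrow(over) > 0) over else NULL)
    data.frame(copy_id = id, status = st$status, detail = st$detail,
               stringsAsFactors = FALSE)
  }))
  motifs <- do.call(rbind, lapply(prov$copy_id, function(id) {
    pr <- extract_feature_sequence(hapA, paste0(id, "_prom"))$seq
    hits <- scan_promoter_motifs(pr)
    if (nrow(hits) == 0) return(NULL)
    cbind(copy_id = id, hits)
  }))

  # --- expression attribution -------------------------------------------
  db <- copy_reference_db(prov$copy_id, locus = hapA$locus,
                          inbred = hapA$inbred,
                          sequence = unlist(gene_cds))
  clones_n <- simulate_clone_library(db, sim_cfg$expression_fractions,
                                     sim_cfg$n_clones,
                                     sim_cfg$clone_error_rate,
                                     derive_seed(seed, "clones_normal"),
                                     sample = "endosperm")
  clones_c <- simulate_clone_library(db, reset_fractions(sim_cfg$expression_fractions),
                                     sim_cfg$n_clones,
                                     sim_cfg$clone_error_rate,
                                     derive_seed(seed, "clones_cultured"),
                                     sample = "cultured_endosperm")
  prof_n <- expression_profile(
    assign_clones(clones_n, db, config$score_min, config$margin_min),
    "endosperm", copy_ids = prov$copy_id)
  prof_c <- expression_profile(
    assign_clones(clones_c, db, config$score_min, config$margin_min),
    "cultured_endosperm", copy_ids = prov$copy_id)
  expr_cmp <- compare_profiles(prof_n, prof_c, alpha = config$alpha,
                               fold_min = config$fold_min,
                               confidence = config$confidence)

  # --- methylation ------------------------------------------------------
  prom <- extract_feature_sequence(hapA, paste0(prov$copy_id[1], "_prom"))$seq
  ctx <- cytosine_contexts(prom)
  meth_profiles <- lapply(names(METH_SCENARIO), function(tissue) {
    probs <- sim_cfg$methylation_probs %||%
      unname(METH_SCENARIO[[tissue]][ctx$context])
    reads <- simulate_bisulfite_reads(
      prom, probs, sim_cfg$conversion_failure_rate, sim_cfg$n_bs_reads,
      derive_seed(seed, paste0("bs_", tissue)),
      locus = "z1A", tissue = tissue)
    call_site_methylation(reads, prom)
  })
  names(meth_profiles) <- names(METH_SCENARIO)
  meth_cmp <- compare_tissue_profiles(
    meth_profiles[c("endosperm", "cultured_endosperm", "leaf")],
    min_coverage = config$min_coverage)

  manifest <- list(
    package = "haplozein",
    version = as.character(packageVersion("haplozein")),
    mode = config$mode, seed = seed,
    clock = unclass(config$clock),
    n_boot = config$n_boot,
    thresholds = config[c("alpha", "confidence", "min_identity",
                          "fold_min", "min_coverage", "margin_min")],
    counts = list(
      n_features_hapA = nrow(hapA$features),
      n_features_hapB = nrow(hapB$features),
      n_events_dated = nrow(dating),
      clones_normal = list(assigned = prof_n$n_assigned,
                           ambiguous = prof_n$n_ambiguous,
                           unassigned = prof_n$n_unassigned),
      clones_cultured = list(assigned = prof_c$n_assigned,
                             ambiguous = prof_c$n_ambiguous,
                             unassigned = prof_c$n_unassigned),
      bs_reads_used = vapply(meth_profiles, `[[`, 0L, "n_reads_used"),
      bs_reads_dropped = vapply(meth_profiles, `[[`, 0L, "n_reads_dropped")))

  bundle <- structure(list(
    hapA = hapA, hapB = hapB, truth = truth,
    dating = dating, chronology = chron, trees = trees,
    composition = composition, copy_status = status, motifs = motifs,
    expression = list(endosperm = prof_n, cultured_endosperm = prof_c),
    expression_comparison = expr_cmp,
    methylation = meth_profiles, methylation_comparison = meth_cmp,
    conserved = consAB, manifest = manifest),
    class = "report_bundle")
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a report bundle to disk
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed); fixed file names:
#'   dating.tsv, chronology.tsv, trees.nwk, composition.tsv,
#'   copy_status.tsv, motifs.tsv, expression.tsv,
#'   expression_comparison.tsv, methylation_sites.tsv,
#'   methylation_context.tsv, manifest.json.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(bundle$dating, file.path(dir, "dating.tsv"))
  write_tsv(bundle$chronology$events, file.path(dir, "chronology.tsv"))
  ape::write.tree(c(bundle$trees$nj, bundle$trees$upgma),
                  file.path(dir, "trees.nwk"))
  write_tsv(bundle$composition, file.path(dir, "composition.tsv"))
  write_tsv(bundle$copy_status, file.path(dir, "copy_status.tsv"))
  if (!is.null(bundle$motifs))
    write_tsv(bundle$motifs, file.path(dir, "motifs.tsv"))
  expr <- do.call(rbind, lapply(bundle$expression, function(p)
    data.frame(sample = p$sample, copy_id = names(p$counts),
               count = unname(p$counts), percent = unname(p$percents),
               stringsAsFactors = FALSE)))
  write_tsv(expr, file.path(dir, "expression.tsv"))
  write_tsv(bundle$expression_comparison,
            file.path(dir, "expression_comparison.tsv"))
  sites <- do.call(rbind, lapply(bundle$methylation, function(p)
    cbind(tissue = p$tissue, p$sites)))
  write_tsv(sites, file.path(dir, "methylation_sites.tsv"))
  ctx <- do.call(rbind, lapply(bundle$methylation, function(p)
    data.frame(tissue = p$tissue, t(context_averages(p)))))
  write_tsv(ctx, file.path(dir, "methylation_context.tsv"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Fetch a GenBank accession as FASTA (network helper)
#'
#' Optional convenience for users who want to pull the study's deposited
#' BAC sequences; requires internet access and is never called by the
#' package's own analyses or tests.
#'
#' @param accession GenBank accession (e.g. "GQ214225.1").
#' @param dest Destination FASTA path.
#' @return `dest`, invisibly.
#' @export
fetch_accession <- function(accession, dest = paste0(accession, ".fasta")) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&rettype=fasta&retmode=text&id=", accession)
  download.file(url, dest, quiet = TRUE)
  invisible(dest)
}
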