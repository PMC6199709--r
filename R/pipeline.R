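#' Locus-accounting bookkeeping
#'
#' Applies the standard exclusion arithmetic to a registry of scored
#' loci: loci flagged by a secondary orthology check and loci below the
#' minimum-taxon count are removed from the scored set; the remainder
#' is analysed.
#'
#' @param scored Character vector of scored locus ids.
#' @param orthology_flagged Locus ids flagged by the orthology screen.
#' @param below_min_taxa Locus ids with too few taxa.
#' @return list with `n_scored`, `n_flagged`, `n_small`, `n_analysed`
#'   and `analysed` (ids). Counts refer to exclusions intersected with
#'   the scored set, so the invariant
#'   `n_analysed == n_scored - n_flagged - n_small` holds when the two
#'   exclusion sets are disjoint.
#' @export
locus_accounting <- function(scored, orthology_flagged = character(0L),
                             below_min_taxa = character(0L)) {
  flagged <- intersect(scored, orthology_flagged)
  small <- setdiff(intersect(scored, below_min_taxa), flagged)
  analysed <- setdiff(scored, union(flagged, small))
  list(n_scored = length(scored), n_flagged = length(flagged),
       n_small = length(small), n_analysed = length(analysed),
       analysed = analysed)
}

default_pipeline_params <- function() {
  list(prefix_len = 20L, seed_k = 11L, min_score = 50L,
       p_threshold = 0.002, min_overlap = 1L, pct_alarm = 5.0,
       min_taxa = 4L, n_select = NULL, max_quartets = 2000L,
       resolution_margin = 0, ica_threshold = 0.05, seed = 1L)
}

#' Run the curation pipeline end to end
#'
#' Stage order: dedup -> bin -> orthology -> contamination screen ->
#' minimum-taxon filter -> treelikeness selection -> concatenation and
#' statistics -> gene-tree certainty (when trees are supplied). The
#' contamination screen is advisory: it reports suspect pairs but drops
#' nothing. Precomputed bins (`inputs$bins`, TSV contig_id/locus) let a
#' run restart from an intermediate binning artifact.
#'
#' @param config A list (or path to a YAML file) with elements `inputs`
#'   (paths: `reads_r1`, `reads_r2`, `contigs`, `baits`, `bins`,
#'   `loci_dir`, `groups`, `genetrees`, `ref_tree` — all optional except
#'   `loci_dir`), `params` (see [default_pipeline_params()] names) and
#'   `out_dir`.
#' @return The run manifest (list), invisibly written to
#'   `out_dir/manifest.json` when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inputs <- config$inputs
  prm <- utils::modifyList(default_pipeline_params(),
                           if (is.null(config$params)) list() else config$params)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  manifest <- list(version = as.character(utils::packageVersion("capcure")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   config = config, params = prm, stages = list())
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      manifest$stages$failed_stage <<- name
      if (!is.null(out_dir))
        jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE, force = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  mp <- match_params(prm$seed_k, prm$min_score)

  if (!is.null(inputs$reads_r1)) stage("dedup", {
    pairs <- read_fastq_pairs(inputs$reads_r1, inputs$reads_r2)
    dd <- deduplicate_pairs(pairs, dedup_params(prm$prefix_len))
    manifest$stages$dedup <- list(n_pairs = nrow(pairs),
                                   n_kept = nrow(dd$kept),
                                   n_removed = nrow(dd$removed))
  })

  contigs <- NULL; assignments <- NULL; flagged_loci <- character(0L)
  if (!is.null(inputs$contigs)) {
    idx <- stage("bin", {
      contigs <- read_fasta(inputs$contigs)
      build_bait_index(read_fasta(inputs$baits), mp)
    })
    stage("bin", {
      if (!is.null(inputs$bins)) {
        bt <- utils::read.delim(inputs$bins, stringsAsFactors = FALSE)
        assignments <- setNames(bt$locus, bt$contig_id)[names(contigs)]
        manifest$stages$bin <- list(n_contigs = length(contigs),
                                     n_assigned = sum(!is.na(assignments)),
                                     source = "precomputed")
      } else {
        ab <- assign_to_bins(contigs, idx, mp)
        assignments <- setNames(ab$scores$locus, ab$scores$seq_id)[names(contigs)]
        manifest$stages$bin <- list(n_contigs = length(contigs),
                                     n_assigned = nrow(ab$scores),
                                     n_unassigned = length(ab$unassigned),
                                     source = "kmer_matcher")
      }
    })
    stage("orthology", {
      ok <- !is.na(assignments)
      verdicts <- screen_orthology(contigs[ok], assignments[ok], idx, mp)
      flagged <- verdicts$contig_id[verdicts$status == "paralog_flagged"]
      flagged_loci <- unique(verdicts$assigned_locus[
        verdicts$status == "paralog_flagged"])
      manifest$stages$orthology <- list(
        n_screened = nrow(verdicts), n_flagged_contigs = length(flagged),
        n_flagged_loci = length(flagged_loci))
      if (!is.null(out_dir))
        utils::write.table(verdicts, file.path(out_dir, "orthology.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  loci <- stage("load_loci", {
    paths <- sort(list.files(inputs$loci_dir, pattern = "\\.(fa|fasta)$",
                             full.names = TRUE))
    if (!length(paths)) stop("no alignments in ", inputs$loci_dir)
    lapply(paths, read_alignment_fasta)
  })
  names(loci) <- vapply(loci, function(a) a$locus_id, character(1L))

  if (!is.null(inputs$groups)) stage("contamination", {
    rep <- screen_cross_contamination(
      loci, read_taxon_groups(inputs$groups),
      screen_params(prm$p_threshold, prm$min_overlap, prm$pct_alarm))
    manifest$stages$contamination <- list(
      n_pairs_tested = nrow(rep$per_pair),
      max_percentage = rep$max_percentage,
      n_alarms = sum(rep$per_pair$alarm))
    if (!is.null(out_dir))
      utils::write.table(rep$per_pair, file.path(out_dir, "contamination.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  })

  selected <- stage("select", {
    fm <- filter_min_taxa(loci, prm$min_taxa)
    small_ids <- vapply(fm$excluded, function(a) a$locus_id, character(1L))
    scored_pool <- fm$kept
    scores <- score_loci(scored_pool,
                         treelikeness_params(prm$max_quartets,
                                             prm$resolution_margin, prm$seed))
    acct <- locus_accounting(scores$locus_id, flagged_loci, small_ids)
    total_taxa <- length(unique(unlist(lapply(loci, function(a)
      names(a$rows)))))
    pool <- scores[scores$locus_id %in% acct$analysed, , drop = FALSE]
    n_sel <- if (is.null(prm$n_select)) nrow(pool)
             else min(prm$n_select, nrow(pool))
    sel <- select_informative(pool, total_taxa, n_sel)
    manifest$stages$select <- list(
      n_loci_input = length(loci), n_below_min_taxa = length(small_ids),
      n_scored = acct$n_scored, n_flagged_orthology = acct$n_flagged,
      n_analysable = acct$n_analysed, n_selected = nrow(sel))
    if (!is.null(out_dir))
      utils::write.table(sel, file.path(out_dir, "selected.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    sel
  })

  stage("concatenate", {
    sm <- concatenate(loci[selected$locus_id])
    st <- matrix_stats(sm)
    manifest$stages$supermatrix <- st
    if (!is.null(out_dir)) {
      write_phylip_relaxed(sm, file.path(out_dir, "supermatrix.phy"))
      write_partition_file(sm, "DNA", file.path(out_dir, "supermatrix.part"))
    }
  })

  if (!is.null(inputs$genetrees) && !is.null(inputs$ref_tree))
    stage("treesupport", {
      res <- internode_certainty(read_newick(inputs$ref_tree)[[1L]],
                                 read_newick(inputs$genetrees),
                                 prm$ica_threshold)
      manifest$stages$treesupport <- list(
        tc = res$tc, relative_tc = res$relative_tc,
        n_internal_branches = res$n_internal_branches)
      if (!is.null(out_dir))
        utils::write.table(res$per_branch, file.path(out_dir, "ic.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  manifest
}
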