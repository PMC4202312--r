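# Table-style summaries, diagnostics, and the end-to-end pipeline driver.

#' One-decimal percentage, half away from zero
#'
#' `100 * part / whole` rounded half-away-from-zero to one decimal — the
#' rounding rule that reproduces one-decimal percentage tables from their
#' printed counts.
#'
#' @param part,whole Counts with `0 <= part <= whole`, `whole > 0`.
#' @return Numeric percentage with one decimal.
#' @export
#' @examples
#' percent(148, 394)  # 37.6
percent <- function(part, whole) {
  .check(all(whole > 0), "whole must be > 0")
  .check(all(part >= 0 & part <= whole), "need 0 <= part <= whole")
  round_half_away(100 * part / whole, 1L)
}

#' Per-class composite and multicomposite summary
#'
#' One row per class value (including the unknown/NA classes) plus a Total
#' row: sequence count, composite count and percentage, multicomposite count
#' and percentage. Multicomposites are a subset of composites and counted in
#' both columns.
#'
#' @param calls Data frame with `seq_id` and `level` (`"composite"` rows and
#'   `"multicomposite"` rows; a multicomposite id may appear at either or
#'   both levels).
#' @param metadata Metadata data frame covering the sequence set.
#' @param classification `"baltimore"`, `"monophyletic"` or `"nucleic_acid"`.
#' @return Data frame of `class`, `n_sequences`, `n_composites`,
#'   `pct_composites`, `n_multicomposites`, `pct_multicomposites`.
#' @export
class_summary <- function(calls, metadata,
                          classification = c("baltimore", "monophyletic",
                                             "nucleic_acid")) {
  classification <- match.arg(classification)
  multis <- unique(calls$seq_id[calls$level == "multicomposite"])
  comps <- unique(c(calls$seq_id[calls$level == "composite"], multis))
  levels_order <- switch(classification,
                         baltimore = BALTIMORE_LEVELS,
                         monophyletic = MONOPHYLETIC_LEVELS,
                         nucleic_acid = NUCLEIC_LEVELS)
  cls <- metadata[[classification]]
  present <- levels_order[levels_order %in% unique(cls)]
  row_for <- function(label, ids) {
    n <- length(ids)
    nc <- sum(ids %in% comps)
    nm <- sum(ids %in% multis)
    data.frame(class = label, n_sequences = n, n_composites = nc,
               pct_composites = if (n > 0) percent(nc, n) else NA_real_,
               n_multicomposites = nm,
               pct_multicomposites = if (n > 0) percent(nm, n) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(present, function(v)
    row_for(v, metadata$seq_id[cls == v]))
  out <- do.call(rbind, c(rows, list(row_for("Total", metadata$seq_id))))
  rownames(out) <- NULL
  out
}

# -log10 E-value with underflowed E-values capped at the double floor, so
# vanishing E-values stay finite for correlation work.
.neg_log10_e <- function(e) {
  pmin(-log10(pmax(e, 1e-320)), 320)
}

#' Hit-length / E-value diagnostics
#'
#' Squared Pearson correlation between `-log10(best E-value)` and the
#' retained hit's alignment length, over all network edges and over the
#' composite-component edges (those supporting at least one passing
#' triplet), plus the length and E-value histograms per group.
#'
#' @param network An `ssn` object.
#' @param evidence Evidence data frame of passing triplets (`b`, `a`, `c`).
#' @return List with `r2_all_edges`, `r2_composite_component_edges`, and
#'   `histograms` (data frame `group`, `variable`, `bin_low`, `bin_high`,
#'   `count`).
#' @export
diagnostics_correlation <- function(network, evidence) {
  stopifnot(inherits(network, "ssn"))
  e <- network$edges
  key <- paste(e$id1, e$id2, sep = "\r")
  cc_keys <- unique(c(.pair_key(evidence$b, evidence$a),
                      .pair_key(evidence$b, evidence$c)))
  in_cc <- key %in% cc_keys
  r2_of <- function(sel, label) {
    .check(sum(sel) >= 3L, "fewer than 3 edges in group '%s'", label)
    x <- e$aln_length[sel]
    y <- .neg_log10_e(e$evalue[sel])
    .check(stats::sd(x) > 0 && stats::sd(y) > 0,
           "degenerate variance in group '%s'", label)
    stats::cor(x, y)^2
  }
  hist_of <- function(v, width) {
    b <- floor(v / width)
    t <- table(b)
    data.frame(bin_low = as.numeric(names(t)) * width,
               bin_high = (as.numeric(names(t)) + 1) * width,
               count = as.integer(t))
  }
  groups <- list(all = rep(TRUE, nrow(e)), composite_component = in_cc)
  hists <- do.call(rbind, lapply(names(groups), function(g) {
    sel <- groups[[g]]
    rbind(
      cbind(group = g, variable = "aln_length",
            hist_of(e$aln_length[sel], 25)),
      cbind(group = g, variable = "neg_log10_evalue",
            hist_of(.neg_log10_e(e$evalue[sel]), 5)))
  }))
  list(r2_all_edges = r2_of(groups$all, "all"),
       r2_composite_component_edges = r2_of(in_cc, "composite_component"),
       histograms = hists)
}

#' Pipeline configuration
#'
#' @param out_dir Output directory for artifacts (created if needed).
#' @param synthetic A [synthetic_config()] (the simulate stage's conditions).
#' @param detection A [detection_params()].
#' @param safest A [safest_params()].
#' @param stages Stages to run, any of `simulate`, `build`, `detect`,
#'   `safest`, `metrics`, `enrich`, `report`. Stages whose prerequisites are
#'   disabled are skipped with a logged notice.
#' @param inputs When `simulate` is disabled: list with paths `fasta`,
#'   `hits`, `metadata`.
#' @param seed Optional master seed; overrides `synthetic$seed` and seeds
#'   the community sweep and pivot sampling.
#' @param k_pivots Pivot count for approximate betweenness on networks with
#'   more than 2000 nodes (exact betweenness is used at or below that size).
#' @param verbose Log stage counts via `message()`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            synthetic = synthetic_config(),
                            detection = detection_params(),
                            safest = safest_params(),
                            stages = c("simulate", "build", "detect",
                                       "safest", "metrics", "enrich",
                                       "report"),
                            inputs = NULL, seed = NULL, k_pivots = 5000L,
                            verbose = TRUE) {
  known <- c("simulate", "build", "detect", "safest", "metrics", "enrich",
             "report")
  .check(all(stages %in% known), "unknown stage name")
  if (!is.null(seed)) synthetic$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, synthetic = synthetic,
                 detection = detection, safest = safest, stages = stages,
                 inputs = inputs, seed = seed %||% synthetic$seed,
                 k_pivots = k_pivots, verbose = verbose),
            class = "pipeline_config")
}

#' Run the composite-gene pipeline end to end
#'
#' Executes simulate, build, detect, safest, metrics, enrich and report as
#' toggled in the configuration, writing TSV/FASTA/GraphML artifacts under
#' `config$out_dir`. All randomness flows from the configured seed, so a
#' rerun with the same configuration reproduces every output byte for byte.
#' Missing required inputs for an enabled stage raise an error before any
#' work is done.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage run
#'   (`dataset`, `network`, `components`, `composites`, `multicomposites`,
#'   `safest`, `metrics`, `enrichment`, `summaries`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  on_stage <- function(s) s %in% config$stages
  # dependency validation before any work
  needs_data <- c("build", "detect", "safest", "metrics", "enrich", "report")
  if (!on_stage("simulate") && any(vapply(needs_data, on_stage, logical(1L)))) {
    .check(!is.null(config$inputs) &&
             all(c("fasta", "hits", "metadata") %in% names(config$inputs)) &&
             all(file.exists(unlist(config$inputs[c("fasta", "hits",
                                                    "metadata")]))),
           "simulate disabled: inputs$fasta, inputs$hits, inputs$metadata must exist")
  }
  enabled <- config$stages
  drop_with_notice <- function(stage, reason) {
    if (stage %in% enabled) {
      .msg(config$verbose, "stage '%s' disabled: %s", stage, reason)
      enabled <<- setdiff(enabled, stage)
    }
  }
  if (!("build" %in% enabled)) {
    for (s in c("detect", "safest", "metrics", "enrich", "report"))
      drop_with_notice(s, "requires the build stage")
  }
  if (!("detect" %in% enabled)) {
    for (s in c("safest", "enrich", "report"))
      drop_with_notice(s, "requires the detect stage")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  res <- list()

  if (on_stage("simulate")) {
    ds <- simulate_dataset(config$synthetic)
    write_fasta(ds$sequences, out("sequences.fasta"))
    write_metadata_table(ds$metadata, out("metadata.tsv"))
    write_blast_tab(ds$hits, out("hits.tsv"))
    write_truth(ds$truth, out("truth.tsv"))
    .msg(config$verbose, "simulate: %d sequences, %d hit rows",
         nrow(ds$sequences), nrow(ds$hits))
  } else {
    seqs <- read_fasta(config$inputs$fasta)
    meta <- read_metadata_table(config$inputs$metadata)
    seqs$genome_id <- meta$genome_id[match(seqs$seq_id, meta$seq_id)]
    ds <- list(sequences = seqs, metadata = meta, truth = NULL,
               hits = read_blast_tab(config$inputs$hits))
  }
  res$dataset <- ds
  if (!("build" %in% enabled)) return(invisible(res))

  net <- build_network(ds$hits, ds$sequences,
                       config$detection$build_threshold)
  cc <- connected_components(net)
  export_network(net, out("network_edges.tsv"), "edgelist")
  .msg(config$verbose,
       "build: %d nodes, %d edges, %d components (>=2), %d singletons",
       nrow(net$nodes), nrow(net$edges), length(cc$components),
       cc$n_singletons)
  res$network <- net
  res$components <- cc

  calls <- NULL
  if ("detect" %in% enabled) {
    calls <- call_composites(net, config$detection, max_evidence = Inf)
    multis <- call_multicomposites(net, calls, config$detection,
                                   max_evidence = Inf)
    f <- calls$funnel
    .msg(config$verbose,
         "detect: funnel %d -> %d -> %d -> %d; %d composites, %d multicomposites",
         f$n_triplets, f$n_nontransitive, f$n_pass_overlap, f$n_pass_all,
         nrow(calls$calls), nrow(multis$calls))
    all_calls <- rbind(calls$calls, multis$calls)
    utils::write.table(all_calls, out("composite_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(calls$evidence, out("triplet_evidence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$composites <- calls
    res$multicomposites <- multis
  }
  if ("safest" %in% enabled) {
    sf <- apply_safest(calls, net, ds$metadata, config$safest)
    .msg(config$verbose, "safest: %d composites, %d multicomposites",
         nrow(sf$composites), nrow(sf$multicomposites))
    safe_tab <- rbind(calls$calls, res$multicomposites$calls)
    safe_tab$safest <- safe_tab$seq_id %in%
      c(sf$composites$seq_id, sf$multicomposites$seq_id)
    utils::write.table(safe_tab, out("composite_calls_safest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$safest <- sf
  }
  if ("metrics" %in% enabled) {
    part <- louvain_first_pass(net, seed = config$seed)
    sg <- community_supergraph(net, part)
    n <- nrow(net$nodes)
    btw <- if (n <= 2000L)
      betweenness_centrality(net, "exact")
    else
      betweenness_centrality(net, "approximate", k_pivots = config$k_pivots,
                             seed = config$seed)
    labels <- stats::setNames(ds$metadata$baltimore, ds$metadata$seq_id)
    labels[labels == "unknown"] <- NA
    assort <- tryCatch(attribute_assortativity(net, labels),
                       error = function(e) NA_real_)
    metrics_tab <- data.frame(
      seq_id = net$nodes$seq_id,
      community = unname(part$membership[net$nodes$seq_id]),
      betweenness = unname(btw[net$nodes$seq_id]),
      composite = net$nodes$seq_id %in% (calls$calls$seq_id %||% character()))
    utils::write.table(metrics_tab, out("node_metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sg$edges, out("community_supergraph.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    contrast <- if (!is.null(calls) && nrow(calls$calls) > 0 &&
                    nrow(calls$calls) < n)
      group_betweenness_contrast(btw, calls) else NULL
    diag <- if (!is.null(calls) && nrow(calls$evidence) >= 3L)
      diagnostics_correlation(net, calls$evidence) else NULL
    if (!is.null(diag))
      utils::write.table(diag$histograms, out("hit_diagnostics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    .msg(config$verbose,
         "metrics: %d communities (Q = %.3f), assortativity %.3f",
         length(unique(part$membership)), part$modularity, assort)
    res$metrics <- list(partition = part, supergraph = sg, betweenness = btw,
                        assortativity_baltimore = assort,
                        per_class_assortativity = tryCatch(
                          per_class_assortativity(net, labels),
                          error = function(e) numeric()),
                        contrast = contrast, diagnostics = diag)
  }
  if ("enrich" %in% enabled) {
    comp_ids <- unique(calls$calls$seq_id)
    other <- setdiff(ds$metadata$seq_id, comp_ids)
    enr <- enrichment_table(comp_ids, other, ds$metadata)
    utils::write.table(enr, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    .msg(config$verbose, "enrich: %d significant categories",
         sum(enr$significant))
    res$enrichment <- enr
  }
  if ("report" %in% enabled) {
    all_calls <- rbind(calls$calls, res$multicomposites$calls %||% NULL)
    sums <- lapply(c(baltimore = "baltimore", monophyletic = "monophyletic",
                     nucleic_acid = "nucleic_acid"), function(cl)
                       class_summary(all_calls, ds$metadata, cl))
    for (nm in names(sums))
      utils::write.table(sums[[nm]], out(sprintf("summary_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    res$summaries <- sums
  }
  invisible(res)
}
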