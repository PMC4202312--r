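# The three additional stringency conditions defining the "safest" composite
# subset: drop triplets whose component is embedded in a same-genome
# composite (overlapping-gene artifacts), drop calls supported only by a
# single triplet whose two components come from one genome (genes split by
# annotation), and drop calls confined to a single genome with no external
# homolog (genes fused by annotation).

#' Parameters for the safest-subset filters
#'
#' @param embedding_coverage_fraction Fraction of a component's length that
#'   the retained hit must cover for the component to count as "embedded" in
#'   the candidate (default 0.95). Embedding is operationalized as sequence
#'   containment; genomic gene coordinates are outside the data model.
#' @return A `safest_params` list.
#' @export
safest_params <- function(embedding_coverage_fraction = 0.95) {
  .check(is.numeric(embedding_coverage_fraction) &&
           embedding_coverage_fraction > 0 && embedding_coverage_fraction <= 1,
         "embedding_coverage_fraction must be in (0, 1]")
  structure(list(embedding_coverage_fraction = embedding_coverage_fraction),
            class = "safest_params")
}

.genome_of <- function(ids, metadata) {
  g <- metadata$genome_id[match(ids, metadata$seq_id)]
  .check(!anyNA(g), "missing genome_id for seq_id '%s'", ids[which(is.na(g))[1L]])
  g
}

# Coverage of `comp` (the component end) by the retained hit on edge
# (cand, comp), as a fraction of the component's length.
.component_coverage <- function(network, cand, comp) {
  e <- network$edges
  r <- match(.pair_key(cand, comp), paste(e$id1, e$id2, sep = "\r"))
  .check(all(!is.na(r)), "edge %s-%s missing from network",
         cand[which(is.na(r))[1L]], comp[which(is.na(r))[1L]])
  on_first <- e$id1[r] == comp
  span <- ifelse(on_first, e$end1[r] - e$start1[r], e$end2[r] - e$start2[r]) + 1L
  len <- network$nodes$length[match(comp, network$nodes$seq_id)]
  span / len
}

#' Flag triplets whose component is embedded in a same-genome composite
#'
#' A supporting triplet is discarded when either component shares its
#' `genome_id` with the candidate and the retained hit covers at least
#' `params$embedding_coverage_fraction` of that component's length
#' (circumventing overlapping-gene annotation artifacts).
#'
#' @param evidence Evidence data frame (`b`, `a`, `c`, ...) as stored on a
#'   `composite_calls` object.
#' @param network The `ssn` the calls were made on.
#' @param metadata Metadata data frame with `seq_id` and `genome_id`.
#' @param params A [safest_params()] object.
#' @return Logical vector, `TRUE` where the triplet is to be discarded.
#' @export
flag_embedded_same_genome <- function(evidence, network, metadata,
                                      params = safest_params()) {
  if (nrow(evidence) == 0L) return(logical())
  gb <- .genome_of(evidence$b, metadata)
  f <- params$embedding_coverage_fraction
  emb <- function(comp) {
    same <- .genome_of(comp, metadata) == gb
    cov <- .component_coverage(network, evidence$b, comp)
    same & cov >= f
  }
  emb(evidence$a) | emb(evidence$c)
}

#' Flag calls supported by a single triplet from a single genome
#'
#' A call is removed when it is found exclusively in one surviving
#' non-transitive triplet whose two component genes come from one genome
#' (false positives from genes artefactually split during annotation).
#' Requires complete (uncapped) evidence.
#'
#' @param calls Calls data frame (`seq_id`, ...).
#' @param evidence Surviving evidence data frame.
#' @param metadata Metadata with `seq_id` and `genome_id`.
#' @return Logical vector along `calls` rows, `TRUE` where removed.
#' @export
flag_single_triplet_single_genome <- function(calls, evidence, metadata) {
  if (nrow(calls) == 0L) return(logical())
  vapply(calls$seq_id, function(id) {
    tr <- evidence[evidence$b == id, , drop = FALSE]
    nrow(tr) == 1L &&
      .genome_of(tr$a, metadata) == .genome_of(tr$c, metadata)
  }, logical(1L), USE.NAMES = FALSE)
}

#' Flag calls confined to one genome without external homologs
#'
#' A call is removed when every network neighbor of the composite shares its
#' `genome_id` (including the degenerate no-neighbor case), i.e. the gene is
#' only found in one host genome without homologs in any other genome.
#'
#' @param calls Calls data frame.
#' @param network The full `ssn`.
#' @param metadata Metadata with `seq_id` and `genome_id`.
#' @return Logical vector along `calls` rows, `TRUE` where removed.
#' @export
flag_no_external_homolog <- function(calls, network, metadata) {
  if (nrow(calls) == 0L) return(logical())
  e <- network$edges
  vapply(calls$seq_id, function(id) {
    nb <- c(e$id2[e$id1 == id], e$id1[e$id2 == id])
    if (length(nb) == 0L) return(TRUE)
    all(.genome_of(nb, metadata) == .genome_of(id, metadata))
  }, logical(1L), USE.NAMES = FALSE)
}

#' Apply the three safest filters and recompute multicomposites
#'
#' Applies, in order: the embedded-same-genome triplet filter (calls losing
#' all their supporting triplets are dropped), the single-triplet
#' single-genome call filter (counted on triplets surviving the first
#' filter), and the no-external-homolog call filter. Multicomposites are
#' then recomputed on the subgraph induced by the safest composites. If the
#' stored evidence was capped, complete evidence is recomputed from the
#' network first.
#'
#' @param composite_calls A `composite_calls` object (level composite).
#' @param network The `ssn` the calls were made on.
#' @param metadata Metadata with `seq_id` and `genome_id`.
#' @param params A [safest_params()] object.
#' @return A list of class `safest_calls`: `composites` and
#'   `multicomposites` (`composite_calls`-style calls data frames),
#'   `evidence` (surviving triplets), and `removed` (data frame `seq_id`,
#'   `filter`).
#' @export
apply_safest <- function(composite_calls, network, metadata,
                         params = safest_params()) {
  stopifnot(inherits(composite_calls, "composite_calls"))
  if (isTRUE(composite_calls$evidence_capped)) {
    composite_calls <- call_composites(network, composite_calls$params,
                                       max_evidence = Inf)
  }
  calls <- composite_calls$calls
  evidence <- composite_calls$evidence
  removed <- data.frame(seq_id = character(), filter = character(),
                        stringsAsFactors = FALSE)
  if (nrow(calls) > 0L) {
    drop_tr <- flag_embedded_same_genome(evidence, network, metadata, params)
    evidence <- evidence[!drop_tr, , drop = FALSE]
    surv <- table(factor(evidence$b, levels = calls$seq_id))
    gone <- calls$seq_id[surv == 0L]
    if (length(gone)) {
      removed <- rbind(removed, data.frame(seq_id = gone,
                                           filter = "embedded_same_genome",
                                           stringsAsFactors = FALSE))
      calls <- calls[surv > 0L, , drop = FALSE]
    }
    calls$n_supporting_triplets <- as.integer(
      table(factor(evidence$b, levels = calls$seq_id)))

    f2 <- flag_single_triplet_single_genome(calls, evidence, metadata)
    if (any(f2)) {
      removed <- rbind(removed, data.frame(
        seq_id = calls$seq_id[f2], filter = "single_triplet_single_genome",
        stringsAsFactors = FALSE))
      calls <- calls[!f2, , drop = FALSE]
    }
    f3 <- flag_no_external_homolog(calls, network, metadata)
    if (any(f3)) {
      removed <- rbind(removed, data.frame(
        seq_id = calls$seq_id[f3], filter = "no_external_homolog",
        stringsAsFactors = FALSE))
      calls <- calls[!f3, , drop = FALSE]
    }
    evidence <- evidence[evidence$b %in% calls$seq_id, , drop = FALSE]
  }
  multis <- if (nrow(calls) >= 3L) {
    sub <- induced_subnetwork(network, calls$seq_id)
    m <- call_composites(sub, composite_calls$params, max_evidence = Inf)
    m$calls$level <- rep("multicomposite", nrow(m$calls))
    m$calls
  } else {
    data.frame(seq_id = character(), level = character(),
               n_supporting_triplets = integer(), stringsAsFactors = FALSE)
  }
  structure(list(composites = calls, multicomposites = multis,
                 evidence = evidence, removed = removed, params = params),
            class = "safest_calls")
}

#' @export
print.safest_calls <- function(x, ...) {
  cat(sprintf("safest subset: %d composite(s), %d multicomposite(s); %d call(s) removed\n",
              nrow(x$composites), nrow(x$multicomposites), nrow(x$removed)))
  invisible(x)
}
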