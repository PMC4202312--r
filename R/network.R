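# Inclusive sequence-similarity network: one node per sequence, one edge per
# unordered pair with at least one hit below the E-value threshold, keeping
# the best hit's statistics and alignment intervals on both endpoints.

#' Build a sequence similarity network from pairwise hits
#'
#' Joins pairs of sequences with an E-value strictly below `threshold`
#' (boundary hits are excluded). The hit table is symmetrized and multiple
#' hits per pair reduced to one edge by keeping the hit with the smallest
#' E-value; ties are broken by higher bitscore, then by the direction whose
#' query id sorts first, so builds are deterministic. Self-hits never become
#' edges. All sequences become nodes, so sequences without any retained edge
#' are kept as singletons.
#'
#' @param hits Data frame of hits as from [read_blast_tab()] or
#'   [emit_truth_hits()].
#' @param sequences Data frame of sequence records with at least `seq_id` and
#'   `length`; a `genome_id` column is carried onto the nodes when present.
#' @param threshold Inclusion E-value threshold (default `1e-5`); an edge
#'   requires `evalue < threshold`.
#' @return An object of class `ssn`: list with `nodes` (seq_id, length,
#'   genome_id), `edges` (id1, id2, evalue, bitscore, start1, end1, start2,
#'   end2, aln_length, with the interval columns in each endpoint's own
#'   1-based inclusive coordinates), and `threshold`.
#' @export
build_network <- function(hits, sequences, threshold = 1e-5) {
  .check(is.numeric(threshold) && threshold > 0, "threshold must be > 0")
  .check(all(c("seq_id", "length") %in% names(sequences)),
         "sequences must have seq_id and length columns")
  .check(!anyDuplicated(sequences$seq_id), "duplicate seq_id in sequences")
  nodes <- data.frame(seq_id = sequences$seq_id,
                      length = as.integer(sequences$length),
                      genome_id = if ("genome_id" %in% names(sequences))
                        sequences$genome_id else NA_character_,
                      stringsAsFactors = FALSE)
  h <- hits[hits$query_id != hits$subject_id & hits$evalue < threshold, ,
            drop = FALSE]
  if (nrow(h) > 0L) {
    known <- c(h$query_id, h$subject_id) %in% nodes$seq_id
    .check(all(known), "hit references unknown seq_id '%s'",
           c(h$query_id, h$subject_id)[which(!known)[1L]])
    swap <- h$query_id > h$subject_id
    e <- data.frame(
      id1 = ifelse(swap, h$subject_id, h$query_id),
      id2 = ifelse(swap, h$query_id, h$subject_id),
      evalue = h$evalue, bitscore = h$bitscore,
      start1 = ifelse(swap, h$s_start, h$q_start),
      end1   = ifelse(swap, h$s_end, h$q_end),
      start2 = ifelse(swap, h$q_start, h$s_start),
      end2   = ifelse(swap, h$q_end, h$s_end),
      aln_length = h$aln_length,
      stringsAsFactors = FALSE)
    key <- paste(e$id1, e$id2, sep = "\r")
    ord <- order(key, e$evalue, -e$bitscore, h$query_id, method = "radix")
    e <- e[ord, , drop = FALSE]
    e <- e[!duplicated(key[ord]), , drop = FALSE]
    len1 <- nodes$length[match(e$id1, nodes$seq_id)]
    len2 <- nodes$length[match(e$id2, nodes$seq_id)]
    .check(all(e$end1 <= len1 & e$end2 <= len2 & e$start1 >= 1 & e$start2 >= 1),
           "hit interval outside sequence bounds")
    rownames(e) <- NULL
  } else {
    e <- data.frame(id1 = character(), id2 = character(), evalue = numeric(),
                    bitscore = numeric(), start1 = integer(), end1 = integer(),
                    start2 = integer(), end2 = integer(),
                    aln_length = integer(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = e, threshold = threshold),
            class = "ssn")
}

#' @export
print.ssn <- function(x, ...) {
  cc <- connected_components(x)
  cat(sprintf(paste0("Sequence similarity network: %d nodes, %d edges ",
                     "(E < %g)\n  %d connected components of size >= 2, ",
                     "%d singletons\n"),
              nrow(x$nodes), nrow(x$edges), x$threshold,
              length(cc$components), cc$n_singletons))
  invisible(x)
}

#' Coerce a similarity network to an igraph graph
#'
#' @param network An `ssn` object.
#' @return An undirected igraph graph with the edge attributes `evalue`,
#'   `bitscore` and `aln_length`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "ssn"))
  igraph::graph_from_data_frame(
    network$edges[, c("id1", "id2", "evalue", "bitscore", "aln_length")],
    directed = FALSE,
    vertices = network$nodes)
}

#' Connected components and singletons of a similarity network
#'
#' Simple-linkage partition of the node set: components of size >= 2
#' (ordered by decreasing size) are reported separately from singletons.
#'
#' @param network An `ssn` object.
#' @return List with `components` (list of character vectors of seq_ids,
#'   decreasing size), `sizes`, `singletons` (character vector) and
#'   `n_singletons`.
#' @export
connected_components <- function(network) {
  stopifnot(inherits(network, "ssn"))
  memb <- igraph::components(as_igraph(network))$membership
  groups <- split(names(memb), memb)
  sizes <- lengths(groups)
  singles <- unlist(groups[sizes == 1L], use.names = FALSE) %||% character()
  comps <- groups[sizes >= 2L]
  ord <- order(lengths(comps), decreasing = TRUE)
  comps <- unname(comps[ord])
  list(components = comps, sizes = lengths(comps),
       singletons = singles, n_singletons = length(singles))
}

#' Induced subnetwork on a set of sequences
#'
#' Keeps the given nodes and every edge whose two endpoints are both kept,
#' with all edge attributes (E-value, bitscore, intervals) retained.
#'
#' @param network An `ssn` object.
#' @param seq_ids Ids of the nodes to keep; must all exist in the network.
#' @return An `ssn` object.
#' @export
induced_subnetwork <- function(network, seq_ids) {
  stopifnot(inherits(network, "ssn"))
  missing <- setdiff(seq_ids, network$nodes$seq_id)
  .check(length(missing) == 0L, "seq_id absent from network: '%s'",
         missing[1L])
  keep_n <- network$nodes$seq_id %in% seq_ids
  keep_e <- network$edges$id1 %in% seq_ids & network$edges$id2 %in% seq_ids
  structure(list(nodes = network$nodes[keep_n, , drop = FALSE],
                 edges = network$edges[keep_e, , drop = FALSE],
                 threshold = network$threshold),
            class = "ssn")
}

# Fast lookup structures for triplet mining: integer node index, per-node
# incident edge lists, and the unordered-pair key set for O(1) adjacency
# tests via hashed %in%.
ssn_index <- function(network) {
  nodes <- network$nodes$seq_id
  e <- network$edges
  i1 <- match(e$id1, nodes)
  i2 <- match(e$id2, nodes)
  n <- length(nodes)
  inc <- vector("list", n)
  if (nrow(e) > 0L) {
    ii <- c(i1, i2)
    ee <- c(seq_len(nrow(e)), seq_len(nrow(e)))
    ord <- order(ii)
    inc <- unname(split(ee[ord], factor(ii[ord], levels = seq_len(n))))
  } else {
    inc <- rep(list(integer()), n)
  }
  list(nodes = nodes, n = n, i1 = i1, i2 = i2,
       incident = inc,
       pair_keys = paste(pmin(i1, i2), pmax(i1, i2)))
}
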