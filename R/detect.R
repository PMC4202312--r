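# Composite and multicomposite gene calling: a candidate is composite when it
# sits at the center of at least one non-transitive triplet whose two edges
# (i) connect otherwise unconnected neighbors, (ii) hit non-overlapping
# regions of the candidate (tolerance in amino acids), and (iii) are both
# well above the twilight zone (stringency E-value). Multicomposites are the
# same search restricted to the subgraph induced by the composites.

#' Detection parameters for composite calling
#'
#' @param build_threshold E-value used to build the network (default `1e-5`);
#'   non-transitivity of a triplet is judged by the absence of the
#'   component-component edge at this inclusive threshold.
#' @param stringency_threshold Twilight-zone guard (default `1e-10`): both
#'   candidate-component edges must have `evalue <` this, so that no
#'   similarity, however weak, links the two components.
#' @param max_overlap Maximum tolerated overlap, in amino acids, between the
#'   two hits on the candidate (default 20; accounts for a local aligner's
#'   tendency to extend a hit slightly past the homologous region).
#' @return A `detection_params` list.
#' @export
detection_params <- function(build_threshold = 1e-5,
                             stringency_threshold = 1e-10,
                             max_overlap = 20) {
  .check(is.numeric(build_threshold) && build_threshold > 0,
         "build_threshold must be > 0")
  .check(is.numeric(stringency_threshold) &&
           stringency_threshold <= build_threshold,
         "stringency_threshold must be <= build_threshold")
  .check(is.numeric(max_overlap) && max_overlap >= 0, "max_overlap must be >= 0")
  structure(list(build_threshold = build_threshold,
                 stringency_threshold = stringency_threshold,
                 max_overlap = max_overlap),
            class = "detection_params")
}

# Interval of the retained hit on node `node_idx` for edge row `erow`.
.interval_on <- function(edges, erow, is_first) {
  if (is_first) c(edges$start1[erow], edges$end1[erow])
  else c(edges$start2[erow], edges$end2[erow])
}

#' Evaluate one candidate-centered triplet
#'
#' Applies the three conditions to the triplet `a - b - c` centered on the
#' candidate `b`: non-transitivity (no `a`-`c` edge in the network), hit
#' overlap on `b` at most `params$max_overlap` amino acids, and both edge
#' E-values below `params$stringency_threshold`.
#'
#' @param network An `ssn` built at `params$build_threshold`.
#' @param b,a,c Sequence ids; edges `b`-`a` and `b`-`c` must exist.
#' @param params A [detection_params()] object.
#' @return A list of class `triplet_evidence` with fields `candidate`, `a`,
#'   `c`, `nontransitive`, `overlap_aa`, `passes_overlap`,
#'   `passes_stringency`, `ev_ba`, `ev_bc` and `passes_all`.
#' @export
evaluate_triplet <- function(network, b, a, c, params = detection_params()) {
  stopifnot(inherits(network, "ssn"))
  .check(!identical(a, c) && !identical(a, b) && !identical(b, c),
         "triplet nodes must be distinct")
  e <- network$edges
  key <- paste(e$id1, e$id2, sep = "\r")
  find_edge <- function(x, y) {
    r <- match(.pair_key(x, y), key)
    .check(!is.na(r), "required edge %s-%s missing from network", x, y)
    r
  }
  r_ba <- find_edge(b, a)
  r_bc <- find_edge(b, c)
  iv_a <- .interval_on(e, r_ba, e$id1[r_ba] == b)
  iv_c <- .interval_on(e, r_bc, e$id1[r_bc] == b)
  overlap <- max(0L, min(iv_a[2L], iv_c[2L]) - max(iv_a[1L], iv_c[1L]) + 1L)
  nontransitive <- is.na(match(.pair_key(a, c), key))
  structure(list(
    candidate = b, a = a, c = c,
    nontransitive = nontransitive,
    overlap_aa = as.integer(overlap),
    passes_overlap = overlap <= params$max_overlap,
    ev_ba = e$evalue[r_ba], ev_bc = e$evalue[r_bc],
    passes_stringency = e$evalue[r_ba] < params$stringency_threshold &&
      e$evalue[r_bc] < params$stringency_threshold,
    passes_all = nontransitive && overlap <= params$max_overlap &&
      e$evalue[r_ba] < params$stringency_threshold &&
      e$evalue[r_bc] < params$stringency_threshold),
    class = "triplet_evidence")
}

#' Call composite genes from a similarity network
#'
#' Enumerates candidate-centered triplets per node (pairs of its neighbors;
#' the all-triples cube is never materialized) and calls a node composite
#' when at least one triplet passes all three conditions. With
#' `funnel = TRUE` (default) all neighbor pairs are visited and the exact
#' count surviving each condition stage, in the order non-transitivity,
#' overlap, stringency, is reported; with `funnel = FALSE` only pairs of
#' stringent neighbors (`evalue < stringency_threshold`) are visited — the
#' calls are identical and the intermediate stage counts that would require
#' non-stringent pairs are `NA`.
#'
#' @param network An `ssn` built at `params$build_threshold`.
#' @param params A [detection_params()] object.
#' @param max_evidence Maximum number of supporting triplets stored per call
#'   (default 50). `n_supporting_triplets` is always the exact count.
#' @param funnel Report the exact per-condition triplet funnel (see above).
#' @return An object of class `composite_calls`: list with `calls`
#'   (data frame `seq_id`, `level`, `n_supporting_triplets`), `evidence`
#'   (data frame `b`, `a`, `c`, `overlap_aa`, `ev_ba`, `ev_bc`), `funnel`
#'   (named list `n_triplets`, `n_nontransitive`, `n_pass_overlap`,
#'   `n_pass_all`), `params`, and `evidence_capped`.
#' @export
call_composites <- function(network, params = detection_params(),
                            max_evidence = 50L, funnel = TRUE) {
  stopifnot(inherits(network, "ssn"))
  .check(inherits(params, "detection_params"), "params must be detection_params")
  .check(isTRUE(all.equal(network$threshold, params$build_threshold)),
         "network was built at threshold %g, params$build_threshold is %g",
         network$threshold, params$build_threshold)
  idx <- ssn_index(network)
  e <- network$edges
  w <- params$max_overlap
  st <- params$stringency_threshold
  n_triplets <- 0; n_nt <- NA_real_; n_ov <- NA_real_; n_all <- 0
  if (funnel) { n_nt <- 0; n_ov <- 0 }
  call_ids <- character(); call_n <- integer()
  ev_list <- list()
  capped <- FALSE
  for (b in seq_len(idx$n)) {
    erows <- idx$incident[[b]]
    k <- length(erows)
    if (k < 2L) next
    n_triplets <- n_triplets + k * (k - 1) / 2
    nb <- ifelse(idx$i1[erows] == b, idx$i2[erows], idx$i1[erows])
    ev <- e$evalue[erows]
    first <- idx$i1[erows] == b
    s_on_b <- ifelse(first, e$start1[erows], e$start2[erows])
    e_on_b <- ifelse(first, e$end1[erows], e$end2[erows])
    if (!funnel) {
      sel <- which(ev < st)
      if (length(sel) < 2L) next
      nb <- nb[sel]; ev <- ev[sel]
      s_on_b <- s_on_b[sel]; e_on_b <- e_on_b[sel]
      k <- length(sel)
    }
    pr <- utils::combn(k, 2L)
    i <- pr[1L, ]; j <- pr[2L, ]
    keys <- paste(pmin(nb[i], nb[j]), pmax(nb[i], nb[j]))
    nt <- !(keys %in% idx$pair_keys)
    ov <- pmax(0L, pmin(e_on_b[i], e_on_b[j]) - pmax(s_on_b[i], s_on_b[j]) + 1L)
    pass_ov <- nt & ov <= w
    pass_all <- pass_ov & ev[i] < st & ev[j] < st
    if (funnel) {
      n_nt <- n_nt + sum(nt)
      n_ov <- n_ov + sum(pass_ov)
    }
    n_pass <- sum(pass_all)
    if (n_pass > 0L) {
      n_all <- n_all + n_pass
      call_ids <- c(call_ids, idx$nodes[b])
      call_n <- c(call_n, n_pass)
      hit <- which(pass_all)
      if (length(hit) > max_evidence) {
        hit <- hit[seq_len(max_evidence)]
        capped <- TRUE
      }
      ev_list[[length(ev_list) + 1L]] <- data.frame(
        b = idx$nodes[b], a = idx$nodes[nb[i[hit]]], c = idx$nodes[nb[j[hit]]],
        overlap_aa = as.integer(ov[hit]),
        ev_ba = ev[i[hit]], ev_bc = ev[j[hit]],
        stringsAsFactors = FALSE)
    }
  }
  evidence <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(b = character(), a = character(), c = character(),
               overlap_aa = integer(), ev_ba = numeric(), ev_bc = numeric(),
               stringsAsFactors = FALSE)
  structure(list(
    calls = data.frame(seq_id = call_ids, level = rep("composite",
                                                      length(call_ids)),
                       n_supporting_triplets = call_n,
                       stringsAsFactors = FALSE),
    evidence = evidence,
    funnel = list(n_triplets = n_triplets, n_nontransitive = n_nt,
                  n_pass_overlap = n_ov, n_pass_all = n_all),
    params = params, evidence_capped = capped),
    class = "composite_calls")
}

#' Call multicomposite genes on the composite-induced subgraph
#'
#' Re-applies the three triplet conditions within the subgraph induced by the
#' sequences already identified as composite (edges and their attributes
#' retained; non-transitivity is judged by absence of the component-component
#' edge in that subgraph).
#'
#' @param network The full `ssn` the composites were called on.
#' @param composite_calls A `composite_calls` object from [call_composites()].
#' @param params The same [detection_params()] used for the first round.
#' @param max_evidence,funnel Passed on to [call_composites()].
#' @return A `composite_calls` object with `level = "multicomposite"`.
#' @export
call_multicomposites <- function(network, composite_calls,
                                 params = detection_params(),
                                 max_evidence = 50L, funnel = TRUE) {
  stopifnot(inherits(composite_calls, "composite_calls"))
  ids <- composite_calls$calls$seq_id
  sub <- induced_subnetwork(network, ids)
  res <- call_composites(sub, params, max_evidence = max_evidence,
                         funnel = funnel)
  res$calls$level <- rep("multicomposite", nrow(res$calls))
  res
}

#' @export
print.composite_calls <- function(x, ...) {
  lv <- unique(x$calls$level) %||% "composite"
  cat(sprintf("%d %s call(s), %d supporting triplet(s) total\n",
              nrow(x$calls), paste(lv, collapse = "/"),
              x$funnel$n_pass_all))
  f <- x$funnel
  cat(sprintf("  triplet funnel: %s total -> %s nontransitive -> %s overlap-ok -> %s stringent\n",
              format(f$n_triplets, big.mark = ","),
              format(f$n_nontransitive, big.mark = ","),
              format(f$n_pass_overlap, big.mark = ","),
              format(f$n_pass_all, big.mark = ",")))
  invisible(x)
}
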