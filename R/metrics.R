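# Network statistics: first-pass Louvain communities, the community
# supergraph with cycle-edge marks, categorical (Newman) assortativity of
# class labels, and shortest-path betweenness (exact, or approximated from
# random pivots) with the composite/non-composite group contrast.

.metric_graph <- function(network) {
  if (inherits(network, "ssn")) as_igraph(network)
  else if (inherits(network, "igraph")) network
  else stop("network must be an 'ssn' or an igraph graph", call. = FALSE)
}

#' First pass of the Louvain community detection algorithm
#'
#' The local-moving phase only, with no hierarchical aggregation: starting
#' from singleton communities, nodes are swept in a seed-shuffled order and
#' each is moved to the neighboring community yielding the largest positive
#' modularity gain (ties broken toward the smallest community id), until a
#' full sweep makes no move. Edges are treated as unweighted.
#'
#' @param network An `ssn` object or igraph graph; must have at least one
#'   node (a network without edges yields the all-singleton partition with
#'   modularity 0).
#' @param seed Integer seed fixing the sweep order.
#' @return A list of class `community_partition`: `membership` (named
#'   integer vector, community ids consecutive from 1) and `modularity`.
#' @export
louvain_first_pass <- function(network, seed = 1L) {
  g <- .metric_graph(network)
  n <- igraph::vcount(g)
  .check(n > 0L, "empty network: no nodes")
  ids <- igraph::V(g)$name %||% as.character(seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  if (m == 0L) {
    memb <- stats::setNames(seq_len(n), ids)
    return(structure(list(membership = memb, modularity = 0),
                     class = "community_partition"))
  }
  adj <- rep(list(integer()), n)
  tab <- split(c(el[, 2L], el[, 1L]),
               factor(c(el[, 1L], el[, 2L]), levels = seq_len(n)))
  adj <- unname(lapply(tab, as.integer))
  deg <- lengths(adj)
  comm <- seq_len(n)
  tot <- as.numeric(deg)   # sum of degrees per community id
  sweep_order <- withr::with_seed(seed, sample.int(n))
  repeat {
    moved <- FALSE
    for (v in sweep_order) {
      nb <- adj[[v]]
      if (length(nb) == 0L) next
      cv <- comm[v]
      tot[cv] <- tot[cv] - deg[v]
      links <- vapply(split(rep(1L, length(nb)), comm[nb]), sum, numeric(1))
      cand <- as.integer(names(links))
      # gain (x 1/m) of joining community C: l_vC/m - deg_v * tot_C / (2 m^2)
      gain <- links / m - deg[v] * tot[cand] / (2 * m * m)
      best <- which(gain > 1e-12)
      if (length(best) > 0L) {
        best <- best[order(-gain[best], cand[best])][1L]
        target <- cand[best]
      } else {
        target <- cv
      }
      if (target != cv) moved <- TRUE
      comm[v] <- target
      tot[target] <- tot[target] + deg[v]
    }
    if (!moved) break
  }
  memb <- match(comm, unique(comm))
  q <- igraph::modularity(g, memb)
  structure(list(membership = stats::setNames(as.integer(memb), ids),
                 modularity = q),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community partition: %d communities over %d nodes, modularity %.4f\n",
              length(unique(x$membership)), length(x$membership),
              x$modularity))
  invisible(x)
}

#' Pool communities into a supergraph and mark cycle edges
#'
#' One supernode per community (with its size); one superedge per community
#' pair with the count of inter-community edges. Each superedge is flagged
#' `in_cycle` when it lies on some cycle of the supergraph, i.e. when it is
#' not a bridge (sequence divergence alone produces trees/chains of
#' communities, never cycles).
#'
#' @param network An `ssn` object or igraph graph.
#' @param partition A `community_partition` (or a named membership vector).
#' @return A list of class `community_supergraph`: `nodes` (data frame
#'   `community`, `size`) and `edges` (data frame `c1`, `c2`, `n_edges`,
#'   `in_cycle`, plus `log_width = 1 + log(n_edges)` as a display attribute).
#' @export
community_supergraph <- function(network, partition) {
  g <- .metric_graph(network)
  memb <- if (inherits(partition, "community_partition"))
    partition$membership else partition
  ids <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  .check(all(ids %in% names(memb)), "partition does not cover all nodes")
  mv <- memb[ids]
  nodes <- data.frame(community = as.integer(sort(unique(mv))),
                      size = as.integer(table(mv)[as.character(sort(unique(mv)))]))
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(c1 = integer(), c2 = integer(), n_edges = integer(),
                      in_cycle = logical(), log_width = numeric())
  if (nrow(el) > 0L) {
    ca <- mv[el[, 1L]]
    cb <- mv[el[, 2L]]
    inter <- ca != cb
    if (any(inter)) {
      lo <- pmin(ca[inter], cb[inter])
      hi <- pmax(ca[inter], cb[inter])
      cnt <- table(paste(lo, hi))
      parts <- strsplit(names(cnt), " ", fixed = TRUE)
      edges <- data.frame(
        c1 = as.integer(vapply(parts, `[`, "", 1L)),
        c2 = as.integer(vapply(parts, `[`, "", 2L)),
        n_edges = as.integer(cnt))
      edges$in_cycle <- cycle_edges(edges, nodes$community)
      edges$log_width <- 1 + log(edges$n_edges)
    }
  }
  structure(list(nodes = nodes, edges = edges),
            class = "community_supergraph")
}

#' Flag edges participating in cycles
#'
#' An edge lies on some cycle if and only if it is not a bridge
#' (equivalently: it belongs to the union of the cycles of any cycle basis).
#'
#' @param x A `community_supergraph`, an igraph graph, or an edge data frame
#'   whose first two columns are the endpoints.
#' @param vertices Optional vertex ids (for the data-frame form, to include
#'   isolated vertices; irrelevant to the flags).
#' @return Logical vector along the edges, `TRUE` for cycle edges.
#' @export
cycle_edges <- function(x, vertices = NULL) {
  g <- if (inherits(x, "community_supergraph")) {
    igraph::graph_from_data_frame(x$edges[, c("c1", "c2")], directed = FALSE,
                                  vertices = as.character(x$nodes$community))
  } else if (inherits(x, "igraph")) {
    x
  } else {
    df <- as.data.frame(x)[, 1:2]
    df[] <- lapply(df, as.character)
    v <- if (is.null(vertices)) unique(unlist(df)) else as.character(vertices)
    igraph::graph_from_data_frame(df, directed = FALSE, vertices = v)
  }
  if (igraph::ecount(g) == 0L) return(logical())
  flags <- rep(TRUE, igraph::ecount(g))
  flags[igraph::bridges(g)] <- FALSE
  flags
}

.edge_labels <- function(network, labels, exclude_unlabeled) {
  e <- if (inherits(network, "ssn")) network$edges[, c("id1", "id2")] else
    stats::setNames(as.data.frame(igraph::as_edgelist(.metric_graph(network))),
                    c("id1", "id2"))
  la <- unname(labels[e$id1])
  lb <- unname(labels[e$id2])
  ok <- !is.na(la) & !is.na(lb)
  if (!exclude_unlabeled)
    .check(all(ok), "unlabeled node on an edge and exclude_unlabeled = FALSE")
  data.frame(la = la[ok], lb = lb[ok], stringsAsFactors = FALSE)
}

#' Newman categorical assortativity of node labels
#'
#' Computes `r = (sum_i e_ii - sum_i a_i b_i) / (1 - sum_i a_i b_i)` over the
#' edge-endpoint mixing matrix, counting each undirected edge in both
#' orientations. `r = 1` means edges only join like-labeled nodes; negative
#' values mean disassortative mixing.
#'
#' @param network An `ssn` object or igraph graph.
#' @param labels Named character vector, `names` = node ids.
#' @param exclude_unlabeled Drop edges with an unlabeled (`NA`) endpoint
#'   (default `TRUE`); with `FALSE`, such edges are an error.
#' @return The assortativity coefficient (length-1 numeric).
#' @export
attribute_assortativity <- function(network, labels, exclude_unlabeled = TRUE) {
  el <- .edge_labels(network, labels, exclude_unlabeled)
  .check(nrow(el) > 0L, "no edge with both endpoints labeled")
  cats <- sort(unique(c(el$la, el$lb)))
  .check(length(cats) > 1L, paste0(
    "assortativity undefined: all labeled edges join nodes of the single ",
    "label '%s' (this is not r = 1, which requires >= 2 labels)"), cats[1L])
  t1 <- table(factor(el$la, cats), factor(el$lb, cats))
  e_mix <- (t1 + t(t1)) / (2 * nrow(el))
  ab <- sum(rowSums(e_mix) * colSums(e_mix))
  (sum(diag(e_mix)) - ab) / (1 - ab)
}

#' Per-class assortativity via binary indicator labels
#'
#' For each class `c`, the assortativity of the indicator labeling (`c` vs
#' not-`c`), the standard construction for class-wise coefficients. Classes
#' absent from every labeled edge endpoint have no edges to evaluate and are
#' omitted from the result.
#'
#' @inheritParams attribute_assortativity
#' @return Named numeric vector, one coefficient per evaluable class.
#' @export
per_class_assortativity <- function(network, labels, exclude_unlabeled = TRUE) {
  el <- .edge_labels(network, labels, exclude_unlabeled)
  .check(nrow(el) > 0L, "no edge with both endpoints labeled")
  out <- numeric()
  for (cl in sort(unique(c(el$la, el$lb)))) {
    ind <- stats::setNames(ifelse(labels == cl, cl, ".other"), names(labels))
    r <- tryCatch(attribute_assortativity(network, ind, exclude_unlabeled),
                  error = function(e) NULL)
    if (!is.null(r)) out[cl] <- r
  }
  out
}

#' Betweenness centrality, exact or pivot-approximated
#'
#' Normalized shortest-path betweenness (endpoints excluded; undirected
#' normalization `2 / ((n-1)(n-2))`). The approximate mode is the random-
#' pivot estimator: single-source dependency accumulation from `k` pivots
#' sampled uniformly without replacement, rescaled by `n/k` — an unbiased
#' estimate that reproduces the exact values when `k = n`.
#'
#' @param network An `ssn` object or igraph graph.
#' @param mode `"exact"` or `"approximate"`.
#' @param k_pivots Number of pivots for the approximate mode (default 5000);
#'   values above the node count are clamped with a notice.
#' @param seed Integer seed for pivot sampling.
#' @param normalized Divide by `(n-1)(n-2)/2` (default `TRUE`).
#' @return Named numeric vector of centralities.
#' @export
betweenness_centrality <- function(network, mode = c("exact", "approximate"),
                                   k_pivots = 5000L, seed = 1L,
                                   normalized = TRUE) {
  mode <- match.arg(mode)
  g <- .metric_graph(network)
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name %||% as.character(seq_len(n))
  if (n < 3L)
    return(stats::setNames(numeric(n), ids))
  if (mode == "exact") {
    b <- igraph::betweenness(g, directed = FALSE, normalized = normalized)
    return(stats::setNames(as.numeric(b), ids))
  }
  .check(k_pivots >= 1L, "k_pivots must be >= 1")
  if (k_pivots > n) {
    message(sprintf("k_pivots = %d exceeds node count %d; clamped to %d",
                    k_pivots, n, n))
    k_pivots <- n
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- rep(list(integer()), n)
  if (nrow(el) > 0L) {
    tab <- split(c(el[, 2L], el[, 1L]),
                 factor(c(el[, 1L], el[, 2L]), levels = seq_len(n)))
    adj <- unname(lapply(tab, as.integer))
  }
  pivots <- withr::with_seed(seed, sample.int(n, k_pivots))
  bc <- numeric(n)
  for (s in pivots) {
    dist <- rep(-1L, n); sigma <- numeric(n)
    preds <- rep(list(integer()), n)
    dist[s] <- 0L; sigma[s] <- 1
    queue <- integer(n); queue[1L] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (v in queue[tail:1L]) {
      for (p in preds[[v]])
        delta[p] <- delta[p] + sigma[p] / sigma[v] * (1 + delta[v])
    }
    delta[s] <- 0
    bc <- bc + delta
  }
  bc <- bc * (n / k_pivots) / 2
  if (normalized) bc <- bc * 2 / ((n - 1) * (n - 2))
  stats::setNames(bc, ids)
}

#' Betweenness contrast between composite and non-composite sequences
#'
#' Arithmetic mean centrality per group and their ratio, reported both to one
#' decimal and as the nearest integer multiple.
#'
#' @param centralities Named numeric vector covering all nodes.
#' @param composite_ids Character vector of composite seq_ids, or a
#'   `composite_calls` object.
#' @return List with `mean_composite`, `mean_noncomposite`, `ratio`,
#'   `ratio_1dp`, `ratio_int`.
#' @export
group_betweenness_contrast <- function(centralities, composite_ids) {
  if (inherits(composite_ids, "composite_calls"))
    composite_ids <- composite_ids$calls$seq_id
  is_comp <- names(centralities) %in% composite_ids
  .check(any(is_comp), "composite group is empty")
  .check(!all(is_comp), "non-composite group is empty")
  mc <- mean(centralities[is_comp])
  mn <- mean(centralities[!is_comp])
  ratio <- mc / mn
  list(mean_composite = mc, mean_noncomposite = mn, ratio = ratio,
       ratio_1dp = round_half_away(ratio, 1L),
       ratio_int = if (is.finite(ratio) && abs(ratio) < .Machine$integer.max)
         as.integer(round_half_away(ratio, 0L)) else NA_integer_)
}
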