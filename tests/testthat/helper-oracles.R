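# Fixture builders and independent oracles used across the suite.

# Build a small similarity network from an edge specification. `edges` is a
# data frame with columns a, b, evalue and optionally sa, ea, sb, eb (the
# hit interval on each endpoint; defaults to [1, 50]).
mk_net <- function(edges, lengths = NULL, threshold = 1e-5,
                   extra_nodes = character()) {
  ids <- unique(c(edges$a, edges$b, extra_nodes))
  if (is.null(lengths)) lengths <- stats::setNames(rep(500L, length(ids)), ids)
  n_e <- nrow(edges)
  if (is.null(edges$sa)) { edges$sa <- rep(1L, n_e); edges$ea <- rep(50L, n_e) }
  if (is.null(edges$sb)) { edges$sb <- rep(1L, n_e); edges$eb <- rep(50L, n_e) }
  hits <- if (n_e == 0L) data.frame(
    query_id = character(), subject_id = character(), pident = numeric(),
    aln_length = integer(), mismatches = integer(), gapopen = integer(),
    q_start = integer(), q_end = integer(), s_start = integer(),
    s_end = integer(), evalue = numeric(), bitscore = numeric(),
    stringsAsFactors = FALSE)
  else data.frame(
    query_id = edges$a, subject_id = edges$b,
    pident = 90, aln_length = pmax(edges$ea - edges$sa, edges$eb - edges$sb) + 1L,
    mismatches = 0L, gapopen = 0L,
    q_start = edges$sa, q_end = edges$ea,
    s_start = edges$sb, s_end = edges$eb,
    evalue = edges$evalue, bitscore = -log10(edges$evalue) * 2,
    stringsAsFactors = FALSE)
  seqs <- data.frame(seq_id = ids, length = unname(lengths[ids]),
                     genome_id = paste0("g_", ids), stringsAsFactors = FALSE)
  build_network(hits, seqs, threshold)
}

# Random similarity network: Erdos-Renyi topology with random stringencies
# and random hit intervals on both endpoints.
random_ssn <- function(n, p = 0.15, seed = 1L, len = 300L,
                       threshold = 1e-5) {
  withr::with_seed(seed, {
    ids <- sprintf("s%02d", seq_len(n))
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < p
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) == 0L)
      return(mk_net(data.frame(a = character(), b = character(),
                               evalue = numeric()), extra_nodes = ids,
                    threshold = threshold))
    ev <- 10^(-stats::runif(nrow(pairs), 6, 30))
    sa <- sample.int(len - 60L, nrow(pairs), replace = TRUE)
    sb <- sample.int(len - 60L, nrow(pairs), replace = TRUE)
    wa <- sample(30:200, nrow(pairs), replace = TRUE)
    wb <- sample(30:200, nrow(pairs), replace = TRUE)
    mk_net(data.frame(a = ids[pairs[, 1L]], b = ids[pairs[, 2L]],
                      evalue = ev,
                      sa = sa, ea = pmin(len, sa + wa),
                      sb = sb, eb = pmin(len, sb + wb),
                      stringsAsFactors = FALSE),
           lengths = stats::setNames(rep(len, n), ids),
           extra_nodes = ids, threshold = threshold)
  })
}

# Adjacency/interval matrices of a network, the representation the brute
# oracles work from.
net_matrices <- function(net) {
  ids <- net$nodes$seq_id
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  EV <- matrix(NA_real_, n, n)
  S <- matrix(NA_integer_, n, n)
  E <- matrix(NA_integer_, n, n)
  e <- net$edges
  i <- match(e$id1, ids); j <- match(e$id2, ids)
  for (r in seq_len(nrow(e))) {
    A[i[r], j[r]] <- A[j[r], i[r]] <- TRUE
    EV[i[r], j[r]] <- EV[j[r], i[r]] <- e$evalue[r]
    S[i[r], j[r]] <- e$start1[r]; E[i[r], j[r]] <- e$end1[r]
    S[j[r], i[r]] <- e$start2[r]; E[j[r], i[r]] <- e$end2[r]
  }
  list(ids = ids, A = A, EV = EV, S = S, E = E)
}

# Brute-force composite calls: every candidate-centered unordered neighbor
# pair, evaluated from the adjacency/interval matrices (vectorized per
# candidate but independent of the package's incident-edge enumeration).
brute_composites <- function(net, params = detection_params()) {
  m <- net_matrices(net)
  n <- length(m$ids)
  out_ids <- character(); out_n <- integer()
  for (b in seq_len(n)) {
    nb <- which(m$A[b, ])
    if (length(nb) < 2L) next
    pass <- 0L
    for (a in nb) for (cc in nb) {
      if (cc <= a) next
      if (m$A[a, cc]) next
      # interval of edge (b, x) on b is S[b, x]..E[b, x]
      ov <- min(m$E[b, a], m$E[b, cc]) - max(m$S[b, a], m$S[b, cc]) + 1L
      if (max(0L, ov) > params$max_overlap) next
      if (m$EV[b, a] >= params$stringency_threshold) next
      if (m$EV[b, cc] >= params$stringency_threshold) next
      pass <- pass + 1L
    }
    if (pass > 0L) { out_ids <- c(out_ids, m$ids[b]); out_n <- c(out_n, pass) }
  }
  data.frame(seq_id = out_ids, n_supporting_triplets = out_n,
             stringsAsFactors = FALSE)
}

# Bridge oracle: an edge is on a cycle iff deleting it leaves the number of
# connected components unchanged.
bridge_removal_cycle_flags <- function(edge_df) {
  g <- igraph::graph_from_data_frame(edge_df[, 1:2], directed = FALSE)
  base <- igraph::count_components(g)
  vapply(seq_len(nrow(edge_df)), function(k)
    igraph::count_components(igraph::delete_edges(g, k)) == base,
    logical(1L))
}

# Exact two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, using binomial coefficients directly.
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  n <- r1 + r2
  denom <- choose(n, c1)
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / denom
  obs <- choose(r1, a) * choose(r2, c1 - a) / denom
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# All set partitions of 1..n as membership vectors (restricted growth
# strings); n must stay tiny.
all_partitions <- function(n) {
  out <- list()
  rec <- function(memb, k) {
    if (length(memb) == n) { out[[length(out) + 1L]] <<- memb; return() }
    for (c in seq_len(k + 1L)) rec(c(memb, c), max(k, c))
  }
  rec(integer(), 0L)
  out
}

# Connected components by iterated neighborhood expansion (transitive
# closure), independent of igraph.
closure_components <- function(net) {
  ids <- net$nodes$seq_id
  comp <- stats::setNames(seq_along(ids), ids)
  e <- net$edges
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(e))) {
      ca <- comp[e$id1[r]]; cb <- comp[e$id2[r]]
      if (ca != cb) {
        comp[comp == max(ca, cb)] <- min(ca, cb)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

default_truth_sets <- function(ds) {
  lv <- ds$truth$levels
  list(composite = lv$seq_id[lv$level %in% c("composite", "multicomposite")],
       multicomposite = lv$seq_id[lv$level == "multicomposite"],
       component = lv$seq_id[lv$level == "component"])
}
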