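# Synthetic gene families with planted fusion events and a ground-truth
# derived hit table. Root families are independent random amino-acid
# strings (unrelated with overwhelming probability); members diverge by
# i.i.d. substitutions and rare geometric-length indels; composites fuse a
# prefix of a fresh member of one family to a suffix of a fresh member of
# another; multicomposites fuse junction-covering parts of two composites.
# Hits are derived from the exact shared-ancestry coordinates under a simple
# Karlin-Altschul-shaped E-value surrogate, so the whole pipeline is
# testable without running an aligner.

#' Configuration for the synthetic gene-family generator
#'
#' @param n_families Number of unrelated root families.
#' @param members_per_family Diverged members generated per family.
#' @param root_length_range Root length range in amino acids.
#' @param substitution_divergence Per-site substitution probability `d` of a
#'   member relative to its root (must be < 0.5).
#' @param indel_rate Per-site indel event rate; lengths are geometric
#'   (mean 2). Kept rare so truth coordinate maps stay piecewise-linear.
#' @param n_composites Planted fusions (prefix of one family + suffix of
#'   another; distinct family pairs).
#' @param n_multicomposites Planted double fusions of two composites with
#'   disjoint family pairs.
#' @param segment_fraction_range Range of the fused prefix/suffix fractions.
#'   Fractions of at least ~0.6 guarantee that two composites reusing a
#'   family share a long stretch of its root, so family reuse produces
#'   either a linking edge or a large overlap instead of spurious triplets.
#' @param n_genomes Genomes to assign round-robin.
#' @param noise_hit_rate Per-unrelated-pair probability of a spurious weak
#'   hit with E-value uniform in `[1e-6, 1e-5)` (just inside the build
#'   threshold, to exercise thresholding). Default 0: at these stringencies
#'   false hits between unrelated sequences are not expected.
#' @param seed Master seed; all generator randomness derives from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_families = 30L, members_per_family = 10L,
                             root_length_range = c(200L, 500L),
                             substitution_divergence = 0.15,
                             indel_rate = 0.01,
                             n_composites = 20L, n_multicomposites = 5L,
                             segment_fraction_range = c(0.6, 0.9),
                             n_genomes = 50L, noise_hit_rate = 0,
                             seed = 42L) {
  .check(n_families >= 1 && members_per_family >= 0 && n_genomes >= 1 &&
           n_composites >= 0 && n_multicomposites >= 0,
         "counts must be non-negative (>= 1 family and genome)")
  .check(substitution_divergence >= 0 && substitution_divergence < 0.5,
         "substitution_divergence must be in [0, 0.5)")
  .check(all(segment_fraction_range > 0 & segment_fraction_range < 1) &&
           diff(segment_fraction_range) >= 0,
         "segment_fraction_range must lie within (0, 1)")
  .check(indel_rate >= 0 && noise_hit_rate >= 0 && noise_hit_rate <= 1,
         "rates must be valid probabilities")
  .check(!(n_composites > 0 && n_families < 2),
         "n_composites > 0 requires n_families >= 2")
  .check(!(n_multicomposites > 0 && n_composites < 2),
         "n_multicomposites > 0 requires n_composites >= 2")
  structure(as.list(environment()), class = "synthetic_config")
}

.pick_other_residue <- function(res) {
  code <- match(res, AA20)
  AA20[((code - 1L + sample.int(19L, length(res), replace = TRUE)) %% 20L) + 1L]
}

# A diverged copy of a root: substitutions at rate d, then indel events at
# rate indel_rate with geometric lengths. Returns residues plus the exact
# root-position map (NA = inserted residue).
.mutate_member <- function(root, d, indel_rate) {
  L <- length(root)
  res <- root
  sub <- which(stats::runif(L) < d)
  if (length(sub)) res[sub] <- .pick_other_residue(res[sub])
  rootpos <- seq_len(L)
  n_ind <- stats::rbinom(1L, L, indel_rate)
  if (n_ind > 0L) {
    at <- sample.int(L, n_ind)
    lens <- stats::rgeom(n_ind, 0.5) + 1L
    is_ins <- stats::runif(n_ind) < 0.5
    ord <- order(at, decreasing = TRUE)
    for (i in ord) {
      if (is_ins[i]) {
        k <- which(!is.na(rootpos) & rootpos <= at[i])
        k <- if (length(k)) max(k) else 0L
        res <- append(res, sample(AA20, lens[i], replace = TRUE), after = k)
        rootpos <- append(rootpos, rep(NA_integer_, lens[i]), after = k)
      } else {
        rm <- which(!is.na(rootpos) & rootpos >= at[i] &
                      rootpos <= at[i] + lens[i] - 1L)
        if (length(rm) && length(rm) < length(res)) {
          res <- res[-rm]
          rootpos <- rootpos[-rm]
        }
      }
    }
  }
  list(res = res, rootpos = rootpos)
}

# Ancestry arrays -> truth segments (maximal co-linear blocks).
.segments_of <- function(seq_id, level, anc) {
  idx <- which(!is.na(anc$family))
  if (length(idx) == 0L)
    return(NULL)
  rp <- anc$rootpos[idx]
  fam <- anc$family[idx]
  brk <- c(TRUE, diff(idx) != 1L | diff(rp) != 1L | diff(fam) != 0L)
  grp <- cumsum(brk)
  first <- idx[!duplicated(grp)]
  last <- idx[rev(!duplicated(rev(grp)))]
  data.frame(seq_id = seq_id, level = level,
             family_id = sprintf("f%02d", anc$family[first]),
             seq_start = first, seq_end = last,
             root_start = anc$rootpos[first], root_end = anc$rootpos[last],
             stringsAsFactors = FALSE)
}

.family_class <- function(fam) {
  balt <- BALTIMORE_LEVELS[((fam - 1L) %% 7L) + 1L]
  data.frame(baltimore = balt,
             monophyletic = as.character(((fam - 1L) %% 5L) + 1L),
             nucleic_acid = ifelse(balt %in% c("I", "II", "VII"),
                                   "DNA", "RNA"),
             stringsAsFactors = FALSE)
}

#' Generate diverged gene families (no fusions yet)
#'
#' Creates `n_families` unrelated uniform-random roots and
#' `members_per_family` diverged members each, assigns genomes round-robin
#' and class labels per family (Baltimore/monophyletic/nucleic-acid cycles,
#' random 1-2 functional-category letters per sequence), and records exact
#' per-sequence ancestry. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_dataset` list: `sequences` (seq_id, genome_id,
#'   length, residues), `metadata`, `truth` (`levels` and `segments` data
#'   frames), `ancestry` (internal coordinate maps), `roots`, `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    F <- config$n_families
    roots <- lapply(seq_len(F), function(i) {
      L <- config$root_length_range[1L] +
        sample.int(diff(config$root_length_range) + 1L, 1L) - 1L
      sample(AA20, L, replace = TRUE)
    })
    ids <- character(); anc <- list(); fam_of <- integer()
    for (f in seq_len(F)) {
      for (k in seq_len(config$members_per_family)) {
        id <- sprintf("f%02d_m%02d", f, k)
        a <- .mutate_member(roots[[f]], config$substitution_divergence,
                            config$indel_rate)
        a$family <- ifelse(is.na(a$rootpos), NA_integer_, f)
        ids <- c(ids, id)
        anc[[id]] <- a
        fam_of <- c(fam_of, f)
      }
    }
    n <- length(ids)
    genomes <- sprintf("g%03d", ((seq_len(n) - 1L) %% config$n_genomes) + 1L)
    sequences <- data.frame(
      seq_id = ids, genome_id = genomes,
      length = vapply(anc, function(a) length(a$res), integer(1L),
                      USE.NAMES = FALSE),
      residues = vapply(anc, function(a) paste(a$res, collapse = ""),
                        character(1L), USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
    cls <- .family_class(fam_of)
    ncat <- sample(1:2, n, replace = TRUE)
    metadata <- data.frame(
      seq_id = ids, genome_id = genomes,
      baltimore = cls$baltimore, monophyletic = cls$monophyletic,
      nucleic_acid = cls$nucleic_acid,
      categories = vapply(ncat, function(k)
        paste(sample(cog_categories(), k), collapse = ""), character(1L)),
      stringsAsFactors = FALSE)
    segs <- do.call(rbind, lapply(ids, function(id)
      .segments_of(id, "component", anc[[id]])))
    truth <- structure(list(
      levels = data.frame(seq_id = ids,
                          level = rep("component", n),
                          stringsAsFactors = FALSE),
      segments = segs %||% .empty_segments()),
      class = "synthetic_truth")
    structure(list(sequences = sequences, metadata = metadata, truth = truth,
                   ancestry = anc, roots = roots, config = config,
                   next_genome = n),
              class = "synthetic_dataset")
  })
}

.empty_segments <- function() {
  data.frame(seq_id = character(), level = character(),
             family_id = character(), seq_start = integer(),
             seq_end = integer(), root_start = integer(),
             root_end = integer(), stringsAsFactors = FALSE)
}

.append_sequence <- function(dataset, id, anc, level, class_fam) {
  cfg <- dataset$config
  dataset$next_genome <- dataset$next_genome + 1L
  genome <- sprintf("g%03d", ((dataset$next_genome - 1L) %% cfg$n_genomes) + 1L)
  dataset$ancestry[[id]] <- anc
  dataset$sequences <- rbind(dataset$sequences, data.frame(
    seq_id = id, genome_id = genome, length = length(anc$res),
    residues = paste(anc$res, collapse = ""), stringsAsFactors = FALSE))
  cls <- .family_class(class_fam)
  dataset$metadata <- rbind(dataset$metadata, data.frame(
    seq_id = id, genome_id = genome,
    baltimore = cls$baltimore, monophyletic = cls$monophyletic,
    nucleic_acid = cls$nucleic_acid,
    categories = paste(sample(cog_categories(), sample(1:2, 1L)),
                       collapse = ""),
    stringsAsFactors = FALSE))
  dataset$truth$levels <- rbind(dataset$truth$levels, data.frame(
    seq_id = id, level = level, stringsAsFactors = FALSE))
  dataset$truth$segments <- rbind(dataset$truth$segments,
                                  .segments_of(id, level, anc))
  dataset
}

#' Plant composite and multicomposite sequences
#'
#' Each composite joins the prefix (fraction `u1`) of a fresh member of one
#' family to the suffix (fraction `u2`) of a fresh member of a different
#' family, the fractions drawn from `segment_fraction_range`; each family
#' pair is used at most once. Each multicomposite joins a junction-covering
#' prefix part of one composite to a junction-covering suffix part of a
#' second composite with a disjoint family pair (so its segments trace to
#' four root families), then diverges by fresh substitutions. Exact junction
#' and segment coordinates are recorded in the truth.
#'
#' @param dataset A `synthetic_dataset` from [generate_dataset()].
#' @return The updated dataset (new sequences, metadata rows, truth entries,
#'   and a `junctions` element giving each planted fusion point).
#' @export
plant_composites <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  cfg <- dataset$config
  if (cfg$n_composites == 0L) return(dataset)
  withr::with_seed(cfg$seed + 1L, {
    F <- cfg$n_families
    all_pairs <- utils::combn(F, 2L)
    .check(cfg$n_composites <= ncol(all_pairs),
           paste0("not enough distinct family pairs for %d composites; ",
                  "raise n_families"), cfg$n_composites)
    # multicomposite parents need composites with disjoint family pairs:
    # reserve 2 per multicomposite over non-overlapping families up front
    n_res <- 2L * cfg$n_multicomposites
    .check(2L * n_res <= F,
           paste0("multicomposite parents need %d families with disjoint ",
                  "pairs; raise n_families"), 2L * n_res)
    pair_mat <- matrix(integer(), nrow = 2L, ncol = 0L)
    if (n_res > 0L)
      pair_mat <- matrix(sample.int(F, 2L * n_res), nrow = 2L)
    if (cfg$n_composites > n_res) {
      key <- function(m) paste(pmin(m[1L, ], m[2L, ]), pmax(m[1L, ], m[2L, ]))
      free <- which(!(key(all_pairs) %in% key(pair_mat)))
      pick <- sample(free, cfg$n_composites - n_res)
      pair_mat <- cbind(pair_mat, all_pairs[, pick, drop = FALSE])
    }
    fr <- cfg$segment_fraction_range
    d <- cfg$substitution_divergence
    junctions <- integer()
    comp_fams <- list()
    for (k in seq_len(cfg$n_composites)) {
      f1 <- pair_mat[1L, k]; f2 <- pair_mat[2L, k]
      m1 <- .mutate_member(dataset$roots[[f1]], d, cfg$indel_rate)
      m2 <- .mutate_member(dataset$roots[[f2]], d, cfg$indel_rate)
      u1 <- stats::runif(1L, fr[1L], fr[2L])
      u2 <- stats::runif(1L, fr[1L], fr[2L])
      n1 <- max(1L, round(u1 * length(m1$res)))
      n2 <- max(1L, round(u2 * length(m2$res)))
      i1 <- seq_len(n1)
      i2 <- seq.int(length(m2$res) - n2 + 1L, length(m2$res))
      anc <- list(res = c(m1$res[i1], m2$res[i2]),
                  rootpos = c(m1$rootpos[i1], m2$rootpos[i2]),
                  family = c(ifelse(is.na(m1$rootpos[i1]), NA_integer_, f1),
                             ifelse(is.na(m2$rootpos[i2]), NA_integer_, f2)))
      id <- sprintf("c%02d", k)
      anc$junction <- n1
      dataset <- .append_sequence(dataset, id, anc, "composite", f1)
      junctions[id] <- n1
      comp_fams[[id]] <- c(f1, f2)
    }
    if (cfg$n_multicomposites > 0L) {
      cids <- names(comp_fams)
      for (k in seq_len(cfg$n_multicomposites)) {
        p1 <- cids[2L * k - 1L]; p2 <- cids[2L * k]
        a1 <- dataset$ancestry[[p1]]; a2 <- dataset$ancestry[[p2]]
        w1 <- stats::runif(1L, fr[1L], fr[2L])
        w2 <- stats::runif(1L, fr[1L], fr[2L])
        j1 <- a1$junction; j2 <- a2$junction
        cut1 <- j1 + round(w1 * (length(a1$res) - j1))   # covers p1's junction
        from2 <- j2 - round(w2 * j2) + 1L                # covers p2's junction
        i1 <- seq_len(cut1)
        i2 <- seq.int(from2, length(a2$res))
        res <- c(a1$res[i1], a2$res[i2])
        sub <- which(stats::runif(length(res)) < d)
        if (length(sub)) res[sub] <- .pick_other_residue(res[sub])
        anc <- list(res = res,
                    rootpos = c(a1$rootpos[i1], a2$rootpos[i2]),
                    family = c(a1$family[i1], a2$family[i2]),
                    junction = cut1)
        id <- sprintf("mc%02d", k)
        dataset <- .append_sequence(dataset, id, anc, "multicomposite",
                                    comp_fams[[p1]][1L])
        junctions[id] <- cut1
        attr(dataset$truth, "parents") <-
          c(attr(dataset$truth, "parents"),
            stats::setNames(list(c(p1, p2)), id))
      }
    }
    dataset$junctions <- junctions
    dataset
  })
}

#' Derive the all-vs-all hit table from planted ancestry
#'
#' For every ordered pair of sequences sharing ancestry on a common
#' family-root interval, emits one hit per maximal shared root interval
#' (short indels are bridged, as a gapped local alignment would): the
#' coordinates are the mapped shared intervals on each sequence, the
#' bitscore is `S = lambda * Lseg * (1 - 2 * d_pair)` clamped at 0 with
#' `d_pair` the realized mismatch fraction over the interval, and
#' `E = min(1, m * n * 2^-S)` for sequence lengths m, n. Pairs with no
#' shared ancestry get no hit, except optional noise hits between random
#' unrelated pairs with E-value uniform in `[1e-6, 1e-5)` at
#' `config$noise_hit_rate`.
#'
#' @param dataset A `synthetic_dataset` (after [plant_composites()]).
#' @param lambda Score scale of the E-value surrogate (default 2.0); the
#'   model only needs to be monotone in segment length and divergence.
#' @return A hit data frame in the layout of [read_blast_tab()].
#' @export
emit_truth_hits <- function(dataset, lambda = 2.0) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  anc <- dataset$ancestry
  ids <- dataset$sequences$seq_id
  lens <- stats::setNames(dataset$sequences$length, ids)
  fams <- sort(unique(unlist(lapply(anc, function(a)
    unique(a$family[!is.na(a$family)])))))
  rows <- list()
  for (f in fams) {
    carriers <- ids[vapply(anc[ids], function(a) f %in% a$family, logical(1L))]
    if (length(carriers) < 2L) next
    Lf <- length(dataset$roots[[f]])
    maps <- lapply(anc[carriers], function(a) {
      m <- rep(NA_integer_, Lf)
      i <- which(!is.na(a$family) & a$family == f)
      m[a$rootpos[i]] <- i
      m
    })
    for (i in seq_len(length(carriers) - 1L)) {
      for (j in seq.int(i + 1L, length(carriers))) {
        A <- carriers[i]; B <- carriers[j]
        shared <- which(!is.na(maps[[i]]) & !is.na(maps[[j]]))
        if (length(shared) == 0L) next
        # One gapped alignment per shared family interval: rare indel holes
        # are bridged, positions present in both sequences score.
        Lseg <- length(shared)
        pa <- maps[[i]][shared]; pb <- maps[[j]][shared]
        mism <- sum(anc[[A]]$res[pa] != anc[[B]]$res[pb])
        d_pair <- mism / Lseg
        S <- max(0, lambda * Lseg * (1 - 2 * d_pair))
        E <- min(1, as.numeric(lens[A]) * as.numeric(lens[B]) * 2^(-S))
        alen <- max(max(pa) - min(pa), max(pb) - min(pb)) + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = c(A, B), subject_id = c(B, A),
          pident = 100 * (1 - d_pair), aln_length = alen,
          mismatches = mism, gapopen = 0L,
          q_start = c(min(pa), min(pb)), q_end = c(max(pa), max(pb)),
          s_start = c(min(pb), min(pa)), s_end = c(max(pb), max(pa)),
          evalue = E, bitscore = S, stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    empty_hits()[, setdiff(names(empty_hits()), "self")]
  if (dataset$config$noise_hit_rate > 0 && length(ids) >= 2L) {
    hits <- rbind(hits, .noise_hits(dataset, lambda))
  }
  hits$self <- hits$query_id == hits$subject_id
  rownames(hits) <- NULL
  hits
}

# Spurious weak hits between unrelated pairs, E-value uniform in [1e-6, 1e-5).
.noise_hits <- function(dataset, lambda) {
  anc <- dataset$ancestry
  ids <- dataset$sequences$seq_id
  lens <- stats::setNames(dataset$sequences$length, ids)
  fam_sets <- lapply(anc[ids], function(a) unique(a$family[!is.na(a$family)]))
  withr::with_seed(dataset$config$seed + 2L, {
    n <- length(ids)
    target <- stats::rbinom(1L, choose(n, 2L), dataset$config$noise_hit_rate)
    out <- list()
    seen <- character()
    tries <- 0L
    while (length(out) < target && tries < 50L * (target + 1L)) {
      tries <- tries + 1L
      ij <- sample.int(n, 2L)
      A <- ids[ij[1L]]; B <- ids[ij[2L]]
      key <- .pair_key(A, B)
      if (key %in% seen) next
      if (length(intersect(fam_sets[[A]], fam_sets[[B]])) > 0L) next
      seen <- c(seen, key)
      E <- stats::runif(1L, 1e-6, 1e-5)
      S <- -log2(E / (as.numeric(lens[A]) * as.numeric(lens[B])))
      w <- 30L
      qs <- sample.int(max(1L, lens[A] - w), 1L)
      ss <- sample.int(max(1L, lens[B] - w), 1L)
      out[[length(out) + 1L]] <- data.frame(
        query_id = A, subject_id = B, pident = 25, aln_length = w,
        mismatches = 22L, gapopen = 0L,
        q_start = qs, q_end = min(lens[A], qs + w - 1L),
        s_start = ss, s_end = min(lens[B], ss + w - 1L),
        evalue = E, bitscore = S, stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else
      empty_hits()[, setdiff(names(empty_hits()), "self")]
  })
}

#' One-call synthetic study: families, fusions and hit table
#'
#' Runs [generate_dataset()], [plant_composites()] and [emit_truth_hits()]
#' under one configuration; byte-identical outputs for identical seeds.
#'
#' @param config A [synthetic_config()].
#' @param lambda E-value model scale, see [emit_truth_hits()].
#' @return The `synthetic_dataset` with an additional `hits` element.
#' @export
simulate_dataset <- function(config = synthetic_config(), lambda = 2.0) {
  dataset <- plant_composites(generate_dataset(config))
  dataset$hits <- emit_truth_hits(dataset, lambda = lambda)
  dataset
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  lv <- table(x$truth$levels$level)
  cat(sprintf("synthetic dataset: %d sequences (%s), %d families, seed %d\n",
              nrow(x$sequences),
              paste(sprintf("%d %s", as.integer(lv), names(lv)),
                    collapse = ", "),
              x$config$n_families, x$config$seed))
  invisible(x)
}

#' Write / read the planted ground truth
#'
#' TSV with columns
#' `seq_id level family_id seq_start seq_end root_start root_end`, one row
#' per ancestry segment; the pair round-trips exactly. An empty truth writes
#' a header-only file.
#'
#' @param truth A `synthetic_truth` object (from a dataset's `truth` field).
#' @param path Output path.
#' @return `path` invisibly for the writer; a `synthetic_truth` for the
#'   reader.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  utils::write.table(truth$segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(rep("character", 3L),
                                         rep("integer", 4L)))
  .check(identical(names(df), names(.empty_segments())),
         "truth header must be '%s'",
         paste(names(.empty_segments()), collapse = " "))
  bad <- which(df$seq_start > df$seq_end | df$root_start > df$root_end |
                 df$seq_start < 1L | df$root_start < 1L)
  .check(length(bad) == 0L, "malformed interval in truth row %d", bad[1L])
  lv <- df[!duplicated(df$seq_id), c("seq_id", "level")]
  rownames(lv) <- NULL
  structure(list(levels = lv, segments = df), class = "synthetic_truth")
}
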