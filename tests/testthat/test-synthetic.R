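small_cfg <- function(...) {
  synthetic_config(n_families = 4L, members_per_family = 3L,
                   root_length_range = c(150L, 250L),
                   n_composites = 2L, n_multicomposites = 0L,
                   n_genomes = 6L, seed = 101L, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_families = 1L, n_composites = 1L,
                                n_multicomposites = 0L),
               "n_families")
  expect_error(synthetic_config(n_composites = 1L, n_multicomposites = 1L),
               "n_composites")
  expect_error(synthetic_config(substitution_divergence = 0.6), "0.5")
  expect_error(synthetic_config(segment_fraction_range = c(0.5, 1.2)),
               "segment_fraction_range")
})

test_that("a fusion-free dataset is all components", {
  cfg <- synthetic_config(n_families = 2L, members_per_family = 3L,
                          n_composites = 0L, n_multicomposites = 0L,
                          n_genomes = 3L, seed = 5L)
  ds <- plant_composites(generate_dataset(cfg))
  expect_equal(nrow(ds$sequences), 6L)
  expect_true(all(ds$truth$levels$level == "component"))
})

test_that("generation is deterministic: same seed, identical outputs", {
  cfg <- small_cfg()
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(d1$metadata, d2$metadata)
  expect_identical(d1$truth$segments, d2$truth$segments)
  expect_identical(d1$hits, d2$hits)
})

test_that("zero divergence and zero indels reproduce the roots exactly", {
  cfg <- synthetic_config(n_families = 3L, members_per_family = 2L,
                          substitution_divergence = 0, indel_rate = 0,
                          n_composites = 0L, n_multicomposites = 0L,
                          n_genomes = 2L, seed = 9L)
  ds <- generate_dataset(cfg)
  for (f in 1:3) {
    root <- paste(ds$roots[[f]], collapse = "")
    members <- ds$sequences$residues[startsWith(ds$sequences$seq_id,
                                                sprintf("f%02d", f))]
    expect_true(all(members == root))
  }
})

test_that("planted composites carry two-family segments with the junction recorded", {
  ds <- plant_composites(generate_dataset(small_cfg()))
  segs <- ds$truth$segments
  for (id in names(ds$junctions)) {
    s <- segs[segs$seq_id == id, ]
    expect_gte(length(unique(s$family_id)), 2L)
    j <- ds$junctions[[id]]
    len <- ds$sequences$length[ds$sequences$seq_id == id]
    # segments before the junction belong to one family, after to the other
    fam_pre <- unique(s$family_id[s$seq_end <= j])
    fam_post <- unique(s$family_id[s$seq_start > j])
    expect_length(fam_pre, 1L)
    expect_length(fam_post, 1L)
    expect_false(fam_pre == fam_post)
    expect_true(all(s$seq_end <= len))
  }
})

test_that("junction position follows the drawn prefix fraction", {
  # wide fraction range exercises the u-dependence of the junction
  cfg <- synthetic_config(n_families = 2L, members_per_family = 2L,
                          segment_fraction_range = c(0.45, 0.55),
                          n_composites = 1L, n_multicomposites = 0L,
                          n_genomes = 2L, seed = 77L)
  ds <- plant_composites(generate_dataset(cfg))
  segs <- ds$truth$segments
  comp <- segs[segs$seq_id == "c01", ]
  j <- ds$junctions[["c01"]]
  pre_fam <- comp$family_id[comp$seq_end <= j][1]
  root_len <- length(ds$roots[[as.integer(sub("f", "", pre_fam))]])
  # the prefix is a ~0.45-0.55 fraction of the donor member (itself close to
  # the root length up to rare indels)
  expect_gt(j / root_len, 0.35)
  expect_lt(j / root_len, 0.65)
})

test_that("multicomposites trace to at least three root families", {
  cfg <- synthetic_config(n_families = 8L, members_per_family = 2L,
                          n_composites = 4L, n_multicomposites = 2L,
                          n_genomes = 5L, seed = 21L)
  ds <- plant_composites(generate_dataset(cfg))
  segs <- ds$truth$segments
  mc <- ds$truth$levels$seq_id[ds$truth$levels$level == "multicomposite"]
  expect_length(mc, 2L)
  for (id in mc)
    expect_gte(length(unique(segs$family_id[segs$seq_id == id])), 3L)
  parents <- attr(ds$truth, "parents")
  expect_length(parents, 2L)
})

test_that("truth-derived hits follow the score model in the undiverged limit", {
  # two identical copies of one root: S = lambda * L, E = m*n*2^-S
  cfg <- synthetic_config(n_families = 1L, members_per_family = 2L,
                          root_length_range = c(300L, 300L),
                          substitution_divergence = 0, indel_rate = 0,
                          n_composites = 0L, n_multicomposites = 0L,
                          n_genomes = 2L, seed = 3L)
  hits <- emit_truth_hits(generate_dataset(cfg))
  expect_equal(nrow(hits), 2L)  # both orientations
  expect_equal(hits$bitscore, c(600, 600))
  expect_equal(hits$evalue, rep(min(1, 300 * 300 * 2^-600), 2L))
  expect_lt(hits$evalue[1], 1e-10)
  expect_equal(hits$q_start[1], 1L)
  expect_equal(hits$q_end[1], 300L)
})

test_that("short highly diverged shared segments produce no usable hit", {
  # hand-built ancestry: 25 shared positions at 44% mismatch -> S small,
  # E clamped at 1 -> never an edge
  res_a <- rep("A", 25L); res_b <- c(rep("C", 11L), rep("A", 14L))
  ds <- structure(list(
    sequences = data.frame(seq_id = c("x", "y"), genome_id = c("g1", "g2"),
                           length = c(25L, 25L),
                           residues = c(paste(res_a, collapse = ""),
                                        paste(res_b, collapse = "")),
                           stringsAsFactors = FALSE),
    ancestry = list(
      x = list(res = res_a, rootpos = 1:25, family = rep(1L, 25L)),
      y = list(res = res_b, rootpos = 1:25, family = rep(1L, 25L))),
    roots = list(rep("A", 25L)),
    config = synthetic_config(n_families = 1L, members_per_family = 2L,
                              n_composites = 0L, n_multicomposites = 0L,
                              n_genomes = 1L, seed = 1L)),
    class = "synthetic_dataset")
  hits <- emit_truth_hits(ds)
  d_pair <- 11 / 25
  expect_equal(hits$bitscore[1], 2 * 25 * (1 - 2 * d_pair))
  expect_equal(hits$evalue[1], 1)  # clamped
  net <- build_network(hits, ds$sequences)
  expect_equal(nrow(net$edges), 0L)
})

test_that("unrelated families share no hits unless noise is enabled", {
  cfg <- synthetic_config(n_families = 3L, members_per_family = 3L,
                          n_composites = 0L, n_multicomposites = 0L,
                          n_genomes = 3L, seed = 13L)
  hits <- emit_truth_hits(generate_dataset(cfg))
  fam <- function(id) sub("_m.*", "", id)
  expect_true(all(fam(hits$query_id) == fam(hits$subject_id)))

  cfg_noise <- synthetic_config(n_families = 3L, members_per_family = 3L,
                                n_composites = 0L, n_multicomposites = 0L,
                                n_genomes = 3L, noise_hit_rate = 0.3,
                                seed = 13L)
  hits_n <- emit_truth_hits(generate_dataset(cfg_noise))
  noise <- hits_n[fam(hits_n$query_id) != fam(hits_n$subject_id), ]
  expect_gt(nrow(noise), 0L)
  expect_true(all(noise$evalue >= 1e-6 & noise$evalue < 1e-5))
})

test_that("planted composites always show the detectable fusion pattern", {
  ds <- simulate_dataset(synthetic_config())
  net <- build_network(ds$hits, ds$sequences)
  segs <- ds$truth$segments
  e <- net$edges
  key <- paste(e$id1, e$id2)
  has_edge <- function(a, b, stringent = FALSE) {
    r <- match(paste(pmin(a, b), pmax(a, b)), key)
    if (is.na(r)) return(FALSE)
    if (stringent) e$evalue[r] < 1e-10 else TRUE
  }
  comp_ids <- ds$truth$levels$seq_id[ds$truth$levels$level == "composite"]
  for (id in comp_ids) {
    fams <- unique(segs$family_id[segs$seq_id == id])
    members <- lapply(fams, function(f) sprintf("%s_m01", f))
    # a stringent edge into each parent family, and no edge between parents
    expect_true(all(vapply(members, function(m) has_edge(id, m, TRUE),
                           logical(1))))
    expect_false(has_edge(members[[1]], members[[2]]))
  }
})

test_that("truth tables round-trip and reject malformed intervals", {
  ds <- plant_composites(generate_dataset(small_cfg()))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(ds$truth, path)
  back <- read_truth(path)
  expect_equal(back$segments, ds$truth$segments, ignore_attr = TRUE)

  empty <- structure(list(levels = ds$truth$levels[0, ],
                          segments = ds$truth$segments[0, ]),
                     class = "synthetic_truth")
  write_truth(empty, path)
  expect_equal(length(readLines(path)), 1L)  # header only
  expect_equal(nrow(read_truth(path)$segments), 0L)

  writeLines(c(paste(names(ds$truth$segments), collapse = "\t"),
               "s1\tcomponent\tf01\t10\t5\t1\t6"), path)
  expect_error(read_truth(path), "malformed interval")
})
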