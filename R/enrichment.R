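# Functional-category composition and enrichment: per-sequence category
# weights (fractional for composition plots, full for count tables) and a
# two-sided Fisher exact test of each category against the combination of
# every other category, with Bonferroni family-wise control.

#' Per-sequence functional-category weights
#'
#' In `fractional` mode a sequence annotated with m categories contributes
#' `1/m` to each (genes assigned to multiple categories are redistributed
#' evenly — the convention for composition plots); in `full` mode it
#' contributes 1 to each (for count tables). Sequences without any category
#' are excluded entirely.
#'
#' @param metadata Data frame with `seq_id` and `categories` (string of
#'   one-letter categories per sequence, possibly empty).
#' @param mode `"fractional"` or `"full"`.
#' @return Data frame `seq_id`, `category`, `weight` (long form).
#' @export
category_weights <- function(metadata, mode = c("fractional", "full")) {
  mode <- match.arg(mode)
  cats <- strsplit(metadata$categories, "", fixed = TRUE)
  m <- lengths(cats)
  keep <- m > 0L
  out <- data.frame(
    seq_id = rep(metadata$seq_id[keep], m[keep]),
    category = unlist(cats[keep], use.names = FALSE),
    stringsAsFactors = FALSE)
  out$weight <- if (mode == "fractional")
    rep(1 / m[keep], m[keep]) else 1
  out
}

# Two-sided Fisher exact p for a 2x2 table: sum of hypergeometric
# probabilities not exceeding the observed table's probability (with the
# customary 1 + 1e-7 relative tolerance for ties).
.fisher_p_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(list(p = 1, degenerate = TRUE))
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= obs * (1 + 1e-7)])
  list(p = min(1, p), degenerate = FALSE)
}

#' Two-sided Fisher exact test of one category between two gene sets
#'
#' Builds the 2x2 table of annotated sequences (rows: set A, set B; columns:
#' carrying the category, carrying only other categories) and computes the
#' exact two-sided p by summing hypergeometric probabilities no larger than
#' the observed table's. When the natural comparison is a subset against its
#' superset (e.g. composites vs the whole data set), pass the complement as
#' `setB` so the table stays well-defined.
#'
#' @param setA,setB Character vectors of seq_ids (disjoint).
#' @param category One-letter category to test.
#' @param metadata Data frame with `seq_id` and `categories`.
#' @param weights_mode Category counting mode (only `"full"` yields integer
#'   tables suitable for the exact test).
#' @return A list of class `enrichment_result`: `category`, `table` (2x2
#'   matrix), `direction` (`"enriched"`/`"depleted"`/`"none"` in set A
#'   relative to set B), `p`, `degenerate`.
#' @export
fisher_category_test <- function(setA, setB, category, metadata,
                                 weights_mode = "full") {
  .check(identical(weights_mode, "full"),
         "the exact test requires weights_mode = 'full'")
  .check(length(intersect(setA, setB)) == 0L,
         "setA and setB must be disjoint (pass the complement, not the superset)")
  w <- category_weights(metadata, "full")
  count <- function(ids) {
    ann <- unique(w$seq_id[w$seq_id %in% ids])
    has <- unique(w$seq_id[w$seq_id %in% ids & w$category == category])
    c(with_cat = length(has), without = length(ann) - length(has))
  }
  ca <- count(setA); cb <- count(setB)
  tab <- matrix(c(ca, cb), nrow = 2L, byrow = TRUE,
                dimnames = list(c("setA", "setB"),
                                c("category", "other_categories")))
  res <- .fisher_p_two_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  pa <- if (sum(tab[1, ]) > 0) tab[1, 1] / sum(tab[1, ]) else NA_real_
  pb <- if (sum(tab[2, ]) > 0) tab[2, 1] / sum(tab[2, ]) else NA_real_
  direction <- if (res$degenerate || is.na(pa) || is.na(pb) || pa == pb)
    "none" else if (pa > pb) "enriched" else "depleted"
  structure(list(category = category, table = tab, direction = direction,
                 p = res$p, degenerate = res$degenerate),
            class = "enrichment_result")
}

#' Category-by-category enrichment table with Bonferroni control
#'
#' One two-sided Fisher exact test per category of the alphabet; a category
#' is flagged significant when `p < alpha / m` with `m` the number of
#' categories tested (computed exactly). Both directions (enrichment and
#' depletion of set A relative to set B) are reported.
#'
#' @param setA,setB Disjoint character vectors of seq_ids.
#' @param metadata Data frame with `seq_id` and `categories`.
#' @param categories Category alphabet (default the 25 letters of
#'   [cog_categories()]).
#' @param alpha Family-wise significance level (default 0.05). The per-test
#'   threshold `alpha / m` can be overridden via `per_test_alpha`.
#' @param per_test_alpha Optional explicit per-test threshold.
#' @return Data frame with one row per category: counts, `direction`, `p`,
#'   `significant`.
#' @export
enrichment_table <- function(setA, setB, metadata,
                             categories = cog_categories(), alpha = 0.05,
                             per_test_alpha = NULL) {
  m <- length(categories)
  .check(m >= 1L, "need at least one category")
  thr <- per_test_alpha %||% (alpha / m)
  rows <- lapply(categories, function(cat) {
    r <- fisher_category_test(setA, setB, cat, metadata)
    data.frame(category = cat,
               a_with = r$table[1, 1], a_without = r$table[1, 2],
               b_with = r$table[2, 1], b_without = r$table[2, 2],
               direction = r$direction, p = r$p,
               significant = !r$degenerate && r$p < thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "per_test_alpha") <- thr
  out
}
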