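# Readers and writers for the standard formats the pipeline touches:
# BLAST tabular (outfmt 6), FASTA, the per-sequence metadata table, and
# network exports (edge list, GraphML). All downstream stages consume the
# plain data frames defined here.

BLAST_TAB_COLS <- c("query_id", "subject_id", "pident", "aln_length",
                    "mismatches", "gapopen", "q_start", "q_end",
                    "s_start", "s_end", "evalue", "bitscore")

METADATA_COLS <- c("seq_id", "genome_id", "baltimore", "monophyletic",
                   "nucleic_acid", "categories")

BALTIMORE_LEVELS <- c("I", "II", "III", "IV", "V", "VI", "VII", "unknown")
MONOPHYLETIC_LEVELS <- c("1", "2", "3", "4", "5", "NA")
NUCLEIC_LEVELS <- c("DNA", "RNA", "unknown")

#' Read an all-vs-all similarity hit table (BLAST tabular, outfmt 6)
#'
#' Parses the 12-column tab-separated layout (qid, sid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore). Extra
#' trailing columns are tolerated and ignored; blank lines are skipped.
#' Self-hits (qid == sid) are kept but flagged in the `self` column, since
#' network construction drops them.
#'
#' @param path Path to the tab-separated hit table.
#' @return A data frame with one row per hit, columns as in the 12-column
#'   layout plus a logical `self` flag. Coordinates are 1-based inclusive.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 12L)
  .check(length(bad) == 0L,
         "malformed hit row at line %d: expected >= 12 tab-separated fields, got %d",
         lineno[bad[1L]], nf[bad[1L]])
  m <- t(vapply(parts, function(p) p[1:12], character(12L)))
  hits <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                     stringsAsFactors = FALSE)
  num_cols <- c(pident = 3L, aln_length = 4L, mismatches = 5L, gapopen = 6L,
                q_start = 7L, q_end = 8L, s_start = 9L, s_end = 10L,
                evalue = 11L, bitscore = 12L)
  for (nm in names(num_cols)) {
    v <- suppressWarnings(as.numeric(m[, num_cols[[nm]]]))
    bad <- which(is.na(v))
    .check(length(bad) == 0L, "non-numeric %s ('%s') at line %d",
           nm, m[bad[1L], num_cols[[nm]]], lineno[bad[1L]])
    hits[[nm]] <- v
  }
  ints <- c("aln_length", "mismatches", "gapopen",
            "q_start", "q_end", "s_start", "s_end")
  for (nm in ints) hits[[nm]] <- as.integer(hits[[nm]])
  bad <- which(hits$q_start > hits$q_end | hits$s_start > hits$s_end)
  .check(length(bad) == 0L, "inverted alignment interval at line %d",
         lineno[bad[1L]])
  bad <- which(hits$evalue < 0)
  .check(length(bad) == 0L, "negative E-value at line %d", lineno[bad[1L]])
  hits$self <- hits$query_id == hits$subject_id
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pident = numeric(), aln_length = integer(),
             mismatches = integer(), gapopen = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             evalue = numeric(), bitscore = numeric(), self = logical(),
             stringsAsFactors = FALSE)
}

#' Write a hit table in BLAST tabular layout
#'
#' @param hits Data frame as returned by [read_blast_tab()] (the `self`
#'   column, if present, is not written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  out <- hits[, BLAST_TAB_COLS, drop = FALSE]
  out$evalue <- formatC(out$evalue, format = "g", digits = 6)
  out$pident <- formatC(out$pident, format = "f", digits = 2)
  out$bitscore <- formatC(out$bitscore, format = "f", digits = 1)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' The header token up to the first whitespace is the sequence id.
#'
#' @param path FASTA file.
#' @return Data frame with columns `seq_id`, `length`, `residues`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  .check(length(dup) == 0L, "duplicate seq_id in FASTA: '%s'", dup[1L])
  w <- Biostrings::width(set)
  .check(all(w > 0L), "empty sequence in FASTA: '%s'", ids[which(w == 0L)[1L]])
  data.frame(seq_id = ids, length = as.integer(w),
             residues = as.character(set), stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records Data frame with `seq_id` and `residues` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  .check(all(c("seq_id", "residues") %in% names(records)),
         "records must have seq_id and residues columns")
  .check(!anyDuplicated(records$seq_id), "duplicate seq_id in records")
  .check(all(nchar(records$residues) > 0L), "empty residue string")
  set <- Biostrings::AAStringSet(records$residues)
  names(set) <- records$seq_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read the per-sequence metadata table
#'
#' Tab-separated with header
#' `seq_id genome_id baltimore monophyletic nucleic_acid categories`.
#' Empty class fields map to the unknown tokens (`unknown` for Baltimore and
#' nucleic acid, `NA` for the monophyletic class); any other undeclared value
#' is rejected. Category letters must come from `alphabet`.
#'
#' @param path Metadata TSV.
#' @param alphabet Declared category alphabet (default [cog_categories()]).
#' @return Data frame keyed by `seq_id` with the metadata columns; the
#'   monophyletic class is kept as character (`"NA"` = unassigned).
#' @export
read_metadata_table <- function(path, alphabet = cog_categories()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          na.strings = NULL, check.names = FALSE)
  .check(identical(names(df), METADATA_COLS),
         "metadata header must be '%s'", paste(METADATA_COLS, collapse = " "))
  dup <- df$seq_id[duplicated(df$seq_id)]
  .check(length(dup) == 0L, "duplicated seq_id in metadata: '%s'", dup[1L])
  df$baltimore[df$baltimore == ""] <- "unknown"
  df$monophyletic[df$monophyletic == ""] <- "NA"
  df$nucleic_acid[df$nucleic_acid == ""] <- "unknown"
  chk <- function(col, levels) {
    bad <- setdiff(unique(df[[col]]), levels)
    .check(length(bad) == 0L, "undeclared %s value: '%s'", col, bad[1L])
  }
  chk("baltimore", BALTIMORE_LEVELS)
  chk("monophyletic", MONOPHYLETIC_LEVELS)
  chk("nucleic_acid", NUCLEIC_LEVELS)
  letters_used <- unique(unlist(strsplit(df$categories, "", fixed = TRUE)))
  bad <- setdiff(letters_used, alphabet)
  .check(length(bad) == 0L, "category letter outside declared alphabet: '%s'",
         bad[1L])
  df
}

#' Write a per-sequence metadata table
#'
#' @param metadata Data frame with the columns of [read_metadata_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata_table <- function(metadata, path) {
  utils::write.table(metadata[, METADATA_COLS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a similarity network for external viewers
#'
#' `edgelist` writes the 3-column `id1 id2 evalue` table (Cytoscape/Gephi
#' importable); `graphml` writes GraphML with edge attributes (evalue,
#' bitscore, aln_length) and any node attributes supplied.
#'
#' @param network An [build_network()] object.
#' @param path Output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @param node_attributes Optional data frame with a `seq_id` column and one
#'   column per attribute (e.g. class labels, composite status, community id);
#'   may cover a subset of nodes.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("edgelist", "graphml"),
                           node_attributes = NULL) {
  stopifnot(inherits(network, "ssn"))
  format <- match.arg(format)
  if (format == "edgelist") {
    out <- network$edges[, c("id1", "id2", "evalue"), drop = FALSE]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    g <- as_igraph(network)
    if (!is.null(node_attributes)) {
      .check("seq_id" %in% names(node_attributes),
             "node_attributes needs a seq_id column")
      i <- match(igraph::V(g)$name, node_attributes$seq_id)
      for (nm in setdiff(names(node_attributes), "seq_id")) {
        v <- node_attributes[[nm]][i]
        if (is.logical(v)) v <- as.integer(v)  # GraphML-safe
        g <- igraph::set_vertex_attr(g, nm, value = v)
      }
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a 3-column edge list written by [export_network()]
#'
#' @param path Edge-list TSV (`id1 id2 evalue`, with header).
#' @return Data frame with columns `id1`, `id2`, `evalue`.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric"))
  .check(identical(names(df), c("id1", "id2", "evalue")),
         "edge list header must be 'id1 id2 evalue'")
  df
}
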