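#' Construct an ortholog map
#'
#' A one-to-one mapping between gene ids of two genomes. No gene may appear
#' in more than one pair; if genomes are supplied, every id must resolve to
#' a locus.
#'
#' @param genome_a,genome_b Genome ids (strings) or [genome_record()]s.
#' @param pairs Data frame with columns `gene_a`, `gene_b`.
#' @return An object of class `ortholog_map`.
#' @export
ortholog_map <- function(genome_a, genome_b, pairs) {
  ga <- if (inherits(genome_a, "genome_record")) genome_a$genome_id else as.character(genome_a)
  gb <- if (inherits(genome_b, "genome_record")) genome_b$genome_id else as.character(genome_b)
  pairs <- data.frame(gene_a = as.character(pairs$gene_a),
                      gene_b = as.character(pairs$gene_b),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(pairs$gene_a) || anyDuplicated(pairs$gene_b)) {
    stop("ortholog map is not one-to-one")
  }
  if (inherits(genome_a, "genome_record") &&
      !all(pairs$gene_a %in% genome_genes(genome_a))) {
    stop("ortholog map references genes absent from genome ", ga)
  }
  if (inherits(genome_b, "genome_record") &&
      !all(pairs$gene_b %in% genome_genes(genome_b))) {
    stop("ortholog map references genes absent from genome ", gb)
  }
  structure(list(genome_a = ga, genome_b = gb, pairs = pairs),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat("ortholog_map:", x$genome_a, "<->", x$genome_b, "-", nrow(x$pairs), "pairs\n")
  invisible(x)
}

#' Identity ortholog map between genomes sharing gene ids
#'
#' Convenience for simulated genomes, whose leaves inherit the ancestral
#' gene ids: orthology is the identity on the shared id set.
#'
#' @param a,b [genome_record()]s.
#' @return An [ortholog_map()].
#' @export
identity_ortholog_map <- function(a, b) {
  shared <- intersect(genome_genes(a), genome_genes(b))
  ortholog_map(a, b, data.frame(gene_a = shared, gene_b = shared,
                                stringsAsFactors = FALSE))
}

#' Read a two-column ortholog TSV
#'
#' @param path TSV with header columns `gene_a`, `gene_b`.
#' @param genome_a,genome_b Genome ids or records the columns belong to.
#' @return An [ortholog_map()].
#' @export
read_ortholog_table <- function(path, genome_a, genome_b) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(tab))) {
    stop("ortholog table must have columns gene_a, gene_b")
  }
  ortholog_map(genome_a, genome_b, tab)
}

#' Write an ortholog map as TSV
#' @param map An [ortholog_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(map, path) {
  utils::write.table(map$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.blast_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a BLAST tabular hit file
#'
#' Accepts the standard 12-column tabular dialect (`-outfmt 6`:
#' qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), headerless.
#'
#' @param path File path.
#' @return Data frame with the standard column names.
#' @export
read_blast_tab <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 12L) stop("expected >= 12 tab-separated columns (outfmt 6)")
  tab <- tab[, 1:12]
  names(tab) <- .blast_cols
  tab
}

# unique best-scoring subject per query; exact bitscore ties disqualify
.best_hits <- function(hits) {
  if (!all(c("qseqid", "sseqid", "bitscore") %in% names(hits))) {
    stop("hit table needs columns qseqid, sseqid, bitscore")
  }
  if (nrow(hits) == 0L) return(character(0))
  key <- paste(hits$qseqid, hits$sseqid, sep = "\r")
  best_hsp <- tapply(hits$bitscore, key, max)
  q <- sub("\r.*", "", names(best_hsp))
  s <- sub(".*\r", "", names(best_hsp))
  sc <- as.numeric(best_hsp)
  top <- tapply(sc, q, max)
  at_top <- sc == top[q]
  n_top <- tapply(at_top, q, sum)
  ok <- at_top & (n_top[q] == 1L)
  stats::setNames(s[ok], q[ok])
}

#' Reciprocal best hit orthologs from tabular similarity hits
#'
#' A pair (a, b) is accepted iff b is the unique best-scoring subject for
#' query a in the A-vs-B table and a is the unique best-scoring subject for
#' query b in the B-vs-A table. "Best" is highest bitscore; an exact tie for
#' the top score disqualifies that query entirely (no pair), a deterministic
#' and conservative rule. Multiple HSPs per (query, subject) are collapsed
#' to their maximum bitscore first.
#'
#' @param hits_ab Hits with queries from genome A, subjects from genome B
#'   (data frame with `qseqid`, `sseqid`, `bitscore`, e.g. from
#'   [read_blast_tab()]).
#' @param hits_ba The reverse direction.
#' @param genome_a,genome_b Genome ids or [genome_record()]s.
#' @return An [ortholog_map()].
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, genome_a = "A", genome_b = "B") {
  ids_a <- union(hits_ab$qseqid, hits_ba$sseqid)
  ids_b <- union(hits_ab$sseqid, hits_ba$qseqid)
  clash <- intersect(ids_a, ids_b)
  if (length(clash)) {
    stop("gene ids appear in both genomes' id spaces: ",
         paste(utils::head(clash, 3), collapse = ", "))
  }
  fwd <- .best_hits(hits_ab)
  rev <- .best_hits(hits_ba)
  a <- names(fwd)
  keep <- !is.na(rev[fwd]) & rev[fwd] == a
  keep[is.na(keep)] <- FALSE
  ortholog_map(genome_a, genome_b,
               data.frame(gene_a = a[keep], gene_b = unname(fwd[keep]),
                          stringsAsFactors = FALSE))
}
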