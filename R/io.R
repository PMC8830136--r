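#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]; sequences are
#' uppercased and gap characters (`-`) are preserved, so both unaligned and
#' aligned FASTA can be read.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write gene features as GFF3
#'
#' Features use the internal 0-based half-open convention and are converted to
#' the 1-based inclusive coordinates of GFF3. Each feature becomes a `gene`
#' line with `ID`, `Name` and `gene_biotype` attributes.
#'
#' @param features data.frame with columns `name`, `start`, `end`, `strand`,
#'   `kind` (CDS/rRNA/tRNA), optionally `copy`.
#' @param seqid sequence identifier for column 1.
#' @param path output path.
#' @param seqlen total sequence length, written as a `##sequence-region`
#'   pragma when given.
#' @export
write_gff3 <- function(features, seqid, path, seqlen = NULL) {
  ids <- features$name
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  attr_col <- sprintf("ID=%s;Name=%s;gene_biotype=%s",
                      ids, features$name, features$kind)
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   seqid, "panplastome", "gene",
                   features$start + 1L, features$end,
                   features$strand, attr_col)
  header <- "##gff-version 3"
  if (!is.null(seqlen)) {
    header <- c(header, sprintf("##sequence-region %s 1 %d", seqid, seqlen))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

## pull one attribute out of a GFF3 column-9 string
gff_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(sprintf("(?:^|;)%s=[^;]*", key), attrs))
  val <- sub(sprintf("^(?:;)?%s=", key), "", m)
  out <- rep(NA_character_, length(attrs))
  out[grepl(sprintf("(?:^|;)%s=", key), attrs)] <- val
  out
}

#' Read gene features from a GFF3 file
#'
#' Gene names are canonicalised through a small alias table (currently
#' psbN/pbf1, which are two names for the same gene). Coordinates are
#' converted to the internal 0-based half-open convention.
#'
#' @param path GFF3 path.
#' @return data.frame with columns `name`, `start`, `end`, `strand`, `kind`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- utils::read.table(text = lines, sep = "\t", quote = "",
                         comment.char = "", stringsAsFactors = FALSE)
  f <- f[f$V3 %in% c("gene", "CDS", "rRNA", "tRNA"), , drop = FALSE]
  if (any(f$V3 == "gene")) f <- f[f$V3 == "gene", , drop = FALSE]
  name <- gff_attr(f$V9, "Name")
  id <- gff_attr(f$V9, "ID")
  name[is.na(name)] <- id[is.na(name)]
  kind <- gff_attr(f$V9, "gene_biotype")
  kind[is.na(kind)] <- "CDS"
  data.frame(name = canonical_gene_name(name),
             start = f$V4 - 1L, end = f$V5,
             strand = f$V7, kind = kind,
             stringsAsFactors = FALSE)
}

## alias table applied at parse time; extend as needed
GENE_ALIASES <- c(pbf1 = "psbN")

#' Canonicalise gene symbols through the alias table
#' @param name character vector of gene symbols.
#' @return canonical symbols (e.g. pbf1 -> psbN).
#' @export
canonical_gene_name <- function(name) {
  hit <- name %in% names(GENE_ALIASES)
  name[hit] <- GENE_ALIASES[name[hit]]
  name
}

#' Write a per-position coverage track as TSV
#'
#' Two columns, 1-based `position` and integer `depth`.
#'
#' @param depth numeric vector of per-position depths.
#' @param path output path.
#' @export
write_coverage_tsv <- function(depth, path) {
  utils::write.table(data.frame(position = seq_along(depth), depth = depth),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a coverage track TSV
#' @param path TSV with columns position, depth.
#' @return numeric depth vector ordered by position.
#' @export
read_coverage_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  d$depth[order(d$position)]
}

## alignment helpers: alignments are character matrices, rows = samples ----

#' Convert named gapped sequences to an alignment matrix
#' @param seqs named character vector, equal-length gapped strings.
#' @return character matrix, one row per sequence.
#' @export
aln_matrix <- function(seqs) {
  if (is.matrix(seqs)) return(seqs)
  stopifnot(length(unique(nchar(seqs))) == 1)
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

#' Convert an alignment matrix back to gapped strings
#' @param mat character matrix.
#' @return named character vector.
#' @export
aln_strings <- function(mat) {
  setNames(apply(mat, 1, paste, collapse = ""), rownames(mat))
}

#' Read an aligned FASTA file as an alignment matrix
#' @param path aligned FASTA.
#' @return character matrix, rows named by record id.
#' @export
read_alignment <- function(path) aln_matrix(read_fasta(path))

#' Write an alignment matrix as aligned FASTA
#' @param mat character matrix.
#' @param path output path.
#' @export
write_alignment <- function(mat, path) write_fasta(aln_strings(mat), path)
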