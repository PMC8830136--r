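#' Circular gene order of an annotated plastome
#'
#' Orders genes by start coordinate and collapses IR-duplicated genes to a
#' single representative copy (the IRa-resident copy when a partition is
#' present, otherwise the first copy by coordinate).
#'
#' @param p a `plastome`.
#' @return character vector of gene symbols in circular order.
#' @export
gene_order <- function(p) {
  f <- p$features[order(p$features$start), , drop = FALSE]
  if (anyDuplicated(f$name)) {
    if (!is.null(p$partition) && iv_len(p$partition$ira) > 0) {
      n <- nchar(p$sequence)
      in_irb <- vapply(seq_len(nrow(f)), function(i)
        circ_contains(p$partition$irb, f$start[i], n), TRUE)
      drop <- in_irb & f$name %in% f$name[duplicated(f$name) | duplicated(f$name, fromLast = TRUE)]
      f <- f[!drop, , drop = FALSE]
    }
    f <- f[!duplicated(f$name), , drop = FALSE]
  }
  f$name
}

#' Gene pairs with conserved microsynteny across all samples
#'
#' Returns the ordered pairs of genes that are adjacent, in the same relative
#' order, in every sample's circular gene order. Adjacency ignores strand:
#' the spacer between two genes exists regardless of their orientations.
#'
#' @param orders named list of circular gene orders (from [gene_order()]);
#'   include outgroup samples here if conservation should extend to them.
#' @return data.frame with columns `a`, `b`, ordered by the position of `a`
#'   in the first sample's order; empty (with a warning) if no pair is
#'   conserved.
#' @export
conserved_adjacent_pairs <- function(orders) {
  if (length(orders) < 2) stop("need >= 2 samples")
  adj_keys <- lapply(orders, function(o) {
    if (length(o) < 2) return(character(0))
    paste(o, c(o[-1], o[1]), sep = "\r")
  })
  common <- Reduce(intersect, adj_keys)
  if (length(common) == 0) {
    warning("no conserved adjacent gene pairs")
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(common, "\r", fixed = TRUE)
  out <- data.frame(a = vapply(parts, `[`, "", 1),
                    b = vapply(parts, `[`, "", 2),
                    stringsAsFactors = FALSE)
  ref <- orders[[1]]
  out[order(match(out$a, ref)), , drop = FALSE]
}

## representative feature of a gene: the IRa copy for duplicated genes
rep_feature <- function(p, gene) {
  f <- p$features[p$features$name == gene, , drop = FALSE]
  if (nrow(f) == 0) stop(sprintf("gene %s absent in %s", gene, p$sample_id))
  if (nrow(f) > 1) {
    if (!is.null(p$partition) && iv_len(p$partition$ira) > 0) {
      n <- nchar(p$sequence)
      in_ira <- vapply(seq_len(nrow(f)), function(i)
        circ_contains(p$partition$ira, f$start[i], n), TRUE)
      if (any(in_ira)) f <- f[in_ira, , drop = FALSE]
    }
    if (nrow(f) > 1) {
      warning(sprintf("gene %s has multiple intervals in %s; using the first",
                      gene, p$sample_id))
      f <- f[1, , drop = FALSE]
    }
  }
  f
}

#' Extract genic and intergenic regions shared across samples
#'
#' Genic regions are the annotated gene intervals (reverse-complemented to
#' coding orientation for minus-strand genes). Intergenic regions are the
#' gaps between microsynteny-conserved adjacent gene pairs. A pair is dropped
#' globally, and recorded in the drop log, when in any sample the two genes
#' overlap, the spacer has zero length, or the gap contains another annotated
#' feature (as happens for the single-copy junction that is bridged by the
#' second IR copy).
#'
#' @param plastomes named list of `plastome`s.
#' @param pairs data.frame from [conserved_adjacent_pairs()].
#' @param reference sample id whose plastome order arranges the keys
#'   (default: first).
#' @return object of class `region_set`: list with `keys` (data.frame
#'   `key`, `kind`, `name`), `sequences` (key -> named character vector by
#'   sample) and `drops` (data.frame `key`, `reason`).
#' @export
extract_regions <- function(plastomes, pairs, reference = names(plastomes)[1]) {
  ref_order <- gene_order(plastomes[[reference]])
  drops <- list()
  seqs <- list()

  for (g in ref_order) {
    key <- paste0("genic:", g)
    cell <- vapply(plastomes, function(p) {
      f <- suppressWarnings(rep_feature(p, g))
      s <- substr(p$sequence, f$start + 1, f$end)
      if (f$strand == "-") revcomp(s) else s
    }, "")
    seqs[[key]] <- cell
  }

  for (r in seq_len(nrow(pairs))) {
    a <- pairs$a[r]; b <- pairs$b[r]
    key <- paste0("intergenic:", a, "-", b)
    cell <- setNames(character(length(plastomes)), names(plastomes))
    reason <- NULL
    for (sid in names(plastomes)) {
      p <- plastomes[[sid]]
      n <- nchar(p$sequence)
      fa <- suppressWarnings(rep_feature(p, a))
      fb <- suppressWarnings(rep_feature(p, b))
      iva <- c(fa$start, fa$end); ivb <- c(fb$start, fb$end)
      if (circ_overlap(iva, ivb, n)) { reason <- "overlap"; break }
      gaplen <- (fb$start - fa$end) %% n
      if (gaplen == 0) { reason <- "zero_length"; break }
      gap <- c(fa$end %% n, fa$end %% n + gaplen)
      others <- p$features[!(p$features$name %in% c(a, b)), , drop = FALSE]
      if (nrow(others) > 0 &&
          any(vapply(others$start, function(s0) circ_contains(gap, s0, n), TRUE))) {
        reason <- "contains_feature"; break
      }
      cell[sid] <- circ_substr(p$sequence, gap[1], gap[2], n)
    }
    if (is.null(reason)) seqs[[key]] <- cell
    else drops[[length(drops) + 1L]] <- data.frame(key = key, reason = reason,
                                                  stringsAsFactors = FALSE)
  }

  ## interleave keys in reference plastome order: gene, following spacer, ...
  ordered_keys <- character(0)
  for (g in ref_order) {
    ordered_keys <- c(ordered_keys, paste0("genic:", g))
    nxt <- pairs$b[pairs$a == g]
    if (length(nxt) == 1) {
      k <- paste0("intergenic:", g, "-", nxt)
      if (k %in% names(seqs)) ordered_keys <- c(ordered_keys, k)
    }
  }
  ordered_keys <- c(ordered_keys, setdiff(names(seqs), ordered_keys))
  seqs <- seqs[ordered_keys]

  keys <- data.frame(key = ordered_keys,
                     kind = sub(":.*$", "", ordered_keys),
                     name = sub("^[a-z]+:", "", ordered_keys),
                     stringsAsFactors = FALSE)
  structure(list(keys = keys, sequences = seqs,
                 drops = if (length(drops)) do.call(rbind, drops) else
                   data.frame(key = character(0), reason = character(0),
                              stringsAsFactors = FALSE),
                 samples = names(plastomes)),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d regions (%d genic, %d intergenic) x %d samples; %d dropped\n",
              nrow(x$keys), sum(x$keys$kind == "genic"),
              sum(x$keys$kind == "intergenic"), length(x$samples),
              nrow(x$drops)))
  invisible(x)
}

#' Harmonize the orientation of one region's sequences across samples
#'
#' Keeps or reverse-complements each sequence so that it shares the larger
#' number of k-mers with the first sample's sequence (the same intent as an
#' aligner's direction-adjustment option). Ties keep the forward orientation.
#'
#' @param seqs named character vector of unaligned sequences (>= 2).
#' @param k kmer size used for the shared-kmer criterion.
#' @return the sequences, consistently stranded.
#' @export
harmonize_orientation <- function(seqs, k = 11L) {
  if (length(seqs) < 2) stop("need >= 2 sequences")
  refk <- unique(seq_kmers(seqs[[1]], k))
  out <- seqs
  for (i in seq_along(seqs)[-1]) {
    fwd <- length(intersect(unique(seq_kmers(seqs[[i]], k)), refk))
    rc <- revcomp(seqs[[i]])
    rev <- length(intersect(unique(seq_kmers(rc, k)), refk))
    if (rev > fwd) out[[i]] <- rc
  }
  out
}

#' Write a region set as per-region multi-FASTA files plus a drop log
#'
#' @param rs a `region_set`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_region_set <- function(rs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(rs$sequences)) {
    fn <- paste0(sub(":", "_", key, fixed = TRUE), ".fasta")
    write_fasta(rs$sequences[[key]], file.path(dir, fn))
  }
  utils::write.table(rs$drops, file.path(dir, "drops.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
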