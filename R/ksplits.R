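#' Build a canonical kmer profile across samples
#'
#' Counts canonical kmers (the lexicographic minimum of a kmer and its
#' reverse complement) per sample and removes kmers whose total count across
#' the whole dataset equals one — a singleton filter that discards
#' unsupported, likely erroneous kmers.
#'
#' @param samples named list/vector of sequences, or a named list of
#'   character vectors (e.g. read sets) per sample.
#' @param k kmer length (default 31).
#' @return object of class `kmer_profile`: list with `k`, `samples` and
#'   `counts`, a data.table (sample, kmer, count).
#' @export
build_profile <- function(samples, k = 31L) {
  if (is.character(samples)) samples <- as.list(samples)
  stopifnot(length(samples) >= 1, !is.null(names(samples)))
  parts <- list()
  for (sid in names(samples)) {
    seqs <- samples[[sid]]
    km <- unlist(lapply(seqs, seq_kmers, k = k), use.names = FALSE)
    if (length(km) == 0) {
      warning(sprintf("sample %s has no sequence of length >= k", sid))
      next
    }
    dt <- data.table::data.table(kmer = canonical_kmers(km))
    dt <- dt[, list(count = .N), by = "kmer"]
    dt[, "sample" := sid]
    parts[[sid]] <- dt
  }
  counts <- data.table::rbindlist(parts)
  if (nrow(counts) > 0) {
    tot <- counts[, list(total = sum(count)), by = "kmer"]
    keep <- tot$kmer[tot$total > 1L]
    counts <- counts[counts$kmer %in% keep, ]
  }
  structure(list(k = k, samples = names(samples), counts = counts),
            class = "kmer_profile")
}

## canonical representation of a split: the side NOT containing the reference
## taxon (the lexicographically smallest label), as a sorted "|"-joined key
split_key <- function(side, taxa) {
  ref <- min(taxa)
  if (ref %in% side) side <- setdiff(taxa, side)
  paste(sort(side), collapse = "|")
}

split_set <- function(taxa, keys, weights) {
  df <- data.frame(key = keys, weight = weights, stringsAsFactors = FALSE)
  df$size <- lengths(strsplit(df$key, "|", fixed = TRUE))
  df <- df[order(-df$weight, df$size, df$key), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(taxa = sort(taxa), splits = df), class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  cat(sprintf("<split_set> %d taxa, %d splits, total weight %.4g\n",
              length(x$taxa), nrow(x$splits), sum(x$splits$weight)))
  invisible(x)
}

#' Infer phylogenetic splits from kmer presence patterns
#'
#' Each kmer's presence pattern — the set of samples containing it — is a
#' candidate bipartition of the sample set. Pattern weights: `count` is the
#' number of distinct kmers sharing the pattern; `geom` sums, over those
#' kmers, the geometric mean of the kmer's counts in the samples carrying
#' it; `geom2` additionally divides each kmer's geometric mean by one plus
#' the mean count in the remaining samples (with presence-defined patterns
#' that mean is zero, so `geom2` coincides with `geom` — kept as a separate
#' option to mirror the robustness comparison it supports). Patterns
#' covering a single sample or all samples are trivial and discarded.
#'
#' @param profile a [build_profile()] result.
#' @param weight_fn `"count"`, `"geom"` or `"geom2"`.
#' @param top `"all"` or `"10n"`: keep only the 10 * n_taxa heaviest splits
#'   (ties at the cutoff are kept).
#' @return a `split_set` ordered by descending weight.
#' @export
infer_splits <- function(profile, weight_fn = c("count", "geom", "geom2"),
                         top = c("all", "10n")) {
  weight_fn <- match.arg(weight_fn)
  top <- match.arg(top)
  taxa <- sort(profile$samples)
  if (length(taxa) < 4) stop("need >= 4 samples for nontrivial splits")
  counts <- profile$counts
  if (nrow(counts) == 0) return(split_set(taxa, character(0), numeric(0)))
  per_kmer <- counts[, list(
    pattern = paste(sort(sample), collapse = "|"),
    n_in = length(sample),
    gmean = exp(mean(log(count)))), by = "kmer"]
  # drop trivial patterns: singleton sides (on either side) and the full set
  per_kmer <- per_kmer[per_kmer$n_in >= 2 & per_kmer$n_in <= length(taxa) - 2L, ]
  if (nrow(per_kmer) == 0) return(split_set(taxa, character(0), numeric(0)))
  # geom2: discount by mean count outside the side (zero here), +1 smoothing
  per_kmer$w <- switch(weight_fn,
                       count = 1,
                       geom = per_kmer$gmean,
                       geom2 = per_kmer$gmean / (1 + 0))
  agg <- per_kmer[, list(weight = sum(w)), by = "pattern"]
  keys <- vapply(strsplit(agg$pattern, "|", fixed = TRUE),
                 split_key, "", taxa = taxa)
  # sides that become trivial after canonicalisation (complement of a
  # singleton) are still nontrivial splits; empty keys cannot occur here
  df <- data.frame(key = keys, weight = agg$weight, stringsAsFactors = FALSE)
  df <- stats::aggregate(weight ~ key, df, sum)
  ss <- split_set(taxa, df$key, df$weight)
  if (top == "10n" && nrow(ss$splits) > 10L * length(taxa)) {
    cutoff <- ss$splits$weight[10L * length(taxa)]
    ss$splits <- ss$splits[ss$splits$weight >= cutoff, , drop = FALSE]
  }
  ss
}

## are two canonical split sides (both excluding the reference taxon)
## compatible, i.e. realizable on one tree? With the reference excluded this
## reduces to: nested or disjoint.
sides_compatible <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0L || i == length(a) || i == length(b)
}

#' Greedy compatible tree from a weighted split set
#'
#' Splits are visited in decreasing weight (ties: smaller side first, then
#' lexicographic key) and accepted when pairwise compatible with everything
#' accepted so far. The accepted set is laminar once sides are expressed
#' relative to a reference taxon, hence tree-realizable; the returned tree
#' carries branch lengths equal to split weights scaled by the total weight.
#'
#' @param splits a `split_set`.
#' @return list with `tree` (`phylo`), `newick`, and `accepted` (the
#'   accepted split keys in acceptance order).
#' @export
strict_tree <- function(splits) {
  taxa <- splits$taxa
  df <- splits$splits
  accepted <- list()
  acc_keys <- character(0)
  for (r in seq_len(nrow(df))) {
    side <- strsplit(df$key[r], "|", fixed = TRUE)[[1]]
    if (all(vapply(accepted, function(a) sides_compatible(a$side, side), TRUE))) {
      accepted[[length(accepted) + 1L]] <- list(side = side,
                                                weight = df$weight[r])
      acc_keys <- c(acc_keys, df$key[r])
    }
  }
  total <- sum(df$weight)
  if (total <= 0) total <- 1
  newick <- laminar_newick(taxa, accepted, total)
  list(tree = ape::read.tree(text = newick), newick = newick,
       accepted = acc_keys)
}

## build newick from a laminar family of clusters (all excluding the
## reference taxon, which hangs off the root)
laminar_newick <- function(taxa, accepted, total) {
  build <- function(members, clusters) {
    # clusters are strict subsets of members; pick the maximal ones
    maximal <- Filter(function(cl) !any(vapply(
      clusters, function(o) length(o$side) > length(cl$side) &&
        all(cl$side %in% o$side), TRUE)), clusters)
    parts <- character(0)
    used <- character(0)
    for (cl in maximal) {
      inner <- Filter(function(o) length(o$side) < length(cl$side) &&
                        all(o$side %in% cl$side), clusters)
      parts <- c(parts, sprintf("%s:%g", build(cl$side, inner),
                                cl$weight / total))
      used <- c(used, cl$side)
    }
    loose <- setdiff(members, used)
    parts <- c(parts, sprintf("%s:0", loose))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(build(taxa, accepted), ";")
}

#' Write a split set as a SplitsTree-readable NEXUS document
#'
#' Emits TAXA and SPLITS blocks; weights are written with six decimals.
#'
#' @param splits a `split_set`.
#' @param path output path; when `NULL` the document is returned as a
#'   character vector.
#' @return the path (invisibly) or the document lines.
#' @export
to_splits_nexus <- function(splits, path = NULL) {
  taxa <- splits$taxa
  n <- length(taxa)
  df <- splits$splits
  idx <- lapply(strsplit(df$key, "|", fixed = TRUE),
                function(side) sort(match(side, taxa)))
  mat_lines <- if (nrow(df) == 0) character(0) else
    sprintf("[%d]\t%.6f\t%s,", seq_len(nrow(df)), df$weight,
            vapply(idx, paste, "", collapse = " "))
  doc <- c("#NEXUS",
           "BEGIN TAXA;",
           sprintf("DIMENSIONS NTAX=%d;", n),
           "TAXLABELS",
           sprintf("[%d] '%s'", seq_len(n), taxa),
           ";",
           "END;",
           "BEGIN SPLITS;",
           sprintf("DIMENSIONS NTAX=%d NSPLITS=%d;", n, nrow(df)),
           "FORMAT LABELS=NO WEIGHTS=YES;",
           "MATRIX",
           mat_lines,
           ";",
           "END;")
  if (is.null(path)) return(doc)
  writeLines(doc, path)
  invisible(path)
}

#' Read a split set from the module's NEXUS representation
#'
#' @param x path or character vector of NEXUS lines as written by
#'   [to_splits_nexus()].
#' @return a `split_set`.
#' @export
read_splits_nexus <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  tl <- grep("^\\[\\d+\\] '", lines)
  taxa <- sub("^\\[\\d+\\] '(.*)'$", "\\1", lines[tl])
  mstart <- grep("^MATRIX$", lines)
  taxa_in_matrix <- grepl("^\\[\\d+\\]\t", lines)
  rows <- lines[taxa_in_matrix & seq_along(lines) > mstart]
  if (length(rows) == 0) return(split_set(taxa, character(0), numeric(0)))
  f <- strsplit(sub(",$", "", rows), "\t")
  weights <- as.numeric(vapply(f, `[`, "", 2))
  keys <- vapply(f, function(p) {
    side <- taxa[as.integer(strsplit(p[3], " ")[[1]])]
    split_key(side, taxa)
  }, "")
  split_set(taxa, keys, weights)
}
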