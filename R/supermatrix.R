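#' Trim alignment columns by gap content and minimum similarity
#'
#' Keeps a column when its non-gap fraction is at least `gap_keep` and its
#' similarity — the frequency of the majority non-gap residue among non-gap
#' residues — is at least `min_similarity`. Defaults follow common practice
#' for plastome supermatrices (gap threshold 0.8, minimum average similarity
#' 0.001).
#'
#' @param aln alignment matrix or named gapped strings.
#' @param gap_keep minimum non-gap fraction per column.
#' @param min_similarity minimum majority-residue frequency per column.
#' @return trimmed alignment matrix (possibly with zero columns).
#' @export
trim_alignment <- function(aln, gap_keep = 0.8, min_similarity = 0.001) {
  m <- aln_matrix(aln)
  keep <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    res <- col[col != "-"]
    nf <- length(res) / length(col)
    if (nf < gap_keep) return(FALSE)
    if (length(res) == 0) return(FALSE)
    sim <- max(table(res)) / length(res)
    sim >= min_similarity
  }, TRUE)
  m[, keep, drop = FALSE]
}

## summary statistics of a concatenated matrix
matrix_summary <- function(m) {
  pats <- unique(apply(m, 2, paste, collapse = ""))
  inv <- vapply(seq_len(ncol(m)), function(j) {
    res <- m[, j]; res <- res[res != "-" & res != "N"]
    length(unique(res)) == 1
  }, TRUE)
  list(n_sites = ncol(m),
       n_site_patterns = length(pats),
       gap_fraction = mean(m == "-"),
       invariant_fraction = if (ncol(m) == 0) NA_real_ else mean(inv))
}

#' Concatenate region alignments into a supermatrix
#'
#' Columns are appended in the order of the input list; the partition map
#' records each region's column interval (0-based half-open). The summary
#' reports alignment sites, distinct site patterns, the gap fraction over
#' all cells and the fraction of invariant columns (columns with a single
#' distinct non-gap, non-N residue).
#'
#' @param alns named list of alignment matrices over the same sample set.
#' @return object of class `supermatrix`: list with `rows`, `mat`,
#'   `partition_map` (data.frame key, start, end) and `summary`.
#' @export
concatenate <- function(alns) {
  stopifnot(length(alns) >= 1)
  rows <- sort(rownames(aln_matrix(alns[[1]])))
  mats <- lapply(names(alns), function(key) {
    m <- aln_matrix(alns[[key]])
    missing <- setdiff(rows, rownames(m))
    extra <- setdiff(rownames(m), rows)
    if (length(missing) || length(extra))
      stop(sprintf("sample-set mismatch in %s: missing [%s], extra [%s]",
                   key, paste(missing, collapse = ","),
                   paste(extra, collapse = ",")))
    m[rows, , drop = FALSE]
  })
  widths <- vapply(mats, ncol, 0L)
  ends <- cumsum(widths)
  pm <- data.frame(key = names(alns), start = ends - widths, end = ends,
                   stringsAsFactors = FALSE)
  mat <- do.call(cbind, mats)
  rownames(mat) <- rows
  structure(list(rows = rows, mat = mat, partition_map = pm,
                 summary = matrix_summary(mat)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<supermatrix> %d samples x %d sites (%d regions); patterns %d; gaps %.2f%%; invariant %.2f%%\n",
              length(x$rows), s$n_sites, nrow(x$partition_map),
              s$n_site_patterns, 100 * s$gap_fraction,
              100 * s$invariant_fraction))
  invisible(x)
}

## strip the first and last codon (start/stop) from a CDS alignment and check
## codon structure on the remaining columns
strip_terminal_codons <- function(m) {
  if (ncol(m) < 9) return(NULL)
  m2 <- m[, 4:(ncol(m) - 3), drop = FALSE]
  if (ncol(m2) %% 3 != 0) return(NULL)
  m2
}

#' Build the five standard supermatrix variants
#'
#' (I) all genic regions, (II) all intergenic regions, (III) protein-coding
#' sequences with start and stop codons removed, (IV) first and second codon
#' positions of (III), (V) third codon positions of (III). A CDS whose
#' alignment length is not a multiple of three after terminal-codon removal
#' cannot be assigned codon positions by column index and is excluded from
#' (III)-(V) with a warning.
#'
#' @param alns named list of alignments (keys `genic:*` / `intergenic:*`),
#'   typically trimmed, used for matrices (I) and (II).
#' @param cds_names gene names (without the `genic:` prefix) annotated as
#'   protein-coding.
#' @param cds_alns alignments used for the codon matrices (III)-(V);
#'   defaults to `alns`, but complete untrimmed CDS alignments should be
#'   supplied when available because column trimming breaks codon structure.
#' @return list with supermatrices `genic`, `intergenic`, `cds`, `pos12`,
#'   `pos3`, and `excluded_cds` (keys dropped from the codon matrices).
#' @export
build_matrices <- function(alns, cds_names, cds_alns = alns) {
  kinds <- sub(":.*$", "", names(alns))
  genic <- alns[kinds == "genic"]
  intergenic <- alns[kinds == "intergenic"]
  cds_keys <- paste0("genic:", cds_names)
  cds_alns <- cds_alns[names(cds_alns) %in% cds_keys]

  stripped <- list()
  excluded <- character(0)
  for (key in names(cds_alns)) {
    m2 <- strip_terminal_codons(aln_matrix(cds_alns[[key]]))
    if (is.null(m2)) excluded <- c(excluded, key) else stripped[[key]] <- m2
  }
  if (length(excluded))
    warning(sprintf("CDS region(s) excluded from codon matrices (length not a multiple of 3): %s",
                    paste(excluded, collapse = ", ")))
  pos12 <- lapply(stripped, function(m) {
    m[, (seq_len(ncol(m)) - 1L) %% 3L != 2L, drop = FALSE]
  })
  pos3 <- lapply(stripped, function(m) {
    m[, (seq_len(ncol(m)) - 1L) %% 3L == 2L, drop = FALSE]
  })
  list(genic = if (length(genic)) concatenate(genic) else NULL,
       intergenic = if (length(intergenic)) concatenate(intergenic) else NULL,
       cds = if (length(stripped)) concatenate(stripped) else NULL,
       pos12 = if (length(pos12)) concatenate(pos12) else NULL,
       pos3 = if (length(pos3)) concatenate(pos3) else NULL,
       excluded_cds = excluded)
}

## do columns of `m` separate samples i and j (differing non-gap/non-N)?
pairs_separated_by <- function(m, unsep_pairs) {
  sep <- logical(nrow(unsep_pairs))
  for (p in seq_len(nrow(unsep_pairs))) {
    a <- m[unsep_pairs[p, 1], ]; b <- m[unsep_pairs[p, 2], ]
    ok <- a != "-" & b != "-" & a != "N" & b != "N"
    sep[p] <- any(a[ok] != b[ok])
  }
  sep
}

#' Select a minimal diagnostic region set
#'
#' Regions are added in order of increasing alignment identity (the most
#' variable first); after each addition every still-unseparated sample pair
#' is tested — a pair is separated when some column of an already selected
#' region carries differing non-gap, non-N residues for the two samples.
#' Selection stops as soon as all pairs are separated.
#'
#' @param alns named list of alignments over a shared sample set.
#' @param identities named numeric vector of per-region identities (same
#'   keys); computed with [percent_identity()] when missing.
#' @return list with `selected` (keys in selection order), `separated`
#'   (logical: all pairs separated) and `unseparated_pairs` (matrix of
#'   sample pairs still identical; empty when separated).
#' @export
select_diagnostic_regions <- function(alns, identities = NULL) {
  if (is.null(identities))
    identities <- vapply(alns, percent_identity, 0)
  ord <- names(alns)[order(identities[names(alns)])] # stable: ties keep input order
  samples <- sort(rownames(aln_matrix(alns[[1]])))
  unsep <- t(utils::combn(samples, 2))
  selected <- character(0)
  for (key in ord) {
    selected <- c(selected, key)
    m <- aln_matrix(alns[[key]])[samples, , drop = FALSE]
    hit <- pairs_separated_by(m, unsep)
    unsep <- unsep[!hit, , drop = FALSE]
    if (nrow(unsep) == 0) break
  }
  list(selected = selected, separated = nrow(unsep) == 0,
       unseparated_pairs = unsep)
}

#' Neighbor-joining tree from a supermatrix
#'
#' Pairwise p-distances ignore columns with a gap or N in either row; the
#' tree is computed with the standard neighbor-joining agglomeration
#' ([ape::nj()]) on rows in label order.
#'
#' @param sm a `supermatrix` (or plain alignment matrix).
#' @return unrooted `phylo` with branch lengths.
#' @export
nj_tree <- function(sm) {
  m <- if (inherits(sm, "supermatrix")) sm$mat else aln_matrix(sm)
  if (nrow(m) < 3) stop("need >= 3 rows")
  m <- m[order(rownames(m)), , drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- m[i, ]; b <- m[j, ]
    ok <- a != "-" & b != "-" & a != "N" & b != "N"
    if (!any(ok)) stop(sprintf("no comparable columns between %s and %s",
                               rownames(m)[i], rownames(m)[j]))
    d[i, j] <- d[j, i] <- mean(a[ok] != b[ok])
  }
  ape::nj(stats::as.dist(d))
}

#' Write a supermatrix as relaxed PHYLIP plus a RAxML-style partition file
#'
#' @param sm a `supermatrix`.
#' @param phylip_path,partition_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_supermatrix <- function(sm, phylip_path = NULL, partition_path = NULL) {
  if (!is.null(phylip_path)) {
    lines <- c(sprintf("%d %d", length(sm$rows), ncol(sm$mat)),
               sprintf("%s  %s", sm$rows, aln_strings(sm$mat)))
    writeLines(lines, phylip_path)
  }
  if (!is.null(partition_path)) {
    pm <- sm$partition_map
    nm <- gsub("[^A-Za-z0-9_]", "_", pm$key)
    writeLines(sprintf("DNA, %s = %d-%d", nm, pm$start + 1L, pm$end),
               partition_path)
  }
  invisible(c(phylip_path, partition_path))
}
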