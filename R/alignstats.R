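## shared column predicates -------------------------------------------------
## A column is conserved iff it contains no gap and all rows carry the same
## nucleotide; N is treated as missing and excluded from the unanimity check
## provided >= 2 non-N residues remain (a column reduced to fewer than two
## informative residues can be neither conserved nor variant).

col_is_conserved <- function(col) {
  if (any(col == "-")) return(FALSE)
  res <- col[col != "N"]
  if (length(res) < 2) return(FALSE)
  all(res == res[1])
}

col_snv_alleles <- function(col) {
  unique(col[col != "-" & col != "N"])
}

#' Alignment identity of a region alignment
#'
#' The fraction of alignment columns in which every row carries the same
#' non-gap nucleotide. Any gap in a column makes it non-conserved; N is
#' missing data. Subsetting `rows` computes the identity with or without
#' outgroup accessions.
#'
#' @param aln alignment matrix (or named gapped strings).
#' @param rows optional row names to subset before computing.
#' @return fraction in [0, 1].
#' @export
percent_identity <- function(aln, rows = NULL) {
  m <- aln_matrix(aln)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  if (nrow(m) < 2) stop("identity undefined for a single-row alignment")
  if (ncol(m) == 0) stop("empty alignment")
  cons <- vapply(seq_len(ncol(m)), function(j) col_is_conserved(m[, j]), TRUE)
  mean(cons)
}

#' Call SNV and InDel events in one region alignment
#'
#' An SNV is an alignment column with at least two distinct non-gap, non-N
#' nucleotides among the rows (one event per column). An InDel event is a
#' maximal run of consecutive gap columns within one row (one event per run,
#' length = run length).
#'
#' @param aln alignment matrix or named gapped strings.
#' @param key region key recorded in the output tables.
#' @return list with `snvs` (data.frame key, column, alleles), `indels`
#'   (data.frame key, sample, start, length; `start` is the 1-based first
#'   gap column), `n_rows` and `length`.
#' @export
call_variants <- function(aln, key = "region") {
  m <- aln_matrix(aln)
  snv_cols <- which(vapply(seq_len(ncol(m)), function(j)
    length(col_snv_alleles(m[, j])) >= 2, TRUE))
  snvs <- data.frame(key = rep(key, length(snv_cols)), column = snv_cols,
                     alleles = vapply(snv_cols, function(j)
                       paste(sort(col_snv_alleles(m[, j])), collapse = "/"), ""),
                     stringsAsFactors = FALSE)
  rows <- rownames(m) %||% paste0("row", seq_len(nrow(m)))
  ind <- list()
  for (i in seq_len(nrow(m))) {
    r <- rle(m[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gp <- which(r$values)
    for (g in gp) {
      ind[[length(ind) + 1L]] <- data.frame(
        key = key, sample = rows[i], start = starts[g],
        length = r$lengths[g], stringsAsFactors = FALSE)
    }
  }
  indels <- if (length(ind)) do.call(rbind, ind) else
    data.frame(key = character(0), sample = character(0),
               start = integer(0), length = integer(0),
               stringsAsFactors = FALSE)
  list(snvs = snvs, indels = indels, n_rows = nrow(m), length = ncol(m))
}

#' Variant table over a set of region alignments
#'
#' Calls variants per region and computes normalized densities: event count
#' divided by the alignment length and by the number of rows
#' (species/accessions).
#'
#' @param alns named list of alignments (names = region keys).
#' @param classes optional named vector mapping keys to `genic`/`intergenic`;
#'   defaults to the prefix of the key.
#' @return object of class `variant_table`: list with `snvs`, `indels` and
#'   `densities` (data.frame key, class, length, n_rows, snv_count,
#'   indel_count, snv_density, indel_density, in input key order).
#' @export
variant_table <- function(alns, classes = NULL) {
  if (is.null(classes))
    classes <- setNames(sub(":.*$", "", names(alns)), names(alns))
  snvs <- list(); indels <- list(); dens <- list()
  for (key in names(alns)) {
    v <- call_variants(alns[[key]], key)
    snvs[[key]] <- v$snvs
    indels[[key]] <- v$indels
    dens[[key]] <- data.frame(
      key = key, class = unname(classes[key]), length = v$length,
      n_rows = v$n_rows, snv_count = nrow(v$snvs),
      indel_count = nrow(v$indels),
      snv_density = nrow(v$snvs) / v$length / v$n_rows,
      indel_density = nrow(v$indels) / v$length / v$n_rows,
      stringsAsFactors = FALSE)
  }
  structure(list(snvs = do.call(rbind, unname(snvs)),
                 indels = do.call(rbind, unname(indels)),
                 densities = do.call(rbind, unname(dens))),
            class = "variant_table")
}

#' Reading-frame analysis of indel lengths
#'
#' Compares the proportion of frame-preserving indels (length a multiple of
#' three) between genic and intergenic regions with a two-sided Fisher exact
#' test. Frame-preserving indels are expected to be enriched in genes, where
#' a frame-shifting indel would disrupt the protein.
#'
#' @param indels data.frame with columns `length` and `class`
#'   (genic/intergenic), e.g. the `indels` of a [variant_table()] joined with
#'   its `densities$class`, or simulator truth.
#' @return list with `prop_genic_mod3`, `prop_intergenic_mod3`, `table`
#'   (2x2: class x mod3), `p_value` (NA with a warning when a class is
#'   empty).
#' @export
frame_analysis <- function(indels) {
  mod3 <- indels$length %% 3 == 0
  cls <- factor(indels$class, levels = c("genic", "intergenic"))
  tab <- table(class = cls, mod3 = factor(mod3, levels = c(TRUE, FALSE)))
  prop <- function(w) {
    n <- sum(tab[w, ])
    if (n == 0) NA_real_ else tab[w, "TRUE"] / n
  }
  pg <- prop("genic"); pi_ <- prop("intergenic")
  if (any(rowSums(tab) == 0)) {
    warning("a region class has no indels; exact test skipped")
    p <- NA_real_
  } else {
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
  list(prop_genic_mod3 = pg, prop_intergenic_mod3 = pi_,
       table = tab, p_value = p)
}

#' Genic vs intergenic identity contrast
#'
#' Class means and a two-sided Wilcoxon rank-sum (Mann-Whitney U) test on
#' per-region alignment identities.
#'
#' @param genic,intergenic numeric vectors of per-region identities (>= 2
#'   values each).
#' @return list with `mean_genic`, `mean_intergenic`, `p_value`.
#' @export
identity_contrast <- function(genic, intergenic) {
  if (length(genic) < 2 || length(intergenic) < 2)
    stop("need >= 2 identities per class")
  p <- suppressWarnings(
    stats::wilcox.test(genic, intergenic, alternative = "two.sided")$p.value)
  list(mean_genic = mean(genic), mean_intergenic = mean(intergenic),
       p_value = p)
}

#' Rank regions by variant density (hotspots)
#'
#' Stable descending order by density within each region class; ties keep
#' the plastome order of the input table.
#'
#' @param vt a [variant_table()].
#' @param what `"snv"` or `"indel"` density.
#' @return named list with `genic` and `intergenic` key vectors, densest
#'   first.
#' @export
hotspot_ranking <- function(vt, what = c("snv", "indel")) {
  what <- match.arg(what)
  d <- vt$densities
  colname <- paste0(what, "_density")
  out <- lapply(c(genic = "genic", intergenic = "intergenic"), function(cl) {
    sub <- d[d$class == cl, , drop = FALSE]
    sub$key[order(-sub[[colname]])] # order() is stable: ties keep input order
  })
  out
}

#' Indel size spectrum per region class
#'
#' @param indels data.frame with `length` and `class` columns.
#' @return data.frame (class, length, count, mod3) covering every observed
#'   length per class; empty input gives an empty frame.
#' @export
indel_size_spectrum <- function(indels) {
  if (nrow(indels) == 0)
    return(data.frame(class = character(0), length = integer(0),
                      count = integer(0), mod3 = logical(0),
                      stringsAsFactors = FALSE))
  agg <- as.data.frame(table(class = indels$class, length = indels$length),
                       stringsAsFactors = FALSE)
  agg <- agg[agg$Freq > 0, , drop = FALSE]
  agg$length <- as.integer(agg$length)
  out <- data.frame(class = agg$class, length = agg$length,
                    count = agg$Freq, mod3 = agg$length %% 3 == 0,
                    stringsAsFactors = FALSE)
  out[order(out$class, out$length), , drop = FALSE]
}

#' Per-region identity table with and without outgroup rows
#'
#' @param alns named list of alignments.
#' @param outgroups character vector of outgroup row names (may be empty).
#' @return data.frame (key, class, identity_all, identity_ingroup).
#' @export
identity_table <- function(alns, outgroups = character(0)) {
  rows <- lapply(names(alns), function(key) {
    m <- aln_matrix(alns[[key]])
    ing <- setdiff(rownames(m), outgroups)
    data.frame(key = key, class = sub(":.*$", "", key),
               identity_all = percent_identity(m),
               identity_ingroup = if (length(ing) >= 2)
                 percent_identity(m, ing) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
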