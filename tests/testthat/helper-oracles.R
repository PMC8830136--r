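# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately use naive loops, separate from any package
# code path they check.

# column/run enumeration: SNV count, conserved-column identity, indel events
oracle_variants <- function(m) {
  n_snv <- 0L
  cons <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    res <- col[col != "-" & col != "N"]
    if (length(unique(res)) >= 2) n_snv <- n_snv + 1L
    if (!any(col == "-") && length(res) >= 2 && length(unique(res)) == 1)
      cons <- cons + 1L
  }
  lens <- integer(0)
  for (i in seq_len(nrow(m))) {
    cur <- 0L
    for (j in seq_len(ncol(m))) {
      if (m[i, j] == "-") {
        cur <- cur + 1L
      } else if (cur > 0L) {
        lens <- c(lens, cur)
        cur <- 0L
      }
    }
    if (cur > 0L) lens <- c(lens, cur)
  }
  list(snv = n_snv, identity = cons / ncol(m),
       n_indel = length(lens), indel_lengths = sort(lens))
}

random_alignment <- function(nrow = sample(2:4, 1), ncol = sample(5:30, 1),
                             p_gap = 0.15, p_n = 0.05) {
  chars <- sample(c("A", "C", "G", "T", "N", "-"), nrow * ncol, replace = TRUE,
                  prob = c(rep((1 - p_gap - p_n) / 4, 4), p_n, p_gap))
  m <- matrix(chars, nrow, ncol)
  rownames(m) <- paste0("s", seq_len(nrow))
  m
}

# supermatrix summary recomputed naively
oracle_summary <- function(m) {
  pats <- character(0)
  inv <- 0L
  for (j in seq_len(ncol(m))) {
    pats <- union(pats, paste(m[, j], collapse = ""))
    res <- m[, j]
    res <- res[res != "-" & res != "N"]
    if (length(unique(res)) == 1) inv <- inv + 1L
  }
  list(n_sites = ncol(m), n_site_patterns = length(pats),
       gap_fraction = sum(m == "-") / length(m),
       invariant_fraction = inv / ncol(m))
}

# trimming predicate recomputed per column
oracle_trim_keep <- function(m, gap_keep, min_similarity) {
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    res <- col[col != "-"]
    if (length(res) / length(col) < gap_keep) return(FALSE)
    if (length(res) == 0) return(FALSE)
    max(table(res)) / length(res) >= min_similarity
  }, TRUE)
}

# split compatibility via the explicit four-intersection definition
oracle_compatible <- function(sideA, sideB, taxa) {
  Ac <- setdiff(taxa, sideA)
  Bc <- setdiff(taxa, sideB)
  any(c(length(intersect(sideA, sideB)), length(intersect(sideA, Bc)),
        length(intersect(Ac, sideB)), length(intersect(Ac, Bc))) == 0)
}

# greedy maximal compatible prefix over an ordered split table
oracle_greedy_prefix <- function(keys, taxa) {
  sides <- strsplit(keys, "|", fixed = TRUE)
  acc <- list()
  acc_keys <- character(0)
  for (i in seq_along(sides)) {
    ok <- all(vapply(acc, function(a) oracle_compatible(a, sides[[i]], taxa), TRUE))
    if (ok) {
      acc[[length(acc) + 1L]] <- sides[[i]]
      acc_keys <- c(acc_keys, keys[i])
    }
  }
  acc_keys
}

# small, fast simulation configuration shared by several tests
small_cfg <- function(seed, taxa = paste0("t", 1:6), ...) {
  sim_config(seed = seed, taxa = taxa, genome_len = 8000L, n_genes = 6L,
             gene_len_range = c(300L, 600L), spacer_len_range = c(60L, 300L),
             ...)
}

rf_between <- function(t1, t2) {
  compare_splits(splits_from_tree(t1), splits_from_tree(t2))$rf_distance
}
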