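test_that("trimming keeps gapless identical alignments and removes gappy columns", {
  m <- aln_matrix(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_identical(trim_alignment(m), m)

  five <- rbind(c("A", "A"), c("A", "-"), c("A", "-"),
                c("A", "A"), c("A", "A"))
  rownames(five) <- paste0("s", 1:5)
  out <- trim_alignment(five)  # col 2 has non-gap fraction 0.6 < 0.8
  expect_equal(ncol(out), 1)
  expect_equal(unname(out[, 1]), rep("A", 5))
})

test_that("trimming equals the brute-force per-column predicate on fuzzed alignments", {
  set.seed(61)
  for (i in 1:50) {
    m <- random_alignment(nrow = sample(3:6, 1), p_gap = 0.3)
    keep <- oracle_trim_keep(m, 0.8, 0.001)
    expect_identical(trim_alignment(m), m[, keep, drop = FALSE])
    # a stricter similarity threshold
    keep2 <- oracle_trim_keep(m, 0.5, 0.7)
    expect_identical(trim_alignment(m, 0.5, 0.7), m[, keep2, drop = FALSE])
  }
})

test_that("concatenation tiles partitions and computes the summary", {
  a1 <- aln_matrix(c(x = "ACGTACGTAC", y = "ACGTACGTAC"))
  a2 <- aln_matrix(c(x = "TTTTTTTTTT", y = "TTTTTTTTTT"))
  sm <- concatenate(list(`genic:a` = a1, `genic:b` = a2))
  expect_equal(ncol(sm$mat), 20)
  expect_equal(sm$partition_map$start, c(0, 10))
  expect_equal(sm$partition_map$end, c(10, 20))
  expect_equal(sm$summary$invariant_fraction, 1.0)
  expect_equal(sm$summary$n_site_patterns, 4)  # AA, CC, GG, TT columns
  expect_equal(sm$summary$gap_fraction, 0)

  expect_error(concatenate(list(a = a1, b = aln_matrix(c(x = "AC", z = "AC")))),
               "mismatch")
})

test_that("matrix summaries match brute-force recomputation on fuzzed supermatrices", {
  set.seed(62)
  for (i in 1:30) {
    parts <- lapply(1:3, function(j) {
      m <- random_alignment(nrow = 4, ncol = sample(5:15, 1))
      rownames(m) <- paste0("s", 1:4)
      m
    })
    names(parts) <- paste0("genic:r", 1:3)
    sm <- concatenate(parts)
    o <- oracle_summary(sm$mat)
    expect_equal(sm$summary$n_sites, o$n_sites)
    expect_equal(sm$summary$n_site_patterns, o$n_site_patterns)
    expect_equal(sm$summary$gap_fraction, o$gap_fraction)
    expect_equal(sm$summary$invariant_fraction, o$invariant_fraction)
    # concatenation conserves per-region column counts
    expect_equal(sum(vapply(parts, ncol, 0L)), ncol(sm$mat))
  }
})

test_that("codon matrices split a CDS alignment by position and reunite to (III)", {
  # 12-column CDS = 4 codons; start/stop removal leaves 6 columns
  m <- aln_matrix(c(a = "ATGAAACCCTAA", b = "ATGAAACCGTAA"))
  bm <- build_matrices(list(`genic:x` = m), "x")
  expect_equal(bm$cds$summary$n_sites, 6)
  expect_equal(bm$pos12$summary$n_sites, 4)
  expect_equal(bm$pos3$summary$n_sites, 2)
  # (IV) union (V) = (III) as a column multiset
  cols <- function(sm) sort(apply(sm$mat, 2, paste, collapse = ""))
  expect_equal(sort(c(cols(bm$pos12), cols(bm$pos3))), cols(bm$cds))

  # non-codon-faithful CDS is excluded with a warning
  m2 <- aln_matrix(c(a = "ATGAAAACCCTAA", b = "ATGAAAACCGTAA"))
  expect_warning(bm2 <- build_matrices(list(`genic:x` = m, `genic:y` = m2),
                                       c("x", "y")),
                 "excluded")
  expect_equal(bm2$excluded_cds, "genic:y")
})

test_that("simulated frame-clean CDS alignments survive codon partitioning intact", {
  cfg <- small_cfg(63, p_frame_genic = 1)  # all genic indels multiples of 3
  sim <- simulate_plastomes(cfg)
  alns <- lapply(sim$truth$true_alignments,
                 function(m) m[rownames(m) != "ancestor", , drop = FALSE])
  cl <- sim$ancestor$features
  cds <- unique(cl$name[cl$kind == "CDS"])
  bm <- build_matrices(alns, cds)
  # (III) equals the concatenated true CDS alignments minus terminal codons
  expected <- sum(vapply(alns[paste0("genic:", cds)], ncol, 0L)) - 6L * length(cds)
  expect_equal(bm$cds$summary$n_sites, expected)
  expect_equal(bm$excluded_cds, character(0))
  expect_equal(bm$pos12$summary$n_sites, 2 * bm$pos3$summary$n_sites)
})

test_that("diagnostic selection is a minimal identity-ordered prefix", {
  base <- c(s1 = "AAAA", s2 = "AAAA", s3 = "AAAA")
  only <- list(`genic:a` = aln_matrix(c(s1 = "AAAA", s2 = "AAAA", s3 = "AAAA")),
               `genic:b` = aln_matrix(c(s1 = "ACGT", s2 = "ACGA", s3 = "ACCT")))
  sel <- select_diagnostic_regions(only)
  expect_equal(sel$selected, "genic:b")  # the single variable region suffices
  expect_true(sel$separated)

  # identical samples can never be separated: full list + reported pairs
  same <- list(`genic:a` = aln_matrix(base))
  sel2 <- select_diagnostic_regions(same)
  expect_false(sel2$separated)
  expect_equal(nrow(sel2$unseparated_pairs), 3)

  # the selection order is a prefix of the identity-sorted region list
  set.seed(64)
  alns <- lapply(1:6, function(i) random_alignment(nrow = 4, ncol = 20, p_gap = 0, p_n = 0))
  names(alns) <- paste0("genic:r", 1:6)
  ids <- vapply(alns, percent_identity, 0)
  sel3 <- select_diagnostic_regions(alns, ids)
  expect_equal(sel3$selected,
               names(alns)[order(ids)][seq_along(sel3$selected)])
})

test_that("neighbor joining recovers additive distances and simulated topologies", {
  # hand-built additive 4-taxon matrix
  d <- matrix(c(0, 5, 9, 10,
                5, 0, 10, 11,
                9, 10, 0, 7,
                10, 11, 7, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- ape::nj(as.dist(d))
  expect_equal(unname(ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]]),
               unname(d), tolerance = 1e-9)

  sim <- simulate_plastomes(small_cfg(65, taxa = paste0("t", 1:8)))
  alns <- lapply(sim$truth$true_alignments,
                 function(m) m[rownames(m) != "ancestor", , drop = FALSE])
  sm <- concatenate(lapply(alns, trim_alignment))
  tree <- nj_tree(sm)
  expect_equal(rf_between(tree, sim$tree), 0)

  expect_error(nj_tree(aln_matrix(c(a = "AC", b = "AC"))), ">= 3")
  expect_error(nj_tree(rbind(a = c("A", "-"), b = c("-", "A"), c = c("A", "A"))),
               "no comparable")
})

test_that("supermatrix writers emit parseable PHYLIP and partition files", {
  a1 <- aln_matrix(c(x = "ACGTACGTAC", y = "ACGTACGTAC"))
  sm <- concatenate(list(`genic:a` = a1, `intergenic:b-c` = a1))
  phy <- tempfile(fileext = ".phy"); part <- tempfile(fileext = ".txt")
  write_supermatrix(sm, phy, part)
  lines <- readLines(phy)
  expect_equal(lines[1], "2 20")
  plines <- readLines(part)
  expect_equal(plines, c("DNA, genic_a = 1-10", "DNA, intergenic_b_c = 11-20"))
})
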