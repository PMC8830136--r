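test_that("percent identity counts fully conserved non-gap columns", {
  two <- c(a = strrep("ACGT", 25), b = strrep("ACGT", 25))
  expect_equal(percent_identity(two), 1.0)

  ten <- c(a = "ACGTACGTAC", b = "ACGTACGTAT")
  expect_equal(percent_identity(ten), 0.9)

  # any gap in a column makes it non-conserved
  m <- aln_matrix(c(r1 = "AACAT", r2 = "AACAT", r3 = "A-C-T"))
  m <- m[, c(1, 2, 3, 4, 5)]
  three <- rbind(c("A", "A", "C", "A", "T"),
                 c("A", "A", "C", "-", "T"),
                 c("A", "-", "C", "A", "T"))
  rownames(three) <- paste0("r", 1:3)
  expect_equal(percent_identity(three), 3 / 5)

  expect_error(percent_identity(c(a = "ACGT")), "single-row")
})

test_that("identity is row-permutation invariant and only drops when adding an outgroup", {
  set.seed(51)
  for (i in 1:20) {
    # N-free: with missing data a column can fall below the two-residue
    # minimum for conservation, which breaks subset monotonicity by design
    m <- random_alignment(nrow = 4, p_n = 0)
    expect_equal(percent_identity(m), percent_identity(m[sample(4), ]))
    sub <- percent_identity(m, rows = rownames(m)[1:3])
    expect_lte(percent_identity(m), sub)
  }
})

test_that("variant calling matches the worked SNV and indel examples", {
  v <- call_variants(c(a = "ACGT", b = "ACGA"))
  expect_equal(nrow(v$snvs), 1)
  expect_equal(v$snvs$column, 4)
  expect_equal(nrow(v$indels), 0)

  v2 <- call_variants(c(a = "AC--GT", b = "ACTTGT"))
  expect_equal(nrow(v2$snvs), 0)
  expect_equal(nrow(v2$indels), 1)
  expect_equal(v2$indels$sample, "a")
  expect_equal(v2$indels$length, 2)
  expect_equal(v2$indels$start, 3)

  # N never creates an SNV and {A,N} columns are not conserved either
  v3 <- call_variants(c(a = "AN", b = "AA"))
  expect_equal(nrow(v3$snvs), 0)
  expect_equal(percent_identity(c(a = "AN", b = "AA")), 0.5)
})

test_that("variant counts and identity match brute-force enumeration on fuzzed alignments", {
  set.seed(52)
  for (i in 1:100) {
    m <- random_alignment()
    o <- oracle_variants(m)
    v <- call_variants(m)
    expect_equal(nrow(v$snvs), o$snv)
    expect_equal(nrow(v$indels), o$n_indel)
    expect_equal(sort(v$indels$length), o$indel_lengths)
    expect_equal(percent_identity(m), o$identity)
  }
})

test_that("frame analysis builds the 2x2 table and exact test as specified", {
  ind <- data.frame(length = c(3, 6, 2, 1, 2),
                    class = c("genic", "genic", "genic",
                              "intergenic", "intergenic"))
  f <- frame_analysis(ind)
  expect_equal(f$prop_genic_mod3, 2 / 3)
  expect_equal(f$prop_intergenic_mod3, 0)
  expect_equal(as.vector(f$table), c(2, 0, 1, 2))
  expect_equal(f$p_value,
               fisher.test(matrix(c(2, 0, 1, 2), 2, byrow = FALSE))$p.value)

  # all frame-preserving in both classes: no signal
  ind2 <- data.frame(length = c(3, 6, 9, 3), class = c("genic", "genic",
                                                       "intergenic", "intergenic"))
  f2 <- frame_analysis(ind2)
  expect_equal(f2$prop_genic_mod3, 1)
  expect_equal(f2$prop_intergenic_mod3, 1)
  expect_equal(f2$p_value, 1)

  expect_warning(f3 <- frame_analysis(data.frame(length = 3, class = "genic")),
                 "no indels")
  expect_true(is.na(f3$p_value))
})

test_that("identity contrast separates fully distinct classes", {
  eq <- identity_contrast(c(0.9, 0.8, 0.7), c(0.9, 0.8, 0.7))
  expect_equal(eq$mean_genic, eq$mean_intergenic)
  expect_equal(eq$p_value, 1)

  ct <- identity_contrast(rep(0.99, 10), rep(0.90, 10))
  expect_equal(ct$mean_genic - ct$mean_intergenic, 0.09)
  expect_lt(ct$p_value, 0.001)
  # tie-free complete separation at n = m = 10: exact rank-sum p = 2 / C(20,10)
  ct2 <- identity_contrast(seq(0.95, 0.99, length.out = 10),
                           seq(0.80, 0.90, length.out = 10))
  expect_equal(ct2$p_value, 2 / choose(20, 10), tolerance = 1e-9)

  expect_error(identity_contrast(0.9, c(0.8, 0.7)), ">= 2")
})

test_that("hotspot ranking is density-descending with plastome-order ties", {
  alns <- list(`intergenic:a-b` = c(x = "AAAA", y = "AAAT"),
               `intergenic:b-c` = c(x = "ATCG", y = "TGCA"),
               `intergenic:c-d` = c(x = "AAAG", y = "AAAT"))
  vt <- variant_table(alns)
  rk <- hotspot_ranking(vt, "snv")
  expect_equal(rk$intergenic[1], "intergenic:b-c")
  # the two single-SNV regions tie; plastome (input) order is preserved
  expect_equal(rk$intergenic[2:3], c("intergenic:a-b", "intergenic:c-d"))
})

test_that("densities are normalised by length and rows, invariant to column duplication", {
  aln <- c(a = "AC--GTAC", b = "ACTTGTAT", c = "ACTTGTAC")
  vt <- variant_table(list(`intergenic:x-y` = aln))
  d <- vt$densities
  expect_equal(d$snv_density, d$snv_count / d$length / d$n_rows)
  # duplicating all columns doubles counts and length: density unchanged
  m <- aln_matrix(aln)
  vt2 <- variant_table(list(`intergenic:x-y` = cbind(m, m)))
  expect_equal(vt2$densities$snv_density, d$snv_density)
})

test_that("indel size spectrum counts lengths per class and marks multiples of three", {
  empty <- indel_size_spectrum(data.frame(length = integer(0), class = character(0)))
  expect_equal(nrow(empty), 0)

  sp <- indel_size_spectrum(data.frame(length = c(1, 1, 3), class = "genic"))
  expect_equal(sp$count[sp$length == 1], 2)
  expect_equal(sp$count[sp$length == 3], 1)
  expect_equal(sp$mod3, c(FALSE, TRUE))

  # simulator truth lengths reproduce the histogram exactly
  sim <- simulate_plastomes(small_cfg(53, indel_rate_genic = 0.005,
                                      indel_rate_intergenic = 0.005))
  ind <- sim$truth$true_indels
  sp2 <- indel_size_spectrum(ind)
  for (r in seq_len(nrow(sp2))) {
    expect_equal(sp2$count[r], sum(ind$length == sp2$length[r] &
                                     ind$class == sp2$class[r]))
  }
})
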