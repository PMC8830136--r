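test_that("kmer profiles canonicalise and apply the singleton filter", {
  # ACGTA, k=3: kmers ACG, CGT, GTA -> canonical ACG, ACG, GTA
  # duplicate the sample so nothing is filtered as a singleton
  pr <- build_profile(list(s1 = "ACGTA", s2 = "ACGTA"), k = 3)
  c1 <- pr$counts[pr$counts$sample == "s1", ]
  expect_setequal(c1$kmer, c("ACG", "GTA"))
  expect_equal(c1$count[c1$kmer == "ACG"], 2L)  # ACG itself + canonical(CGT)
  expect_equal(c1$count[c1$kmer == "GTA"], 1L)
  # identical samples give identical profiles
  c2 <- pr$counts[pr$counts$sample == "s2", ]
  expect_equal(c1[order(c1$kmer), c("kmer", "count")],
               c2[order(c2$kmer), c("kmer", "count")])

  # a kmer occurring exactly once in the whole dataset is removed
  pr2 <- build_profile(list(s1 = "ACGTA", s2 = "TTTTTT"), k = 5)
  expect_false("ACGTA" %in% pr2$counts$kmer)
  expect_true(all(pr2$counts$kmer == "AAAAA"))  # canonical of TTTTT, count 2

  expect_warning(build_profile(list(s1 = "ACGTACGT", s2 = "AC"), k = 5), "length")
})

test_that("constructed presence patterns become splits with the expected count weight", {
  set.seed(71)
  core <- random_dna(300)
  shared_ab <- vapply(1:7, function(i) random_dna(31), "")
  # make the shared kmers specific to samples A and B
  samples <- list(A = c(core, shared_ab), B = c(core, shared_ab),
                  C = core, D = random_dna(300))
  pr <- build_profile(samples, k = 31)
  sp <- infer_splits(pr, weight_fn = "count", top = "all")
  # the AB|CD bipartition is keyed by the side without the reference taxon A
  hit <- sp$splits[sp$splits$key == "C|D", ]
  expect_equal(nrow(hit), 1)
  expect_gte(hit$weight, 7)  # the 7 planted kmers support AB|CD

  # relabeling samples permutes splits identically
  relabeled <- samples
  names(relabeled) <- c("D", "C", "B", "A")
  sp2 <- infer_splits(build_profile(relabeled, k = 31), "count", "all")
  remap <- c(A = "D", B = "C", C = "B", D = "A")
  keys_mapped <- vapply(strsplit(sp$splits$key, "|", fixed = TRUE), function(s)
    panplastome:::split_key(unname(remap[s]), names(samples)), "")
  expect_setequal(keys_mapped, sp2$splits$key)
})

test_that("geom weights use the geometric mean of supporting counts", {
  # X supports {A,B} (counts 2 and 1); Y supports {C,D}; E's kmer is a
  # dataset singleton and is filtered, leaving E outside every pattern
  X <- "ACGTACGTACG"; Y <- "AACCGGTTAAC"; Z <- "ACACACACACG"
  samples <- list(A = c(X, X), B = X, C = Y, D = Y, E = Z)
  pr <- build_profile(samples, k = 11)
  spc <- infer_splits(pr, "count", "all")
  spg <- infer_splits(pr, "geom", "all")
  key_ab <- "C|D|E"  # complement of {A,B} relative to reference taxon A
  expect_equal(spc$splits$weight[spc$splits$key == key_ab], 1)
  # one supporting kmer with counts 2 (A) and 1 (B): geometric mean sqrt(2)
  expect_equal(spg$splits$weight[spg$splits$key == key_ab], sqrt(2))
  expect_equal(spg$splits$weight[spg$splits$key == "C|D"], 1)
  # with presence-defined patterns geom2 coincides with geom
  spg2 <- infer_splits(pr, "geom2", "all")
  expect_equal(spg$splits, spg2$splits)
})

test_that("the strict tree reproduces a known topology and obeys the greedy rule", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  sp <- splits_from_tree(tr)
  st <- strict_tree(sp)
  expect_equal(rf_between(st$tree, tr), 0)

  # two incompatible splits: only the heavier is accepted
  taxa <- c("a", "b", "c", "d", "e")
  ss <- panplastome:::split_set(taxa, c("b|c", "c|d"), c(5, 3))
  st2 <- strict_tree(ss)
  expect_equal(st2$accepted, "b|c")
})

test_that("greedy acceptance equals the brute-force compatible prefix on split soups", {
  set.seed(72)
  taxa <- paste0("t", 1:6)
  for (i in 1:30) {
    nsp <- sample(3:10, 1)
    keys <- unique(vapply(seq_len(nsp), function(j) {
      side <- sample(taxa[-1], sample(2:4, 1))
      panplastome:::split_key(side, taxa)
    }, ""))
    ss <- panplastome:::split_set(taxa, keys, runif(length(keys), 0.1, 5))
    st <- strict_tree(ss)
    expect_equal(st$accepted, oracle_greedy_prefix(ss$splits$key, taxa))
    # the accepted set is realizable: the emitted tree contains every
    # accepted split
    got <- splits_from_tree(st$tree)
    expect_true(all(st$accepted %in% got$splits$key))
  }
})

test_that("NEXUS round trip preserves splits and weights", {
  taxa <- paste0("t", 1:5)
  ss <- panplastome:::split_set(taxa, c("t2|t3", "t4|t5"), c(2.25, 1.5))
  doc <- to_splits_nexus(ss)
  rt <- read_splits_nexus(doc)
  expect_equal(rt$taxa, ss$taxa)
  expect_equal(rt$splits$key, ss$splits$key)
  expect_equal(rt$splits$weight, ss$splits$weight, tolerance = 1e-6)

  # empty split set still yields a valid document
  empty <- panplastome:::split_set(taxa, character(0), numeric(0))
  doc2 <- to_splits_nexus(empty)
  expect_equal(nrow(read_splits_nexus(doc2)$splits), 0)
})

test_that("homoplasy-free simulated data give tree-like, k-robust splits", {
  sim <- simulate_plastomes(small_cfg(73, taxa = paste0("t", 1:6)))
  seqs <- lapply(sim$samples, `[[`, "sequence")
  tops <- list()
  true_keys <- splits_from_tree(sim$tree)$splits$key
  for (k in c(21L, 31L)) {
    sp <- infer_splits(build_profile(seqs, k = k), "count", "all")
    # the heaviest n-3 splits are exactly the true internal splits and are
    # mutually compatible (kmer loss creates lighter, conflicting patterns)
    heavy <- utils::head(sp$splits, length(sp$taxa) - 3)
    expect_setequal(heavy$key, true_keys)
    sides <- strsplit(heavy$key, "|", fixed = TRUE)
    for (x in seq_along(sides)) for (y in seq_len(x - 1)) {
      expect_true(oracle_compatible(sides[[x]], sides[[y]], sp$taxa))
    }
    tops[[as.character(k)]] <- strict_tree(sp)$tree
  }
  expect_equal(rf_between(tops[["21"]], tops[["31"]]), 0)
  expect_equal(rf_between(tops[["21"]], sim$tree), 0)
})

test_that("splits from a tree round-trip through the strict tree for random topologies", {
  set.seed(74)
  for (n in c(5, 6, 8)) {
    tr <- ape::rtree(n)
    st <- strict_tree(splits_from_tree(tr))
    expect_equal(rf_between(st$tree, tr), 0)
  }
})
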