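#' Configuration for the plastome evolution simulator
#'
#' Bundles every tunable of the synthetic plastome generator: the quadripartite
#' architecture (large and small single-copy regions flanked by two inverted
#' repeats), the gene complement, and the class-specific divergence model in
#' which genes accumulate substitutions and indels more slowly than intergenic
#' spacers and genic indel lengths are biased toward multiples of three
#' (reading-frame preservation).
#'
#' Rates are expected events per site per unit branch length. `p_frame_*` is
#' the probability that an indel length is a multiple of three in that region
#' class. Compartment fractions must satisfy `lsc + ssc + 2*ir == 1`.
#'
#' @param seed integer RNG seed; identical configs give byte-identical output.
#' @param taxa leaf labels (used when no tree is supplied).
#' @param tree optional `phylo` or newick string; when `NULL` a seeded random
#'   binary tree over `taxa` is generated with mean root-to-tip depth 0.5.
#' @param genome_len target circular genome length in bp.
#' @param n_genes number of distinct genes (IR-resident genes count once).
#' @param gene_len_range,spacer_len_range bp ranges for gene and spacer draws.
#' @param lsc_frac,ssc_frac,ir_frac compartment length fractions.
#' @param sub_rate_genic,sub_rate_intergenic substitution rates per site.
#' @param indel_rate_genic,indel_rate_intergenic indel event rates per site.
#' @param p_frame_genic,p_frame_intergenic probability of a frame-preserving
#'   (multiple-of-three) indel length per class.
#' @param indel_len_max maximum indel length in bp.
#' @param coverage_depth mean single-copy read depth for coverage tracks.
#' @param coverage_sd Gaussian depth noise (0 = noiseless).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       taxa = paste0("t", 1:8),
                       tree = NULL,
                       genome_len = 24000L,
                       n_genes = 20L,
                       gene_len_range = c(300L, 900L),
                       spacer_len_range = c(80L, 400L),
                       lsc_frac = 0.56, ssc_frac = 0.12, ir_frac = 0.16,
                       sub_rate_genic = 0.01, sub_rate_intergenic = 0.03,
                       indel_rate_genic = 0.001, indel_rate_intergenic = 0.003,
                       p_frame_genic = 0.45, p_frame_intergenic = 0.30,
                       indel_len_max = 12L,
                       coverage_depth = 100, coverage_sd = 0) {
  cfg <- list(seed = as.integer(seed), taxa = taxa, tree = tree,
              genome_len = as.integer(genome_len), n_genes = as.integer(n_genes),
              gene_len_range = as.integer(gene_len_range),
              spacer_len_range = as.integer(spacer_len_range),
              lsc_frac = lsc_frac, ssc_frac = ssc_frac, ir_frac = ir_frac,
              sub_rate_genic = sub_rate_genic,
              sub_rate_intergenic = sub_rate_intergenic,
              indel_rate_genic = indel_rate_genic,
              indel_rate_intergenic = indel_rate_intergenic,
              p_frame_genic = p_frame_genic,
              p_frame_intergenic = p_frame_intergenic,
              indel_len_max = as.integer(indel_len_max),
              coverage_depth = coverage_depth, coverage_sd = coverage_sd)
  rates <- c(cfg$sub_rate_genic, cfg$sub_rate_intergenic,
             cfg$indel_rate_genic, cfg$indel_rate_intergenic)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (abs(cfg$lsc_frac + cfg$ssc_frac + 2 * cfg$ir_frac - 1) > 1e-9)
    stop("compartment fractions must satisfy lsc + ssc + 2*ir = 1")
  if (cfg$p_frame_genic < 0 || cfg$p_frame_genic > 1 ||
      cfg$p_frame_intergenic < 0 || cfg$p_frame_intergenic > 1)
    stop("p_frame values must lie in [0, 1]")
  if (cfg$n_genes < 2) stop("need at least 2 genes")
  class(cfg) <- "sim_config"
  cfg
}

#' Construct an annotated plastome object
#'
#' @param sample_id sample label.
#' @param sequence circular DNA string (uppercase ACGTN).
#' @param features data.frame of gene features (`name`, `start`, `end`,
#'   `strand`, `kind`, `copy`), 0-based half-open coordinates.
#' @param partition optional quadripartite partition as returned by
#'   [detect_quadripartite()].
#' @return object of class `plastome`.
#' @export
plastome <- function(sample_id, sequence, features, partition = NULL) {
  n <- nchar(sequence)
  if (n == 0) stop("empty sequence")
  if (nrow(features) > 0 && any(features$end > n + n))
    stop("feature interval outside sequence")
  structure(list(sample_id = sample_id, sequence = sequence,
                 features = features, partition = partition),
            class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %d bp, %d gene features%s\n", x$sample_id,
              nchar(x$sequence), nrow(x$features),
              if (is.null(x$partition)) "" else ", quadripartite"))
  invisible(x)
}

## draw a gene length (multiple of 3 so CDS carry whole codons)
draw_gene_len <- function(range) {
  lens <- seq.int(3L * as.integer(ceiling(range[1] / 3)), range[2], by = 3L)
  sample(lens, 1L)
}

## compose `total` bp into n spacers, roughly proportional to uniform draws
compose_spacers <- function(n, total, range) {
  if (n == 0) return(integer(0))
  raw <- runif(n, range[1], range[2])
  w <- floor(raw / sum(raw) * total)
  w[1] <- w[1] + (total - sum(w))
  as.integer(w)
}

random_cds <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  inner <- random_dna(len - 6L)
  paste0("ATG", inner, "TAA")
}

#' Build the ancestral annotated plastome
#'
#' Lays out a circular quadripartite molecule: a large single-copy region
#' (LSC), inverted repeat A, a small single-copy region (SSC), and inverted
#' repeat B which is the exact reverse complement of IRa. Genes alternate with
#' spacers; IR boundaries fall on gene boundaries (both IR copies start and
#' end with a gene, as in real plastomes where rRNA operons sit inside the
#' IR). The two bases flanking the IRs are chosen so the inverted repeat is
#' maximal, i.e. the annotated IR coordinates are exactly recoverable from
#' sequence self-complementarity.
#'
#' @param config a [sim_config()].
#' @return a `plastome` with attributes `units` (the gene/spacer layout used
#'   by the evolver) and `ir_coords` (the planted partition).
#' @export
build_ancestor <- function(config) {
  set.seed(config$seed)
  L <- config$genome_len
  lsc_t <- round(L * config$lsc_frac)
  ir_t <- round(L * config$ir_frac)
  ssc_t <- L - lsc_t - 2L * ir_t
  has_ir <- config$ir_frac > 0

  ng <- config$n_genes
  if (has_ir) {
    if (ng < 4L) stop("need >= 4 genes for a quadripartite layout")
    content <- c(lsc = lsc_t, ir = ir_t, ssc = ssc_t)
    # >= 2 IR genes so the internal spacer can absorb the IR length target
    n_ir <- max(2L, round(ng * ir_t / sum(content)))
    n_lsc <- max(1L, round(ng * lsc_t / sum(content)))
    n_ssc <- ng - n_lsc - n_ir
    if (n_ssc < 1L) { n_lsc <- n_lsc - (1L - n_ssc); n_ssc <- 1L }
  } else {
    n_ir <- 0L
    n_lsc <- max(1L, round(ng * lsc_t / (lsc_t + ssc_t)))
    n_ssc <- ng - n_lsc
    if (n_ssc < 1L) { n_lsc <- n_lsc - (1L - n_ssc); n_ssc <- 1L }
  }

  gene_names <- sprintf("g%02d", seq_len(ng))
  idx <- list(lsc = seq_len(n_lsc),
              ir = if (n_ir > 0) n_lsc + seq_len(n_ir) else integer(0),
              ssc = n_lsc + n_ir + seq_len(n_ssc))

  units <- list()
  for (comp in c("lsc", "ir", "ssc")) {
    gi <- idx[[comp]]
    if (length(gi) == 0) next
    glens <- vapply(gi, function(i) draw_gene_len(config$gene_len_range), 0L)
    # IR genes emulate the rRNA operon; single-copy genes are mostly CDS
    kinds <- if (comp == "ir") rep("rRNA", length(gi)) else
      sample(c("CDS", "tRNA"), length(gi), replace = TRUE, prob = c(0.85, 0.15))
    strands <- sample(c("+", "-"), length(gi), replace = TRUE)
    target <- switch(comp, lsc = lsc_t, ir = ir_t, ssc = ssc_t)
    # single-copy compartments: s (g s)+ ; IR compartment: g (s g)*
    n_sp <- if (comp == "ir") length(gi) - 1L else
      if (has_ir) length(gi) + 1L else length(gi)
    sp_total <- target - sum(glens)
    if (sp_total < max(n_sp, 1L))
      stop(sprintf("sizing error: compartment %s too small for its genes (%d bp of genes, %d bp target)",
                   toupper(comp), sum(glens), target))
    sp_lens <- compose_spacers(n_sp, sp_total, config$spacer_len_range)
    if (any(sp_lens < 1)) { # redistribute pathological roundings
      sp_lens[sp_lens < 1] <- 1L
      sp_lens[1] <- sp_lens[1] - (sum(sp_lens) - sp_total)
    }
    comp_units <- list()
    add_gene <- function(j) {
      len <- glens[j]
      seqs <- if (kinds[j] == "CDS") random_cds(len) else random_dna(len)
      list(kind = "gene", name = gene_names[gi[j]], compartment = comp,
           gene_kind = kinds[j], strand = strands[j], seq = seqs)
    }
    add_spacer <- function(j) {
      list(kind = "spacer", name = NA_character_, compartment = comp,
           gene_kind = NA_character_, strand = "+", seq = random_dna(sp_lens[j]))
    }
    if (comp == "ir") {
      for (j in seq_along(gi)) {
        comp_units <- c(comp_units, list(add_gene(j)))
        if (j < length(gi)) comp_units <- c(comp_units, list(add_spacer(j)))
      }
    } else if (has_ir) {
      comp_units <- list(add_spacer(1L))
      for (j in seq_along(gi)) {
        comp_units <- c(comp_units, list(add_gene(j)), list(add_spacer(j + 1L)))
      }
    } else {
      for (j in seq_along(gi)) {
        comp_units <- c(comp_units, list(add_spacer(j)), list(add_gene(j)))
      }
    }
    units <- c(units, comp_units)
  }
  names(units) <- sprintf("u%03d", seq_along(units))

  anc <- assemble_plastome("ancestor", units, has_ir)
  # break accidental IR extension into the flanking single-copy bases
  if (has_ir) {
    units <- fix_ir_flanks(units, anc)
    anc <- assemble_plastome("ancestor", units, has_ir)
  }
  attr(anc, "units") <- units
  anc
}

## bases of a unit as placed on the genome forward strand
unit_genomic <- function(u) {
  if (u$kind == "gene" && u$strand == "-") revcomp(u$seq) else u$seq
}

## assemble a plastome from its unit layout; IRb is the mirrored IRa block
assemble_plastome <- function(sample_id, units, has_ir) {
  comp <- vapply(units, `[[`, "", "compartment")
  lens <- vapply(units, function(u) nchar(u$seq), 0L)
  seqs <- vapply(units, unit_genomic, "")
  block <- function(w) paste(seqs[comp == w], collapse = "")
  lsc_s <- block("lsc"); ira_s <- block("ir"); ssc_s <- block("ssc")
  genome <- paste0(lsc_s, ira_s, ssc_s, if (has_ir) revcomp(ira_s) else "")
  n <- nchar(genome)

  starts <- cumsum(c(0L, lens[-length(lens)]))
  feats <- list()
  for (i in seq_along(units)) {
    u <- units[[i]]
    if (u$kind != "gene") next
    feats[[length(feats) + 1L]] <- data.frame(
      name = u$name, start = starts[i], end = starts[i] + lens[i],
      strand = u$strand, kind = u$gene_kind, copy = "main",
      stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, feats)

  lsc_len <- nchar(lsc_s); ira_len <- nchar(ira_s); ssc_len <- nchar(ssc_s)
  if (has_ir) {
    ira_iv <- c(lsc_len, lsc_len + ira_len)
    irb_iv <- c(lsc_len + ira_len + ssc_len, n)
    # mirror IRa-resident genes into IRb
    in_ira <- features$start >= ira_iv[1] & features$end <= ira_iv[2]
    if (any(in_ira)) {
      f <- features[in_ira, , drop = FALSE]
      mirr <- data.frame(
        name = f$name,
        start = irb_iv[1] + (ira_iv[2] - f$end),
        end = irb_iv[1] + (ira_iv[2] - f$start),
        strand = ifelse(f$strand == "+", "-", "+"),
        kind = f$kind, copy = "irb", stringsAsFactors = FALSE)
      features <- rbind(features, mirr)
    }
    part <- list(lsc = c(0L, lsc_len), ira = ira_iv,
                 ssc = c(lsc_len + ira_len, lsc_len + ira_len + ssc_len),
                 irb = irb_iv, orientation_flag = "canonical")
  } else {
    part <- list(lsc = c(0L, lsc_len + ira_len),
                 ssc = c(lsc_len + ira_len, n),
                 ira = c(0L, 0L), irb = c(0L, 0L),
                 orientation_flag = "canonical")
  }
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  plastome(sample_id, genome, features, part)
}

## mutate the two single-copy bases flanking the IRs so that the inverted
## repeat cannot be extended by chance complementarity
fix_ir_flanks <- function(units, anc) {
  p <- anc$partition
  s <- anc$sequence
  n <- nchar(s)
  char_at <- function(i) substr(s, i + 1, i + 1) # 0-based
  comp <- vapply(units, `[[`, "", "compartment")
  # outer flank: last LSC base vs first genome base (circular after IRb)
  if (char_at(p$ira[1] - 1) == comp_chars(char_at(p$irb[2] %% n))) {
    i <- max(which(comp == "lsc"))
    u <- units[[i]]$seq
    bad <- comp_chars(char_at(p$irb[2] %% n))
    repl <- sample(setdiff(DNA, bad), 1)
    substr(u, nchar(u), nchar(u)) <- repl
    units[[i]]$seq <- u
  }
  # inner flank: first SSC base vs last SSC base
  if (char_at(p$ira[2]) == comp_chars(char_at(p$irb[1] - 1))) {
    i <- min(which(comp == "ssc"))
    u <- units[[i]]$seq
    bad <- comp_chars(char_at(p$irb[1] - 1))
    repl <- sample(setdiff(DNA, bad), 1)
    substr(u, 1, 1) <- repl
    units[[i]]$seq <- u
  }
  units
}

## region key of every unit: genes are "genic:<name>", spacers are
## "intergenic:<prev>-<next>" using the flanking gene names in molecule order
unit_region_keys <- function(units) {
  kind <- vapply(units, `[[`, "", "kind")
  nm <- vapply(units, function(u) u$name %||% NA_character_, "")
  n <- length(units)
  keys <- character(n)
  gene_pos <- which(kind == "gene")
  for (i in seq_len(n)) {
    if (kind[i] == "gene") { keys[i] <- paste0("genic:", nm[i]); next }
    prevg <- if (any(gene_pos < i)) max(gene_pos[gene_pos < i]) else max(gene_pos)
    nextg <- if (any(gene_pos > i)) min(gene_pos[gene_pos > i]) else min(gene_pos)
    keys[i] <- paste0("intergenic:", nm[prevg], "-", nm[nextg])
  }
  keys
}

## --- evolution along a tree -------------------------------------------------

## sample an indel length: geometric with mean 3 truncated at len_max, then
## conditioned on being / not being a multiple of 3 per the class probability
draw_indel_len <- function(p_frame, len_max) {
  lens <- seq_len(len_max)
  w <- stats::dgeom(lens - 1L, prob = 1 / 3)
  is3 <- lens %% 3L == 0L
  if (runif(1) < p_frame) {
    sample(lens[is3], 1L, prob = w[is3])
  } else {
    sample(lens[!is3], 1L, prob = w[!is3])
  }
}

## insert `len` gap columns into alignment matrix after column `after`
insert_gap_cols <- function(M, after, len) {
  gap <- matrix("-", nrow(M), len)
  if (after == 0) cbind(gap, M)
  else if (after == ncol(M)) cbind(M, gap)
  else cbind(M[, seq_len(after), drop = FALSE], gap,
             M[, (after + 1):ncol(M), drop = FALSE])
}

## evolve one region (gene or spacer) along the tree; returns the full
## alignment over all tree nodes plus the list of indel events
evolve_unit_along <- function(chars, tree, sub_rate, indel_rate, p_frame,
                              len_max, is_gene, unit_label) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  M <- matrix("-", ntip + nnode, length(chars))
  M[root, ] <- chars
  edges <- tree$edge
  elen <- tree$edge.length
  events <- list()
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; chd <- edges[e, 2]; bl <- elen[e]
    row <- M[par, ]
    # substitutions: per-site Bernoulli with q = 1 - exp(-rate * t)
    v <- which(row != "-")
    if (sub_rate > 0 && length(v) > 0) {
      q <- 1 - exp(-sub_rate * bl)
      nsub <- rbinom(1L, length(v), q)
      if (nsub > 0) {
        pos <- if (length(v) == 1) v else sample(v, nsub)
        for (p in pos) row[p] <- sample(setdiff(DNA, row[p]), 1L)
      }
    }
    # indels: Poisson number of events, geometric-like lengths, mod-3 bias
    if (indel_rate > 0) {
      nind <- rpois(1L, indel_rate * length(v) * bl)
      for (j in seq_len(nind)) {
        len <- draw_indel_len(p_frame, len_max)
        v <- which(row != "-")
        if (runif(1) < 0.5 && length(v) > 0) { # deletion
          if (length(v) <= len) {
            if (is_gene)
              stop(sprintf("simulation parameters too aggressive: gene %s would be deleted entirely",
                           unit_label))
            len <- length(v) # spacer may vanish
            s <- 1L
          } else {
            s <- sample.int(length(v) - len + 1L, 1L)
          }
          row[v[s:(s + len - 1L)]] <- "-"
          events[[length(events) + 1L]] <-
            list(node = chd, length = len, kind = "deletion")
        } else { # insertion
          anchor <- if (length(v) == 0) 0L else {
            jpos <- sample.int(length(v) + 1L, 1L) - 1L
            if (jpos == 0L) v[1] - 1L else v[jpos]
          }
          M <- insert_gap_cols(M, anchor, len)
          row <- c(row[seq_len(anchor)], sample(DNA, len, replace = TRUE),
                   if (anchor < length(row)) row[(anchor + 1):length(row)])
          events[[length(events) + 1L]] <-
            list(node = chd, length = len, kind = "insertion")
        }
      }
    }
    M[chd, ] <- row
  }
  list(aln = M, events = events)
}

node_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  internal <- tree$node.label
  if (is.null(internal) || !all(nzchar(internal)))
    internal <- paste0("node", seq_len(tree$Nnode))
  c(tree$tip.label, internal)
}

#' Evolve an ancestral plastome along a phylogeny
#'
#' Each gene and spacer evolves independently along the tree under a
#' uniform-rate, equal-frequency substitution model and a Poisson indel
#' process whose lengths follow a truncated geometric law conditioned on the
#' class-specific probability of being a multiple of three. The inverted
#' repeat evolves once and both copies receive identical mutations. Indels
#' never cross a gene/spacer boundary, so region classes stay clean.
#'
#' @param ancestor output of [build_ancestor()].
#' @param tree `phylo` object or newick string with branch lengths, >= 3 tips.
#' @param config the [sim_config()] used to build the ancestor.
#' @return list with `samples` (named list of `plastome`s) and `truth`, a
#'   list holding `true_tree`, `true_alignments` (region key -> alignment
#'   matrix over ancestor + tips), `true_indels` (data.frame region, sample,
#'   length, class, kind) and `ir_coords` (per-sample partitions).
#' @export
evolve_along_tree <- function(ancestor, tree, config) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (length(tree$tip.label) < 3) stop("tree must have >= 3 leaves")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  tree <- ape::reorder.phylo(tree, "cladewise") # parents before children
  set.seed(config$seed + 1L)

  units <- attr(ancestor, "units")
  if (is.null(units)) stop("ancestor must come from build_ancestor()")
  keys <- unit_region_keys(units)
  labs <- node_labels(tree)
  tips <- tree$tip.label
  has_ir <- iv_len(ancestor$partition$ira) > 0

  alns <- list()
  indels <- list()
  evolved_units <- lapply(seq_along(units), function(i) units[[i]])
  names(evolved_units) <- names(units)
  tip_units <- lapply(tips, function(t) evolved_units)
  names(tip_units) <- tips

  seen_keys <- character(0)
  for (i in seq_along(units)) {
    u <- units[[i]]
    is_gene <- u$kind == "gene"
    cls <- if (is_gene) "genic" else "intergenic"
    res <- evolve_unit_along(
      str_chars(u$seq), tree,
      sub_rate = if (is_gene) config$sub_rate_genic else config$sub_rate_intergenic,
      indel_rate = if (is_gene) config$indel_rate_genic else config$indel_rate_intergenic,
      p_frame = if (is_gene) config$p_frame_genic else config$p_frame_intergenic,
      len_max = config$indel_len_max,
      is_gene = is_gene, unit_label = u$name %||% keys[i])
    key <- keys[i]
    if (!(key %in% seen_keys)) { # IR genes keyed once; every unit is unique anyway
      rows <- rbind(ancestor = res$aln[length(tips) + 1L, ],
                    res$aln[seq_along(tips), , drop = FALSE])
      rownames(rows) <- c("ancestor", tips)
      alns[[key]] <- rows
      seen_keys <- c(seen_keys, key)
    }
    for (ev in res$events) {
      indels[[length(indels) + 1L]] <- data.frame(
        region = key, sample = labs[ev$node], length = ev$length,
        class = cls, kind = ev$kind, stringsAsFactors = FALSE)
    }
    for (t in seq_along(tips)) {
      seq_t <- paste(res$aln[t, ][res$aln[t, ] != "-"], collapse = "")
      if (is_gene && nchar(seq_t) == 0)
        stop(sprintf("gene %s deleted entirely in %s", u$name, tips[t]))
      tip_units[[t]][[i]]$seq <- seq_t
    }
  }

  samples <- lapply(tips, function(t)
    assemble_plastome(t, tip_units[[t]], has_ir))
  names(samples) <- tips
  for (t in tips) attr(samples[[t]], "units") <- tip_units[[t]]

  truth <- list(
    true_tree = tree,
    true_alignments = alns,
    true_indels = if (length(indels)) do.call(rbind, indels) else
      data.frame(region = character(0), sample = character(0),
                 length = integer(0), class = character(0),
                 kind = character(0), stringsAsFactors = FALSE),
    ir_coords = lapply(samples, function(s) s$partition),
    region_keys = keys)
  list(samples = samples, truth = truth)
}

## seeded random tree over the config's taxa, mean root-to-tip depth `depth`;
## a branch-length floor keeps every edge long enough to carry signal
sim_tree <- function(config, depth = 0.5, min_bl_frac = 0.05) {
  set.seed(config$seed + 7L)
  tr <- ape::rtree(length(config$taxa), tip.label = sample(config$taxa))
  d <- ape::node.depth.edgelength(tr)
  tr$edge.length <- tr$edge.length / mean(d[seq_along(config$taxa)]) * depth
  tr$edge.length <- pmax(tr$edge.length, min_bl_frac * depth)
  tr
}

#' Run the full plastome simulation
#'
#' Builds the ancestor, obtains the guide tree (from `config$tree` or a
#' seeded random tree), evolves all samples and returns everything downstream
#' stages need as ground truth.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `tree`, `ancestor`, `samples`, `truth`.
#' @export
simulate_plastomes <- function(config) {
  ancestor <- build_ancestor(config)
  tree <- config$tree
  if (is.null(tree)) tree <- sim_tree(config)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  ev <- evolve_along_tree(ancestor, tree, config)
  list(config = config, tree = ev$truth$true_tree, ancestor = ancestor,
       samples = ev$samples, truth = ev$truth)
}

#' Emit a per-position read-coverage track for one sample
#'
#' The track is laid over the collapsed assembly scaffold (LSC + one IR copy
#' + SSC, the representation in which the inverted repeat shows doubled read
#' depth relative to the single-copy regions). Positions are 1-based in the
#' returned data.frame.
#'
#' @param sample a `plastome` with a quadripartite partition.
#' @param config a [sim_config()] providing `coverage_depth`/`coverage_sd`.
#' @return data.frame (position, depth) with attribute `ir_interval`, the
#'   planted collapsed-IR interval (0-based half-open).
#' @export
emit_coverage_track <- function(sample, config) {
  p <- sample$partition
  if (is.null(p)) stop("sample has no quadripartite partition")
  set.seed(config$seed + 2L)
  lsc <- iv_len(p$lsc); ira <- iv_len(p$ira); ssc <- iv_len(p$ssc)
  depth <- c(rep(config$coverage_depth, lsc),
             rep(2 * config$coverage_depth, ira),
             rep(config$coverage_depth, ssc))
  if (config$coverage_sd > 0)
    depth <- round(depth + stats::rnorm(length(depth), 0, config$coverage_sd))
  out <- data.frame(position = seq_along(depth), depth = depth)
  attr(out, "ir_interval") <- c(lsc, lsc + ira)
  out
}

#' Write a simulation to disk
#'
#' Emits per-sample FASTA and GFF3 under `samples/`, true per-region
#' alignments under `alignments/` (files `genic_<name>.fasta` /
#' `intergenic_<name>.fasta`, ancestor row included), the true tree as
#' newick, per-sample coverage TSVs and a region class table.
#'
#' @param sim output of [simulate_plastomes()].
#' @param dir output directory (created).
#' @param ancestor_rows keep the ancestor row in alignment files.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, ancestor_rows = TRUE) {
  dir.create(file.path(dir, "samples"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
  for (s in sim$samples) {
    write_fasta(setNames(s$sequence, s$sample_id),
                file.path(dir, "samples", paste0(s$sample_id, ".fasta")))
    write_gff3(s$features, s$sample_id,
               file.path(dir, "samples", paste0(s$sample_id, ".gff3")),
               seqlen = nchar(s$sequence))
    cov <- emit_coverage_track(s, sim$config)
    utils::write.table(cov, file.path(dir, "coverage",
                                      paste0(s$sample_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  classes <- list()
  for (key in names(sim$truth$true_alignments)) {
    mat <- sim$truth$true_alignments[[key]]
    if (!ancestor_rows) mat <- mat[rownames(mat) != "ancestor", , drop = FALSE]
    fn <- paste0(sub(":", "_", key, fixed = TRUE), ".fasta")
    write_alignment(mat, file.path(dir, "alignments", fn))
    classes[[length(classes) + 1L]] <- data.frame(
      key = key, kind = sub(":.*$", "", key), stringsAsFactors = FALSE)
  }
  gk <- do.call(rbind, classes)
  feat <- sim$ancestor$features
  gk$gene_kind <- feat$kind[match(sub("^genic:", "", gk$key), feat$name)]
  utils::write.table(gk, file.path(dir, "classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "true_tree.nwk"))
  invisible(dir)
}
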