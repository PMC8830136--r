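#' Validated configuration for the two analysis pipelines
#'
#' Defaults follow the settings used throughout the package: trimming gap
#' threshold 0.8 and minimum similarity 0.001, kmer size 31, count split
#' weights with the `10n` output rule.
#'
#' @param aln_dir directory of per-region aligned FASTA files
#'   (`genic_*.fasta` / `intergenic_*.fasta`).
#' @param fasta_dir directory of per-sample FASTA files (kmer pipeline).
#' @param classes_file optional TSV (key, kind, gene_kind) marking CDS
#'   regions for the codon matrices.
#' @param out_dir artifact directory.
#' @param outgroups outgroup sample ids.
#' @param gap_keep,min_similarity trimming thresholds.
#' @param k kmer size.
#' @param weight_fn split weight function (`count`, `geom`, `geom2`).
#' @param top split output rule (`all`, `10n`).
#' @param reference_tree optional newick path/string for comparison.
#' @param seed RNG seed recorded in the manifest.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(aln_dir = NULL, fasta_dir = NULL,
                            classes_file = NULL, out_dir = tempfile("pp_"),
                            outgroups = character(0),
                            gap_keep = 0.8, min_similarity = 0.001,
                            k = 31L, weight_fn = "count", top = "10n",
                            reference_tree = NULL, seed = 1L) {
  cfg <- list(aln_dir = aln_dir, fasta_dir = fasta_dir,
              classes_file = classes_file, out_dir = out_dir,
              outgroups = outgroups, gap_keep = gap_keep,
              min_similarity = min_similarity, k = as.integer(k),
              weight_fn = match.arg(weight_fn, c("count", "geom", "geom2")),
              top = match.arg(top, c("all", "10n")),
              reference_tree = reference_tree, seed = as.integer(seed))
  if (cfg$gap_keep < 0 || cfg$gap_keep > 1) stop("gap_keep must be in [0,1]")
  if (cfg$k < 3 || cfg$k %% 2 == 0) stop("k must be an odd integer >= 3")
  class(cfg) <- "pipeline_config"
  cfg
}

read_region_alignments <- function(dir) {
  files <- sort(list.files(dir, pattern = "^(genic|intergenic)_.*\\.fasta$",
                           full.names = TRUE))
  if (length(files) == 0) stop(sprintf("validation error: no region alignments in %s", dir))
  alns <- lapply(files, read_alignment)
  names(alns) <- sub("_", ":", sub("\\.fasta$", "", basename(files)))
  alns
}

write_manifest <- function(files, cfg, path) {
  files <- files[file.exists(files)]
  manifest <- list(
    config = unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)],
    artifacts = data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the alignment-based pipeline
#'
#' Reads per-region alignments, computes identity and variant tables, the
#' reading-frame and identity contrasts, trims and concatenates the
#' supermatrix variants, selects the diagnostic region set and infers a
#' neighbor-joining tree. All artifacts plus a manifest (config snapshot and
#' md5 per file) are written to `out_dir`.
#'
#' @param cfg a [pipeline_config()] with `aln_dir` set.
#' @return list with the in-memory results (`identities`, `variants`,
#'   `frame`, `contrast`, `matrices`, `diagnostic`, `tree`, `manifest`).
#' @export
run_alignment_pipeline <- function(cfg) {
  if (is.null(cfg$aln_dir)) stop("validation error: aln_dir not set")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  alns <- read_region_alignments(cfg$aln_dir)
  # drop non-sample rows (a simulator ancestor row) and outgroups do stay
  alns <- lapply(alns, function(m) m[rownames(m) != "ancestor", , drop = FALSE])

  ids <- identity_table(alns, cfg$outgroups)
  vt <- variant_table(alns)
  ind <- merge(vt$indels, vt$densities[, c("key", "class")], by = "key")
  frame <- if (all(c("genic", "intergenic") %in% ind$class))
    frame_analysis(ind) else NULL
  contrast <- identity_contrast(ids$identity_all[ids$class == "genic"],
                                ids$identity_all[ids$class == "intergenic"])

  trimmed <- lapply(alns, trim_alignment,
                    gap_keep = cfg$gap_keep, min_similarity = cfg$min_similarity)
  trimmed <- trimmed[vapply(trimmed, ncol, 0L) > 0]
  cds_names <- character(0)
  if (!is.null(cfg$classes_file)) {
    cl <- utils::read.table(cfg$classes_file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    cds_names <- sub("^genic:", "", cl$key[!is.na(cl$gene_kind) &
                                             cl$gene_kind == "CDS"])
  }
  mats <- build_matrices(trimmed, cds_names, cds_alns = alns)
  full <- concatenate(trimmed)
  diag_ids <- setNames(ids$identity_all, ids$key)
  diagnostic <- select_diagnostic_regions(alns, diag_ids)
  tree <- nj_tree(full)

  out <- function(f) file.path(cfg$out_dir, f)
  utils::write.table(ids, out("identities.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(vt$densities, out("densities.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ind, out("indels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(indel_size_spectrum(ind), out("indel_spectrum.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_supermatrix(full, out("supermatrix.phy"), out("partitions.txt"))
  writeLines(diagnostic$selected, out("diagnostic_regions.txt"))
  ape::write.tree(tree, out("nj_tree.nwk"))
  summaries <- lapply(Filter(Negate(is.null),
                             mats[c("genic", "intergenic", "cds", "pos12", "pos3")]),
                      `[[`, "summary")
  summaries$full <- full$summary
  jsonlite::write_json(summaries, out("matrix_summaries.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- write_manifest(
    out(c("identities.tsv", "densities.tsv", "indels.tsv",
          "indel_spectrum.tsv", "supermatrix.phy", "partitions.txt",
          "diagnostic_regions.txt", "nj_tree.nwk", "matrix_summaries.json")),
    cfg, out("manifest.json"))
  list(identities = ids, variants = vt, frame = frame, contrast = contrast,
       matrices = mats, full = full, diagnostic = diagnostic, tree = tree,
       manifest = manifest)
}

#' Run the kmer-split pipeline
#'
#' Reads per-sample FASTA files, builds the canonical kmer profile, infers
#' weighted splits, writes them as NEXUS, extracts the greedy compatible
#' (strict) tree, and — when a reference tree is supplied — reports the
#' split-set comparison.
#'
#' @param cfg a [pipeline_config()] with `fasta_dir` set.
#' @return list with `profile`, `splits`, `strict`, `comparison` (NULL
#'   without a reference tree) and `manifest`.
#' @export
run_ksplit_pipeline <- function(cfg) {
  if (is.null(cfg$fasta_dir)) stop("validation error: fasta_dir not set")
  files <- sort(list.files(cfg$fasta_dir, pattern = "\\.(fasta|fa|fastq)$",
                           full.names = TRUE))
  if (length(files) == 0)
    stop(sprintf("validation error: no FASTA files in %s", cfg$fasta_dir))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- lapply(files, function(f) unname(read_fasta(f)))
  names(samples) <- sub("\\.(fasta|fa|fastq)$", "", basename(files))
  profile <- build_profile(samples, k = cfg$k)
  splits <- infer_splits(profile, weight_fn = cfg$weight_fn, top = cfg$top)
  strict <- strict_tree(splits)
  out <- function(f) file.path(cfg$out_dir, f)
  to_splits_nexus(splits, out("splits.nex"))
  sp_tab <- splits$splits
  utils::write.table(sp_tab, out("splits.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(strict$newick, out("strict_tree.nwk"))
  comparison <- NULL
  if (!is.null(cfg$reference_tree)) {
    ref <- splits_from_tree(cfg$reference_tree)
    comparison <- compare_splits(splits_from_tree(strict$tree), ref)
    jsonlite::write_json(comparison, out("comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- write_manifest(
    out(c("splits.nex", "splits.tsv", "strict_tree.nwk", "comparison.json")),
    cfg, out("manifest.json"))
  list(profile = profile, splits = splits, strict = strict,
       comparison = comparison, manifest = manifest)
}
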