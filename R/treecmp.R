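#' Splits induced by the internal edges of a tree
#'
#' Each internal edge of the unrooted tree contributes one bipartition of
#' the leaf set, weighted by the branch length (1 when lengths are absent).
#' Trivial (leaf-edge) splits are excluded. Rooted input is unrooted on
#' parse.
#'
#' @param tree a `phylo`, newick string or newick file path.
#' @return a `split_set`.
#' @export
splits_from_tree <- function(tree) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else
      ape::read.tree(text = tree)
  }
  if (is.null(tree) || is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("parse error: tree has missing or unlabeled leaves")
  if (length(tree$tip.label) < 4) stop("need >= 4 leaves")
  tree <- ape::unroot(tree)
  taxa <- tree$tip.label
  ntip <- length(taxa)
  has_len <- !is.null(tree$edge.length)
  # leaf sets of the clade below each internal (non-root) node
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- taxa[i]
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; chd <- tr$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[chd]])
  }
  keys <- character(0); weights <- numeric(0)
  for (e in seq_len(nrow(tr$edge))) {
    chd <- tr$edge[e, 2]
    if (chd <= ntip) next # leaf edge: trivial split
    side <- desc[[chd]]
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    keys <- c(keys, split_key(side, taxa))
    weights <- c(weights, if (has_len) tr$edge.length[e] else 1)
  }
  if (anyDuplicated(keys)) { # possible only for degenerate zero-size clades
    agg <- tapply(weights, keys, sum)
    keys <- names(agg); weights <- as.numeric(agg)
  }
  split_set(taxa, keys, weights)
}

#' Compare a predicted split set against a reference
#'
#' Split identity is by bipartition membership only; weights enter the
#' weighted scores. Precision is the total weight of correctly predicted
#' splits divided by the total weight of all predicted splits; recall is the
#' analogous ratio with reference weights. The weighted symmetric set
#' distance sums, over splits present in exactly one of the two sets, that
#' set's own weights; the Robinson-Foulds distance is the plain size of the
#' symmetric difference.
#'
#' @param predicted,reference `split_set`s (or `phylo` trees, converted via
#'   [splits_from_tree()]) over the same taxon set.
#' @return list with `precision`, `recall`, `f1`,
#'   `weighted_symmetric_distance`, `rf_distance`.
#' @export
compare_splits <- function(predicted, reference) {
  if (inherits(predicted, "phylo")) predicted <- splits_from_tree(predicted)
  if (inherits(reference, "phylo")) reference <- splits_from_tree(reference)
  if (!identical(predicted$taxa, reference$taxa))
    stop(sprintf("taxon-set mismatch: only in predicted [%s]; only in reference [%s]",
                 paste(setdiff(predicted$taxa, reference$taxa), collapse = ","),
                 paste(setdiff(reference$taxa, predicted$taxa), collapse = ",")))
  p <- predicted$splits; r <- reference$splits
  shared_p <- p$key %in% r$key
  shared_r <- r$key %in% p$key
  wp <- sum(p$weight); wr <- sum(r$weight)
  precision <- if (wp > 0) sum(p$weight[shared_p]) / wp else
    as.numeric(nrow(r) == 0)
  recall <- if (wr > 0) sum(r$weight[shared_r]) / wr else
    as.numeric(nrow(p) == 0)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       weighted_symmetric_distance =
         sum(p$weight[!shared_p]) + sum(r$weight[!shared_r]),
       rf_distance = sum(!shared_p) + sum(!shared_r))
}

#' All-vs-all comparison of named split sets
#'
#' Every collection serves once as prediction and once as reference.
#'
#' @param collections named list of `split_set`s (or trees) over shared
#'   taxa, length >= 2.
#' @return list with `reports` (long data.frame: predicted, reference,
#'   precision, recall, f1, weighted_symmetric_distance, rf_distance) and
#'   `rf_matrix`.
#' @export
all_vs_all <- function(collections) {
  stopifnot(length(collections) >= 2, !is.null(names(collections)))
  collections <- lapply(collections, function(x)
    if (inherits(x, "phylo")) splits_from_tree(x) else x)
  nm <- names(collections)
  rows <- list()
  rf <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in nm) for (j in nm) {
    rep_ <- compare_splits(collections[[i]], collections[[j]])
    rows[[paste(i, j)]] <- data.frame(
      predicted = i, reference = j, precision = rep_$precision,
      recall = rep_$recall, f1 = rep_$f1,
      weighted_symmetric_distance = rep_$weighted_symmetric_distance,
      rf_distance = rep_$rf_distance, stringsAsFactors = FALSE)
    rf[i, j] <- rep_$rf_distance
  }
  list(reports = do.call(rbind, unname(rows)), rf_matrix = rf)
}
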