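#' Detect the quadripartite plastome architecture from sequence
#'
#' Finds the maximal-length pair of non-overlapping intervals whose sequences
#' are exact reverse complements of each other (the two inverted-repeat
#' copies), handling repeats that cross the origin of the circular molecule
#' by searching on the doubled sequence. The two single-copy arcs between the
#' repeats are labelled LSC (the longer) and SSC (the shorter); IRa is the
#' copy that immediately follows the LSC.
#'
#' Candidate repeats are seeded with exact 32-mer matches against the reverse
#' complement, grouped by anti-diagonal (the sum of the two start
#' coordinates, which is constant along an inverted-repeat pair), and
#' extended base by base to maximality.
#'
#' @param sequence circular DNA string, or a `plastome`.
#' @param min_ir_len minimum inverted-repeat length to report (bp).
#' @return list with 0-based half-open intervals `lsc`, `ssc`, `ira`, `irb`
#'   (an interval with `end > n` wraps past the origin), `orientation_flag`,
#'   and `has_ir`. When no repeat of the required length exists the IRs are
#'   empty, the whole molecule is labelled LSC and a warning is raised.
#' @export
detect_quadripartite <- function(sequence, min_ir_len = 500L) {
  if (inherits(sequence, "plastome")) sequence <- sequence$sequence
  n <- nchar(sequence)
  if (n < 4L * min_ir_len)
    stop("sequence shorter than 4 * min_ir_len")
  w <- 32L
  D <- paste0(sequence, sequence)
  starts <- seq_len(2L * n - w + 1L)
  kmers <- substring(D, starts, starts + w - 1L)
  pos_by_kmer <- split(starts, kmers)
  # cap hyper-repetitive seeds (low-complexity guard)
  pos_by_kmer <- pos_by_kmer[lengths(pos_by_kmer) <= 100L]

  best <- NULL
  antidiag <- new.env(parent = emptyenv())
  for (K in names(pos_by_kmer)) {
    P <- pos_by_kmer[[K]]
    P <- P[P <= n]
    if (length(P) == 0) next
    rc <- revcomp(K)
    Q <- pos_by_kmer[[rc]]
    if (is.null(Q)) next
    for (i in P) {
      js <- Q[Q >= i + w & Q <= i + n - 1L]
      for (j in js) {
        s <- as.character(i + j)
        antidiag[[s]] <- c(antidiag[[s]], i)
      }
    }
  }
  cands <- ls(antidiag)
  best_len <- 0L; best_iv <- NULL
  for (s_ch in cands) {
    s <- as.integer(s_ch)
    is <- sort(unique(antidiag[[s_ch]]))
    # maximal runs of consecutive seed starts along one anti-diagonal
    runs <- split(is, cumsum(c(1L, diff(is) != 1L)))
    for (r in runs) {
      imin <- r[1]; imax <- r[length(r)]
      L1 <- imin; L2 <- imax + w - 1L
      R1 <- s - imax; R2 <- s - imin + w - 1L
      len <- L2 - L1 + 1L
      if (len < min_ir_len) next
      if (R1 <= L2) next # overlapping halves
      # circular disjointness of the two loci
      a <- c((L1 - 1L) %% n, (L1 - 1L) %% n + len)
      b <- c((R1 - 1L) %% n, (R1 - 1L) %% n + len)
      if (circ_overlap(a, b, n)) next
      if (len > best_len) { best_len <- len; best_iv <- list(a = a, b = b) }
    }
  }

  if (is.null(best_iv)) {
    warning("no inverted repeat >= min_ir_len found; whole molecule labelled LSC")
    return(list(lsc = c(0L, n), ssc = c(n, n), ira = c(0L, 0L),
                irb = c(0L, 0L), orientation_flag = "canonical",
                has_ir = FALSE))
  }

  a <- best_iv$a; b <- best_iv$b
  # single-copy arcs between the repeats (circular complement)
  arc1 <- c(a[2] %% n, a[2] %% n + (b[1] - a[2]) %% n)
  arc2 <- c(b[2] %% n, b[2] %% n + (a[1] - b[2] %% n) %% n)
  if (iv_len(arc1) >= iv_len(arc2)) {
    lsc <- arc1; ssc <- arc2; ira <- b; irb <- a
  } else {
    lsc <- arc2; ssc <- arc1; ira <- a; irb <- b
  }
  list(lsc = lsc, ssc = ssc, ira = ira, irb = irb,
       orientation_flag = "canonical", has_ir = TRUE)
}

#' Detect the inverted repeat from a read-coverage track
#'
#' In a collapsed assembly the IR shows roughly doubled read depth relative
#' to the single-copy regions. The single-copy baseline is first taken as the
#' median depth, candidate doubled positions are flagged, the baseline is
#' re-estimated as the mean over non-candidate positions, and the maximal
#' contiguous run whose depth ratio lies in `[factor_low, factor_high]` is
#' returned.
#'
#' @param track numeric depth vector or data.frame (position, depth).
#' @param factor_low,factor_high acceptable depth ratio band for the IR.
#' @return 0-based half-open interval `c(start, end)`; `c(0, 0)` for a flat
#'   track with no doubled segment.
#' @export
detect_ir_by_coverage <- function(track, factor_low = 1.5, factor_high = 2.5) {
  if (is.data.frame(track)) track <- track$depth[order(track$position)]
  if (length(track) == 0) stop("empty coverage track")
  m0 <- stats::median(track)
  if (m0 <= 0) stop("non-positive baseline depth")
  cand <- track / m0 >= factor_low & track / m0 <= factor_high
  base <- if (all(cand)) m0 else mean(track[!cand])
  keep <- track / base >= factor_low & track / base <= factor_high
  if (!any(keep)) return(c(0L, 0L))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  i <- ok[which.max(r$lengths[ok])]
  c(starts[i] - 1L, ends[i])
}

#' Normalize the SSC orientation of an annotated plastome
#'
#' The small single-copy region can occur in either orientation between the
#' inverted repeats; both variants co-occur in living cells. A fixed
#' convention makes samples comparable: the canonical orientation is the one
#' in which the SSC sequence is lexicographically smaller than its reverse
#' complement. A non-canonical SSC is reverse-complemented in place and the
#' features it contains are remapped (coordinates mirrored, strands
#' flipped). Idempotent.
#'
#' @param p a `plastome` with a non-wrapping quadripartite partition.
#' @return the normalized `plastome`.
#' @export
normalize_orientation <- function(p) {
  part <- p$partition
  if (is.null(part)) stop("partition required")
  iv <- part$ssc
  if (iv_len(iv) == 0) return(p)
  if (iv[2] > nchar(p$sequence)) stop("wrapping SSC not supported; relinearize first")
  ssc <- substr(p$sequence, iv[1] + 1, iv[2])
  rc <- revcomp(ssc)
  if (ssc <= rc) {
    p$partition$orientation_flag <- "canonical"
    return(p)
  }
  straddle <- p$features$start < iv[1] & p$features$end > iv[1] |
    p$features$start < iv[2] & p$features$end > iv[2]
  if (any(straddle))
    stop(sprintf("cannot remap feature(s) straddling the SSC boundary: %s",
                 paste(p$features$name[straddle], collapse = ", ")))
  seq2 <- paste0(substr(p$sequence, 1, iv[1]), rc,
                 substr(p$sequence, iv[2] + 1, nchar(p$sequence)))
  f <- p$features
  inside <- f$start >= iv[1] & f$end <= iv[2]
  ns <- iv[1] + iv[2] - f$end[inside]
  ne <- iv[1] + iv[2] - f$start[inside]
  f$start[inside] <- ns
  f$end[inside] <- ne
  f$strand[inside] <- ifelse(f$strand[inside] == "+", "-", "+")
  f <- f[order(f$start), , drop = FALSE]
  rownames(f) <- NULL
  p$sequence <- seq2
  p$features <- f
  p$partition$orientation_flag <- "canonical"
  p
}
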