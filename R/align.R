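#' Global alignment of two sequences
#'
#' Banded Needleman-Wunsch-Gotoh alignment with affine gaps.  A gap of
#' length L costs `gap_open + gap_ext * L`.  The band is widened
#' automatically to cover the length difference of the two sequences.
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gap_open,gap_ext scoring parameters (defaults
#'   +1/-1/2/1).
#' @param band extra band half-width beyond the length difference;
#'   `NULL` chooses `max(64, 5%% of the shorter sequence)`.
#' @param free_subject_ends when `TRUE`, leading and trailing gaps in
#'   `b` are free (semi-global placement of `a` within `b`).
#' @return A list with gapped strings `a` and `b` (equal length, `-` for
#'   gaps) and the optimal `score`.
#' @export
align_pair <- function(a, b, match = 1L, mismatch = -1L,
                       gap_open = 2L, gap_ext = 1L, band = NULL,
                       free_subject_ends = FALSE) {
  if (is.null(band)) {
    band <- max(64L, as.integer(0.05 * min(nchar(a), nchar(b))))
  }
  cpp_nw_align(a, b, match, mismatch, gap_open, gap_ext,
               as.integer(band), free_subject_ends)
}

#' Anchor-based alignment of two near-identical assemblies
#'
#' For each chromosome present in both assemblies, k-mers unique in both
#' genomes seed exact-match anchors; anchors are chained collinearly
#' (maximum total anchored length, ties broken by leftmost query start)
#' and the regions between successive anchors — and before the first and
#' after the last — are closed by banded global alignment.  The genomes
#' are assumed collinear and co-oriented: one block is produced per
#' shared chromosome.  Blocks shorter than `min_block` are discarded.
#' Chromosomes for which no anchor is found are reported as unaligned
#' rather than silently dropped.
#'
#' @param query,subject assemblies (see [as_genome()]).
#' @param k anchor k-mer size (>= 11).
#' @param min_block minimum block length (alignment columns) to retain.
#' @return A list of alignment blocks.  Each block is a list with
#'   `query_chrom`, `q_start`, `q_end`, `subject_chrom`, `s_start`,
#'   `s_end` (0-based half-open), `orientation`, and gapped strings
#'   `q_aln`/`s_aln`; unaligned chromosomes yield a block with
#'   `unaligned = TRUE`.
#' @export
anchor_align <- function(query, subject, k = 15L, min_block = 0L) {
  query <- as_genome(query)
  subject <- as_genome(subject)
  if (!length(query) || !length(subject)) stop("empty assembly")
  if (k < 11L) stop("k must be >= 11")
  shared <- intersect(names(query), names(subject))
  blocks <- list()
  for (chrom in shared) {
    q <- query[[chrom]]
    s <- subject[[chrom]]
    if (q == s) {  # fast path for byte-identical chromosomes
      blocks[[length(blocks) + 1L]] <- list(
        query_chrom = chrom, q_start = 0L, q_end = nchar(q),
        subject_chrom = chrom, s_start = 0L, s_end = nchar(s),
        orientation = "+", q_aln = q, s_aln = s)
      next
    }
    anchors <- cpp_find_anchors(q, s, as.integer(k))
    if (nrow(anchors) == 0L) {
      blocks[[length(blocks) + 1L]] <- list(
        query_chrom = chrom, subject_chrom = chrom, unaligned = TRUE)
      next
    }
    chain <- chain_anchors(anchors)
    aln <- stitch_alignment(q, s, chain)
    blocks[[length(blocks) + 1L]] <- c(
      list(query_chrom = chrom, q_start = 0L, q_end = nchar(q),
           subject_chrom = chrom, s_start = 0L, s_end = nchar(s),
           orientation = "+"),
      aln)
  }
  if (min_block > 0L) {
    blocks <- Filter(function(b) isTRUE(b$unaligned) ||
                       nchar(b$q_aln) >= min_block, blocks)
  }
  blocks
}

## Collinear chaining: maximum-weight increasing chain over anchor
## segments (weight = segment length), ties broken by leftmost query
## start.  Anchors come sorted by q0.  O(n^2); the merged anchors of
## near-identical genomes number in the hundreds, but guard anyway.
chain_anchors <- function(anchors) {
  n <- nrow(anchors)
  if (n > 20000L) {  # keep the longest segments if pathological
    keep <- order(anchors[, "len"], decreasing = TRUE)[1:20000]
    anchors <- anchors[sort(keep), , drop = FALSE]
    n <- nrow(anchors)
  }
  q0 <- anchors[, "q0"]; s0 <- anchors[, "s0"]; len <- anchors[, "len"]
  best <- as.numeric(len)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    j <- which(q0[1:(i - 1)] + len[1:(i - 1)] <= q0[i] &
               s0[1:(i - 1)] + len[1:(i - 1)] <= s0[i])
    if (length(j)) {
      cand <- best[j] + len[i]
      b <- which.max(cand)   # which.max takes the first (leftmost) tie
      if (cand[b] > best[i]) {
        best[i] <- cand[b]
        prev[i] <- j[b]
      }
    }
  }
  i <- which.max(best)
  path <- integer(0)
  while (!is.na(i)) {
    path <- c(i, path)
    i <- prev[i]
  }
  anchors[path, , drop = FALSE]
}

## Close inter-anchor segments with banded global alignment and
## concatenate into one gapped alignment per chromosome.
stitch_alignment <- function(q, s, chain) {
  qa_parts <- character(0)
  sa_parts <- character(0)
  qpos <- 0L; spos <- 0L
  close_segment <- function(qseg, sseg) {
    if (!nchar(qseg) && !nchar(sseg)) return(c("", ""))
    if (!nchar(qseg)) return(c(strrep("-", nchar(sseg)), sseg))
    if (!nchar(sseg)) return(c(qseg, strrep("-", nchar(qseg))))
    al <- align_pair(qseg, sseg)
    c(al$a, al$b)
  }
  for (i in seq_len(nrow(chain))) {
    a0 <- chain[i, "q0"]; b0 <- chain[i, "s0"]; l <- chain[i, "len"]
    seg <- close_segment(substr0(q, qpos, a0), substr0(s, spos, b0))
    anchor_seq <- substr0(q, a0, a0 + l)
    qa_parts <- c(qa_parts, seg[1], anchor_seq)
    sa_parts <- c(sa_parts, seg[2], anchor_seq)
    qpos <- a0 + l; spos <- b0 + l
  }
  seg <- close_segment(substr0(q, qpos, nchar(q)), substr0(s, spos, nchar(s)))
  list(q_aln = paste0(paste(qa_parts, collapse = ""), seg[1]),
       s_aln = paste0(paste(sa_parts, collapse = ""), seg[2]))
}

#' Tally columns of an alignment block
#'
#' Counts matches, mismatches, N-masked columns, and maximal
#' insertion/deletion runs (insertions are bases present in the query
#' and absent from the subject).  With `mask_n`, any gap-free column in
#' which either base is N is counted only as `n_masked_columns`.
#'
#' @param block an alignment block from [anchor_align()], or any list
#'   with gapped strings `q_aln` and `s_aln`.
#' @param mask_n logical; exclude N-containing columns from
#'   match/mismatch tallies.
#' @return A list of counts: `matches`, `mismatches`,
#'   `n_masked_columns`, `insertion_runs`, `insertion_bases`,
#'   `deletion_runs`, `deletion_bases`.
#' @export
count_columns <- function(block, mask_n = TRUE) {
  if (isTRUE(block$unaligned)) {
    stop("cannot count columns of an unaligned block (",
         block$query_chrom, ")")
  }
  qa <- charToRaw(block$q_aln)
  sa <- charToRaw(block$s_aln)
  if (length(qa) != length(sa)) {
    stop("malformed block: aligned strings differ in length (",
         block$query_chrom, ")")
  }
  gap <- charToRaw("-")
  nn <- charToRaw("N")
  qgap <- qa == gap
  sgap <- sa == gap
  if (any(qgap & sgap)) {
    stop("malformed block: gap aligned to gap (", block$query_chrom, ")")
  }
  gapfree <- !qgap & !sgap
  has_n <- gapfree & (qa == nn | sa == nn)
  if (!mask_n) has_n[] <- FALSE
  eq <- gapfree & !has_n & qa == sa
  run_stats <- function(isgap) {
    r <- rle(isgap)
    list(runs = sum(r$values), bases = sum(r$lengths[r$values]))
  }
  ins <- run_stats(sgap)   # query has sequence, subject a gap
  del <- run_stats(qgap)
  list(matches = sum(eq),
       mismatches = sum(gapfree & !has_n & !eq),
       n_masked_columns = sum(has_n),
       insertion_runs = ins$runs, insertion_bases = ins$bases,
       deletion_runs = del$runs, deletion_bases = del$bases)
}
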