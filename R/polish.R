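#' Find undetermined (N) regions in a draft assembly
#'
#' @param assembly draft assembly (see [as_genome()]).
#' @return A data.frame of maximal N runs with columns `chrom`, `start`,
#'   `end` (0-based half-open), sorted by chromosome then start.
#' @export
find_gaps <- function(assembly) {
  assembly <- as_genome(assembly)
  out <- lapply(names(assembly), function(cn) {
    runs <- char_runs(assembly[[cn]], "N")
    if (!nrow(runs)) return(NULL)
    cbind(data.frame(chrom = cn, stringsAsFactors = FALSE), runs)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Place the flanks of a gap in a relative assembly
#'
#' Extracts the sequences `flank_length` bases 5' and 3' of a gap in
#' the draft and locates each in the relative assembly, requiring at
#' least 95% identity over at least 90% of the flank.  A flank with a
#' second candidate location scoring within 5% of the best is marked
#' ambiguous; flanks placed on different chromosomes or in reversed
#' order are discordant.  Gaps at chromosome ends (a truncated or
#' absent flank) are never placeable.
#'
#' @param gap one row of [find_gaps()] output (or a list with `chrom`,
#'   `start`, `end`).
#' @param draft the draft assembly.
#' @param relative a relative assembly to search.
#' @param flank_length flank size in bases (default 1000, >= 50).
#' @return A list with `status` (`placed`, `unplaced`, `ambiguous` or
#'   `discordant`), flank locations (`chrom`, `start5`, `end5`,
#'   `start3`, `end3`) and `distance`, the number of relative bases
#'   between the flanks (negative when the placements overlap).
#' @export
place_flanks <- function(gap, draft, relative, flank_length = 1000L) {
  if (flank_length < 50L) stop("flank_length must be >= 50")
  draft <- as_genome(draft)
  relative <- as_genome(relative)
  dseq <- draft[[gap$chrom]]
  f5_start <- gap$start - flank_length
  f3_end <- gap$end + flank_length
  if (f5_start < 0L || f3_end > nchar(dseq)) {
    return(list(status = "unplaced", reason = "gap at chromosome end"))
  }
  f5 <- substr0(dseq, f5_start, gap$start)
  f3 <- substr0(dseq, gap$end, f3_end)
  p5 <- locate_flank(f5, relative)
  p3 <- locate_flank(f3, relative)
  if (p5$status != "placed" || p3$status != "placed") {
    st <- if ("ambiguous" %in% c(p5$status, p3$status)) "ambiguous"
          else "unplaced"
    return(list(status = st, reason = paste(p5$status, p3$status)))
  }
  if (p5$chrom != p3$chrom) {
    return(list(status = "discordant", reason = "different chromosomes"))
  }
  if (p3$start < p5$start) {
    return(list(status = "discordant", reason = "flanks in reversed order"))
  }
  list(status = "placed", chrom = p5$chrom,
       start5 = p5$start, end5 = p5$end,
       start3 = p3$start, end3 = p3$end,
       distance = p3$start - p5$end)
}

## best placement of one flank across all chromosomes of `relative`;
## exact matches first, then mismatch-tolerant search
locate_flank <- function(flank, relative, max_div = 0.05,
                         ambiguity_margin = 0.05) {
  if (grepl("^N+$", flank)) return(list(status = "unplaced"))
  len <- nchar(flank)
  pat <- Biostrings::DNAString(flank)
  hits <- list()
  for (cn in names(relative)) {
    subj <- Biostrings::DNAString(relative[[cn]])
    mm_budget <- as.integer(max_div * len)
    ## pattern Ns (nearby gaps inside the flank) match any subject base
    m <- Biostrings::matchPattern(pat, subj, max.mismatch = mm_budget,
                                  with.indels = FALSE,
                                  fixed = c(pattern = FALSE,
                                            subject = TRUE))
    if (length(m)) {
      mm <- Biostrings::neditAt(pat, subj, at = IRanges::start(m),
                                with.indels = FALSE,
                                fixed = c(pattern = FALSE,
                                          subject = TRUE))
      for (i in seq_along(m)) {
        hits[[length(hits) + 1L]] <- list(
          chrom = cn, start = IRanges::start(m)[i] - 1L,
          end = IRanges::end(m)[i], score = 1 - mm[i] / len)
      }
    }
  }
  if (!length(hits)) return(list(status = "unplaced"))
  scores <- vapply(hits, `[[`, 0, "score")
  ord <- order(scores, decreasing = TRUE)
  best <- hits[[ord[1]]]
  if (length(hits) > 1 &&
      scores[ord[2]] >= scores[ord[1]] - ambiguity_margin) {
    return(list(status = "ambiguous"))
  }
  c(list(status = "placed"), best)
}

#' Decide how to treat one gap given placements in two relatives
#'
#' The sequences between the placed flanks in the two relatives are
#' compared: identical sequences are copied in (`fill_identical`);
#' equal-length sequences differing at up to `max_ambiguous` positions
#' give a consensus with N at each disagreement (`fill_consensus`);
#' more disagreements give `skip_too_ambiguous`; unequal lengths give
#' `skip_length_mismatch` (no attempt is made to arbitrate); flanks
#' overlapping in both relatives indicate erroneously duplicated draft
#' sequence and give `trim_overlap` with the smaller overlap.
#'
#' @param placement_a,placement_b [place_flanks()] results for the two
#'   relatives.
#' @param relative_a,relative_b the relative assemblies.
#' @param max_ambiguous maximum tolerated disagreeing positions
#'   (default 10).
#' @return A list with `verdict`, and `infill` (fill verdicts) or
#'   `trim` (overlap trim length), plus `n_ambiguous` for consensus
#'   fills.
#' @export
decide_gap <- function(placement_a, placement_b,
                       relative_a, relative_b, max_ambiguous = 10L) {
  if (placement_a$status != "placed" || placement_b$status != "placed") {
    return(list(verdict = "unplaced",
                reason = paste(placement_a$status, placement_b$status)))
  }
  da <- placement_a$distance
  db <- placement_b$distance
  if (da < 0L && db < 0L) {
    return(list(verdict = "trim_overlap",
                trim = as.integer(min(-da, -db))))
  }
  if (da < 0L || db < 0L) {
    return(list(verdict = "unplaced",
                reason = "relatives disagree on flank overlap"))
  }
  relative_a <- as_genome(relative_a)
  relative_b <- as_genome(relative_b)
  seq_a <- substr0(relative_a[[placement_a$chrom]],
                   placement_a$end5, placement_a$start3)
  seq_b <- substr0(relative_b[[placement_b$chrom]],
                   placement_b$end5, placement_b$start3)
  if (identical(seq_a, seq_b)) {
    return(list(verdict = "fill_identical", infill = seq_a,
                n_ambiguous = 0L))
  }
  if (nchar(seq_a) != nchar(seq_b)) {
    return(list(verdict = "skip_length_mismatch"))
  }
  va <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  vb <- strsplit(seq_b, "", fixed = TRUE)[[1]]
  diff <- va != vb
  if (sum(diff) > max_ambiguous) {
    return(list(verdict = "skip_too_ambiguous"))
  }
  va[diff] <- "N"
  list(verdict = "fill_consensus", infill = paste(va, collapse = ""),
       n_ambiguous = sum(diff))
}

#' Apply gap decisions to a draft assembly
#'
#' Decisions are applied right-to-left per chromosome so coordinates
#' remain valid.  Fills replace the N run with the relative-derived
#' sequence; overlap trims delete the N run together with the
#' superfluous duplicated bases 3' of it.  Non-N draft bases are never
#' altered except within trim spans.
#'
#' @param draft the draft assembly.
#' @param gaps [find_gaps()] rows the decisions refer to.
#' @param decisions list of [decide_gap()] results, parallel to `gaps`.
#' @return A list with the polished `assembly` and `report`, a list of
#'   class `polish_report` with `bases_added` (defined bases written),
#'   `bases_removed` (defined bases deleted by trims), `gaps_filled`,
#'   `gaps_trimmed`, `gaps_skipped_by_reason`, `n_remaining` and
#'   `n_stretches_remaining`.
#' @export
apply_decisions <- function(draft, gaps, decisions) {
  draft <- as_genome(draft)
  if (nrow(gaps) != length(decisions)) {
    stop("gaps and decisions must be parallel")
  }
  if (nrow(gaps)) {
    key <- paste(gaps$chrom, gaps$start)
    if (anyDuplicated(key)) {
      stop("decisions reference duplicate gaps: ",
           key[duplicated(key)][1])
    }
  }
  bases_added <- 0L
  bases_removed <- 0L
  gaps_filled <- 0L
  gaps_trimmed <- 0L
  skipped <- c(skip_length_mismatch = 0L, skip_too_ambiguous = 0L,
               unplaced = 0L)
  ord <- order(gaps$chrom, -gaps$start)
  for (i in ord) {
    d <- decisions[[i]]
    g <- gaps[i, ]
    seq <- draft[[g$chrom]]
    if (d$verdict %in% c("fill_identical", "fill_consensus")) {
      draft[g$chrom] <- splice_string(seq, g$start, g$end, d$infill)
      bases_added <- bases_added +
        nchar(gsub("N", "", d$infill, fixed = TRUE))
      gaps_filled <- gaps_filled + 1L
    } else if (d$verdict == "trim_overlap") {
      trim_end <- min(nchar(seq), g$end + d$trim)
      removed <- substr0(seq, g$end, trim_end)
      draft[g$chrom] <- splice_string(seq, g$start, trim_end, "")
      bases_removed <- bases_removed +
        nchar(gsub("N", "", removed, fixed = TRUE))
      gaps_trimmed <- gaps_trimmed + 1L
    } else {
      nm <- if (d$verdict %in% names(skipped)) d$verdict else "unplaced"
      skipped[nm] <- skipped[nm] + 1L
    }
  }
  n_remaining <- sum(vapply(draft, function(s)
    nchar(gsub("[^N]", "", s)), 0L))
  n_stretches <- nrow(find_gaps(draft))
  report <- structure(list(
    bases_added = bases_added, bases_removed = bases_removed,
    gaps_filled = gaps_filled, gaps_trimmed = gaps_trimmed,
    gaps_skipped_by_reason = skipped,
    n_remaining = n_remaining,
    n_stretches_remaining = n_stretches), class = "polish_report")
  list(assembly = draft, report = report)
}

#' @export
print.polish_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Polish report: +%d bp defined sequence, -%d bp removed, ",
    "%d gaps filled, %d trimmed\n  skipped: %s\n  remaining: %d Ns in %d stretches\n"),
    x$bases_added, x$bases_removed, x$gaps_filled, x$gaps_trimmed,
    paste(names(x$gaps_skipped_by_reason),
          x$gaps_skipped_by_reason, sep = "=", collapse = ", "),
    x$n_remaining, x$n_stretches_remaining))
  invisible(x)
}

#' Polish a draft assembly against two relative assemblies
#'
#' Runs the full flanking-consensus workflow: find maximal N runs,
#' place 5'/3' flanks in both relatives, decide each gap
#' (copy / consensus / skip / trim), and apply the decisions.
#'
#' @param draft the draft assembly to polish.
#' @param relative_a,relative_b two higher-quality relative assemblies.
#' @param flank_length flank size in bases (default 1000).
#' @param max_ambiguous maximum consensus disagreements (default 10).
#' @return A list with `assembly`, `report`, `gaps` and `decisions`.
#' @export
polish_assembly <- function(draft, relative_a, relative_b,
                            flank_length = 1000L, max_ambiguous = 10L) {
  draft <- as_genome(draft)
  relative_a <- as_genome(relative_a)
  relative_b <- as_genome(relative_b)
  gaps <- find_gaps(draft)
  decisions <- lapply(seq_len(nrow(gaps)), function(i) {
    g <- gaps[i, ]
    pa <- place_flanks(g, draft, relative_a, flank_length)
    pb <- place_flanks(g, draft, relative_b, flank_length)
    decide_gap(pa, pb, relative_a, relative_b, max_ambiguous)
  })
  res <- apply_decisions(draft, gaps, decisions)
  c(res, list(gaps = gaps, decisions = decisions))
}
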