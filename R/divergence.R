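#' Delete homopolymer runs from an assembly
#'
#' Removes (deletes, does not collapse) every maximal run of `min_run`
#' or more identical non-N bases, case-insensitively.  Deletion of one
#' run can fuse flanking bases into a new qualifying run, so the pass is
#' repeated to a fixed point: the result contains no run of `min_run`
#' identical non-N characters.
#'
#' @param assembly genome assembly (see [as_genome()]).
#' @param min_run minimum run length to delete (>= 2; default 5, the
#'   run length at which long-read homopolymer calls become unreliable).
#' @return The stripped assembly (chromosomes may be empty strings).
#' @export
strip_homopolymers <- function(assembly, min_run = 5L) {
  assembly <- as_genome(assembly)
  if (min_run < 2L) stop("min_run must be >= 2")
  pat <- sprintf("([ACGT])\\1{%d,}", min_run - 1L)
  strip1 <- function(s) {
    repeat {
      s2 <- gsub(pat, "", s, perl = TRUE)
      if (identical(s2, s)) return(s2)
      s <- s2
    }
  }
  vapply(assembly, strip1, "")
}

#' Pairwise divergence metrics between two assemblies
#'
#' Aligns two near-identical assemblies ([anchor_align()]) and computes
#' gap-excluded and gap-compressed identity and per-Mb difference
#' frequencies over the retained blocks:
#' \itemize{
#'   \item gap-excluded identity = matches / (matches + mismatches) over
#'     gap-free (and, with `mask_n`, N-free) columns; indels ignored.
#'   \item gap-compressed divergence = (mismatches + indel runs) /
#'     (matches + mismatches + indel runs): each maximal indel run is a
#'     single difference event.
#' }
#' Per-Mb rates use the corresponding denominators.  With
#' `strip_homopolymers = TRUE`, homopolymer runs are deleted from *both*
#' genomes and the alignment recomputed, and the block-length filter is
#' applied after stripping.
#'
#' @param query,subject assemblies (see [as_genome()]).
#' @param min_block minimum alignment block length retained (default
#'   1 Mb as for chromosome-scale comparisons; lower it for small test
#'   genomes).
#' @param mask_n exclude columns containing N from the tallies.
#' @param strip_homopolymers also compute (or only compute, see
#'   `modes`) metrics after homopolymer deletion.
#' @param k anchor k-mer size passed to [anchor_align()].
#' @return An object of class `divergence_report`: a data.frame with
#'   one row per masking mode and columns `mode`,
#'   `gap_excluded_identity`, `gap_compressed_divergence`,
#'   `gap_excluded_diffs_per_mb`, `gap_compressed_diffs_per_mb`,
#'   `total_block_length`, `n_blocks`, plus attribute `counts` (the
#'   summed column tallies per mode).  Modes with no qualifying block
#'   carry NA metrics and `qualifying = FALSE`.
#' @export
pairwise_divergence <- function(query, subject, min_block = 1000000L,
                                mask_n = TRUE,
                                strip_homopolymers = FALSE,
                                k = 15L) {
  query <- as_genome(query)
  subject <- as_genome(subject)
  modes <- if (strip_homopolymers) {
    c("with_homopolymers", "without_homopolymers")
  } else "with_homopolymers"
  rows <- list()
  counts_by_mode <- list()
  for (mode in modes) {
    if (mode == "without_homopolymers") {
      q <- strip_homopolymers(query)
      s <- strip_homopolymers(subject)
    } else {
      q <- query; s <- subject
    }
    blocks <- anchor_align(q, s, k = k, min_block = min_block)
    blocks <- Filter(function(b) !isTRUE(b$unaligned), blocks)
    if (!length(blocks)) {
      rows[[mode]] <- data.frame(
        mode = mode, qualifying = FALSE,
        gap_excluded_identity = NA_real_,
        gap_compressed_divergence = NA_real_,
        gap_excluded_diffs_per_mb = NA_real_,
        gap_compressed_diffs_per_mb = NA_real_,
        total_block_length = 0L, n_blocks = 0L,
        stringsAsFactors = FALSE)
      next
    }
    tallies <- lapply(blocks, count_columns, mask_n = mask_n)
    tot <- Reduce(function(x, y) Map(`+`, x, y), tallies)
    counts_by_mode[[mode]] <- tot
    ge_den <- tot$matches + tot$mismatches
    events <- tot$mismatches + tot$insertion_runs + tot$deletion_runs
    gc_den <- ge_den + tot$insertion_runs + tot$deletion_runs
    rows[[mode]] <- data.frame(
      mode = mode, qualifying = TRUE,
      gap_excluded_identity = tot$matches / ge_den,
      gap_compressed_divergence = events / gc_den,
      gap_excluded_diffs_per_mb = tot$mismatches * 1e6 / ge_den,
      gap_compressed_diffs_per_mb = events * 1e6 / gc_den,
      total_block_length =
        sum(vapply(blocks, function(b) nchar(b$q_aln), 0)),
      n_blocks = length(blocks),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "counts") <- counts_by_mode
  class(out) <- c("divergence_report", class(out))
  out
}

#' Expected number of nucleotide changes in a genome compartment
#'
#' Multiplies a per-Mb difference rate by genome size and by the
#' fraction of the genome in the compartment of interest (e.g. introns
#' at 5% or exons at 40% of a compact fungal genome).
#'
#' @param rate_per_mb differences per Mb.
#' @param genome_size_mb genome size in Mb.
#' @param fraction compartment fraction of the genome, in `[0, 1]`.
#' @return A list with `expected` (raw value) and `rounded` (nearest
#'   integer).
#' @examples
#' expected_change_count(5, 31.14, 0.05)  # ~8 intronic changes
#' @export
expected_change_count <- function(rate_per_mb, genome_size_mb, fraction) {
  if (rate_per_mb < 0 || genome_size_mb < 0 || fraction < 0) {
    stop("all arguments must be >= 0")
  }
  x <- rate_per_mb * genome_size_mb * fraction
  list(expected = x, rounded = round(x))
}

#' Convert a percent divergence to base spacing between differences
#'
#' A divergence of 0.002% corresponds to one difference per 50 kb.
#'
#' @param percent divergence as a percentage (> 0).
#' @return Bases per difference.
#' @examples
#' divergence_spacing(0.002)   # 50000
#' divergence_spacing(0.0005)  # 2e5
#' @export
divergence_spacing <- function(percent) {
  if (percent <= 0) stop("percent must be > 0")
  100 / percent
}

#' Write a divergence report as TSV and JSON
#'
#' @param report a `divergence_report` from [pairwise_divergence()].
#' @param path output path without extension; `<path>.tsv` and
#'   `<path>.json` are written.
#' @param query,subject labels for the compared assemblies.
#' @return Invisibly, the two paths.
#' @export
write_divergence_report <- function(report, path,
                                    query = "query", subject = "subject") {
  tab <- cbind(data.frame(query = query, subject = subject,
                          stringsAsFactors = FALSE),
               as.data.frame(report))
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(tab, json, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}
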