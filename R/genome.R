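#' Genome assemblies
#'
#' A genome assembly is represented as a named character vector of
#' uppercase chromosome sequences over the alphabet A/C/G/T/N.  Functions
#' throughout the package accept either such a vector or a
#' [Biostrings::DNAStringSet]; [as_genome()] normalises to the internal
#' form (lowercase input is uppercased on read).
#'
#' @param x a named character vector or a `DNAStringSet`.
#' @return A named character vector of uppercase sequences.
#' @examples
#' as_genome(c(chr1 = "acgtn"))
#' @export
as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  if (!is.character(x)) {
    stop("genome must be a named character vector or DNAStringSet")
  }
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    stop("all chromosomes must be named")
  }
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("non-ACGTN characters in chromosome(s): ",
         paste(names(x)[bad], collapse = ", "))
  }
  x
}

#' Read a genome assembly from FASTA
#'
#' @param path path to a (possibly gzipped) FASTA file.
#' @return A named character vector of uppercase sequences (see
#'   [as_genome()]).
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  dss <- Biostrings::readDNAStringSet(path)
  names(dss) <- sub("\\s.*$", "", names(dss))
  as_genome(dss)
}

#' Write a genome assembly to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param genome assembly (see [as_genome()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_genome <- function(genome, path) {
  genome <- as_genome(genome)
  dss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, path, width = 60L)
  invisible(path)
}

#' Reverse complement
#'
#' @param seq a single DNA string (A/C/G/T/N).
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## Maximal runs of a character class in a sequence; returns a data.frame
## with 0-based half-open [start, end).
char_runs <- function(seq, chars) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]] %in% chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

## Maximal homopolymer runs >= min_run of non-N bases.
## Returns data.frame(start, end, base), 0-based half-open.
homopolymer_runs <- function(seq, min_run = 5L) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$lengths >= min_run & r$values != "N"
  data.frame(start = starts[keep], end = ends[keep],
             base = r$values[keep], stringsAsFactors = FALSE)
}

## Random DNA of length n at a given GC fraction.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## Replace [start, end) (0-based half-open) of a string with `replacement`.
splice_string <- function(seq, start, end, replacement) {
  paste0(substr(seq, 1L, start), replacement,
         substr(seq, end + 1L, nchar(seq)))
}

## Extract [start, end) 0-based half-open.
substr0 <- function(seq, start, end) {
  if (end <= start) return("")
  substr(seq, start + 1L, end)
}

## sample() without the length-1 numeric surprise
sample_from <- function(x, size = 1L, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}
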