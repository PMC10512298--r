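#' Gene models
#'
#' A gene model describes the stranded exon/CDS structure of one
#' protein-coding gene on an assembly.  Coordinates are 0-based,
#' half-open, and stored in genomic (leftmost-first) order regardless of
#' strand; 1-based coordinates appear only in human-readable output.
#'
#' @param gene_id,protein_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds integer matrices with columns `start`, `end`
#'   (0-based half-open), rows sorted by `start` and non-overlapping.
#'   Every CDS interval must lie within an exon.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds,
                       protein_id = paste0(gene_id, ".p")) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  cds <- matrix(as.integer(cds), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  cds <- cds[order(cds[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1]) || any(cds[, 2] <= cds[, 1])) {
    stop("empty or inverted interval in gene ", gene_id)
  }
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] < exons[-nrow(exons), 2])) {
    stop("overlapping exons in gene ", gene_id)
  }
  structure(list(gene_id = gene_id, protein_id = protein_id,
                 chrom = chrom, strand = strand,
                 exons = exons, cds = cds),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d strand %s, %d exon(s)\n",
              x$gene_id, x$protein_id, x$chrom,
              gene_span(x)[1] + 1L, gene_span(x)[2], x$strand,
              nrow(x$exons)))
  invisible(x)
}

## [start, end) genomic span of a gene (first exon start to last exon end)
gene_span <- function(model) {
  c(min(model$exons[, 1]), max(model$exons[, 2]))
}

## spliced CDS length in bases
cds_length <- function(model) sum(model$cds[, 2] - model$cds[, 1])

#' Splice and translate a gene model against an assembly
#'
#' Extracts the CDS intervals, concatenates them (reverse-complementing
#' for minus-strand genes), and translates with the standard nuclear
#' code.  Translation stops at the first stop codon; the trailing stop is
#' not part of the protein.  Codons containing N translate to `X`
#' (indeterminate).
#'
#' @param model a [gene_model()].
#' @param assembly genome assembly (see [as_genome()]).
#' @return A list with elements `cds` (spliced CDS string, coding
#'   orientation) and `protein` (amino-acid string, no trailing stop).
#' @export
splice_and_translate <- function(model, assembly) {
  assembly <- as_genome(assembly)
  chrom <- assembly[[model$chrom]]
  if (max(model$exons[, 2]) > nchar(chrom)) {
    stop("gene ", model$gene_id, " extends past end of ", model$chrom)
  }
  pieces <- apply(model$cds, 1L,
                  function(iv) substr0(chrom, iv[1], iv[2]))
  cds <- paste(pieces, collapse = "")
  if (model$strand == "-") cds <- revcomp(cds)
  list(cds = cds, protein = translate_cds(cds))
}

## Translate a CDS string; stops at first stop codon, N codons -> X.
translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0) return("")
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- GENETIC_CODE_1[codons]
  aa[is.na(aa)] <- "X"   # any codon containing N or other ambiguity
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1L)]
  paste(aa, collapse = "")
}

GENETIC_CODE_1 <- Biostrings::GENETIC_CODE

## three-letter amino-acid codes for report rendering
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
         Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
         L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
         S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
         X = "Xaa", "*" = "STOP")

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS features with the CDS phase column
#' populated.  Coordinates are converted to the 1-based fully-closed GFF3
#' convention.
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    sp <- gene_span(m)
    lines <- sprintf("%s\tclonediv\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     m$chrom, sp[1] + 1L, sp[2], m$strand, m$gene_id)
    mrna_id <- paste0(m$gene_id, ".t1")
    lines <- c(lines, sprintf(
      "%s\tclonediv\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
      m$chrom, sp[1] + 1L, sp[2], m$strand, mrna_id, m$gene_id))
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines, sprintf(
        "%s\tclonediv\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        m$chrom, m$exons[i, 1] + 1L, m$exons[i, 2], m$strand,
        mrna_id, i, mrna_id))
    }
    ## phase: bases to skip to reach the next codon start, in coding order
    ord <- if (m$strand == "+") seq_len(nrow(m$cds)) else rev(seq_len(nrow(m$cds)))
    done <- 0L
    phase <- integer(nrow(m$cds))
    for (i in ord) {
      phase[i] <- (3L - (done %% 3L)) %% 3L
      done <- done + (m$cds[i, 2] - m$cds[i, 1])
    }
    for (i in seq_len(nrow(m$cds))) {
      lines <- c(lines, sprintf(
        "%s\tclonediv\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
        m$chrom, m$cds[i, 1] + 1L, m$cds[i, 2], m$strand, phase[i],
        mrna_id, mrna_id))
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS features (the dialect written by
#' [write_gff3()] and standard single-transcript annotations) into a
#' list of [gene_model()] objects sorted by chromosome and start.
#'
#' @param path path to a GFF3 file.
#' @return A list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    type = as.character(gr$type),
                    id = if (is.null(gr$ID)) NA_character_ else gr$ID,
                    parent = vapply(as.list(gr$Parent), function(p)
                      if (length(p)) p[[1]] else NA_character_, ""),
                    stringsAsFactors = FALSE)
  mrna <- tab[tab$type == "mRNA", , drop = FALSE]
  models <- vector("list", nrow(mrna))
  for (i in seq_len(nrow(mrna))) {
    mid <- mrna$id[i]
    ex <- tab[tab$type == "exon" & tab$parent %in% mid,
              c("start", "end"), drop = FALSE]
    cd <- tab[tab$type == "CDS" & tab$parent %in% mid,
              c("start", "end"), drop = FALSE]
    if (!nrow(ex)) ex <- cd
    models[[i]] <- gene_model(
      gene_id = mrna$parent[i], chrom = mrna$chrom[i],
      strand = mrna$strand[i],
      exons = as.matrix(ex), cds = as.matrix(cd))
  }
  sort_gene_models(models)
}

## sort a list of models by chromosome then start
sort_gene_models <- function(models) {
  if (!length(models)) return(models)
  chroms <- vapply(models, `[[`, "", "chrom")
  starts <- vapply(models, function(m) gene_span(m)[1], 0L)
  models[order(chroms, starts)]
}
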