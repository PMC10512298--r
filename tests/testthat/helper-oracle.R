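## Independent full-matrix Needleman-Wunsch oracle (Biostrings) with the
## package's scoring scheme: match +1, mismatch -1, gap open -2,
## gap extend -1 (a gap of length L costs 2 + L).
nw_oracle <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
    gapOpening = 2, gapExtension = 1)
  ins <- Biostrings::nindel(pa)@insertion
  del <- Biostrings::nindel(pa)@deletion
  list(score = Biostrings::score(pa),
       mismatches = Biostrings::nmismatch(pa),
       ## Biostrings "insertion" = gap in the pattern (extra subject
       ## sequence) = this package's deletion_runs, and vice versa
       deletion_runs = unname(del[1]), deletion_bases = unname(del[2]),
       insertion_runs = unname(ins[1]), insertion_bases = unname(ins[2]))
}

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, TRUE), collapse = "")

other_base <- function(b) sample(setdiff(BASES, b), 1)

## mutate `a` with well-separated substitutions and small indels so the
## optimal alignment is essentially unique
mutate_seq <- function(a, n_events, min_space = 40L, p_sub = 0.6,
                       p_ins = 0.2, max_indel = 5L) {
  n <- nchar(a)
  sites <- sort(sample(seq(min_space, n - min_space), n_events))
  sites <- sites[c(TRUE, diff(sites) > min_space)]
  b <- a
  for (p in rev(sites)) {
    r <- runif(1)
    if (r < p_sub) {
      substr(b, p, p) <- other_base(substr(b, p, p))
    } else if (r < p_sub + p_ins) {
      b <- paste0(substr(b, 1, p), rand_seq(sample(max_indel, 1)),
                  substr(b, p + 1, nchar(b)))
    } else {
      b <- paste0(substr(b, 1, p),
                  substr(b, p + sample(max_indel, 1) + 1, nchar(b)))
    }
  }
  b
}

## small fully-coding test gene: ATG + sense codons + stop, split by one
## intron when requested
make_test_gene <- function(n_codons = 40, intron_len = 0, strand = "+",
                           flank = 60, chrom = "chr1", gene_id = "gX") {
  codons <- c("ATG",
              sample(setdiff(clonediv:::sense_codons(),
                             c("ATG")), n_codons - 2, TRUE),
              sample(c("TAA", "TAG", "TGA"), 1))
  cds <- paste(codons, collapse = "")
  clen <- nchar(cds)
  if (intron_len > 0) {
    cut <- clen %/% 2 + 1   # split mid-CDS, not at a codon boundary
    intron <- paste0("GT", rand_seq(intron_len - 4), "AG")
    locus <- paste0(substr(cds, 1, cut), intron,
                    substr(cds, cut + 1, clen))
    exons <- rbind(c(0, cut), c(cut + intron_len, nchar(locus)))
  } else {
    locus <- cds
    exons <- rbind(c(0, clen))
  }
  if (strand == "-") {
    locus <- clonediv::revcomp(locus)
    ll <- nchar(locus)
    exons <- cbind(ll - exons[, 2], ll - exons[, 1])
    exons <- exons[order(exons[, 1]), , drop = FALSE]
  }
  left <- rand_seq(flank)
  right <- rand_seq(flank)
  chrom_seq <- paste0(left, locus, right)
  model <- clonediv::gene_model(gene_id, chrom, strand,
                                exons + flank, exons + flank)
  list(model = model, assembly = stats::setNames(chrom_seq, chrom),
       locus = locus, cds_fwd = cds)
}

## default desk-scale trio used by several tests
make_trio <- function(seed = 42, chrom_len = 120000, n_chrom = 2,
                      gene_count = 50, snv = 60, indel = 15, ...) {
  cfg <- clonediv::sim_config(n_chromosomes = n_chrom,
                              chromosome_length = chrom_len,
                              gene_count = gene_count, seed = seed)
  spec <- clonediv::variant_spec(snv_rate_per_mb = snv,
                                 indel_rate_per_mb = indel)
  clonediv::simulate_trio(cfg, spec_ab = spec, spec_bc = spec, ...)
}
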