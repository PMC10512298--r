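test_that("splicing and translation follow the standard nuclear code", {
  g <- make_test_gene(n_codons = 10)
  st <- splice_and_translate(g$model, g$assembly)
  expect_identical(st$cds, g$cds_fwd)
  expect_identical(nchar(st$protein), 9L)  # trailing stop excluded
  ## direct codon-table checks used by the protein-change rendering
  expect_identical(clonediv:::translate_cds("ATGAGCTAA"), "MS")
  expect_identical(clonediv:::GENETIC_CODE_1[["AGC"]], "S")  # Ser
  expect_identical(clonediv:::GENETIC_CODE_1[["ACC"]], "T")  # Thr
  expect_identical(clonediv:::GENETIC_CODE_1[["CAG"]], "Q")  # Gln
  expect_identical(clonediv:::GENETIC_CODE_1[["TAG"]], "*")  # stop
  ## N codons are indeterminate and internal stops truncate
  expect_identical(clonediv:::translate_cds("ATGANCTGG"), "MXW")
  expect_identical(clonediv:::translate_cds("ATGTAAAAATGG"), "M")
})

test_that("translation is strand-safe", {
  set.seed(30)
  for (intron in c(0, 30)) {
    fwd <- make_test_gene(n_codons = 30, intron_len = intron,
                          strand = "+")
    p_fwd <- splice_and_translate(fwd$model, fwd$assembly)$protein
    ## place the reverse-complemented locus on the minus strand
    chrom <- fwd$assembly[[1]]
    rc <- c(chr1 = clonediv::revcomp(chrom))
    L <- nchar(chrom)
    ex <- fwd$model$exons
    ex_rc <- cbind(L - ex[, 2], L - ex[, 1])
    m_rc <- gene_model("gX", "chr1", "-", ex_rc, ex_rc)
    p_rev <- splice_and_translate(m_rc, rc)$protein
    expect_identical(p_rev, p_fwd)
  }
})

test_that("substitution effects are classified by re-translation", {
  set.seed(31)
  g <- make_test_gene(n_codons = 50)
  m <- g$model
  chrom <- g$assembly[[1]]
  flank <- 60
  ## find a Leu CTT codon or plant one at codon 20
  cds <- g$cds_fwd
  substr(chrom, flank + 3 * 19 + 1, flank + 3 * 19 + 3) <- "CTT"
  asm <- c(chr1 = chrom)
  pos <- flank + 3 * 19    # 0-based genomic position of the C
  ## CTT -> TTT: missense Leu -> Phe
  cls <- classify_change(m, chrom, pos, "C", "T")
  expect_identical(cls$effect, "missense")
  expect_identical(cls$protein_change,
                   sprintf("Leu(CTT) %d Phe(TTT)", 20L))
  ## CAG -> TAG: nonsense with STOP rendering
  substr(chrom, flank + 3 * 24 + 1, flank + 3 * 24 + 3) <- "CAG"
  cls <- classify_change(m, chrom, flank + 3 * 24, "C", "T")
  expect_identical(cls$effect, "nonsense")
  expect_identical(cls$protein_change,
                   sprintf("Gln(CAG) %d STOP(TAG)", 25L))
  ## GCT -> GCC: synonymous (third-position wobble)
  substr(chrom, flank + 3 * 29 + 1, flank + 3 * 29 + 3) <- "GCT"
  cls <- classify_change(m, chrom, flank + 3 * 29 + 2, "T", "C")
  expect_identical(cls$effect, "synonymous")
  expect_identical(cls$protein_change, "")
})

test_that("indels in the CDS are frameshift or in-frame", {
  set.seed(32)
  g <- make_test_gene(n_codons = 60)
  chrom <- g$assembly[[1]]
  pos <- 60 + 45   # inside the CDS
  ## single-base insertion: frameshift, premature stop
  cls <- classify_change(g$model, chrom, pos, "", "C")
  expect_identical(cls$effect, "frameshift")
  expect_identical(cls$protein_change, "Premature stop")
  ## 3-base deletion: in-frame
  ref3 <- clonediv:::substr0(chrom, pos, pos + 3)
  cls <- classify_change(g$model, chrom, pos, ref3, "")
  expect_identical(cls$effect, "inframe_indel")
  ## loss of a 20-base duplication that restores the reading frame
  unit <- clonediv:::substr0(chrom, pos - 20, pos)
  chrom_dup <- clonediv:::splice_string(chrom, pos, pos, unit)
  ex_dup <- g$model$exons
  ex_dup[ex_dup[, 2] >= pos, 2] <- ex_dup[ex_dup[, 2] >= pos, 2] + 20
  m_dup <- gene_model("gX", "chr1", "+", ex_dup, ex_dup)
  cls <- classify_change(m_dup, chrom_dup, pos, unit, "")
  expect_identical(cls$effect, "frameshift")
  expect_identical(cls$protein_change, "Restores reading frame")
})

test_that("intron, splice-site and intergenic changes are recognized", {
  set.seed(33)
  g <- make_test_gene(n_codons = 40, intron_len = 40)
  m <- g$model
  chrom <- g$assembly[[1]]
  intron_start <- m$exons[1, 2]
  intron_end <- m$exons[2, 1]
  mid <- intron_start + 15
  cls <- classify_change(m, chrom, mid,
                         clonediv:::substr0(chrom, mid, mid + 1), "A")
  ## the planted base may equal A; use a guaranteed different alt
  alt <- other_base(clonediv:::substr0(chrom, mid, mid + 1))
  cls <- classify_change(m, chrom, mid,
                         clonediv:::substr0(chrom, mid, mid + 1), alt)
  expect_identical(cls$effect, "intronic")
  ## donor dinucleotide
  cls <- classify_change(m, chrom, intron_start,
                         clonediv:::substr0(chrom, intron_start,
                                            intron_start + 1), "C")
  expect_identical(cls$effect, "splice_site")
  ## acceptor dinucleotide
  cls <- classify_change(m, chrom, intron_end - 1,
                         clonediv:::substr0(chrom, intron_end - 1,
                                            intron_end), "C")
  expect_identical(cls$effect, "splice_site")
  ## outside the gene
  cls <- classify_change(m, chrom, 5,
                         clonediv:::substr0(chrom, 5, 6), "N")
  expect_identical(cls$region, "intergenic")
})

test_that("diff_gene localizes and classifies constructed edits", {
  set.seed(34)
  g <- make_test_gene(n_codons = 80, intron_len = 50)
  m <- g$model
  chrom <- g$assembly[[1]]
  sp <- clonediv:::gene_span(m)
  locus <- clonediv:::substr0(chrom, sp[1], sp[2])
  ## derived locus: one exonic substitution + one intronic substitution
  exon_local <- 30L
  intron_local <- (m$exons[1, 2] - sp[1]) + 10L
  der <- locus
  substr(der, exon_local + 1, exon_local + 1) <-
    other_base(substr(locus, exon_local + 1, exon_local + 1))
  substr(der, intron_local + 1, intron_local + 1) <-
    other_base(substr(locus, intron_local + 1, intron_local + 1))
  ev <- diff_gene(m, c(chr1 = chrom), der)
  expect_identical(nrow(ev), 2L)
  expect_setequal(ev$local_pos, c(exon_local, intron_local))
  expect_setequal(ev$region, c("exon", "intron"))
  ## no differences: empty table
  expect_identical(nrow(diff_gene(m, c(chr1 = chrom), locus)), 0L)
})

test_that("sequential mapping places genes syntenically", {
  tr <- make_trio(seed = 35, chrom_len = 80000, n_chrom = 1,
                  gene_count = 25, snv = 0, indel = 0)
  ## identical source and target: full coverage and identity
  pl <- sequential_map(tr$genes_b, tr$b, tr$b, window = 50000)
  expect_true(all(pl$coverage == 1))
  expect_true(all(pl$identity == 1))
  expect_true(all(pl$synteny_ok))
  expect_false(any(pl$contains_n))
  ## a single SNV inside one gene lowers only that gene's identity
  m <- tr$genes_b[[10]]
  sp <- clonediv:::gene_span(m)
  target <- tr$b
  p <- sp[1] + 40
  seqs <- target[[m$chrom]]
  substr(seqs, p + 1, p + 1) <- other_base(substr(seqs, p + 1, p + 1))
  target[m$chrom] <- seqs
  pl2 <- sequential_map(tr$genes_b, tr$b, target, window = 50000)
  expect_lt(pl2$identity[10], 1)
  expect_identical(pl2$coverage[10], 1)
  expect_true(all(pl2$identity[-10] == 1))
  ## an N run inside a gene flags contains_n
  target_n <- tr$b
  seqs <- target_n[[m$chrom]]
  substr(seqs, sp[1] + 51, sp[1] + 60) <- strrep("N", 10)
  target_n[m$chrom] <- seqs
  pl3 <- sequential_map(tr$genes_b, tr$b, target_n, window = 50000)
  expect_true(pl3$contains_n[10])
  ## a gene deleted from the target is unplaced, not an error
  target_d <- tr$b
  seqs <- target_d[[m$chrom]]
  target_d[m$chrom] <- paste0(clonediv:::substr0(seqs, 0, sp[1] - 30),
                              clonediv:::substr0(seqs, sp[2] + 30,
                                                 nchar(seqs)))
  pl4 <- sequential_map(tr$genes_b, tr$b, target_d, window = 50000)
  expect_identical(pl4$coverage[10], 0)
})

test_that("homopolymer artifact flagging follows the pre-mutation rule", {
  ctx <- paste0("ACGTACGTAC", "AAAAAA", "GTACGTACGT")  # 6-run at 10..16
  ## 1-base deletion inside the run: flagged
  expect_true(flag_homopolymer_artifact(ctx, 12, "A", ""))
  ## 1-base insertion of the run base at its edge: flagged
  expect_true(flag_homopolymer_artifact(ctx, 10, "", "A"))
  ## substitution in mixed context: not flagged
  ctx2 <- "ACGTGACGTGACGTGACGTG"
  expect_false(flag_homopolymer_artifact(ctx2, 9, "G", "T"))
  ## insertion extending a 4-run to 5: pre-mutation run is short, not
  ## flagged at min_run = 5
  ctx3 <- paste0("ACGTACGTAC", "AAAA", "GTCGTACGTC")
  expect_false(flag_homopolymer_artifact(ctx3, 12, "", "A"))
  ## substitution that extends a 5-run at its boundary: flagged
  ctx4 <- paste0("ACGTACGTAC", "AAAAA", "CTCGTACGTC")
  expect_true(flag_homopolymer_artifact(ctx4, 15, "C", "A"))
  ## deletion of a non-homopolymer segment: not flagged
  expect_false(flag_homopolymer_artifact(ctx2, 8, "TG", ""))
})

test_that("k-mer support verdicts follow the count thresholds", {
  set.seed(36)
  ctx_ref <- rand_seq(81)
  ctx_alt <- ctx_ref
  substr(ctx_alt, 41, 41) <- other_base(substr(ctx_ref, 41, 41))
  mk_reads <- function(ctx, n, len = 50) {
    Biostrings::DNAStringSet(vapply(seq_len(n), function(i) {
      at <- sample(10:25, 1)
      clonediv:::substr0(ctx, at, at + len)
    }, ""))
  }
  ## all reads carry the alternate allele: supported
  res <- kmer_support(ctx_ref, ctx_alt, var_at = 40, ref_len = 1,
                      alt_len = 1, reads = mk_reads(ctx_alt, 8))
  expect_identical(res$verdict, "supported")
  ## all reads carry the reference: refuted
  res <- kmer_support(ctx_ref, ctx_alt, var_at = 40, ref_len = 1,
                      alt_len = 1, reads = mk_reads(ctx_ref, 8))
  expect_identical(res$verdict, "refuted")
  ## an even mixture: mixed (sequence heterogeneity in the population)
  both <- c(mk_reads(ctx_ref, 6), mk_reads(ctx_alt, 6))
  res <- kmer_support(ctx_ref, ctx_alt, var_at = 40, ref_len = 1,
                      alt_len = 1, reads = both)
  expect_identical(res$verdict, "mixed")
  ## no read covers the site: untested
  res <- kmer_support(ctx_ref, ctx_alt, var_at = 40, ref_len = 1,
                      alt_len = 1,
                      reads = Biostrings::DNAStringSet(rand_seq(50)))
  expect_identical(res$verdict, "untested")
  ## reverse-complement reads count too
  rc_reads <- Biostrings::DNAStringSet(
    vapply(1:8, function(i) revcomp(clonediv:::substr0(
      ctx_alt, 15, 70)), ""))
  res <- kmer_support(ctx_ref, ctx_alt, var_at = 40, ref_len = 1,
                      alt_len = 1, reads = rc_reads)
  expect_identical(res$verdict, "supported")
  expect_error(kmer_support(ctx_ref, ctx_alt, 40, 1, 1,
                            mk_reads(ctx_alt, 2), k = 30), "odd")
})

test_that("lenient FASTQ reading skips malformed records", {
  d <- withr::local_tempdir()
  path <- file.path(d, "reads.fq")
  writeLines(c("@r1", "ACGTACGTACGT", "+", "IIIIIIIIIIII",
               "@r2", "ACGTACGT", "+", "III",          # bad qual length
               "@r3", "TTTTACGTACGT", "+", "IIIIIIIIIIII"), path)
  expect_message(res <- clonediv:::read_fastq_lenient(path), "skipped 1")
  expect_length(res, 2)
})

test_that("polarization follows the three-strain logic table", {
  expect_identical(polarize_mutation("C", "C", "T"), "B>C")
  expect_identical(polarize_mutation("G", "C", "C"), "A>B")
  expect_identical(polarize_mutation("A", "A", "A"), "none")
  expect_identical(polarize_mutation("A", "G", "A"), "conflict")
  expect_identical(polarize_mutation("A", "G", "T"), "conflict")
  expect_identical(polarize_mutation("N", "G", "T"), "indeterminate")
  expect_identical(polarize_mutation(NA, "G", "T"), "indeterminate")
  ## indel alleles polarize as strings
  expect_identical(polarize_mutation("", "", "ACG"), "B>C")
})
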