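test_that("generation is deterministic and writes byte-identical files", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 100000,
                    gene_count = 40, seed = 1)
  anc1 <- generate_ancestor(cfg)
  anc2 <- generate_ancestor(cfg)
  expect_identical(anc1, anc2)
  d <- withr::local_tempdir()
  write_genome(anc1$assembly, file.path(d, "a1.fa"))
  write_genome(anc2$assembly, file.path(d, "a2.fa"))
  write_gff3(anc1$genes, file.path(d, "a1.gff3"))
  write_gff3(anc2$genes, file.path(d, "a2.gff3"))
  expect_identical(readLines(file.path(d, "a1.fa")),
                   readLines(file.path(d, "a2.fa")))
  expect_identical(readLines(file.path(d, "a1.gff3")),
                   readLines(file.path(d, "a2.gff3")))
})

test_that("realized exon and intron fractions track the configuration", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 1000000,
                    gene_count = 400, exon_fraction = 0.40,
                    intron_fraction = 0.05, seed = 2)
  anc <- generate_ancestor(cfg)
  ## count annotated bases from the emitted GFF3
  d <- withr::local_tempdir()
  write_gff3(anc$genes, file.path(d, "g.gff3"))
  models <- read_gene_models(file.path(d, "g.gff3"))
  exon_b <- sum(vapply(models, function(m)
    sum(m$exons[, 2] - m$exons[, 1]), 0))
  span_b <- sum(vapply(models, function(m)
    diff(clonediv:::gene_span(m)), 0))
  total <- sum(nchar(anc$assembly))
  expect_gte(exon_b / total, 0.32)
  expect_lte(exon_b / total, 0.48)
  expect_gte((span_b - exon_b) / total, 0.04)
  expect_lte((span_b - exon_b) / total, 0.06)
})

test_that("gene models are internally consistent and genes carry
           homopolymer tracts at a nonzero rate", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_length = 80000,
                    gene_count = 30, homopolymer_tract_rate = 1, seed = 3)
  anc <- generate_ancestor(cfg)
  for (m in anc$genes) {
    expect_true(all(m$exons[, 2] > m$exons[, 1]))
    if (nrow(m$exons) > 1) {
      expect_true(all(m$exons[-1, 1] >= m$exons[-nrow(m$exons), 2]))
    }
    st <- splice_and_translate(m, anc$assembly)
    expect_identical(nchar(st$cds) %% 3L, 0L)
    expect_identical(substr(st$cds, 1, 3), "ATG")
    expect_true(substr(st$cds, nchar(st$cds) - 2, nchar(st$cds)) %in%
                  c("TAA", "TAG", "TGA"))
    expect_identical(substr(st$protein, 1, 1), "M")
    expect_false(grepl("\\*", st$protein))
  }
  runs <- do.call(rbind, lapply(names(anc$assembly), function(cn)
    clonediv:::homopolymer_runs(anc$assembly[[cn]], 5)))
  expect_gt(nrow(runs), 50)   # tracts present throughout the genome
})

test_that("gene_count 0 gives an annotation-free genome and an empty
           GFF3; infeasible gene counts fail loudly", {
  cfg <- sim_config(chromosome_length = 20000, gene_count = 0, seed = 4)
  anc <- generate_ancestor(cfg)
  expect_length(anc$genes, 0)
  d <- withr::local_tempdir()
  write_gff3(anc$genes, file.path(d, "empty.gff3"))
  expect_identical(readLines(file.path(d, "empty.gff3")),
                   "##gff-version 3")
  bad <- sim_config(chromosome_length = 10000, gene_count = 500, seed = 4)
  expect_error(generate_ancestor(bad), "infeasible")
})

test_that("zero-rate variant specs are the identity", {
  cfg <- sim_config(chromosome_length = 40000, gene_count = 15, seed = 5)
  anc <- generate_ancestor(cfg)
  pv <- plant_variants(anc$assembly, anc$genes, variant_spec(), seed = 6)
  expect_identical(pv$assembly, anc$assembly)
  expect_identical(nrow(pv$truth), 0L)
})

test_that("planted variants round-trip and verify their class labels", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_length = 60000,
                    gene_count = 24, seed = 7)
  anc <- generate_ancestor(cfg)
  spec <- variant_spec(snv_rate_per_mb = 150, indel_rate_per_mb = 40)
  pv <- plant_variants(anc$assembly, anc$genes, spec, seed = 8)
  expect_gt(nrow(pv$truth), 5)
  ## round trip: truth applied to the ancestor reproduces the strain
  rt <- apply_variants(anc$assembly, pv$truth)
  expect_identical(rt$assembly, pv$assembly)
  ## class fidelity: re-classify each coding plant against the models
  gene_of <- function(chrom, pos) {
    for (m in anc$genes) {
      sp <- clonediv:::gene_span(m)
      if (m$chrom == chrom && pos >= sp[1] && pos < sp[2]) return(m)
    }
    NULL
  }
  for (i in seq_len(nrow(pv$truth))) {
    tr <- pv$truth[i, ]
    if (!tr$class %in% c("synonymous", "missense", "nonsense",
                         "frameshift")) next
    m <- gene_of(tr$chrom, tr$pos0)
    expect_false(is.null(m))
    cls <- classify_change(m, anc$assembly[[tr$chrom]], tr$pos0,
                           tr$ref, tr$alt)
    expect_identical(cls$effect, tr$class)
  }
  ## nonsense plants really create stops: a mutated CAG must become TAG
  ns <- pv$truth[pv$truth$class == "nonsense", , drop = FALSE]
  for (i in seq_len(nrow(ns))) {
    m <- gene_of(ns$chrom[i], ns$pos0[i])
    mut <- apply_variants(anc$assembly, ns[i, ])$assembly
    p_anc <- splice_and_translate(m, anc$assembly)$protein
    p_mut <- splice_and_translate(m, mut)$protein
    expect_lt(nchar(p_mut), nchar(p_anc))
  }
})

test_that("planted SNV counts are Poisson at the requested rate", {
  ## rate 5/Mb on a 2 Mb genome: mean count over 100 seeds within
  ## 3 standard errors of 10
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 2000000,
                    gene_count = 0, seed = 9)
  anc <- generate_ancestor(cfg)
  spec <- variant_spec(snv_rate_per_mb = 5,
                       class_mix = c(intergenic = 1, intronic = 0,
                                     synonymous = 0, missense = 0,
                                     nonsense = 0, frameshift = 0))
  counts <- vapply(1:100, function(s)
    nrow(plant_variants(anc$assembly, list(), spec, seed = s)$truth), 0L)
  se <- sqrt(10) / sqrt(100)
  expect_lt(abs(mean(counts) - 10), 3 * se)
})

test_that("tandem duplications and reversions are planted and undone", {
  cfg <- sim_config(chromosome_length = 60000, gene_count = 20, seed = 10)
  anc <- generate_ancestor(cfg)
  spec <- variant_spec(tandem_duplications = list(
    list(region = "cds", unit = 20)))
  pv <- plant_variants(anc$assembly, anc$genes, spec, seed = 11)
  tr <- pv$truth
  expect_identical(nrow(tr), 1L)
  expect_identical(nchar(tr$alt), 20L)
  ## a 20-base CDS duplication breaks the reading frame
  expect_identical(tr$class, "tandem_duplication:frameshift")
  ## the inserted copy duplicates the preceding unit
  der <- pv$assembly[[tr$chrom]]
  expect_identical(
    clonediv:::substr0(der, tr$pos0_derived, tr$pos0_derived + 20),
    clonediv:::substr0(der, tr$pos0_derived - 20, tr$pos0_derived))
  ## reversion deletes it again, restoring the ancestor
  rev_spec <- variant_spec(reversions = list(tr))
  rv <- plant_variants(pv$assembly, pv$genes, rev_spec, seed = 12,
                       interval = "B>C")
  expect_identical(rv$assembly, anc$assembly)
})

test_that("artifact injection respects its contracts", {
  cfg <- sim_config(chromosome_length = 100000, gene_count = 30,
                    homopolymer_tract_rate = 1, seed = 13)
  anc <- generate_ancestor(cfg)
  ## zero rates: identity
  ia <- inject_artifacts(anc$assembly, artifact_spec(), seed = 14)
  expect_identical(ia$assembly, anc$assembly)
  expect_identical(nrow(ia$artifacts), 0L)
  ## homopolymer errors only change run lengths of runs >= 5
  ia <- inject_artifacts(anc$assembly,
                         artifact_spec(homopolymer_error_rate = 0.5),
                         seed = 15)
  expect_gt(nrow(ia$artifacts), 0)
  for (i in seq_len(nrow(ia$artifacts))) {
    a <- ia$artifacts[i, ]
    pre <- anc$assembly[[a$chrom]]
    run_pre <- clonediv:::homopolymer_runs(pre, 5)
    expect_true(any(run_pre$start == a$pos0))
  }
  ## a +1 error on an isolated AAAAA run gives AAAAAA
  toy <- c(c1 = paste0(strrep("ACGT", 8), "G", "AAAAA", "C",
                       strrep("TGCA", 8)))
  for (s in 1:20) {
    it <- inject_artifacts(toy, artifact_spec(homopolymer_error_rate = 1),
                           seed = s)
    d <- it$artifacts$detail[1]
    expect_identical(nchar(it$assembly[[1]]), nchar(toy[[1]]) + d)
    if (d == 1) {
      expect_match(it$assembly[[1]], "GAAAAAAC")
    }
  }
  ## 10 N-gaps of length 50 on 100 kb: exactly 10 maximal runs of 50
  ig <- inject_artifacts(anc$assembly,
                         artifact_spec(n_gap_count = 10,
                                       n_gap_length_range = c(50, 50)),
                         seed = 16)
  gaps <- find_gaps(ig$assembly)
  expect_identical(nrow(gaps), 10L)
  expect_true(all(gaps$end - gaps$start == 50))
  ## infeasible N-gap fails
  expect_error(
    inject_artifacts(c(c1 = rand_seq(100)),
                     artifact_spec(n_gap_count = 1,
                                   n_gap_length_range = c(500, 500)),
                     seed = 17),
    "exceeds chromosome")
})

test_that("trio construction polarizes variants by interval and the
           truth table writer round-trips", {
  tr <- make_trio(seed = 20, chrom_len = 60000, n_chrom = 1,
                  gene_count = 20, snv = 80, indel = 20)
  expect_setequal(unique(tr$truth$interval), c("A>B", "B>C"))
  ## A>B variants present in b and c but not a; B>C only in c
  ab <- tr$truth[tr$truth$interval == "A>B", ]
  expect_identical(apply_variants(tr$a, ab)$assembly, tr$b)
  d <- withr::local_tempdir()
  write_truth_table(tr$truth, file.path(d, "truth.tsv"))
  back <- read.delim(file.path(d, "truth.tsv"),
                     colClasses = c(REF = "character",
                                    ALT = "character"))
  expect_identical(nrow(back), nrow(tr$truth))
  expect_identical(back$POS0, tr$truth$pos0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(exon_fraction = 0.8, intron_fraction = 0.3),
               "<= 1")
  expect_error(sim_config(gc_fraction = 1.2), "proportions")
  expect_error(sim_config(chromosome_length = 0), "positive")
  expect_error(variant_spec(snv_rate_per_mb = -1), ">= 0")
  expect_error(variant_spec(class_mix = c(intergenic = 1)), "class_mix")
  expect_error(artifact_spec(homopolymer_error_rate = 2), "\\[0, 1\\]")
})
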