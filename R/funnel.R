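#' Telescoping report of the mutation-classification funnel
#'
#' Candidate gene mutations are excluded in stages: genes identical in
#' all three strains, genes whose differences are all intronic, genes
#' removed because their exonic differences are all synonymous or their
#' sequence contains N, homopolymer assembly artifacts, and finally the
#' confirmed mutated genes.  The counts telescope:
#' `candidates = total_genes - identical`,
#' `candidates = intronic_only + exonic_candidates`,
#' `exonic_candidates = removed_synonymous_or_n + remaining`,
#' `remaining = homopolymer_artifacts + confirmed`.
#'
#' Derived percentages (share of identical genes, share of intronic
#' candidates) are reported to one decimal, truncated.
#'
#' @param total_genes,candidates,exonic_candidates,
#'   removed_synonymous_or_n,homopolymer_artifacts stage counts.
#' @return An object of class `funnel_report` (a list of stage counts
#'   and derived percentages).
#' @export
funnel_report <- function(total_genes, candidates, exonic_candidates,
                          removed_synonymous_or_n,
                          homopolymer_artifacts) {
  identical_genes <- total_genes - candidates
  intronic_only <- candidates - exonic_candidates
  remaining <- exonic_candidates - removed_synonymous_or_n
  confirmed <- remaining - homopolymer_artifacts
  counts <- c(total_genes = total_genes, identical = identical_genes,
              candidates = candidates, intronic_only = intronic_only,
              exonic_candidates = exonic_candidates,
              removed_synonymous_or_n = removed_synonymous_or_n,
              remaining = remaining,
              homopolymer_artifacts = homopolymer_artifacts,
              confirmed = confirmed)
  if (any(counts < 0)) {
    stop("funnel stage counts do not telescope (negative stage)")
  }
  trunc1 <- function(x) if (is.nan(x)) NA_real_ else floor(x * 10) / 10
  out <- list(
    counts = counts,
    identical_pct = trunc1(100 * identical_genes / total_genes),
    intronic_pct = trunc1(100 * intronic_only / candidates))
  class(out) <- "funnel_report"
  out
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Mutation-classification funnel\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-24s %d\n", nm, x$counts[[nm]]))
  }
  cat(sprintf("  identical: %.1f%%  intronic among candidates: %.1f%%\n",
              x$identical_pct, x$intronic_pct))
  invisible(x)
}

#' Run the gene-comparison funnel over a strain trio
#'
#' Gene models are defined on the middle (reference) strain B.  Each
#' gene is mapped syntenically onto strains A and C
#' ([sequential_map()]), genes identical in all three strains are set
#' aside, and the differences of the remaining candidates are
#' classified ([classify_change()]), polarized onto a culture interval
#' ([polarize_mutation()]) and screened for homopolymer assembly
#' artifacts ([flag_homopolymer_artifact()]).  Optional short-read sets
#' add a k-mer support verdict per mutation ([kmer_support()]).
#'
#' @param genes gene models on the reference strain.
#' @param strain_a,reference,strain_c the three assemblies (A is
#'   ancestral, C the most derived).
#' @param window synteny window for [sequential_map()].
#' @param k anchor k-mer size.
#' @param min_run homopolymer run threshold for artifact flagging.
#' @param reads optional named list with elements `a`, `b`, `c`:
#'   `DNAStringSet`s or FASTQ paths used for k-mer support.
#' @param reads_k,reads_min_count k-mer support parameters.
#' @return A list with `report` (a [funnel_report()]), `mutations` (a
#'   data.frame of confirmed candidate mutations with rendered protein
#'   changes, appearance intervals, artifact flags and support
#'   verdicts), and `gene_status` (per-gene funnel assignment).
#' @export
run_funnel <- function(genes, strain_a, reference, strain_c,
                       window = 500000L, k = 15L, min_run = 5L,
                       reads = NULL, reads_k = 31L,
                       reads_min_count = 3L) {
  strain_a <- as_genome(strain_a)
  reference <- as_genome(reference)
  strain_c <- as_genome(strain_c)
  need <- unique(vapply(genes, `[[`, "", "chrom"))
  for (nm in c("strain_a", "strain_c")) {
    g <- if (nm == "strain_a") strain_a else strain_c
    missing <- setdiff(need, names(g))
    if (length(missing)) {
      stop("chromosome(s) absent from ", nm, ": ",
           paste(missing, collapse = ", "))
    }
  }
  pa <- sequential_map(genes, reference, strain_a, window = window, k = k)
  pc <- sequential_map(genes, reference, strain_c, window = window, k = k)

  n <- length(genes)
  status <- character(n)
  mut_rows <- list()
  for (gi in seq_len(n)) {
    m <- genes[[gi]]
    sp <- gene_span(m)
    chrom_seq <- reference[[m$chrom]]
    locus_b <- substr0(chrom_seq, sp[1], sp[2])
    ident_a <- !is.na(pa$q_aln[gi]) && pa$q_aln[gi] == pa$s_aln[gi]
    ident_c <- !is.na(pc$q_aln[gi]) && pc$q_aln[gi] == pc$s_aln[gi]
    if (ident_a && ident_c) {
      status[gi] <- "identical"
      next
    }
    has_n <- isTRUE(pa$contains_n[gi]) || isTRUE(pc$contains_n[gi]) ||
      grepl("N", locus_b, fixed = TRUE)
    unplaced <- is.na(pa$q_aln[gi]) || is.na(pc$q_aln[gi])
    if (unplaced || has_n) {
      status[gi] <- "removed"     # unresolvable or N-containing
      next
    }
    ev_a <- alignment_events(pa$q_aln[gi], pa$s_aln[gi])
    ev_c <- alignment_events(pc$q_aln[gi], pc$s_aln[gi])
    sites <- merge_events(ev_a, ev_c)
    if (!nrow(sites)) {  # placements differ only by alignment jitter
      status[gi] <- "identical"
      next
    }
    sites$interval <- vapply(seq_len(nrow(sites)), function(i)
      polarize_mutation(sites$a[i], sites$b[i], sites$c[i]), "")
    if (any(sites$interval == "indeterminate")) {
      status[gi] <- "removed"
      next
    }
    sites <- sites[sites$interval != "none", , drop = FALSE]
    if (!nrow(sites)) { status[gi] <- "identical"; next }

    cls <- vector("list", nrow(sites))
    hp <- logical(nrow(sites))
    for (i in seq_len(nrow(sites))) {
      si <- sites[i, ]
      gpos <- sp[1] + si$local_pos
      if (si$interval == "B>C") {
        cls[[i]] <- classify_change(m, chrom_seq, gpos, si$b, si$c)
      } else {  # A>B or conflict: the reference carries the derived allele
        cls[[i]] <- classify_observed(m, chrom_seq, gpos,
                                      anc = si$a, obs = si$b)
      }
      ## artifact screen against the curated reference context: flag a
      ## site when either non-reference allele is a homopolymer-length
      ## change of a qualifying run in the reference
      hp[i] <- (si$a != si$b &&
                  flag_homopolymer_artifact(chrom_seq, gpos, si$b, si$a,
                                            min_run = min_run)) ||
               (si$c != si$b &&
                  flag_homopolymer_artifact(chrom_seq, gpos, si$b, si$c,
                                            min_run = min_run))
    }
    sites$region <- vapply(cls, `[[`, "", "region")
    sites$effect <- vapply(cls, `[[`, "", "effect")
    sites$protein_change <- vapply(cls, `[[`, "", "protein_change")
    sites$aa_pos <- vapply(cls, function(x) as.integer(x$aa_pos), 1L)
    sites$homopolymer_flag <- hp

    if (all(sites$region == "intron")) {
      status[gi] <- "intronic_only"
      next
    }
    exonic <- sites[sites$region != "intron", , drop = FALSE]
    if (any(exonic$effect == "indeterminate")) {
      status[gi] <- "removed"
      next
    }
    nonsyn <- exonic[!(exonic$effect %in% c("synonymous", "none")), ,
                     drop = FALSE]
    if (!nrow(nonsyn)) {
      status[gi] <- "removed"     # all exonic changes synonymous
      next
    }
    if (all(nonsyn$homopolymer_flag)) {
      status[gi] <- "artifact"
      next
    }
    status[gi] <- "confirmed"
    keep <- nonsyn[!nonsyn$homopolymer_flag, , drop = FALSE]
    keep$gene_id <- m$gene_id
    keep$protein_id <- m$protein_id
    keep$chrom <- m$chrom
    keep$gene_start0 <- sp[1]
    keep$gene_end0 <- sp[2]
    mut_rows[[length(mut_rows) + 1L]] <- keep
  }

  tab <- table(factor(status, levels = c("identical", "intronic_only",
                                         "removed", "artifact",
                                         "confirmed")))
  candidates <- n - tab[["identical"]]
  exonic_candidates <- candidates - tab[["intronic_only"]]
  report <- funnel_report(
    total_genes = n, candidates = candidates,
    exonic_candidates = exonic_candidates,
    removed_synonymous_or_n = tab[["removed"]],
    homopolymer_artifacts = tab[["artifact"]])

  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
    empty_mutation_table()
  if (nrow(mutations)) {
    mutations$pos0 <- mutations$gene_start0 + mutations$local_pos
    mutations$mutation <- render_mutation(mutations)
    mutations$support <- "untested"
    if (!is.null(reads)) {
      mutations$support <- vapply(seq_len(nrow(mutations)), function(i) {
        support_for(mutations[i, ], reference, strain_a, strain_c,
                    reads, reads_k, reads_min_count)
      }, "")
    }
    mutations <- mutations[order(mutations$chrom, mutations$pos0), ]
    rownames(mutations) <- NULL
    cols <- c("gene_id", "protein_id", "chrom", "pos0", "local_pos",
              "type", "a", "b", "c", "interval", "region", "effect",
              "mutation", "protein_change", "aa_pos",
              "homopolymer_flag", "support")
    mutations <- mutations[, cols]
  }
  list(report = report, mutations = mutations,
       gene_status = data.frame(
         gene_id = vapply(genes, `[[`, "", "gene_id"),
         status = status, stringsAsFactors = FALSE))
}

empty_mutation_table <- function() {
  data.frame(gene_id = character(0), protein_id = character(0),
             chrom = character(0), pos0 = integer(0),
             local_pos = integer(0), type = character(0),
             a = character(0), b = character(0), c = character(0),
             interval = character(0), region = character(0),
             effect = character(0), mutation = character(0),
             protein_change = character(0), aa_pos = integer(0),
             homopolymer_flag = logical(0), support = character(0),
             stringsAsFactors = FALSE)
}

## join per-strain difference events into one site table with alleles
## (a, b, c); b is the reference allele
merge_events <- function(ev_a, ev_c) {
  key_a <- paste(ev_a$local_pos, ev_a$type)
  key_c <- paste(ev_c$local_pos, ev_c$type)
  keys <- union(key_a, key_c)
  rows <- lapply(keys, function(kk) {
    ia <- match(kk, key_a)
    ic <- match(kk, key_c)
    src <- if (!is.na(ia)) ev_a[ia, ] else ev_c[ic, ]
    b <- src$ref
    data.frame(local_pos = src$local_pos, type = src$type, b = b,
               a = if (!is.na(ia)) ev_a$alt[ia] else b,
               c = if (!is.na(ic)) ev_c$alt[ic] else b,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$local_pos), , drop = FALSE]
}

## Table-style rendering: "C1377T", "ins 209 C", "del 196 AGC",
## ancestral allele first, 1-based position within the gene locus
render_mutation <- function(mut) {
  vapply(seq_len(nrow(mut)), function(i) {
    anc <- if (mut$interval[i] == "B>C") mut$b[i] else mut$a[i]
    der <- if (mut$interval[i] == "B>C") mut$c[i] else mut$b[i]
    p1 <- mut$local_pos[i] + 1L
    if (mut$type[i] == "snv") {
      sprintf("%s%d%s", anc, p1, der)
    } else if (nchar(der) > nchar(anc)) {
      sprintf("ins %d %s", p1, der)
    } else {
      sprintf("del %d %s", p1, anc)
    }
  }, "")
}

## k-mer support verdict for one confirmed mutation: the derived allele
## is checked in the reads of the strain(s) expected to carry it
support_for <- function(mut, reference, strain_a, strain_c,
                        reads, k, min_count) {
  rad <- k + 5L
  chrom_seq <- reference[[mut$chrom]]
  gpos <- mut$pos0
  b_allele <- mut$b
  anc <- if (mut$interval == "B>C") mut$b else mut$a
  der <- if (mut$interval == "B>C") mut$c else mut$b
  w0 <- max(0L, gpos - rad)
  ctx_b <- substr0(chrom_seq, w0, min(nchar(chrom_seq),
                                      gpos + nchar(b_allele) + rad))
  var_at <- gpos - w0
  mk_ctx <- function(allele) {
    splice_string(ctx_b, var_at, var_at + nchar(b_allele), allele)
  }
  rd <- if (mut$interval == "B>C") reads$c else reads$b
  if (is.null(rd)) return("untested")
  res <- kmer_support(ref_context = mk_ctx(anc), alt_context = mk_ctx(der),
                      var_at = var_at, ref_len = nchar(anc),
                      alt_len = nchar(der), reads = rd, k = k,
                      min_count = min_count)
  res$verdict
}

#' Write a mutation table as TSV
#'
#' Columns follow the layout of a per-gene mutation summary: gene and
#' protein identifiers, location (1-based), appearance interval,
#' mutation and protein change.
#'
#' @param mutations mutation data.frame from [run_funnel()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_mutation_table <- function(mutations, path) {
  out <- data.frame(
    Gene = mutations$gene_id, Protein_ID = mutations$protein_id,
    Location = sprintf("%s:%d", mutations$chrom, mutations$pos0 + 1L),
    Mutation_appearance = sub(">", " > ", mutations$interval),
    Mutation = mutations$mutation,
    Protein_change = mutations$protein_change,
    Effect = mutations$effect,
    Homopolymer_flag = mutations$homopolymer_flag,
    Support = mutations$support,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write confirmed mutations as a minimal haploid VCF 4.2
#'
#' INFO keys: EFFECT, INTERVAL, HPFLAG, SUPPORT.  Indels are rendered
#' with the conventional anchor base.
#'
#' @param mutations mutation data.frame from [run_funnel()].
#' @param reference the reference assembly (for anchor bases and
#'   contig headers).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_mutation_vcf <- function(mutations, reference, path) {
  reference <- as_genome(reference)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(reference),
                       nchar(reference)),
               "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Mutation effect class\">",
               "##INFO=<ID=INTERVAL,Number=1,Type=String,Description=\"Culture interval of appearance\">",
               "##INFO=<ID=HPFLAG,Number=0,Type=Flag,Description=\"Homopolymer artifact flag\">",
               "##INFO=<ID=SUPPORT,Number=1,Type=String,Description=\"Read k-mer support verdict\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample"),
             con)
  for (i in seq_len(nrow(mutations))) {
    mu <- mutations[i, ]
    ## REF is the allele of the reference assembly; ALT the allele of
    ## the strain that differs (INFO/INTERVAL carries the direction)
    ref <- mu$b
    alt <- if (mu$interval == "B>C") mu$c else mu$a
    pos <- mu$pos0
    if (!nchar(ref) || !nchar(alt)) {  # indel: prepend anchor base
      anchor <- substr0(reference[[mu$chrom]], pos - 1L, pos)
      ref <- paste0(anchor, ref)
      alt <- paste0(anchor, alt)
      pos <- pos - 1L
    }
    info <- sprintf("EFFECT=%s;INTERVAL=%s;SUPPORT=%s%s",
                    mu$effect, mu$interval, mu$support,
                    if (isTRUE(mu$homopolymer_flag)) ";HPFLAG" else "")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT\t1",
                       mu$chrom, pos + 1L, ref, alt, info), con)
  }
  invisible(path)
}
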