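## ---- effect classification --------------------------------------------

## Region of a variant footprint within (or outside) a gene model.
## pos/ref in genomic 0-based coordinates of the chromosome carrying `ref`.
region_of <- function(m, pos, ref) {
  sp <- gene_span(m)
  foot <- if (nchar(ref)) pos:(pos + nchar(ref) - 1L) else
    c(max(sp[1], pos - 1L), pos)          # insertion: flanking bases
  foot <- foot[foot >= 0]
  if (all(foot < sp[1] | foot >= sp[2])) return("intergenic")
  in_exon <- vapply(foot, function(p)
    any(m$exons[, 1] <= p & p < m$exons[, 2]), TRUE)
  if (any(in_exon)) return("exon")
  if (nrow(m$exons) > 1) {
    for (i in seq_len(nrow(m$exons) - 1L)) {
      d0 <- m$exons[i, 2]; a1 <- m$exons[i + 1L, 1]
      sites <- c(d0, d0 + 1L, a1 - 2L, a1 - 1L)
      if (any(foot %in% sites)) return("splice_site")
    }
  }
  "intron"
}

## Shift local CDS intervals through an edit at local position `pos`
## replacing `rlen` bases by `alen` bases.
shift_cds_local <- function(cds, pos, rlen, alen) {
  delta <- alen - rlen
  t(apply(cds, 1L, function(r) {
    if (r[1] >= pos + rlen) return(r + delta)
    if (r[2] <= pos) return(r)
    c(r[1], r[2] + delta)
  }))
}

## codon vector of a CDS string (drops any trailing partial codon)
codon_split <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (!n) return(character(0))
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Classify the effect of a sequence change on a gene
#'
#' `classify_change()` classifies the change `ref -> alt` at genomic
#' position `pos` (0-based) on the chromosome string `chrom_seq`, which
#' must carry `ref`; `classify_observed()` classifies `anc -> obs`
#' where the chromosome carries the *derived* allele `obs` (used when a
#' mutation arose on the lineage leading to the annotated genome).
#'
#' Exonic changes are classified by re-translation of the ancestral and
#' derived CDS: `synonymous` (protein unchanged), `missense`,
#' `nonsense` (new stop codon), `frameshift` (CDS indel of length not
#' divisible by 3) or `inframe_indel`; intron-boundary dinucleotide
#' changes are `splice_site`.  Protein changes are rendered in the
#' three-letter form `"Ser(AGC) 347 Thr(ACC)"` (`"Premature stop"` for
#' truncations; `"Restores reading frame"` when the derived allele
#' rescues a truncated frame).
#'
#' @param m a [gene_model()].
#' @param chrom_seq the chromosome sequence string.
#' @param pos 0-based genomic position of the change.
#' @param ref,alt,anc,obs alleles as strings; `""` denotes the empty
#'   side of a pure insertion or deletion.
#' @return A list with `region`, `effect`, `protein_change`, `aa_pos`
#'   (1-based residue of the first change, NA for non-coding) and
#'   `cds_pos` (0-based CDS offset, NA for non-coding).
#' @export
classify_change <- function(m, chrom_seq, pos, ref, alt) {
  classify_core(m, chrom_seq, pos, on_chrom = ref, other = alt,
                chrom_is_ancestral = TRUE)
}

#' @rdname classify_change
#' @export
classify_observed <- function(m, chrom_seq, pos, anc, obs) {
  classify_core(m, chrom_seq, pos, on_chrom = obs, other = anc,
                chrom_is_ancestral = FALSE)
}

classify_core <- function(m, chrom_seq, pos, on_chrom, other,
                          chrom_is_ancestral) {
  if (nchar(on_chrom) &&
      substr0(chrom_seq, pos, pos + nchar(on_chrom)) != on_chrom) {
    stop("allele does not match chromosome at position ", pos)
  }
  region <- region_of(m, pos, on_chrom)
  none <- list(region = region, effect = region, protein_change = "",
               aa_pos = NA_integer_, cds_pos = NA_integer_)
  if (region == "intergenic") return(none)
  if (region == "intron") { none$effect <- "intronic"; return(none) }
  if (region == "splice_site") { none$effect <- "splice_site"; return(none) }

  sp <- gene_span(m)
  local <- pos - sp[1]
  locus_chrom <- substr0(chrom_seq, sp[1], sp[2])
  cds_local <- m$cds - sp[1]
  locus_edit <- splice_string(locus_chrom, local, local + nchar(on_chrom),
                              other)
  cds_edit <- shift_cds_local(cds_local, local, nchar(on_chrom),
                              nchar(other))
  splice_local <- function(locus, cds) {
    s <- paste(apply(cds, 1L, function(iv) substr0(locus, iv[1], iv[2])),
               collapse = "")
    if (m$strand == "-") s <- revcomp(s)
    s
  }
  if (chrom_is_ancestral) {
    cds_anc <- splice_local(locus_chrom, cds_local)
    cds_der <- splice_local(locus_edit, cds_edit)
  } else {
    cds_anc <- splice_local(locus_edit, cds_edit)
    cds_der <- splice_local(locus_chrom, cds_local)
  }

  ## footprint inside an exon but outside the CDS (UTR): no effect
  in_cds <- any(m$cds[, 1] <= pos & pos < m$cds[, 2]) ||
    (!nchar(on_chrom) && any(m$cds[, 1] < pos & pos < m$cds[, 2]))
  if (!in_cds) { none$effect <- "none"; return(none) }

  delta <- nchar(cds_der) - nchar(cds_anc)
  ## CDS offset of the change, in coding order
  gp <- if (m$strand == "+") pos else pos + max(0L, nchar(on_chrom) - 1L)
  cds_pos <- genomic_to_cds(m, gp)

  if (delta != 0L) {
    effect <- if (abs(delta) %% 3L) "frameshift" else "inframe_indel"
    p_anc <- translate_cds(cds_anc)
    p_der <- translate_cds(cds_der)
    pc <- if (nchar(p_der) < nchar(p_anc)) "Premature stop"
          else if (effect == "frameshift" && nchar(p_der) > nchar(p_anc))
            "Restores reading frame"
          else "In-frame indel"
    return(list(region = "exon", effect = effect, protein_change = pc,
                aa_pos = cds_pos %/% 3L + 1L, cds_pos = cds_pos))
  }

  ca <- codon_split(cds_anc); cd <- codon_split(cds_der)
  aa_a <- unname(GENETIC_CODE_1[ca]); aa_a[is.na(aa_a)] <- "X"
  aa_d <- unname(GENETIC_CODE_1[cd]); aa_d[is.na(aa_d)] <- "X"
  diffpos <- which(ca != cd)
  if (!length(diffpos)) {
    none$effect <- "none"; none$region <- "exon"; return(none)
  }
  i <- diffpos[1]
  if ("X" %in% c(aa_a[i], aa_d[i])) {
    return(list(region = "exon", effect = "indeterminate",
                protein_change = "", aa_pos = i, cds_pos = cds_pos))
  }
  effect <- if (aa_a[i] == aa_d[i]) "synonymous"
            else if (aa_d[i] == "*") "nonsense"
            else "missense"
  pc <- if (effect == "synonymous") "" else
    sprintf("%s(%s) %d %s(%s)", AA3[[aa_a[i]]], ca[i], i,
            AA3[[aa_d[i]]], cd[i])
  list(region = "exon", effect = effect, protein_change = pc,
       aa_pos = i, cds_pos = cds_pos)
}

## 0-based CDS offset (coding order) of genomic position gpos
genomic_to_cds <- function(m, gpos) {
  lens <- m$cds[, 2] - m$cds[, 1]
  hit <- which(m$cds[, 1] <= gpos & gpos < m$cds[, 2])
  if (!length(hit)) {  # insertion point at an interval edge
    hit <- which.min(abs(m$cds[, 1] - gpos))
    gpos <- max(m$cds[hit, 1], min(gpos, m$cds[hit, 2] - 1L))
  }
  fwd <- sum(lens[seq_len(hit - 1L)]) + (gpos - m$cds[hit, 1])
  if (m$strand == "+") fwd else sum(lens) - 1L - fwd
}

## ---- syntenic mapping --------------------------------------------------

#' Sequentially map gene loci from a source assembly onto a target
#'
#' Genes are processed in chromosome order.  Each gene locus is sought
#' within a sliding window beginning at the previous gene's placement
#' end (synteny constraint); a gene missing from the window is sought
#' over the whole chromosome before being reported unplaced, and a
#' placement that does not advance monotonically is flagged
#' `synteny_ok = FALSE`.  Placement uses unique k-mer anchors followed
#' by banded global alignment of the locus against the anchored target
#' segment.
#'
#' @param genes list of [gene_model()] sorted by chromosome and start.
#' @param source assembly carrying the models.
#' @param target assembly to map onto.
#' @param window synteny window size in bases (default 500 kb).
#' @param k anchor k-mer size.
#' @return A data.frame with one row per gene: `gene_id`, `chrom`,
#'   `coverage`, `identity`, `t_start`, `t_end` (0-based half-open on
#'   the target), `synteny_ok`, `contains_n`, plus the aligned gapped
#'   strings `q_aln`/`s_aln` for downstream difference calling.
#' @export
sequential_map <- function(genes, source, target, window = 500000L,
                           k = 15L) {
  source <- as_genome(source)
  target <- as_genome(target)
  n <- length(genes)
  out <- data.frame(gene_id = character(n), chrom = character(n),
                    coverage = numeric(n), identity = numeric(n),
                    t_start = NA_integer_, t_end = NA_integer_,
                    synteny_ok = NA, contains_n = NA,
                    q_aln = NA_character_, s_aln = NA_character_,
                    stringsAsFactors = FALSE)
  prev_end <- setNames(rep(0L, length(target)), names(target))
  margin <- 30L   # flanking context; resolves indels at locus edges
  for (gi in seq_len(n)) {
    m <- genes[[gi]]
    out$gene_id[gi] <- m$gene_id
    out$chrom[gi] <- m$chrom
    sp <- gene_span(m)
    schrom <- source[[m$chrom]]
    gseq <- substr0(schrom, sp[1], sp[2])
    ext0 <- max(0L, sp[1] - margin)
    ext1 <- min(nchar(schrom), sp[2] + margin)
    gext <- substr0(schrom, ext0, ext1)
    mg_l <- sp[1] - ext0
    if (!m$chrom %in% names(target)) next
    tchrom <- target[[m$chrom]]
    tlen <- nchar(tchrom)
    glen <- nchar(gseq)
    w0 <- prev_end[[m$chrom]]
    w1 <- min(tlen, w0 + window + nchar(gext))
    pl <- place_locus(gext, tchrom, w0, w1, k)
    from_window <- TRUE
    if (is.null(pl)) {
      pl <- place_locus(gext, tchrom, 0L, tlen, k)
      from_window <- FALSE
    }
    if (!is.null(pl)) {
      pl <- slice_to_locus(pl, mg_l, glen)
    }
    if (is.null(pl)) {
      out$coverage[gi] <- 0
      out$identity[gi] <- 0
      out$contains_n[gi] <- grepl("N", gseq, fixed = TRUE)
      out$synteny_ok[gi] <- FALSE
      next
    }
    cc <- count_columns(list(q_aln = pl$q_aln, s_aln = pl$s_aln),
                        mask_n = FALSE)
    out$coverage[gi] <- (cc$matches + cc$mismatches) / glen
    out$identity[gi] <- if (cc$matches + cc$mismatches > 0)
      cc$matches / (cc$matches + cc$mismatches) else 0
    out$t_start[gi] <- pl$t_start
    out$t_end[gi] <- pl$t_end
    out$synteny_ok[gi] <- from_window && pl$t_start >= w0
    out$contains_n[gi] <- grepl("N", gseq, fixed = TRUE) ||
      grepl("N", pl$t_seq, fixed = TRUE)
    out$q_aln[gi] <- pl$q_aln
    out$s_aln[gi] <- pl$s_aln
    prev_end[m$chrom] <- pl$t_end
  }
  out
}

## Restrict a placed alignment of a margin-extended locus to the locus
## proper: keep the columns aligning reference bases
## [mg_l, mg_l + glen) and adjust the target interval accordingly.
slice_to_locus <- function(pl, mg_l, glen) {
  qa <- charToRaw(pl$q_aln)
  sa <- charToRaw(pl$s_aln)
  gap <- charToRaw("-")
  refpos <- cumsum(qa != gap)        # 1-based ref ordinal per column
  keep <- which(qa != gap & refpos > mg_l & refpos <= mg_l + glen)
  if (!length(keep)) return(NULL)
  c1 <- keep[1]; c2 <- keep[length(keep)]
  lead_t <- sum(sa[seq_len(c1 - 1L)] != gap)
  cols <- c1:c2
  t_bases <- sum(sa[cols] != gap)
  list(q_aln = rawToChar(qa[cols]), s_aln = rawToChar(sa[cols]),
       t_start = pl$t_start + lead_t,
       t_end = pl$t_start + lead_t + t_bases,
       t_seq = rawToChar(sa[cols][sa[cols] != gap]))
}

## Place one locus within target[w0, w1); returns NULL when no anchor.
place_locus <- function(gseq, tchrom, w0, w1, k, pad = 30L) {
  wseq <- substr0(tchrom, w0, w1)
  anchors <- cpp_find_anchors(gseq, wseq, as.integer(k))
  if (!nrow(anchors)) return(NULL)
  chain <- chain_anchors(anchors)
  first <- chain[1, ]; last <- chain[nrow(chain), ]
  s_begin <- max(0L, first["s0"] - first["q0"] - pad)
  s_end <- min(nchar(wseq),
               last["s0"] + last["len"] +
                 (nchar(gseq) - (last["q0"] + last["len"])) + pad)
  tseg <- substr0(wseq, s_begin, s_end)
  al <- align_pair(gseq, tseg, free_subject_ends = TRUE)
  ## trim terminal columns where the locus is gapped (the pad)
  qa <- charToRaw(al$a); sa <- charToRaw(al$b)
  gap <- charToRaw("-")
  nongap <- which(qa != gap)
  if (!length(nongap)) return(NULL)
  lo <- nongap[1]; hi <- nongap[length(nongap)]
  lead_t <- sum(sa[seq_len(lo - 1L)] != gap)
  trail_t <- sum(sa[seq(hi + 1L, length.out = length(sa) - hi)] != gap)
  q_aln <- rawToChar(qa[lo:hi])
  s_aln <- rawToChar(sa[lo:hi])
  t_start <- w0 + s_begin + lead_t
  t_end <- w0 + s_end - trail_t
  list(q_aln = q_aln, s_aln = s_aln, t_start = as.integer(t_start),
       t_end = as.integer(t_end),
       t_seq = gsub("-", "", s_aln, fixed = TRUE))
}

#' Difference events between a reference gene locus and its counterpart
#'
#' Walks the gapped alignment of the reference locus against the
#' orthologous target locus and emits one event per mismatch column and
#' per maximal gap run, with 0-based positions local to the reference
#' locus.  `ref`/`alt` are the reference and target alleles (`""` for
#' the empty side of an indel).
#'
#' @param q_aln,s_aln gapped aligned strings (reference, target), as
#'   produced by [sequential_map()] or [align_pair()].
#' @return A data.frame with columns `local_pos`, `type`
#'   (`snv`/`ins`/`del`; `ins` means extra sequence in the target),
#'   `ref`, `alt`.
#' @export
alignment_events <- function(q_aln, s_aln) {
  qa <- strsplit(q_aln, "", fixed = TRUE)[[1]]
  sa <- strsplit(s_aln, "", fixed = TRUE)[[1]]
  if (length(qa) != length(sa)) stop("aligned strings differ in length")
  qpos <- cumsum(qa != "-")   # 1-based ref position of each column
  state <- ifelse(qa == "-", "ins", ifelse(sa == "-", "del",
                  ifelse(qa == sa, "m", "x")))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    v <- r$values[i]
    if (v == "m") next
    cols <- starts[i]:ends[i]
    if (v == "x") {
      for (cl in cols) {
        out[[length(out) + 1L]] <- data.frame(
          local_pos = qpos[cl] - 1L, type = "snv",
          ref = qa[cl], alt = sa[cl], stringsAsFactors = FALSE)
      }
    } else if (v == "ins") {
      out[[length(out) + 1L]] <- data.frame(
        local_pos = qpos[starts[i]],   # insert before this ref base
        type = "ins", ref = "",
        alt = paste(sa[cols], collapse = ""), stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        local_pos = qpos[starts[i]] - 1L, type = "del",
        ref = paste(qa[cols], collapse = ""), alt = "",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(local_pos = integer(0), type = character(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Compare one gene between two assemblies
#'
#' Aligns the gene locus of `model` on `assembly` against the
#' orthologous locus sequence `other_locus` and classifies every
#' difference (the target allele is treated as the derived state).
#'
#' @param model a [gene_model()].
#' @param assembly assembly carrying the model.
#' @param other_locus orthologous locus sequence from the other strain.
#' @return A data.frame of candidate mutations: `gene_id`, `chrom`,
#'   `pos0` (genomic, reference), `local_pos` (0-based in the locus),
#'   `type`, `ref`, `alt`, `region`, `effect`, `protein_change`,
#'   `aa_pos`.
#' @export
diff_gene <- function(model, assembly, other_locus) {
  assembly <- as_genome(assembly)
  sp <- gene_span(model)
  chrom_seq <- assembly[[model$chrom]]
  gseq <- substr0(chrom_seq, sp[1], sp[2])
  al <- align_pair(gseq, other_locus)
  ev <- alignment_events(al$a, al$b)
  if (!nrow(ev)) {
    return(cbind(ev, data.frame(gene_id = character(0),
                                chrom = character(0), pos0 = integer(0),
                                region = character(0),
                                effect = character(0),
                                protein_change = character(0),
                                aa_pos = integer(0))))
  }
  cls <- lapply(seq_len(nrow(ev)), function(i) {
    classify_change(model, chrom_seq, sp[1] + ev$local_pos[i],
                    ev$ref[i], ev$alt[i])
  })
  data.frame(gene_id = model$gene_id, chrom = model$chrom,
             pos0 = sp[1] + ev$local_pos,
             local_pos = ev$local_pos, type = ev$type,
             ref = ev$ref, alt = ev$alt,
             region = vapply(cls, `[[`, "", "region"),
             effect = vapply(cls, `[[`, "", "effect"),
             protein_change = vapply(cls, `[[`, "", "protein_change"),
             aa_pos = vapply(cls, function(x)
               as.integer(x$aa_pos), 1L),
             stringsAsFactors = FALSE)
}

## ---- artifact flagging, read support, polarization ---------------------

#' Flag a candidate mutation as a homopolymer assembly artifact
#'
#' A mutation is flagged when it is an indel consisting of copies of a
#' single base whose pre-mutation run (the run containing or adjacent
#' to the indel) is at least `min_run` long, or a substitution that
#' creates or extends a run of at least `min_run` identical bases.  The
#' threshold is applied to the pre-mutation run length for indels, so a
#' 1-base insertion extending a 4-run to 5 is *not* flagged at
#' `min_run = 5`.
#'
#' @param context pre-mutation sequence context (e.g. the reference
#'   chromosome or locus); must span at least `2 * min_run` around the
#'   site.
#' @param pos 0-based position of the mutation within `context`.
#' @param ref,alt alleles (`""` for the empty side of an indel).
#' @param min_run minimum homopolymer run length (default 5).
#' @return Logical flag.
#' @export
flag_homopolymer_artifact <- function(context, pos, ref, alt,
                                      min_run = 5L) {
  rad <- max(12L, 2L * min_run)
  w0 <- max(0L, pos - rad)
  w1 <- min(nchar(context), pos + nchar(ref) + rad)
  pre <- substr0(context, w0, w1)
  p_local <- pos - w0
  if (nchar(ref) != nchar(alt)) {
    ## an indel is a homopolymer artifact when it only changes the
    ## lengths of existing runs that are >= min_run before the
    ## mutation: the run-length encodings must agree base for base,
    ## differing only in the lengths of qualifying runs (this also
    ## catches compound length errors in adjacent runs)
    post <- paste0(substr0(pre, 0L, p_local), alt,
                   substr0(pre, p_local + nchar(ref), nchar(pre)))
    rp <- rle(strsplit(pre, "", fixed = TRUE)[[1]])
    rq <- rle(strsplit(post, "", fixed = TRUE)[[1]])
    if (length(rp$values) != length(rq$values) ||
        any(rp$values != rq$values)) {
      return(FALSE)
    }
    changed <- which(rp$lengths != rq$lengths)
    return(length(changed) > 0 && all(rp$lengths[changed] >= min_run))
  }
  ## substitution: does it create or extend a qualifying run?
  post <- paste0(substr0(pre, 0L, p_local), alt,
                 substr0(pre, p_local + nchar(ref), nchar(pre)))
  runs <- homopolymer_runs(post, min_run)
  if (!nrow(runs)) return(FALSE)
  any(runs$start <= p_local & p_local < runs$end)
}

#' Check read k-mer support for the two alleles of a mutation
#'
#' Counts exact occurrences (both strands) of the k-mers spanning the
#' variant in the reference-allele and alternate-allele contexts, and
#' compares the best-supported spanning k-mer of each allele against
#' `min_count`.
#'
#' @param ref_context,alt_context sequence context carrying the
#'   reference and the alternate allele respectively; the variant must
#'   sit `var_at` bases into each context.
#' @param var_at 0-based offset of the variant within the contexts.
#' @param ref_len,alt_len allele lengths within the two contexts (0 for
#'   the empty side of an indel).
#' @param reads a `DNAStringSet` of reads, or a path to a FASTQ file
#'   (malformed records are skipped with a message).
#' @param k k-mer size (odd).
#' @param min_count minimal count for an allele to be considered
#'   supported.
#' @return A list with `verdict` (`supported`, `refuted`, `mixed` or
#'   `untested`), `ref_count` and `alt_count`.
#' @export
kmer_support <- function(ref_context, alt_context, var_at,
                         ref_len, alt_len, reads, k = 31L,
                         min_count = 3L) {
  if (k %% 2L == 0L) stop("k must be odd")
  if (is.character(reads) && length(reads) == 1L) {
    reads <- read_fastq_lenient(reads)
  }
  count_allele <- function(context, vlen) {
    L <- nchar(context)
    if (L < k) return(0L)
    vend <- var_at + max(1L, vlen)
    t0 <- max(0L, var_at - k + 1L)
    t1 <- max(t0, min(L - k, vend - 1L))
    starts <- seq(t0, t1)
    kmers <- unique(substring(context, starts + 1L, starts + k))
    kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
    if (!length(kmers)) return(0L)
    counts <- vapply(kmers, function(km) {
      fwd <- sum(Biostrings::vcountPattern(km, reads))
      rev <- sum(Biostrings::vcountPattern(revcomp(km), reads))
      fwd + rev
    }, 0L)
    max(counts)
  }
  rc <- count_allele(ref_context, ref_len)
  ac <- count_allele(alt_context, alt_len)
  verdict <- if (ac >= min_count && rc < min_count) "supported"
    else if (rc >= min_count && ac < min_count) "refuted"
    else if (rc >= min_count && ac >= min_count) "mixed"
    else "untested"
  list(verdict = verdict, ref_count = rc, alt_count = ac)
}

## FASTQ reader that skips malformed records with a message
## (Biostrings's reader has no skip-and-count semantics, so validation
## is done line-wise here; support checking only needs the sequences)
read_fastq_lenient <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  n <- length(lines) %/% 4L
  seqs <- character(0)
  skipped <- 0L
  for (i in seq_len(n)) {
    hdr <- lines[4L * i - 3L]; seq <- lines[4L * i - 2L]
    plus <- lines[4L * i - 1L]; qual <- lines[4L * i]
    if (startsWith(hdr, "@") && startsWith(plus, "+") &&
        nchar(seq) == nchar(qual) && !grepl("[^ACGTNacgtn]", seq)) {
      seqs <- c(seqs, toupper(seq))
    } else skipped <- skipped + 1L
  }
  if (skipped) message("skipped ", skipped, " malformed FASTQ record(s)")
  Biostrings::DNAStringSet(seqs)
}

#' Polarize a mutation onto a culture interval
#'
#' Given the alleles of the three serially related strains A, B, C at
#' one site, assigns the interval in which the mutation arose:
#' `a == b != c` gives `B>C`, `a != b, b == c` gives `A>B`,
#' `a == c != b` is a `conflict` (possible reversion or error), and
#' three equal alleles give `none`.  A missing allele (N or NA) yields
#' `indeterminate`.
#'
#' @param allele_a,allele_b,allele_c allele strings.
#' @return One of `"A>B"`, `"B>C"`, `"conflict"`, `"none"`,
#'   `"indeterminate"`.
#' @export
polarize_mutation <- function(allele_a, allele_b, allele_c) {
  al <- c(allele_a, allele_b, allele_c)
  if (anyNA(al) || any(grepl("N", al, fixed = TRUE))) {
    return("indeterminate")
  }
  if (al[1] == al[2] && al[2] == al[3]) return("none")
  if (al[1] == al[2]) return("B>C")
  if (al[2] == al[3]) return("A>B")
  if (al[1] == al[3]) return("conflict")
  "conflict"
}
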