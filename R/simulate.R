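#' Configuration for the synthetic ancestor generator
#'
#' Defaults describe a compact fungal-style haploid genome: ~40% of the
#' sequence exonic and ~5% intronic, with homopolymer tracts scattered
#' through intergenic and intronic sequence.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length length of each chromosome in bases.
#' @param gc_fraction GC content of random sequence.
#' @param gene_count total number of protein-coding genes.
#' @param exon_fraction,intron_fraction target fractions of the genome
#'   annotated as exon and intron (defaults 0.40 and 0.05).
#' @param homopolymer_tract_rate homopolymer tracts (length >= 5)
#'   embedded per kb of intergenic sequence.
#' @param seed integer seed; generation is deterministic given the
#'   configuration.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 1L, chromosome_length = 100000L,
                       gc_fraction = 0.5, gene_count = 40L,
                       exon_fraction = 0.40, intron_fraction = 0.05,
                       homopolymer_tract_rate = 0.5, seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              gc_fraction = gc_fraction, gene_count = as.integer(gene_count),
              exon_fraction = exon_fraction,
              intron_fraction = intron_fraction,
              homopolymer_tract_rate = homopolymer_tract_rate,
              seed = as.integer(seed))
  props <- c(cfg$gc_fraction, cfg$exon_fraction, cfg$intron_fraction)
  if (any(props < 0 | props > 1)) stop("all proportions must be in [0, 1]")
  if (cfg$exon_fraction + cfg$intron_fraction > 1) {
    stop("exon_fraction + intron_fraction must be <= 1")
  }
  if (cfg$n_chromosomes < 1 || cfg$chromosome_length < 1) {
    stop("lengths must be positive")
  }
  if (cfg$gene_count < 0 || cfg$homopolymer_tract_rate < 0) {
    stop("counts and rates must be >= 0")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Specification of variants to plant between two strains
#'
#' @param snv_rate_per_mb expected single-nucleotide variants per Mb
#'   (events are Poisson-sampled).
#' @param indel_rate_per_mb expected small indels per Mb.
#' @param indel_length_range inclusive range of indel lengths in bases.
#' @param class_mix named proportions over the variant classes
#'   `intergenic`, `intronic`, `synonymous`, `missense`, `nonsense`,
#'   `frameshift`; must sum to 1.  SNVs draw from the first five,
#'   indels from `intergenic`/`intronic`/`frameshift` (renormalised).
#' @param tandem_duplications list of events, each a list with fields
#'   `region` (`"cds"`, `"intron"` or `"intergenic"`), `unit` (length in
#'   bases of the duplicated unit) and optional `copies` (default 1
#'   extra copy).
#' @param reversions list of truth-set rows (as single-row data.frames
#'   or lists) describing prior insertions to delete again, with
#'   `chrom` and `pos0_derived` referring to the assembly being mutated.
#' @return A validated list of class `variant_spec`.
#' @export
variant_spec <- function(snv_rate_per_mb = 0, indel_rate_per_mb = 0,
                         indel_length_range = c(1L, 3L),
                         class_mix = c(intergenic = 0.45, intronic = 0.15,
                                       synonymous = 0.10, missense = 0.20,
                                       nonsense = 0.05, frameshift = 0.05),
                         tandem_duplications = list(),
                         reversions = list()) {
  if (snv_rate_per_mb < 0 || indel_rate_per_mb < 0) {
    stop("rates must be >= 0")
  }
  need <- c("intergenic", "intronic", "synonymous", "missense",
            "nonsense", "frameshift")
  if (!all(need %in% names(class_mix))) {
    stop("class_mix must name all of: ", paste(need, collapse = ", "))
  }
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  structure(list(snv_rate_per_mb = snv_rate_per_mb,
                 indel_rate_per_mb = indel_rate_per_mb,
                 indel_length_range = as.integer(indel_length_range),
                 class_mix = class_mix[need],
                 tandem_duplications = tandem_duplications,
                 reversions = reversions),
            class = "variant_spec")
}

#' Specification of assembly artifacts to inject
#'
#' @param homopolymer_error_rate probability that each homopolymer run
#'   of length >= `min_run` receives a +/-1 or +/-2 length error.
#' @param n_gap_count number of N-gaps to inject.
#' @param n_gap_length_range inclusive range of N-gap lengths.
#' @param min_run minimum run length eligible for homopolymer errors.
#' @return A validated list of class `artifact_spec`.
#' @export
artifact_spec <- function(homopolymer_error_rate = 0, n_gap_count = 0L,
                          n_gap_length_range = c(20L, 100L),
                          min_run = 5L) {
  if (homopolymer_error_rate < 0 || homopolymer_error_rate > 1) {
    stop("homopolymer_error_rate must be in [0, 1]")
  }
  if (n_gap_count < 0) stop("n_gap_count must be >= 0")
  structure(list(homopolymer_error_rate = homopolymer_error_rate,
                 n_gap_count = as.integer(n_gap_count),
                 n_gap_length_range = as.integer(n_gap_length_range),
                 min_run = as.integer(min_run)),
            class = "artifact_spec")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

## all 61 sense codons
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, STOP_CODONS)
}

## Build one gene locus (forward coding orientation), returning the
## locus string plus local exon intervals (0-based half-open).
build_gene_locus <- function(exon_bases, intron_bases, gc) {
  n_codons <- max(4L, exon_bases %/% 3L)
  body <- sample(sense_codons(), n_codons - 2L, replace = TRUE)
  cds <- paste0("ATG", paste(body, collapse = ""),
                sample(STOP_CODONS, 1L))
  clen <- nchar(cds)
  max_introns <- max(0L, intron_bases %/% 25L)
  n_introns <- if (max_introns == 0L) 0L else sample(seq_len(min(3L, max_introns)), 1L)
  if (n_introns == 0L) {
    return(list(locus = cds,
                exons = matrix(c(0L, clen), ncol = 2)))
  }
  ## split CDS at interior points (keep >= 10 bases per exon piece)
  cuts <- sort(sample(seq(10L, clen - 10L), n_introns))
  ilen <- rep(intron_bases %/% n_introns, n_introns)
  make_intron <- function(len) {
    mid <- len - 4L
    inner <- random_dna(mid, gc)
    if (mid >= 10L && runif(1) < 0.4) {  # embed a homopolymer tract
      run <- strrep(sample(c("A", "C", "G", "T"), 1L), sample(5:8, 1L))
      at <- sample(seq_len(mid - nchar(run)), 1L)
      inner <- paste0(substr(inner, 1, at), run,
                      substr(inner, at + nchar(run) + 1L, mid))
      inner <- substr(paste0(inner, random_dna(mid, gc)), 1, mid)
    }
    paste0("GT", inner, "AG")
  }
  pieces <- character(0)
  exons <- matrix(integer(0), ncol = 2)
  at <- 0L   # local coordinate
  prev <- 0L # position within CDS
  for (i in seq_len(n_introns)) {
    ex <- substr(cds, prev + 1L, cuts[i])
    pieces <- c(pieces, ex)
    exons <- rbind(exons, c(at, at + nchar(ex)))
    at <- at + nchar(ex)
    intr <- make_intron(max(25L, ilen[i]))
    pieces <- c(pieces, intr)
    at <- at + nchar(intr)
    prev <- cuts[i]
  }
  ex <- substr(cds, prev + 1L, clen)
  pieces <- c(pieces, ex)
  exons <- rbind(exons, c(at, at + nchar(ex)))
  list(locus = paste(pieces, collapse = ""), exons = exons)
}

## intergenic filler with embedded homopolymer tracts
intergenic_dna <- function(len, gc, tract_rate) {
  if (len <= 0) return("")
  s <- random_dna(len, gc)
  n_tracts <- rpois(1L, tract_rate * len / 1000)
  if (n_tracts > 0 && len > 30L) {
    for (i in seq_len(n_tracts)) {
      run <- strrep(sample(c("A", "C", "G", "T"), 1L), sample(5:10, 1L))
      at <- sample(seq_len(len - nchar(run) - 1L), 1L)
      s <- paste0(substr(s, 1, at), run,
                  substr(s, at + nchar(run) + 1L, len))
    }
  }
  s
}

#' Generate a synthetic ancestral genome and its gene models
#'
#' Chromosomes are random sequence at the requested GC content into
#' which gene loci are laid out evenly; each gene is fully coding
#' (CDS = exons), starts with ATG, ends with a stop codon, and may be
#' split by GT..AG introns.  Exon and intron base fractions match the
#' configuration by construction; homopolymer tracts (runs >= 5) are
#' embedded in intergenic and intronic sequence.
#'
#' @param config a [sim_config()].
#' @return A list with `assembly` (see [as_genome()]), `genes` (list of
#'   [gene_model()]), and `config`.
#' @export
generate_ancestor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$chromosome_length
  total <- config$n_chromosomes * L
  g <- config$gene_count
  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))

  if (g == 0L) {
    assembly <- setNames(vapply(chrom_names, function(cn)
      intergenic_dna(L, config$gc_fraction,
                     config$homopolymer_tract_rate), ""), chrom_names)
    return(list(assembly = assembly, genes = list(), config = config))
  }

  exon_per_gene <- 3L * as.integer(round(config$exon_fraction * total / g / 3))
  intron_per_gene <- as.integer(round(config$intron_fraction * total / g))
  gene_len <- exon_per_gene + intron_per_gene
  per_chrom <- diff(round(seq(0, g, length.out = config$n_chromosomes + 1)))
  if (exon_per_gene < 12L) {
    stop("gene_count infeasible: the exon budget per gene (",
         exon_per_gene, " bases) is below the 12-base minimum CDS")
  }
  if (any(per_chrom * (gene_len + 40L) + 40L > L)) {
    stop("gene_count infeasible: ", max(per_chrom), " genes of ~",
         gene_len, " bases (+40 spacing) exceed chromosome length ", L)
  }

  assembly <- character(0)
  genes <- list()
  gidx <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    ng <- per_chrom[ci]
    pieces <- character(0)
    at <- 0L
    if (ng > 0) {
      spare <- L - ng * gene_len
      gaps <- diff(round(seq(0, spare, length.out = ng + 2L)))  # ng+1 gaps
      for (k in seq_len(ng)) {
        filler <- intergenic_dna(gaps[k], config$gc_fraction,
                                 config$homopolymer_tract_rate)
        pieces <- c(pieces, filler)
        at <- at + nchar(filler)
        gl <- build_gene_locus(exon_per_gene, intron_per_gene,
                               config$gc_fraction)
        strand <- sample(c("+", "-"), 1L)
        locus <- gl$locus
        exons <- gl$exons
        if (strand == "-") {
          locus <- revcomp(locus)
          ll <- nchar(locus)
          exons <- cbind(ll - exons[, 2], ll - exons[, 1])
          exons <- exons[order(exons[, 1]), , drop = FALSE]
        }
        gidx <- gidx + 1L
        genes[[gidx]] <- gene_model(
          gene_id = sprintf("g%04d", gidx),
          chrom = chrom_names[ci], strand = strand,
          exons = exons + at, cds = exons + at,
          protein_id = sprintf("p%04d", gidx))
        pieces <- c(pieces, locus)
        at <- at + nchar(locus)
      }
      tail_len <- L - at
      pieces <- c(pieces, intergenic_dna(tail_len, config$gc_fraction,
                                         config$homopolymer_tract_rate))
    } else {
      pieces <- intergenic_dna(L, config$gc_fraction,
                               config$homopolymer_tract_rate)
    }
    assembly[chrom_names[ci]] <- paste(pieces, collapse = "")
  }
  list(assembly = as_genome(assembly), genes = sort_gene_models(genes),
       config = config)
}

## ---- site selection helpers -------------------------------------------

## TRUE when the footprint [pos, pos+len) neither lies in nor creates a
## homopolymer run >= min_run (checked pre- and post-mutation), so that
## planted variants are never confusable with homopolymer artifacts.
hp_safe <- function(chrom_seq, pos, ref, alt, min_run = 5L) {
  rad <- 12L
  w0 <- max(0L, pos - rad)
  w1 <- min(nchar(chrom_seq), pos + nchar(ref) + rad)
  pre <- substr0(chrom_seq, w0, w1)
  post <- paste0(substr0(chrom_seq, w0, pos), alt,
                 substr0(chrom_seq, pos + nchar(ref), w1))
  no_run <- function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    all(r$lengths < min_run)
  }
  no_run(pre) && no_run(post)
}

far_enough <- function(pos, chrom, placed, min_space = 50L) {
  same <- placed$chrom == chrom
  !any(same & abs(placed$pos0 - pos) < min_space)
}

## position class maps for one chromosome: returns integer vectors of
## 0-based candidate positions
position_classes <- function(models, chrom, chrom_len) {
  in_gene <- rep(FALSE, chrom_len)
  in_exon <- rep(FALSE, chrom_len)
  splice <- rep(FALSE, chrom_len)
  for (m in models) {
    if (m$chrom != chrom) next
    sp <- gene_span(m)
    in_gene[(sp[1] + 1L):sp[2]] <- TRUE
    for (i in seq_len(nrow(m$exons))) {
      in_exon[(m$exons[i, 1] + 1L):m$exons[i, 2]] <- TRUE
    }
    if (nrow(m$exons) > 1) {
      for (i in seq_len(nrow(m$exons) - 1L)) {
        d0 <- m$exons[i, 2]          # intron start, 0-based
        a1 <- m$exons[i + 1L, 1]     # intron end
        splice[c(d0 + 1L, d0 + 2L, a1 - 1L, a1)] <- TRUE
      }
    }
  }
  list(intergenic = which(!in_gene) - 1L,
       intronic = which(in_gene & !in_exon & !splice) - 1L)
}

## ---- planting ----------------------------------------------------------

#' Plant variants into an assembly, producing a derived strain
#'
#' Single-nucleotide variants, small indels, tandem duplications and
#' reversions are placed at sites chosen to realise the requested class
#' mix; every coding plant is verified against the gene models at
#' planting time (a missense plant really changes the encoded amino
#' acid, a nonsense plant really creates a stop, a synonymous plant
#' preserves the protein).  Sites are kept >= 50 bases apart, clear of
#' splice dinucleotides, and outside homopolymer runs, so that planted
#' variants are unambiguous ground truth.
#'
#' @param ancestor assembly to mutate (see [as_genome()]).
#' @param genes gene models on `ancestor`.
#' @param spec a [variant_spec()].
#' @param seed integer seed.
#' @param interval label recorded for each variant (e.g. `"A>B"`).
#' @return A list with `assembly` (the derived strain), `genes` (the
#'   input models lifted through planted indels, i.e. valid on the
#'   derived assembly), and `truth`, a data.frame with columns `chrom`,
#'   `pos0` (0-based, ancestor coordinates), `ref`, `alt` (empty string
#'   for pure insertion/deletion), `class`, `interval`, `pos0_derived`
#'   (coordinates on the derived assembly).
#' @export
plant_variants <- function(ancestor, genes, spec, seed, interval = "A>B") {
  stopifnot(inherits(spec, "variant_spec"))
  ancestor <- as_genome(ancestor)
  set.seed(seed)
  total <- sum(nchar(ancestor))
  coding_req <- sum(spec$class_mix[c("synonymous", "missense",
                                     "nonsense", "frameshift")]) > 0
  if (coding_req && !length(genes) &&
      (spec$snv_rate_per_mb > 0 || spec$indel_rate_per_mb > 0)) {
    stop("coding variant classes requested but no gene models supplied")
  }

  pos_classes <- lapply(setNames(names(ancestor), names(ancestor)),
                        function(cn) position_classes(genes, cn,
                                                      nchar(ancestor[[cn]])))
  placed <- data.frame(chrom = character(0), pos0 = integer(0),
                       ref = character(0), alt = character(0),
                       class = character(0), stringsAsFactors = FALSE)

  add <- function(chrom, pos, ref, alt, class) {
    placed[nrow(placed) + 1L, ] <<- list(chrom, pos, ref, alt, class)
  }

  pick_chrom <- function() {
    sample(names(ancestor), 1L, prob = nchar(ancestor))
  }

  try_place <- function(class, is_indel, indel_len) {
    for (attempt in 1:500) {
      if (class %in% c("intergenic", "intronic")) {
        chrom <- pick_chrom()
        cand <- pos_classes[[chrom]][[if (class == "intergenic")
          "intergenic" else "intronic"]]
        cand <- cand[cand > 30L & cand < nchar(ancestor[[chrom]]) - 30L]
        if (!length(cand)) next
        pos <- sample_from(cand)
        seq <- ancestor[[chrom]]
        if (is_indel) {
          if (runif(1) < 0.5) {  # deletion
            ref <- substr0(seq, pos, pos + indel_len); alt <- ""
          } else {
            ref <- ""; alt <- random_dna(indel_len, 0.5)
          }
          ## an intronic indel must stay inside the intron
          if (class == "intronic" &&
              !all((pos:(pos + max(1L, nchar(ref)) - 1L)) %in%
                   pos_classes[[chrom]]$intronic)) next
        } else {
          ref <- substr0(seq, pos, pos + 1L)
          alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        }
        if (ref == "" && alt == "") next
        if (grepl("N", paste0(ref, substr0(seq, max(0, pos - 12),
                                           min(nchar(seq), pos + 12))))) next
        if (!hp_safe(seq, pos, ref, alt)) next
        if (!far_enough(pos, chrom, placed)) next
        add(chrom, pos, ref, alt, class)
        return(TRUE)
      }
      ## coding classes: pick a gene, then a site within its CDS
      m <- genes[[sample(length(genes), 1L)]]
      seq <- ancestor[[m$chrom]]
      site <- pick_coding_site(m, seq, class, indel_len)
      if (is.null(site)) next
      if (!hp_safe(seq, site$pos, site$ref, site$alt)) next
      if (!far_enough(site$pos, m$chrom, placed)) next
      ## verify the class label against the gene models
      cls <- classify_change(m, seq, site$pos, site$ref, site$alt)
      if (!identical(cls$effect, class)) next
      add(m$chrom, site$pos, site$ref, site$alt, class)
      return(TRUE)
    }
    stop("could not place a variant of class '", class,
         "' after bounded retries")
  }

  ## Poisson event counts at the requested rates
  n_snv <- rpois(1L, spec$snv_rate_per_mb * total / 1e6)
  n_indel <- rpois(1L, spec$indel_rate_per_mb * total / 1e6)
  snv_mix <- spec$class_mix[c("intergenic", "intronic", "synonymous",
                              "missense", "nonsense")]
  indel_mix <- spec$class_mix[c("intergenic", "intronic", "frameshift")]
  if (n_snv > 0 && sum(snv_mix) > 0) {
    for (cl in sample(names(snv_mix), n_snv, replace = TRUE,
                      prob = snv_mix)) {
      try_place(cl, is_indel = FALSE, indel_len = 0L)
    }
  }
  if (n_indel > 0 && sum(indel_mix) > 0) {
    lens <- sample_from(seq(spec$indel_length_range[1],
                            spec$indel_length_range[2]),
                        n_indel, replace = TRUE)
    cls <- sample(names(indel_mix), n_indel, replace = TRUE,
                  prob = indel_mix)
    for (i in seq_len(n_indel)) {
      len <- lens[i]
      if (cls[i] == "frameshift" && len %% 3L == 0L) len <- len + 1L
      try_place(cls[i], is_indel = TRUE, indel_len = len)
    }
  }

  ## tandem duplications: insert an extra copy of the `unit` bases
  ## immediately preceding the chosen point
  for (ev in spec$tandem_duplications) {
    unit <- as.integer(ev$unit)
    copies <- if (is.null(ev$copies)) 1L else as.integer(ev$copies)
    region <- if (is.null(ev$region)) "cds" else ev$region
    done <- FALSE
    for (attempt in 1:500) {
      if (region == "cds") {
        if (!length(genes)) stop("tandem duplication in CDS requested ",
                                 "but no gene models supplied")
        m <- genes[[sample(length(genes), 1L)]]
        seq <- ancestor[[m$chrom]]
        cd <- m$cds[sample(nrow(m$cds), 1L), ]
        if (cd[2] - cd[1] < unit + 20L) next
        pos <- sample_from(seq(cd[1] + unit + 6L, cd[2] - 6L))
        chrom <- m$chrom
      } else {
        chrom <- pick_chrom()
        cand <- pos_classes[[chrom]][[if (region == "intron")
          "intronic" else "intergenic"]]
        cand <- cand[cand > unit + 10L]
        if (!length(cand)) next
        pos <- sample_from(cand)
        seq <- ancestor[[chrom]]
      }
      unit_seq <- substr0(seq, pos - unit, pos)
      alt <- strrep(unit_seq, copies)
      if (grepl("N", unit_seq) || !hp_safe(seq, pos, "", alt)) next
      if (!far_enough(pos, chrom, placed)) next
      cls_label <- if (region == "cds") {
        if ((unit * copies) %% 3L == 0L) "inframe_indel" else "frameshift"
      } else region
      if (region == "cds") {
        cls <- classify_change(m, seq, pos, "", alt)
        if (!identical(cls$effect, cls_label)) next
      }
      add(chrom, pos, "", alt, paste0("tandem_duplication:", cls_label))
      done <- TRUE
      break
    }
    if (!done) stop("could not place tandem duplication of unit ", unit)
  }

  ## reversions: delete a previously inserted segment (coordinates on
  ## *this* assembly, i.e. pos0_derived of the earlier truth row)
  for (rv in spec$reversions) {
    rv <- as.list(rv)
    chrom <- rv$chrom
    pos <- as.integer(rv$pos0_derived)
    ins <- rv$alt
    seq <- ancestor[[chrom]]
    if (substr0(seq, pos, pos + nchar(ins)) != ins) {
      stop("reversion target not present at ", chrom, ":", pos)
    }
    add(chrom, pos, ins, "", "reversion")
  }

  derived <- apply_variants(ancestor, placed)
  lifted <- lift_models(genes, placed)
  truth <- placed
  truth$interval <- rep(interval, nrow(truth))
  truth$pos0_derived <- derived_positions(placed)
  list(assembly = derived$assembly, genes = lifted, truth = truth)
}

## choose a candidate coding site for a requested effect class;
## returns list(pos, ref, alt) in genomic coordinates or NULL
pick_coding_site <- function(m, chrom_seq, class, indel_len) {
  st <- splice_and_translate(m, setNames(chrom_seq, m$chrom)[m$chrom])
  cds <- st$cds
  n_cod <- nchar(cds) %/% 3L
  if (n_cod < 6L) return(NULL)
  ci <- sample(seq(3L, n_cod - 2L), 1L)   # interior codon, 1-based
  codon <- substr(cds, 3L * ci - 2L, 3L * ci)
  if (grepl("N", codon)) return(NULL)
  if (class == "frameshift") {
    cpos <- 3L * (ci - 1L) + sample(0:2, 1L)   # 0-based CDS offset
    gpos <- cds_to_genomic(m, cpos)
    if (runif(1) < 0.5) {
      ref <- substr0(chrom_seq, gpos, gpos + indel_len)
      if (!footprint_in_cds(m, gpos, indel_len)) return(NULL)
      return(list(pos = gpos, ref = ref, alt = ""))
    }
    return(list(pos = gpos, ref = "",
                alt = random_dna(indel_len, 0.5)))
  }
  off <- sample(0:2, 1L)                    # position within codon
  aa_ref <- GENETIC_CODE_1[[codon]]
  cands <- setdiff(c("A", "C", "G", "T"), substr(codon, off + 1L, off + 1L))
  cands <- sample(cands)
  for (nb in cands) {
    alt_codon <- codon
    substr(alt_codon, off + 1L, off + 1L) <- nb
    aa_alt <- GENETIC_CODE_1[[alt_codon]]
    ok <- switch(class,
                 synonymous = aa_alt == aa_ref && aa_alt != "*",
                 missense = aa_alt != aa_ref && aa_alt != "*" && aa_ref != "*",
                 nonsense = aa_alt == "*" && aa_ref != "*",
                 FALSE)
    if (!ok) next
    cpos <- 3L * (ci - 1L) + off
    gpos <- cds_to_genomic(m, cpos)
    ref_g <- substr0(chrom_seq, gpos, gpos + 1L)
    alt_g <- if (m$strand == "+") nb else revcomp(nb)
    if (ref_g == alt_g) next
    return(list(pos = gpos, ref = ref_g, alt = alt_g))
  }
  NULL
}

## genomic 0-based position of CDS offset `cpos` (0-based, coding order)
cds_to_genomic <- function(m, cpos) {
  lens <- m$cds[, 2] - m$cds[, 1]
  if (m$strand == "+") {
    cum <- cumsum(lens)
    i <- which(cpos < cum)[1]
    prev <- if (i == 1L) 0L else cum[i - 1L]
    m$cds[i, 1] + (cpos - prev)
  } else {
    lens_r <- rev(lens)
    cum <- cumsum(lens_r)
    i <- which(cpos < cum)[1]
    prev <- if (i == 1L) 0L else cum[i - 1L]
    ri <- nrow(m$cds) - i + 1L
    m$cds[ri, 2] - 1L - (cpos - prev)
  }
}

## TRUE if [pos, pos+len) lies entirely within one CDS interval
footprint_in_cds <- function(m, pos, len) {
  any(m$cds[, 1] <= pos & pos + len <= m$cds[, 2])
}

#' Apply truth-set variant records to an assembly
#'
#' Records carry ancestor coordinates; they are applied right-to-left
#' per chromosome so positions remain valid.  Re-applying a truth set
#' to the ancestor reproduces the derived assembly byte for byte.
#'
#' @param assembly ancestor assembly.
#' @param truth data.frame with columns `chrom`, `pos0`, `ref`, `alt`.
#' @return A list with the mutated `assembly`.
#' @export
apply_variants <- function(assembly, truth) {
  assembly <- as_genome(assembly)
  if (nrow(truth)) {
    ord <- order(truth$chrom, -truth$pos0)
    for (i in ord) {
      chrom <- truth$chrom[i]
      seq <- assembly[[chrom]]
      pos <- truth$pos0[i]
      ref <- truth$ref[i]
      if (nchar(ref) && substr0(seq, pos, pos + nchar(ref)) != ref) {
        stop("truth record ", i, " does not match assembly at ",
             chrom, ":", pos)
      }
      assembly[chrom] <- splice_string(seq, pos, pos + nchar(ref),
                                       truth$alt[i])
    }
  }
  list(assembly = assembly)
}

## derived-coordinate positions: shift each record by the net length
## change of all records to its left on the same chromosome
derived_positions <- function(truth) {
  if (!nrow(truth)) return(integer(0))
  out <- integer(nrow(truth))
  delta <- nchar(truth$alt) - nchar(truth$ref)
  for (i in seq_len(nrow(truth))) {
    left <- truth$chrom == truth$chrom[i] & truth$pos0 < truth$pos0[i]
    out[i] <- truth$pos0[i] + sum(delta[left])
  }
  out
}

## lift gene models through the planted indels
lift_models <- function(models, truth) {
  if (!nrow(truth) || !length(models)) return(models)
  indels <- truth[nchar(truth$ref) != nchar(truth$alt), , drop = FALSE]
  ## apply right-to-left so earlier coordinates stay valid
  indels <- indels[order(indels$chrom, -indels$pos0), , drop = FALSE]
  for (i in seq_len(nrow(indels))) {
    pos <- indels$pos0[i]
    delta <- nchar(indels$alt[i]) - nchar(indels$ref[i])
    rlen <- nchar(indels$ref[i])
    models <- lapply(models, function(m) {
      if (m$chrom != indels$chrom[i]) return(m)
      shift_iv <- function(iv) {
        t(apply(iv, 1L, function(r) {
          if (r[1] >= pos + rlen) return(r + delta)   # fully right
          if (r[2] <= pos) return(r)                  # fully left
          c(r[1], r[2] + delta)                       # contains the edit
        }))
      }
      m$exons <- shift_iv(m$exons)
      m$cds <- shift_iv(m$cds)
      m
    })
  }
  models
}

#' Inject assembly artifacts (homopolymer length errors and N-gaps)
#'
#' Homopolymer errors change the length of existing runs of
#' `min_run` or more identical bases by +/-1 or +/-2; N-gaps replace
#' defined sequence with runs of N.  Both mimic long-read assembly
#' defects and are recorded exhaustively.
#'
#' @param assembly assembly to perturb.
#' @param spec an [artifact_spec()].
#' @param seed integer seed.
#' @param strain label recorded with each artifact.
#' @return A list with `assembly` and `artifacts`, a data.frame with
#'   columns `chrom`, `pos0` (position on the *input* assembly), `type`
#'   (`homopolymer_error` or `n_gap`), `detail` (signed length change or
#'   gap length), `strain`.
#' @export
inject_artifacts <- function(assembly, spec, seed, strain = "A") {
  stopifnot(inherits(spec, "artifact_spec"))
  assembly <- as_genome(assembly)
  set.seed(seed)
  recs <- data.frame(chrom = character(0), pos0 = integer(0),
                     type = character(0), detail = integer(0),
                     strain = character(0), stringsAsFactors = FALSE)
  ## homopolymer length errors
  if (spec$homopolymer_error_rate > 0) {
    for (chrom in names(assembly)) {
      runs <- homopolymer_runs(assembly[[chrom]], spec$min_run)
      if (!nrow(runs)) next
      hit <- runif(nrow(runs)) < spec$homopolymer_error_rate
      runs <- runs[hit, , drop = FALSE]
      if (!nrow(runs)) next
      runs <- runs[order(-runs$start), , drop = FALSE]  # right-to-left
      seq <- assembly[[chrom]]
      for (i in seq_len(nrow(runs))) {
        d <- sample(c(-2L, -1L, 1L, 2L), 1L)
        len <- runs$end[i] - runs$start[i]
        if (len + d < 1L) d <- 1L
        newrun <- strrep(runs$base[i], len + d)
        seq <- splice_string(seq, runs$start[i], runs$end[i], newrun)
        recs[nrow(recs) + 1L, ] <- list(chrom, runs$start[i],
                                        "homopolymer_error", d, strain)
      }
      assembly[chrom] <- seq
    }
  }
  ## N-gaps
  if (spec$n_gap_count > 0) {
    lens <- sample_from(seq(spec$n_gap_length_range[1],
                            spec$n_gap_length_range[2]),
                        spec$n_gap_count, replace = TRUE)
    taken <- list()
    for (i in seq_len(spec$n_gap_count)) {
      chrom <- sample(names(assembly), 1L, prob = nchar(assembly))
      clen <- nchar(assembly[[chrom]])
      if (lens[i] > clen) {
        stop("requested N-gap of ", lens[i],
             " bases exceeds chromosome ", chrom, " length ", clen)
      }
      for (attempt in 1:200) {
        pos <- sample_from(seq(10L, clen - lens[i] - 10L))
        prev <- taken[[chrom]]
        if (!is.null(prev) &&
            any(pos < prev[, 2] + 1L & pos + lens[i] + 1L > prev[, 1])) next
        taken[[chrom]] <- rbind(prev, c(pos, pos + lens[i]))
        assembly[chrom] <- splice_string(assembly[[chrom]], pos,
                                         pos + lens[i],
                                         strrep("N", lens[i]))
        recs[nrow(recs) + 1L, ] <- list(chrom, pos, "n_gap",
                                        lens[i], strain)
        break
      }
    }
  }
  list(assembly = assembly, artifacts = recs)
}

#' Simulate a serial strain trio with known ground truth
#'
#' Builds an ancestor A, derives B from A and C from B (mirroring
#' serial laboratory culture), so every planted variant has a
#' well-defined appearance interval (`A>B` or `B>C`).  Optional
#' artifact specs perturb the *observed* copies of A and C with
#' homopolymer-length errors and N-gaps while the clean assemblies are
#' retained as ground truth.
#'
#' @param config a [sim_config()] for the ancestor.
#' @param spec_ab,spec_bc [variant_spec()]s for the two culture
#'   intervals.
#' @param artifacts_a,artifacts_c optional [artifact_spec()]s applied
#'   to the observed A and C assemblies.
#' @return A list with clean assemblies `a`, `b`, `c`; observed
#'   assemblies `a_obs`, `c_obs`; gene models `genes_a`, `genes_b`,
#'   `genes_c` (lifted onto each strain); `truth` (all variant records)
#'   and `artifacts`; and `seeds` used per stage.
#' @export
simulate_trio <- function(config,
                          spec_ab = variant_spec(),
                          spec_bc = variant_spec(),
                          artifacts_a = NULL, artifacts_c = NULL) {
  anc <- generate_ancestor(config)
  seed <- config$seed
  ab <- plant_variants(anc$assembly, anc$genes, spec_ab,
                       seed = seed + 1L, interval = "A>B")
  bc <- plant_variants(ab$assembly, ab$genes, spec_bc,
                       seed = seed + 2L, interval = "B>C")
  a_obs <- anc$assembly
  c_obs <- bc$assembly
  artifacts <- data.frame()
  if (!is.null(artifacts_a)) {
    ia <- inject_artifacts(anc$assembly, artifacts_a, seed = seed + 3L,
                           strain = "A")
    a_obs <- ia$assembly
    artifacts <- rbind(artifacts, ia$artifacts)
  }
  if (!is.null(artifacts_c)) {
    ic <- inject_artifacts(bc$assembly, artifacts_c, seed = seed + 4L,
                           strain = "C")
    c_obs <- ic$assembly
    artifacts <- rbind(artifacts, ic$artifacts)
  }
  list(a = anc$assembly, b = ab$assembly, c = bc$assembly,
       a_obs = a_obs, c_obs = c_obs,
       genes_a = anc$genes, genes_b = ab$genes, genes_c = bc$genes,
       truth = rbind(ab$truth, bc$truth), artifacts = artifacts,
       seeds = c(ancestor = seed, ab = seed + 1L, bc = seed + 2L,
                 art_a = seed + 3L, art_c = seed + 4L))
}

#' Write a truth set as a tab-separated table
#'
#' Columns: CHROM, POS0, REF, ALT, CLASS, INTERVAL.
#'
#' @param truth truth data.frame from [plant_variants()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_truth_table <- function(truth, path) {
  out <- data.frame(CHROM = truth$chrom, POS0 = truth$pos0,
                    REF = truth$ref, ALT = truth$alt,
                    CLASS = truth$class, INTERVAL = truth$interval,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
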