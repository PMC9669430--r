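# Fixed structural constants of the simulated loci. One transcript per locus;
# coding genes are 3-exon with a large second intron so intronic lncRNAs fit
# with >= 1 kb clearance on both sides.
SIM_EXON_WIDTHS <- c(300L, 400L, 500L)
SIM_INTRON_WIDTHS <- c(800L, 4000L)
SIM_GENE_SPAN <- sum(SIM_EXON_WIDTHS) + sum(SIM_INTRON_WIDTHS) # 6000
SIM_MRNA_LEN <- sum(SIM_EXON_WIDTHS) # 1200
SIM_CDS_LEN <- 600L
SIM_GENE_SPACING <- 8000L
SIM_FIRST_GENE_START <- 10001L
SIM_LNC_LEN <- 800L
SIM_OVERLAP_LEN <- 150L

#' Configuration for the synthetic dataset generator
#'
#' Defines the study conditions the generator emulates: a small
#' multi-chromosome genome carrying coding genes and planted lncRNA loci of
#' every positional class, an assembly with known-mRNA re-discoveries, short
#' fragments and coding contaminants, and negative-binomial counts for a
#' 3-versus-3 two-group design with planted fold changes.
#'
#' @param seed Integer seed; fully determines every output.
#' @param n_chromosomes,chrom_length Genome shape (bp per chromosome).
#' @param n_coding_genes Number of coding genes (3-exon, alternating strand).
#' @param n_lnc_intergenic,n_lnc_intronic,n_lnc_antisense,n_lnc_exonic
#'   Planted lncRNAs per positional class. The first
#'   `length(cis_distance_spec)` intergenic lncRNAs are placed at the planted
#'   gaps from a gene (concordant cis pairs); the next one, when available,
#'   is planted as a discordant cis pair; the remainder are placed far
#'   (> 100 kb) from every gene.
#' @param n_short_fragments Assembly fragments shorter than 200 nt.
#' @param n_coding_contaminants Assembly candidates carrying a 600-nt ORF.
#' @param group_sizes Integer pair, samples per group (default 3 vs 3,
#'   mirroring a three-animal two-coat-colour design).
#' @param library_sizes Optional per-sample expected totals; `NULL` keeps
#'   equal library sizes.
#' @param nb_dispersion Negative-binomial dispersion `alpha` in
#'   `var = m + alpha m^2`.
#' @param de_fraction Fraction of the not-otherwise-planted coding genes
#'   given a planted fold change.
#' @param de_log2fc Magnitude of every planted log2 fold change. The
#'   default 3 keeps planted effects unambiguous at three replicates per
#'   group so truth-recovery checks hold by construction.
#' @param n_housekeeping Number of non-DE high-abundance background genes
#'   (mean `housekeeping_mean`); they emulate the handful of dominant
#'   transcripts that carry most sequencing mass in real libraries and keep
#'   column-total (library-size) normalisation stable against the planted
#'   fold changes.
#' @param housekeeping_mean Base mean of the housekeeping background genes.
#' @param cis_distance_spec Planted lncRNA-gene gap distances in bp.
#' @param precursor_embed_count Number of differentially expressed lncRNAs
#'   carrying a verbatim embedded miRNA precursor (default 9).
#' @param precursor_length Precursor length in nt.
#' @param n_decoy_precursors Unembedded decoy sequences added to the
#'   precursor database.
#' @return A validated `lnc_sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 3,
                       chrom_length = 500000,
                       n_coding_genes = 60,
                       n_lnc_intergenic = 7,
                       n_lnc_intronic = 6,
                       n_lnc_antisense = 6,
                       n_lnc_exonic = 6,
                       n_short_fragments = 5,
                       n_coding_contaminants = 3,
                       group_sizes = c(3, 3),
                       library_sizes = NULL,
                       nb_dispersion = 0.02,
                       de_fraction = 0.15,
                       de_log2fc = 3,
                       n_housekeeping = 10,
                       housekeeping_mean = 20000,
                       cis_distance_spec = c(1000, 5000, 20000, 50000, 99999),
                       precursor_embed_count = 9,
                       precursor_length = 80,
                       n_decoy_precursors = 6) {
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_coding_genes = as.integer(n_coding_genes),
    n_lnc = c(intergenic = as.integer(n_lnc_intergenic),
              intronic = as.integer(n_lnc_intronic),
              antisense = as.integer(n_lnc_antisense),
              exonic_sense_overlap = as.integer(n_lnc_exonic)),
    n_short_fragments = as.integer(n_short_fragments),
    n_coding_contaminants = as.integer(n_coding_contaminants),
    group_sizes = as.integer(group_sizes),
    library_sizes = library_sizes,
    nb_dispersion = nb_dispersion,
    de_fraction = de_fraction,
    de_log2fc = de_log2fc,
    n_housekeeping = as.integer(n_housekeeping),
    housekeeping_mean = housekeeping_mean,
    cis_distance_spec = as.integer(cis_distance_spec),
    precursor_embed_count = as.integer(precursor_embed_count),
    precursor_length = as.integer(precursor_length),
    n_decoy_precursors = as.integer(n_decoy_precursors)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "lnc_sim_config")
}

#' @noRd
validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_chromosomes, cfg$n_coding_genes, cfg$n_lnc,
              cfg$n_short_fragments, cfg$n_coding_contaminants,
              cfg$precursor_embed_count, cfg$n_decoy_precursors)
  if (any(counts < 0)) abort("all counts must be >= 0")
  if (cfg$n_chromosomes < 1) abort("need at least one chromosome")
  if (length(cfg$group_sizes) != 2 || any(cfg$group_sizes < 1)) {
    abort("group_sizes must be two integers >= 1")
  }
  if (cfg$nb_dispersion <= 0) abort("nb_dispersion must be > 0")
  if (cfg$n_housekeeping < 0 || cfg$housekeeping_mean <= 0) {
    abort("n_housekeeping must be >= 0 and housekeeping_mean > 0")
  }
  if (cfg$n_housekeeping > cfg$n_coding_genes) {
    abort("n_housekeeping cannot exceed n_coding_genes")
  }
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) abort("de_fraction must be in [0, 1]")
  if (cfg$de_log2fc <= 0) abort("de_log2fc must be > 0")
  if (!is.null(cfg$library_sizes) &&
      length(cfg$library_sizes) != sum(cfg$group_sizes)) {
    abort("library_sizes must have one entry per sample")
  }
  n_lnc_total <- sum(cfg$n_lnc)
  if (cfg$precursor_embed_count > n_lnc_total) {
    abort("precursor_embed_count exceeds the number of planted lncRNAs")
  }
  # structural feasibility
  gpc <- gene_counts_per_chrom(cfg)
  if (length(cfg$cis_distance_spec) > 0 || cfg$n_lnc["intergenic"] > 0 ||
      cfg$n_lnc["intronic"] + cfg$n_lnc["antisense"] + cfg$n_lnc["exonic_sense_overlap"] > 0) {
    if (cfg$n_coding_genes == 0 &&
        (length(cfg$cis_distance_spec) > 0 ||
         sum(cfg$n_lnc[c("intronic", "antisense", "exonic_sense_overlap")]) > 0)) {
      abort("host-dependent lncRNAs or cis gaps require n_coding_genes > 0")
    }
  }
  n_hosts_needed <- sum(cfg$n_lnc[c("intronic", "antisense", "exonic_sense_overlap")])
  n_hosts_avail <- sum(pmax(gpc - 1L, 0L))
  if (n_hosts_needed > n_hosts_avail) {
    abort(sprintf("placement infeasible: %d host genes needed, %d available (one gene per chromosome is reserved as the cis anchor)",
                  n_hosts_needed, n_hosts_avail))
  }
  if (cfg$n_coding_genes > 0) {
    anchor_end <- SIM_FIRST_GENE_START - 1L + max(gpc) * SIM_GENE_SPAN +
      (max(gpc) - 1L) * SIM_GENE_SPACING
    right_extent <- anchor_end +
      max(c(cfg$cis_distance_spec + SIM_LNC_LEN, 0L)) + 1000L
    right_extent <- max(right_extent, anchor_end + 140000L)
    if (right_extent + 21000L > cfg$chrom_length) {
      abort(sprintf("placement infeasible: chrom_length %d too small (need >= %d)",
                    cfg$chrom_length, right_extent + 21000L))
    }
  }
  invisible(cfg)
}

#' @noRd
gene_counts_per_chrom <- function(cfg) {
  if (cfg$n_coding_genes == 0) return(rep(0L, cfg$n_chromosomes))
  chrom_of <- sort(rep_len(seq_len(cfg$n_chromosomes), cfg$n_coding_genes))
  tabulate(chrom_of, nbins = cfg$n_chromosomes)
}

# Deterministic locus plan: coordinates for every gene and planted locus.
# All randomness is deferred to sequence/count generation; the plan is a pure
# function of the configuration.
#' @noRd
sim_locus_plan <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  gpc <- gene_counts_per_chrom(cfg)
  genes <- list(); gi <- 0L
  for (ci in seq_len(cfg$n_chromosomes)) {
    pos <- SIM_FIRST_GENE_START
    for (k in seq_len(gpc[ci])) {
      gi <- gi + 1L
      genes[[gi]] <- tibble(
        gene_id = sprintf("GENE_%03d", gi), chrom = chroms[ci],
        strand = if (gi %% 2 == 1) "+" else "-",
        start = pos, end = pos + SIM_GENE_SPAN - 1L,
        local_idx = k, is_anchor = (k == gpc[ci])
      )
      pos <- pos + SIM_GENE_SPAN + SIM_GENE_SPACING
    }
  }
  genes <- if (length(genes)) bind_rows(genes) else
    tibble(gene_id = character(), chrom = character(), strand = character(),
           start = integer(), end = integer(), local_idx = integer(),
           is_anchor = logical())
  # exon coordinates per gene (genomic ascending)
  exon_off <- cumsum(c(0L, SIM_EXON_WIDTHS[1] + SIM_INTRON_WIDTHS[1],
                       SIM_EXON_WIDTHS[2] + SIM_INTRON_WIDTHS[2]))
  gene_exons <- function(g) {
    tibble(gene_id = g$gene_id, transcript_id = paste0(g$gene_id, ".t1"),
           chrom = g$chrom, strand = g$strand,
           start = g$start + exon_off, end = g$start + exon_off + SIM_EXON_WIDTHS - 1L,
           exon_number = 1:3, biotype = "coding")
  }
  exons <- if (nrow(genes)) bind_rows(lapply(seq_len(nrow(genes)),
                                             function(i) gene_exons(genes[i, ]))) else
    tibble(gene_id = character(), transcript_id = character(), chrom = character(),
           strand = character(), start = integer(), end = integer(),
           exon_number = integer(), biotype = character())

  anchors <- filter(genes, .data$is_anchor)
  hosts <- filter(genes, !.data$is_anchor)
  n_intronic <- cfg$n_lnc[["intronic"]]
  n_as <- cfg$n_lnc[["antisense"]]
  n_ex <- cfg$n_lnc[["exonic_sense_overlap"]]
  host_intronic <- hosts[seq_len(n_intronic), , drop = FALSE]
  host_as <- hosts[n_intronic + seq_len(n_as), , drop = FALSE]
  host_ex <- hosts[n_intronic + n_as + seq_len(n_ex), , drop = FALSE]

  loci <- list()
  add <- function(id, role, class, chrom, strand, start, len, host = NA_character_,
                  designed_from = 1L, designed_to = len) {
    loci[[length(loci) + 1]] <<- tibble(
      transcript_id = id, role = role, class = class, chrom = chrom,
      strand = strand, start = as.integer(start), end = as.integer(start + len - 1),
      length = as.integer(len), host_gene = host,
      designed_from = as.integer(designed_from), designed_to = as.integer(designed_to)
    )
  }

  # intronic: inside intron 2 of the host, same strand, 1.6 kb off each boundary
  for (i in seq_len(nrow(host_intronic))) {
    h <- host_intronic[i, ]
    i2s <- h$start + SIM_EXON_WIDTHS[1] + SIM_INTRON_WIDTHS[1] + SIM_EXON_WIDTHS[2]
    add(sprintf("LNC_INTRONIC_%02d", i), "lncrna", "intronic", h$chrom, h$strand,
        i2s + 1600L, SIM_LNC_LEN, h$gene_id)
  }
  # antisense: 150 bp overlap with host exon 2, rest designed in the adjacent intron
  for (i in seq_len(nrow(host_as))) {
    h <- host_as[i, ]
    e2s <- h$start + SIM_EXON_WIDTHS[1] + SIM_INTRON_WIDTHS[1]
    e2e <- e2s + SIM_EXON_WIDTHS[2] - 1L
    lnc_strand <- if (h$strand == "+") "-" else "+"
    len <- SIM_OVERLAP_LEN + 550L
    if (h$strand == "+") {
      start <- e2e - SIM_OVERLAP_LEN + 1L # [e2e-149, e2e+550], designed tx 1..550
    } else {
      start <- e2s - 550L # [e2s-550, e2s+149], lnc is +, designed tx 1..550
    }
    add(sprintf("LNC_AS_%02d", i), "lncrna", "antisense", h$chrom, lnc_strand,
        start, len, h$gene_id, designed_from = 1L, designed_to = 550L)
  }
  # exonic sense overlap: 150 bp overlap with the outermost exon, extending
  # beyond the gene span on the same strand
  for (i in seq_len(nrow(host_ex))) {
    h <- host_ex[i, ]
    len <- SIM_OVERLAP_LEN + 400L
    if (h$strand == "+") {
      start <- h$start - 400L # [e1s-400, e1s+149]
    } else {
      start <- h$end - SIM_OVERLAP_LEN + 1L # [e3e-149, e3e+400]
    }
    add(sprintf("LNC_EXONIC_%02d", i), "lncrna", "exonic_sense_overlap",
        h$chrom, h$strand, start, len, h$gene_id,
        designed_from = 1L, designed_to = 400L)
  }
  # intergenic: planted cis gaps downstream of the per-chromosome anchor gene,
  # one optional discordant pair upstream of the first anchor, remainder far
  n_cis <- length(cfg$cis_distance_spec)
  for (j in seq_len(min(n_cis, cfg$n_lnc[["intergenic"]]))) {
    a <- anchors[(j - 1L) %% nrow(anchors) + 1L, ]
    add(sprintf("LNC_CIS_%02d", j), "lncrna", "intergenic", a$chrom, "+",
        a$end + cfg$cis_distance_spec[j] + 1L, SIM_LNC_LEN, a$gene_id)
  }
  n_left <- cfg$n_lnc[["intergenic"]] - min(n_cis, cfg$n_lnc[["intergenic"]])
  has_disc <- n_left > 0 && nrow(anchors) > 0 && anchors$local_idx[1] >= 2
  if (has_disc) {
    a <- anchors[1, ]
    add("LNC_DISC_01", "lncrna", "intergenic", a$chrom, "+",
        a$start - 2000L - SIM_LNC_LEN, SIM_LNC_LEN, a$gene_id)
    n_left <- n_left - 1L
  }
  for (r in seq_len(n_left)) {
    ci <- (r - 1L) %% cfg$n_chromosomes + 1L
    add(sprintf("LNC_FAR_%02d", r), "lncrna", "intergenic", chroms[ci], "+",
        cfg$chrom_length - 20000L + (ceiling(r / cfg$n_chromosomes) - 1L) * 2000L,
        SIM_LNC_LEN)
  }
  # coding contaminants and short fragments in the free zone right of the anchors
  base_end <- if (nrow(anchors)) max(anchors$end) else SIM_FIRST_GENE_START
  for (k in seq_len(cfg$n_coding_contaminants)) {
    ci <- (k - 1L) %% cfg$n_chromosomes + 1L
    add(sprintf("CODING_CONTAM_%02d", k), "contaminant", NA_character_,
        chroms[ci], "+", base_end + 120000L + ceiling(k / cfg$n_chromosomes) * 3000L,
        860L)
  }
  for (k in seq_len(cfg$n_short_fragments)) {
    ci <- (k - 1L) %% cfg$n_chromosomes + 1L
    add(sprintf("FRAG_%02d", k), "fragment", NA_character_,
        chroms[ci], "+", base_end + 135000L + ceiling(k / cfg$n_chromosomes) * 1200L,
        0L) # fragment lengths drawn at sequence-generation time
  }
  loci <- if (length(loci)) bind_rows(loci) else
    tibble(transcript_id = character(), role = character(), class = character(),
           chrom = character(), strand = character(), start = integer(),
           end = integer(), length = integer(), host_gene = character(),
           designed_from = integer(), designed_to = integer())
  list(chroms = chroms, genes = genes, exons = exons, loci = loci,
       has_disc = has_disc)
}
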