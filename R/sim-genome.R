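# Sequence plumbing for the simulator. The genome is held as one character
# string per chromosome during construction; transcript sequences are written
# strand-aware (minus-strand transcripts are written as their reverse
# complement across ascending exons).

#' @noRd
write_segment <- function(chrom_seq, start, end, content) {
  stopifnot(nchar(content) == end - start + 1)
  paste0(substr(chrom_seq, 1, start - 1), content,
         substr(chrom_seq, end + 1, nchar(chrom_seq)))
}

#' @noRd
extract_interval <- function(chrom_seq, start, end, strand) {
  s <- substr(chrom_seq, start, end)
  if (strand == "-") revcomp(s) else s
}

#' @noRd
write_transcript_seq <- function(chrom_seq, exons, strand, tx_seq) {
  exons <- exons[order(exons$start), ]
  genomic <- if (strand == "-") revcomp(tx_seq) else tx_seq
  off <- 1L
  for (i in seq_len(nrow(exons))) {
    w <- exons$end[i] - exons$start[i] + 1L
    chrom_seq <- write_segment(chrom_seq, exons$start[i], exons$end[i],
                               substr(genomic, off, off + w - 1L))
    off <- off + w
  }
  chrom_seq
}

# Map a transcript-coordinate interval of a single-exon locus to genomic
# coordinates and write `content` (given in transcript orientation).
#' @noRd
write_tx_interval <- function(chrom_seq, locus, tx_from, tx_to, content) {
  if (locus$strand == "+") {
    g1 <- locus$start + tx_from - 1L; g2 <- locus$start + tx_to - 1L
    write_segment(chrom_seq, g1, g2, content)
  } else {
    g1 <- locus$end - tx_to + 1L; g2 <- locus$end - tx_from + 1L
    write_segment(chrom_seq, g1, g2, revcomp(content))
  }
}

#' @noRd
random_mrna <- function() {
  codon_pool <- setdiff(apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES),
                              1, paste, collapse = ""), STOP_CODONS)
  n_codons <- SIM_CDS_LEN / 3L - 2L # minus start and stop
  cds <- paste0("ATG", paste(sample(codon_pool, n_codons, replace = TRUE),
                             collapse = ""), "TAA")
  utr5 <- scrub_motif(random_dna(50L))
  utr3 <- scrub_motif(random_dna(SIM_MRNA_LEN - 50L - SIM_CDS_LEN))
  paste0(utr5, cds, utr3)
}

#' Simulate the reference genome and annotation
#'
#' Builds a deterministic multi-chromosome genome: random A/C/G/T background,
#' coding genes with designed mRNAs (a 600-nt ORF each), and planted lncRNA
#' loci of every positional class. lncRNA bodies are generated ATG-free
#' (motif-scrubbed random sequence) and each locus is re-drawn, bounded and
#' seeded, until its assembled transcript scores noncoding, so planted labels
#' hold exactly. miRNA precursors are embedded verbatim in the designated
#' differentially expressed lncRNAs.
#'
#' @param config An [sim_config()] object.
#' @return A list: `annotation` (exon tibble of the coding genes), `genome`
#'   (named character vector of chromosome sequences), `truth` (planted
#'   ground truth: `loci`, `class_labels`, `de_features`, `expression`,
#'   `cis_pairs`, `precursors`, `precursor_db`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "lnc_sim_config"))
  plan <- sim_locus_plan(config)
  withr::with_seed(config$seed, {
    genome <- setNames(vapply(plan$chroms, function(ch) random_dna(config$chrom_length),
                              character(1)), plan$chroms)

    # fragment lengths (drawn here; the plan leaves them open)
    frag <- plan$loci$role == "fragment"
    if (any(frag)) {
      flen <- sample(100:199, sum(frag), replace = TRUE)
      plan$loci$length[frag] <- flen
      plan$loci$end[frag] <- plan$loci$start[frag] + flen - 1L
      plan$loci$designed_to[frag] <- flen
    }
    if (nrow(plan$loci) && (any(plan$loci$start < 1) ||
                            any(plan$loci$end > config$chrom_length))) {
      abort("placement infeasible: a planted locus falls outside its chromosome")
    }

    # write coding genes
    for (g in unique(plan$exons$gene_id)) {
      ex <- plan$exons[plan$exons$gene_id == g, ]
      genome[[ex$chrom[1]]] <- write_transcript_seq(genome[[ex$chrom[1]]], ex,
                                                    ex$strand[1], random_mrna())
    }

    # differential-expression plan
    lnc_loci <- filter(plan$loci, .data$role == "lncrna")
    n_cis <- sum(startsWith(lnc_loci$transcript_id, "LNC_CIS_"))
    de_order <- c(
      sort(lnc_loci$transcript_id[startsWith(lnc_loci$transcript_id, "LNC_CIS_")]),
      lnc_loci$transcript_id[lnc_loci$transcript_id == "LNC_DISC_01"],
      sort(lnc_loci$transcript_id[startsWith(lnc_loci$transcript_id, "LNC_INTRONIC_")]),
      sort(lnc_loci$transcript_id[startsWith(lnc_loci$transcript_id, "LNC_AS_")]),
      sort(lnc_loci$transcript_id[startsWith(lnc_loci$transcript_id, "LNC_EXONIC_")]),
      sort(lnc_loci$transcript_id[startsWith(lnc_loci$transcript_id, "LNC_FAR_")])
    )
    n_de_lnc <- min(length(de_order),
                    max(config$precursor_embed_count,
                        n_cis + as.integer(plan$has_disc)))
    de_lnc <- de_order[seq_len(n_de_lnc)]
    lnc_dir <- setNames(sample(c("up", "down"), n_de_lnc, replace = TRUE), de_lnc)

    # One direction per anchor gene; every concordant cis lncRNA inherits its
    # anchor's direction (several lncRNAs may share one anchor gene), the
    # discordant one takes the opposite.
    planted_ids <- de_lnc[startsWith(de_lnc, "LNC_CIS_") | de_lnc == "LNC_DISC_01"]
    anchor_of <- setNames(lnc_loci$host_gene[match(planted_ids, lnc_loci$transcript_id)],
                          planted_ids)
    gene_dir <- setNames(sample(c("up", "down"), length(unique(anchor_of)),
                                replace = TRUE), unique(anchor_of))
    cis_rows <- list()
    for (id in planted_ids) {
      g <- anchor_of[[id]]
      conc <- id != "LNC_DISC_01"
      lnc_dir[[id]] <- if (conc) gene_dir[[g]] else
        setdiff(c("up", "down"), gene_dir[[g]])
      gap <- if (conc) config$cis_distance_spec[as.integer(sub("LNC_CIS_", "", id))]
             else 2000L
      cis_rows[[id]] <- tibble(lncrna_id = id, gene_id = g, gap_bp = as.integer(gap),
                               lnc_direction = lnc_dir[[id]],
                               gene_direction = gene_dir[[g]], concordant = conc)
    }
    other_genes <- setdiff(plan$genes$gene_id, names(gene_dir))
    n_extra <- round(config$de_fraction * length(other_genes))
    extra <- sample(other_genes, n_extra)
    gene_dir[extra] <- sample(c("up", "down"), n_extra, replace = TRUE)

    # precursor hosts: the first `precursor_embed_count` DE lncRNAs
    hosts <- de_lnc[seq_len(min(config$precursor_embed_count, n_de_lnc))]

    # lncRNA bodies: ATG-free designed sequence (+ optional embedded
    # precursor), re-drawn until the assembled transcript scores noncoding
    precursor_rows <- list()
    for (i in which(plan$loci$role == "lncrna")) {
      loc <- plan$loci[i, ]
      W <- loc$designed_to - loc$designed_from + 1L
      is_host <- loc$transcript_id %in% hosts
      ok <- FALSE
      for (try in 1:30) {
        des <- scrub_motif(random_dna(W))
        if (is_host) {
          pre <- random_dna(config$precursor_length)
          rel <- 101L
          des <- paste0(substr(des, 1, rel - 1L), pre,
                        substr(des, rel + config$precursor_length, W))
        }
        genome[[loc$chrom]] <- write_tx_interval(genome[[loc$chrom]], loc,
                                                 loc$designed_from, loc$designed_to, des)
        tx <- extract_interval(genome[[loc$chrom]], loc$start, loc$end, loc$strand)
        if (coding_potential(setNames(tx, loc$transcript_id))$label == "noncoding") {
          ok <- TRUE
          if (is_host) {
            ts <- loc$designed_from + rel - 1L
            precursor_rows[[loc$transcript_id]] <- tibble(
              lncrna_id = loc$transcript_id,
              precursor_id = sprintf("PRE_%02d", match(loc$transcript_id, hosts)),
              tx_start = ts, tx_end = ts + config$precursor_length - 1L, seq = pre
            )
          }
          break
        }
      }
      if (!ok) abort(sprintf("could not draw a noncoding sequence for %s",
                             loc$transcript_id))
    }

    # contaminants: 50 nt scrubbed leader, 600-nt ORF, scrubbed tail
    for (i in which(plan$loci$role == "contaminant")) {
      loc <- plan$loci[i, ]
      codon_pool <- setdiff(apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES),
                                  1, paste, collapse = ""), STOP_CODONS)
      orf <- paste0("ATG", paste(sample(codon_pool, 198, replace = TRUE),
                                 collapse = ""), "TAA")
      seqc <- paste0(scrub_motif(random_dna(50L)), orf,
                     scrub_motif(random_dna(loc$length - 50L - 600L)))
      genome[[loc$chrom]] <- write_tx_interval(genome[[loc$chrom]], loc,
                                               1L, loc$length, seqc)
    }

    # base expression means: planted-DE features high and well-separated,
    # background log-normal around 100
    lnc_order <- sort(lnc_loci$transcript_id)
    features <- bind_rows(
      tibble(feature_id = plan$genes$gene_id, kind = "mRNA",
             length = SIM_MRNA_LEN),
      tibble(feature_id = lnc_order, kind = "lncRNA",
             length = plan$loci$length[match(lnc_order, plan$loci$transcript_id)])
    )
    dir_all <- c(gene_dir, lnc_dir)
    features$direction <- ifelse(features$feature_id %in% names(dir_all),
                                 dir_all[features$feature_id], "ns")
    is_de <- features$direction != "ns"
    # non-DE housekeeping genes dominate library mass so that column-total
    # normalisation stays stable against the planted fold changes
    hk_pool <- features$feature_id[features$kind == "mRNA" & !is_de]
    hk <- features$feature_id %in% hk_pool[seq_len(min(config$n_housekeeping,
                                                       length(hk_pool)))]
    features$base_mean <- NA_real_
    # the drawn mean is the LOW expression state of a planted feature: up
    # features start there, down features start at the scaled-up state, so
    # both states stay clear of the counting-noise floor
    m_low <- runif(sum(is_de), 200, 600)
    features$base_mean[is_de] <- ifelse(features$direction[is_de] == "up",
                                        m_low, m_low * 2^config$de_log2fc)
    features$base_mean[hk] <- config$housekeeping_mean * runif(sum(hk), 0.8, 1.2)
    rest <- !is_de & !hk
    features$base_mean[rest] <- rlnorm(sum(rest), meanlog = log(150), sdlog = 0.7)
    features$log2fc <- ifelse(features$direction == "up", config$de_log2fc,
                              ifelse(features$direction == "down", -config$de_log2fc, 0))

    # precursor database: embedded precursors + shuffled decoys
    precursors <- bind_rows(precursor_rows)
    decoys <- if (config$n_decoy_precursors > 0) {
      tibble(precursor_id = sprintf("DECOY_%02d", seq_len(config$n_decoy_precursors)),
             seq = vapply(seq_len(config$n_decoy_precursors),
                          function(i) random_dna(config$precursor_length), character(1)),
             lncrna_id = NA_character_)
    } else tibble(precursor_id = character(), seq = character(), lncrna_id = character())
    precursor_db <- bind_rows(
      if (nrow(precursors)) select(precursors, "precursor_id", "seq", "lncrna_id")
      else tibble(precursor_id = character(), seq = character(), lncrna_id = character()),
      decoys
    )

    truth <- list(
      loci = select(plan$loci, -"designed_from", -"designed_to"),
      class_labels = lnc_loci %>%
        select(transcript_id = "transcript_id", class = "class"),
      de_features = features %>% filter(.data$direction != "ns") %>%
        select("feature_id", "kind", "direction", "log2fc"),
      expression = select(features, "feature_id", "kind", "length",
                          "base_mean", "direction", "log2fc"),
      cis_pairs = if (length(cis_rows)) bind_rows(cis_rows) else
        tibble(lncrna_id = character(), gene_id = character(), gap_bp = integer(),
               lnc_direction = character(), gene_direction = character(),
               concordant = logical()),
      precursors = if (nrow(precursors)) precursors else
        tibble(lncrna_id = character(), precursor_id = character(),
               tx_start = integer(), tx_end = integer(), seq = character()),
      precursor_db = precursor_db
    )
    list(annotation = plan$exons, genome = genome, truth = truth)
  })
}

#' Simulate the transcript assembly
#'
#' Emits the candidate set a transcript assembler would produce on this
#' genome: exact re-discoveries of every known mRNA, sub-200-nt fragments,
#' coding contaminants, and the true lncRNAs of each positional class, with
#' their sequences extracted from the genome (embedded precursors included
#' verbatim).
#'
#' @param annotation,genome,truth Outputs of [simulate_genome()].
#' @param config The same [sim_config()] object.
#' @return A list: `candidates` (exon tibble) and `seqs` (named character
#'   vector of candidate transcript sequences).
#' @export
simulate_assembly <- function(annotation, genome, truth, config) {
  known <- annotation %>%
    mutate(transcript_id = paste0("CAND_", .data$gene_id)) %>%
    select("transcript_id", "gene_id", "chrom", "strand", "start", "end",
           "exon_number")
  loci <- truth$loci %>%
    arrange(factor(.data$role, levels = c("contaminant", "fragment", "lncrna")),
            .data$transcript_id)
  single <- loci %>%
    mutate(gene_id = NA_character_, exon_number = 1L) %>%
    select("transcript_id", "gene_id", "chrom", "strand", "start", "end",
           "exon_number")
  candidates <- bind_rows(known, single)
  spans <- transcript_spans(candidates)
  seqs <- setNames(vapply(seq_len(nrow(spans)), function(i) {
    ex <- candidates[candidates$transcript_id == spans$transcript_id[i], ]
    ex <- ex[order(ex$start), ]
    parts <- vapply(seq_len(nrow(ex)), function(k) {
      substr(genome[[ex$chrom[1]]], ex$start[k], ex$end[k])
    }, character(1))
    s <- paste(parts, collapse = "")
    if (ex$strand[1] == "-") revcomp(s) else s
  }, character(1)), spans$transcript_id)
  list(candidates = candidates, seqs = seqs)
}

#' Simulate negative-binomial counts with planted fold changes
#'
#' Counts are drawn NB(mean, dispersion) per feature and sample, with
#' variance `m + alpha m^2`. Features planted as differentially expressed
#' have their group-2 mean scaled by `2^(+-de_log2fc)`.
#'
#' @param features Tibble (`feature_id`, `length`, `base_mean`, `log2fc`);
#'   defaults to `truth$expression`.
#' @param truth Truth list from [simulate_genome()] (used for defaults).
#' @param config The [sim_config()] object.
#' @return A list: `counts` (tibble, `feature_id` + one column per sample),
#'   `groups` (tibble `sample`, `group`; group 1 = `white`, group 2 =
#'   `brown`), `lengths` (tibble `feature_id`, `length`).
#' @export
simulate_counts <- function(features = NULL, truth = NULL, config) {
  stopifnot(inherits(config, "lnc_sim_config"))
  if (config$nb_dispersion <= 0) abort("nb_dispersion must be > 0")
  if (is.null(features)) features <- truth$expression
  n1 <- config$group_sizes[1]; n2 <- config$group_sizes[2]
  samples <- c(paste0("white_", seq_len(n1)), paste0("brown_", seq_len(n2)))
  groups <- tibble(sample = samples, group = rep(c("white", "brown"), c(n1, n2)))
  libf <- if (is.null(config$library_sizes)) rep(1, n1 + n2) else
    config$library_sizes / mean(config$library_sizes)
  withr::with_seed(stage_seed(config$seed, 1L), {
    mu1 <- features$base_mean
    mu2 <- features$base_mean * 2^features$log2fc
    mu <- cbind(matrix(mu1, nrow = length(mu1), ncol = n1),
                matrix(mu2, nrow = length(mu2), ncol = n2))
    mu <- sweep(mu, 2, libf, "*")
    cnt <- matrix(rnbinom(length(mu), mu = as.numeric(mu),
                          size = 1 / config$nb_dispersion),
                  nrow = nrow(mu), ncol = ncol(mu))
    colnames(cnt) <- samples
    counts <- dplyr::bind_cols(tibble(feature_id = features$feature_id),
                               as_tibble(cnt))
    list(counts = counts, groups = groups,
         lengths = select(features, "feature_id", "length"))
  })
}

#' Simulate a gene-set (GMT) annotation with one planted enriched term
#'
#' @param truth Truth list from [simulate_genome()].
#' @param config The [sim_config()] object.
#' @return A gene-set tibble (`term_id`, `name`, `genes` list column); the
#'   first term collects most planted differentially expressed genes and is
#'   recorded as `attr(, "planted_term")`.
#' @export
simulate_gene_sets <- function(truth, config) {
  gene_ids <- unique(truth$expression$feature_id[truth$expression$kind == "mRNA"])
  de_genes <- intersect(truth$de_features$feature_id, gene_ids)
  if (length(gene_ids) == 0) {
    return(structure(tibble(term_id = character(), name = character(),
                            genes = list()), planted_term = NA_character_))
  }
  withr::with_seed(stage_seed(config$seed, 2L), {
    n_in <- max(1L, floor(0.8 * length(de_genes)))
    planted <- unique(c(sample(de_genes, n_in),
                        sample(setdiff(gene_ids, de_genes),
                               min(2L, length(setdiff(gene_ids, de_genes))))))
    others <- lapply(1:7, function(i) sample(gene_ids, min(8L, length(gene_ids))))
    terms <- tibble(
      term_id = sprintf("TERM_%02d", 1:8),
      name = c("planted pigmentation pathway", sprintf("random pathway %d", 2:8)),
      genes = c(list(planted), others)
    )
    attr(terms, "planted_term") <- "TERM_01"
    terms
  })
}

#' Simulate the complete bundled dataset
#'
#' Runs [simulate_genome()], [simulate_assembly()], [simulate_counts()] and
#' [simulate_gene_sets()] under the configuration's seed and, optionally,
#' writes every input file of the pipeline (GTF annotation and assembly,
#' FASTA genome/transcripts/precursors, count and group TSVs, GMT gene sets,
#' and the planted-truth tables).
#'
#' @param config An [sim_config()] object.
#' @param dir Optional output directory; created if needed.
#' @return A list with components `config`, `annotation`, `genome`, `truth`,
#'   `candidates`, `seqs`, `counts`, `groups`, `lengths`, `gene_sets`, and
#'   (when `dir` is given) `files`, a named vector of written paths.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  gen <- simulate_genome(config)
  asm <- simulate_assembly(gen$annotation, gen$genome, gen$truth, config)
  cnt <- simulate_counts(truth = gen$truth, config = config)
  gs <- simulate_gene_sets(gen$truth, config)
  out <- list(config = config, annotation = gen$annotation, genome = gen$genome,
              truth = gen$truth, candidates = asm$candidates, seqs = asm$seqs,
              counts = cnt$counts, groups = cnt$groups, lengths = cnt$lengths,
              gene_sets = gs)
  if (!is.null(dir)) out$files <- write_sim_dataset(out, dir)
  out
}
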