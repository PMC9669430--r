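small_cfg <- function(seed = 5, ...) {
  sim_config(seed = seed, n_coding_genes = 12, n_lnc_intergenic = 3,
             n_lnc_intronic = 2, n_lnc_antisense = 2, n_lnc_exonic = 2,
             n_short_fragments = 3, n_coding_contaminants = 1,
             cis_distance_spec = c(1000, 50000), precursor_embed_count = 3,
             n_housekeeping = 4, ...)
}

test_that("the generator is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- simulate_dataset(small_cfg(), dir = d1)$files
  f2 <- simulate_dataset(small_cfg(), dir = d2)$files
  for (nm in names(f1)) {
    expect_equal(unname(tools::md5sum(f1[[nm]])), unname(tools::md5sum(f2[[nm]])),
                 label = nm)
  }
  # and a different seed changes the data
  f3 <- simulate_dataset(small_cfg(seed = 6), dir = withr::local_tempdir())$files
  expect_false(tools::md5sum(f1[["genome_fa"]]) == tools::md5sum(f3[["genome_fa"]]))
})

test_that("an empty-annotation config emits zero gene records", {
  cfg <- sim_config(n_coding_genes = 0, n_lnc_intergenic = 0, n_lnc_intronic = 0,
                    n_lnc_antisense = 0, n_lnc_exonic = 0,
                    cis_distance_spec = integer(0), precursor_embed_count = 0,
                    n_housekeeping = 0, n_short_fragments = 2,
                    n_coding_contaminants = 1)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds$annotation), 0)
  expect_equal(length(unique(ds$candidates$transcript_id)), 3)
})

test_that("infeasible placements raise sizing errors", {
  expect_error(sim_config(chrom_length = 50000), "infeasible")
  expect_error(sim_config(n_coding_genes = 3, n_lnc_intronic = 6,
                          n_housekeeping = 0),
               "infeasible|host")
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
})

test_that("planted cis gaps are reproduced exactly by the emitted GTFs", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(small_cfg(), dir = dir)
  # independent re-parse of the emitted files
  ref <- read_gtf(file.path(dir, "reference.gtf"))
  asm <- read_gtf(file.path(dir, "assembly.gtf"))
  gene_spans <- transcript_spans(ref)
  lnc_spans <- transcript_spans(asm)
  for (i in seq_len(nrow(ds$truth$cis_pairs))) {
    pr <- ds$truth$cis_pairs[i, ]
    g <- gene_spans[gene_spans$gene_id == pr$gene_id, ]
    l <- lnc_spans[lnc_spans$transcript_id == pr$lncrna_id, ]
    gap <- max(l$start - g$end - 1, g$start - l$end - 1, 0)
    expect_equal(gap, pr$gap_bp, label = pr$lncrna_id)
  }
  # the 50,000 bp plant is present and exact
  expect_true(50000 %in% ds$truth$cis_pairs$gap_bp)
})

test_that("assembly composition matches the configuration by construction", {
  ds <- simulate_dataset(small_cfg())
  spans <- transcript_spans(ds$candidates)
  expect_equal(sum(spans$length < 200), 3) # n_short_fragments
  expect_equal(sum(grepl("^CODING_CONTAM", spans$transcript_id)), 1)
  expect_equal(sum(grepl("^CAND_GENE", spans$transcript_id)), 12)
  # intronic lncRNAs sit strictly inside one intron of the host, same strand
  loci <- ds$truth$loci
  intr <- loci[!is.na(loci$class) & loci$class == "intronic", ]
  for (i in seq_len(nrow(intr))) {
    host_ex <- ds$annotation[ds$annotation$gene_id == intr$host_gene[i], ]
    host_ex <- host_ex[order(host_ex$start), ]
    istart <- host_ex$end[-nrow(host_ex)] + 1
    iend <- host_ex$start[-1] - 1
    expect_true(any(istart <= intr$start[i] & intr$end[i] <= iend))
    expect_equal(intr$strand[i], host_ex$strand[1])
  }
})

test_that("embedded precursors are exact substrings of their host transcripts", {
  ds <- simulate_dataset(small_cfg())
  expect_equal(nrow(ds$truth$precursors), 3)
  for (i in seq_len(nrow(ds$truth$precursors))) {
    pr <- ds$truth$precursors[i, ]
    host_seq <- ds$seqs[[pr$lncrna_id]]
    expect_equal(nchar(pr$seq), 80)
    # found at the recorded transcript offset...
    expect_equal(substr(host_seq, pr$tx_start, pr$tx_end), pr$seq)
    # ...and by plain substring search on the emitted sequence
    expect_true(grepl(pr$seq, host_seq, fixed = TRUE))
  }
})

test_that("simulated counts match NB moments", {
  # one feature, mean 100, dispersion 0.1, 10,000 draws
  cfg <- sim_config(seed = 8, nb_dispersion = 0.1, group_sizes = c(5000, 5000))
  feats <- tibble::tibble(feature_id = "f", length = 1000,
                          base_mean = 100, log2fc = 0)
  cnt <- simulate_counts(feats, config = cfg)
  x <- as.numeric(cnt$counts[1, -1])
  expect_equal(length(x), 10000)
  se <- sqrt((100 + 0.1 * 100^2) / 10000)
  expect_lt(abs(mean(x) - 100), 3 * se)
  expect_equal(var(x), 100 + 0.1 * 100^2, tolerance = 0.1)
})

test_that("planted log2FC scales the group-2 mean", {
  # log2FC +2 at mean 200 -> group-2 mean ~ 800
  cfg <- sim_config(seed = 9, nb_dispersion = 0.05, group_sizes = c(2000, 2000))
  feats <- tibble::tibble(feature_id = "f", length = 1000,
                          base_mean = 200, log2fc = 2)
  cnt <- simulate_counts(feats, config = cfg)
  g <- cnt$groups
  x2 <- as.numeric(cnt$counts[1, g$sample[g$group == "brown"]])
  x1 <- as.numeric(cnt$counts[1, g$sample[g$group == "white"]])
  expect_equal(mean(x1), 200, tolerance = 0.05)
  expect_equal(mean(x2), 800, tolerance = 0.05)
})

test_that("null counts center group log-ratios on zero", {
  cfg <- sim_config(seed = 10, group_sizes = c(50, 50))
  feats <- tibble::tibble(feature_id = paste0("f", 1:200), length = 1000,
                          base_mean = 500, log2fc = 0)
  cnt <- simulate_counts(feats, config = cfg)
  g <- cnt$groups
  m1 <- rowMeans(cnt$counts[, g$sample[g$group == "white"]])
  m2 <- rowMeans(cnt$counts[, g$sample[g$group == "brown"]])
  expect_lt(abs(mean(log2(m2 / m1))), 0.02)
})

test_that("planted truth is verifiable from the emitted files alone", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(small_cfg(), dir = dir)
  # every planted id exists in the emitted assembly
  asm <- read_gtf(file.path(dir, "assembly.gtf"))
  expect_true(all(ds$truth$class_labels$transcript_id %in% asm$transcript_id))
  expect_true(all(ds$truth$loci$transcript_id %in% asm$transcript_id))
  # DE feature ids exist in the emitted count matrix
  counts <- readr::read_tsv(file.path(dir, "counts.tsv"), show_col_types = FALSE)
  expect_true(all(ds$truth$de_features$feature_id %in% counts$feature_id))
  # precursor fasta round-trips the embedded sequences
  db <- Biostrings::readDNAStringSet(file.path(dir, "precursors.fa"))
  expect_true(all(ds$truth$precursors$seq %in% as.character(db)))
})
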