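# A tiny hand-built reference: one 2-exon coding transcript on chr1:+
ref_exons <- tibble::tibble(
  transcript_id = "REF.t1", gene_id = "REFG", chrom = "chr1", strand = "+",
  start = c(100, 700), end = c(400, 1000), exon_number = 1:2, biotype = "coding"
)

test_that("filter_candidates applies the strict <200 nt rule", {
  cand <- tibble::tibble(
    transcript_id = c("t199", "t200"),
    chrom = "chr1", strand = "+",
    start = c(5000, 8000), end = c(5000 + 198, 8000 + 199)
  )
  res <- filter_candidates(cand, ref_exons)
  expect_equal(res$reason[res$transcript_id == "t199"], "short")
  expect_false(res$retained[res$transcript_id == "t199"])
  expect_true(res$retained[res$transcript_id == "t200"])
})

test_that("known-mRNA candidates are removed by intron-chain equality", {
  cand <- tibble::tibble(
    transcript_id = rep(c("copy", "shifted_ends", "diff_junction"), each = 2),
    chrom = "chr1", strand = "+",
    start = c(100, 700,   50, 700,   100, 750),
    end = c(400, 1000,  400, 1100,  400, 1000)
  )
  res <- filter_candidates(cand, ref_exons)
  expect_equal(res$reason[res$transcript_id == "copy"], "known_mrna")
  # same intron chain with different terminal ends is still a re-discovery
  expect_equal(res$reason[res$transcript_id == "shifted_ends"], "known_mrna")
  # a different junction is novel
  expect_true(res$retained[res$transcript_id == "diff_junction"])
})

test_that("single-exon known matching requires exact interval equality", {
  ref1 <- tibble::tibble(transcript_id = "SE.t1", gene_id = "SEG", chrom = "chr1",
                         strand = "+", start = 100, end = 900, exon_number = 1,
                         biotype = "coding")
  cand <- tibble::tibble(transcript_id = c("exact", "off_by_one"),
                         chrom = "chr1", strand = "+",
                         start = c(100, 101), end = c(900, 900))
  res <- filter_candidates(cand, ref1)
  expect_equal(res$reason[res$transcript_id == "exact"], "known_mrna")
  expect_true(res$retained[res$transcript_id == "off_by_one"])
})

test_that("unknown chromosomes warn and are retained with a flag", {
  cand <- tibble::tibble(transcript_id = "tX", chrom = "chrX", strand = "+",
                         start = 1, end = 500)
  expect_warning(res <- filter_candidates(cand, ref_exons), "chrX|absent")
  expect_true(res$retained)
  expect_equal(res$flag, "unknown_chrom")
})

test_that("every candidate is retained or carries exactly one reason", {
  ds <- default_sim()
  res <- filter_candidates(ds$candidates, ds$annotation)
  expect_equal(nrow(res), length(unique(ds$candidates$transcript_id)))
  expect_true(all(res$retained == is.na(res$reason)))
  # survivor order preserved
  expect_equal(res$transcript_id, unique(ds$candidates$transcript_id))
})

test_that("classification follows the fixed precedence", {
  # host: 2-exon gene with intron 401..699
  t_intronic <- tibble::tibble(transcript_id = "ti", chrom = "chr1", strand = "+",
                               start = 450, end = 650)
  t_anti <- tibble::tibble(transcript_id = "ta", chrom = "chr1", strand = "-",
                           start = 350, end = 600)
  t_exonic <- tibble::tibble(transcript_id = "te", chrom = "chr1", strand = "+",
                             start = 350, end = 600)
  t_inter <- tibble::tibble(transcript_id = "tg", chrom = "chr1", strand = "+",
                            start = 5000, end = 5600)
  all4 <- dplyr::bind_rows(t_intronic, t_anti, t_exonic, t_inter)
  cls <- classify_lncrna(all4, ref_exons)
  got <- setNames(cls$class, cls$transcript_id)
  expect_equal(got[["ti"]], "intronic")
  expect_equal(got[["ta"]], "antisense")
  expect_equal(got[["te"]], "exonic_sense_overlap")
  expect_equal(got[["tg"]], "intergenic")
  # total and exclusive: one class per transcript
  expect_equal(nrow(cls), 4)
  expect_true(all(cls$class %in% c("exonic_sense_overlap", "antisense",
                                   "intronic", "intergenic")))
})

test_that("discovery recovers all planted truth on the simulated assembly", {
  an <- default_analysis()
  ds <- an$ds; disc <- an$disc
  truth_cls <- ds$truth$class_labels
  got <- disc$lncrnas[, c("transcript_id", "class")]
  m <- dplyr::inner_join(truth_cls, got, by = "transcript_id",
                         suffix = c("_truth", "_got"))
  expect_equal(nrow(m), nrow(truth_cls)) # every planted lncRNA identified
  expect_equal(m$class_got, m$class_truth) # all classes exact
  # contaminants coding, planted lncRNAs noncoding
  sc <- disc$scores
  expect_true(all(sc$label[grepl("^CODING_CONTAM", sc$id)] == "coding"))
  expect_true(all(sc$label[sc$id %in% truth_cls$transcript_id] == "noncoding"))
})

test_that("class counts and transcript summaries aggregate correctly", {
  cls <- tibble::tibble(transcript_id = c("a", "b", "c"),
                        class = c("intronic", "intronic", "intergenic"))
  ct <- class_count_table(cls)
  expect_equal(ct$n[ct$class == "intronic"], 2)
  expect_equal(sum(ct$n), 3)
  expect_equal(sum(ct$fraction), 1)
  ex <- dplyr::bind_rows(ref_exons,
                         tibble::tibble(transcript_id = "L1", gene_id = NA,
                                        chrom = "chr1", strand = "+",
                                        start = 2000, end = 2800,
                                        exon_number = 1, biotype = NA))
  ex$kind <- ifelse(ex$transcript_id == "L1", "lncRNA", "mRNA")
  ts <- transcript_summary_table(ex)
  expect_equal(ts$exon_counts$n_exons[ts$exon_counts$kind == "lncRNA"], 1)
  expect_equal(ts$lengths$length[ts$lengths$kind == "lncRNA"], 801)
})
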