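test_that("cis gaps follow closed-interval arithmetic with a strict window", {
  lnc <- tibble::tibble(lncrna_id = "L1", chrom = "chr1", strand = "+",
                        start = 1000, end = 2000)
  mk_gene <- function(s, e) tibble::tibble(gene_id = "G1", transcript_id = "G1.t",
                                           chrom = "chr1", strand = "+",
                                           start = s, end = e, biotype = "coding")
  # gene at [50,000, 60,000]: gap = 50,000 - 2,000 - 1 = 47,999 -> pair
  p <- predict_cis_targets(lnc, mk_gene(50000, 60000))
  expect_equal(p$gap_bp, 47999)
  expect_equal(p$relation, "upstream")
  # gap exactly the window -> no pair (gene starts at end + window + 1)
  expect_equal(nrow(predict_cis_targets(lnc, mk_gene(102001, 110000))), 0)
  # gap window - 1 -> pair
  p2 <- predict_cis_targets(lnc, mk_gene(102000, 110000))
  expect_equal(p2$gap_bp, 99999)
  # overlap -> gap 0, relation overlap
  p3 <- predict_cis_targets(lnc, mk_gene(1500, 2500))
  expect_equal(p3$gap_bp, 0)
  expect_equal(p3$relation, "overlap")
})

test_that("relation is reported in the gene's own orientation", {
  lnc <- tibble::tibble(lncrna_id = "L1", chrom = "chr1", strand = "+",
                        start = 1000, end = 2000)
  minus_gene <- tibble::tibble(gene_id = "G1", transcript_id = "G1.t",
                               chrom = "chr1", strand = "-",
                               start = 50000, end = 60000, biotype = "coding")
  # lncRNA genomically left of a minus-strand gene = downstream of it
  expect_equal(predict_cis_targets(lnc, minus_gene)$relation, "downstream")
})

test_that("predict_cis_targets equals brute force on random loci", {
  withr::with_seed(31, {
    lnc <- tibble::tibble(
      lncrna_id = paste0("L", 1:40),
      chrom = sample(c("chr1", "chr2"), 40, replace = TRUE), strand = "+",
      start = sample.int(4e5, 40))
    lnc$end <- lnc$start + sample(200:2000, 40, replace = TRUE)
    genes <- tibble::tibble(
      gene_id = paste0("G", 1:15),
      transcript_id = paste0("G", 1:15, ".t"),
      chrom = sample(c("chr1", "chr2"), 15, replace = TRUE),
      strand = sample(c("+", "-"), 15, replace = TRUE),
      start = sample.int(4e5, 15), biotype = "coding")
    genes$end <- genes$start + sample(2000:8000, 15, replace = TRUE)
  })
  got <- predict_cis_targets(lnc, genes, window = 100000)
  want <- cis_oracle(lnc, genes, window = 100000)
  key <- function(d) paste(d$lncrna_id, d$gene_id, d$gap_bp)
  expect_setequal(key(got), key(want))
  expect_gte(nrow(got), 500 / 10) # the random layout yields a busy pair set
})

test_that("local_align scores canonical cases and validates input", {
  expect_equal(local_align("ACGT", "ACGT")$score, 8)
  a <- local_align("ACGT", "TTTT")
  expect_equal(a$score, 2) # best single match
  expect_equal(a$identity, 1)
  expect_error(local_align("ACGT", "ACNT"), "outside")
  # empty alignment fields when nothing scores positive is impossible here
  # (any shared base scores), so use disjoint alphabets via mismatch-only
  z <- local_align("AAAA", "CCCC")
  expect_equal(z$score, 0)
  expect_equal(z$coverage, 0)
})

test_that("local_align equals the exhaustive-recursion oracle on random pairs", {
  withr::with_seed(32, {
    for (i in 1:200) {
      n <- sample(5:30, 1); m <- sample(5:30, 1)
      q <- random_seq(n); s <- random_seq(m)
      expect_equal(local_align(q, s)$score, sw_oracle_score(q, s))
    }
    # a handful of longer 50-nt pairs
    for (i in 1:10) {
      q <- random_seq(50); s <- random_seq(50)
      expect_equal(local_align(q, s)$score, sw_oracle_score(q, s))
    }
  })
})

test_that("alignment score is symmetric under query/subject exchange", {
  withr::with_seed(33, {
    for (i in 1:50) {
      q <- random_seq(sample(10:40, 1)); s <- random_seq(sample(10:40, 1))
      expect_equal(local_align(q, s)$score, local_align(s, q)$score)
    }
  })
})

test_that("local_align agrees with Biostrings on scores", {
  withr::with_seed(34, {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                    baseOnly = TRUE)
    for (i in 1:25) {
      q <- random_seq(40); s <- random_seq(40)
      ref <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                           substitutionMatrix = mat,
                                           gapOpening = 0, gapExtension = 2)
      expect_equal(local_align(q, s)$score, Biostrings::score(ref))
    }
  })
})

test_that("precursor_scan finds verbatim embeddings and rejects decoys", {
  withr::with_seed(35, {
    pre <- random_seq(80)
    host <- paste0(random_seq(200), pre, random_seq(300))
    other <- random_seq(600)
  })
  db <- c(P1 = pre, DECOY = local({withr::with_seed(36, random_seq(80))}))
  res <- precursor_scan(c(H = host, O = other), db)
  expect_equal(res$n_dels_with_hit, 1)
  expect_equal(res$hits$del_id, "H")
  expect_equal(res$hits$precursor_id, "P1")
  expect_equal(res$hits$identity, 1)
  expect_equal(res$hits$coverage, 1)
  # shuffled database: zero hits
  shuffled <- vapply(db, function(s) paste(sample(strsplit(s, "")[[1]]),
                                           collapse = ""), character(1))
  res2 <- withr::with_seed(37, precursor_scan(c(H = host), shuffled))
  expect_equal(res2$n_dels_with_hit, 0)
  # empty database: empty result with notice
  expect_message(res3 <- precursor_scan(c(H = host), character(0)), "empty")
  expect_equal(nrow(res3$hits), 0)
})

test_that("core network joins cis pairs with DE directions", {
  cis <- tibble::tibble(lncrna_id = c("L1", "L2", "L3"),
                        gene_id = c("G1", "G2", "G3"),
                        chrom = "chr1", gap_bp = c(0L, 500L, 900L),
                        relation = c("overlap", "upstream", "downstream"))
  dels <- tibble::tibble(feature_id = c("L1", "L2"), direction = c("up", "up"))
  dems <- tibble::tibble(feature_id = c("G1", "G2"), direction = c("up", "down"))
  net <- build_core_network(cis, dels, dems)
  expect_equal(nrow(net$edges), 2) # G3 not a DEM -> no edge
  conc <- setNames(net$edges$concordant, net$edges$del_id)
  expect_true(conc[["L1"]])
  expect_false(conc[["L2"]])
  expect_equal(net$summary$n_cis_genes_dem, 2)
  expect_equal(net$summary$n_concordant, 1)
  expect_equal(net$summary$n_discordant, 1)
})

test_that("edge count is at least the distinct cis-gene/DEM count", {
  # one gene cis to two DELs: 2 edges >= 1 gene
  cis <- tibble::tibble(lncrna_id = c("L1", "L2"), gene_id = "G1",
                        chrom = "chr1", gap_bp = c(100L, 2000L),
                        relation = "upstream")
  dels <- tibble::tibble(feature_id = c("L1", "L2"), direction = c("up", "down"))
  dems <- tibble::tibble(feature_id = "G1", direction = "up")
  net <- build_core_network(cis, dels, dems)
  expect_equal(nrow(net$edges), 2)
  expect_gte(net$summary$n_edges, net$summary$n_cis_genes_dem)
})
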