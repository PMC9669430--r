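mk_groups <- function(n1 = 3, n2 = 3) {
  tibble::tibble(sample = c(paste0("a", 1:n1), paste0("b", 1:n2)),
                 group = rep(c("g1", "g2"), c(n1, n2)))
}

test_that("identical groups give log2fc 0 and p ~ 1", {
  counts <- tibble::tibble(feature_id = "f1",
                           a1 = 10, a2 = 12, a3 = 11,
                           b1 = 10, b2 = 12, b3 = 11)
  res <- de_test(counts, mk_groups(), c(f1 = 1000))
  expect_equal(res$log2fc, 0)
  expect_gt(res$p_value, 0.99)
})

test_that("pseudocount behaviour matches the fold-change formula", {
  # group means 0 and 10 on the FPKM scale with c = 1 -> log2(11/1)
  counts <- tibble::tibble(feature_id = c("f1", "pad"),
                           a1 = c(0, 1000), a2 = c(0, 1000), a3 = c(0, 1000),
                           b1 = c(10, 990), b2 = c(10, 990), b3 = c(10, 990))
  # length/total chosen so FPKM == counts: length 1 kb, total 1000 reads
  res <- de_test(counts, mk_groups(), c(f1 = 1e6, pad = 1e6))
  f1 <- res[res$feature_id == "f1", ]
  expect_equal(f1$mean_fpkm_1, 0)
  expect_equal(f1$mean_fpkm_2, 10)
  expect_equal(f1$log2fc, log2(11 / 1))
})

test_that("t_logfpkm requires two samples per group and points to nb_wald", {
  counts <- tibble::tibble(feature_id = "f1", a1 = 5, b1 = 50, b2 = 60)
  groups <- tibble::tibble(sample = c("a1", "b1", "b2"),
                           group = c("g1", "g2", "g2"))
  expect_error(de_test(counts, groups, c(f1 = 1000)), "nb_wald")
  res <- de_test(counts, groups, c(f1 = 1000), method = "nb_wald")
  expect_true(is.finite(res$p_value))
})

test_that("all-zero features are flagged and excluded from calls", {
  counts <- tibble::tibble(feature_id = c("dead", "live"),
                           a1 = c(0, 10), a2 = c(0, 14), a3 = c(0, 12),
                           b1 = c(0, 120), b2 = c(0, 140), b3 = c(0, 130))
  res <- de_test(counts, mk_groups(), c(dead = 1000, live = 1000))
  expect_true(res$all_zero[res$feature_id == "dead"])
  expect_true(is.na(res$p_value[res$feature_id == "dead"]))
  calls <- call_de(res)
  expect_equal(tidy(calls)$direction[calls$table$feature_id == "dead"], "ns")
})

test_that("bh_fdr reproduces the hand step-up example and validates input", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(1), 1)
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
})

test_that("bh_fdr equals the brute-force step-up on random p-vectors", {
  withr::with_seed(13, {
    for (i in 1:300) {
      p <- runif(sample(1:60, 1))
      expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    }
  })
})

test_that("q-values are nondecreasing in sorted-p order", {
  withr::with_seed(14, p <- runif(500))
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("call_de applies both thresholds", {
  res <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                        mean_fpkm_1 = 1, mean_fpkm_2 = 1,
                        log2fc = c(1.5, 1.5, -2, 0.2),
                        statistic = 1,
                        p_value = c(0.001, 0.9, 0.0001, 0.0001),
                        all_zero = FALSE)
  calls <- call_de(res, fc_cut = 2, q_cut = 0.05)
  d <- setNames(tidy(calls)$direction, tidy(calls)$feature_id)
  expect_equal(d[["a"]], "up")   # log2fc 1.5 >= 1, q small
  expect_equal(d[["b"]], "ns")   # q too large
  expect_equal(d[["c"]], "down")
  expect_equal(d[["d"]], "ns")   # fold change too small
  g <- glance(calls)
  expect_equal(c(g$n_up, g$n_down, g$n_ns), c(1, 1, 2))
})

test_that("planted fold changes are recovered under the stated conditions", {
  # the recovery conditions: |log2FC| = 2, low-state mean >= 200,
  # dispersion 0.05, three replicates per group; the planted fraction (~25%)
  # mirrors the default study conditions, and recovery is averaged over four
  # replicate simulations (200 planted features)
  recov <- vapply(1:4, function(rep_i) {
    withr::with_seed(99 + rep_i, {
      n_de <- 50; n_null <- 150; n_all <- n_de + n_null
      mu <- c(runif(n_de, 200, 1000), rlnorm(n_null, log(300), 0.5))
      lfc <- c(rep(c(2, -2), length.out = n_de), rep(0, n_null))
      base <- ifelse(lfc < 0, mu * 4, mu)
      cnt1 <- matrix(rnbinom(3 * n_all, mu = rep(base, 3), size = 20), ncol = 3)
      cnt2 <- matrix(rnbinom(3 * n_all, mu = rep(base * 2^lfc, 3), size = 20),
                     ncol = 3)
      counts <- dplyr::bind_cols(
        tibble::tibble(feature_id = paste0("f", seq_len(n_all))),
        tibble::as_tibble(setNames(as.data.frame(cbind(cnt1, cnt2)),
                                   c(paste0("a", 1:3), paste0("b", 1:3))))
      )
      res <- de_test(counts, mk_groups(),
                     setNames(rep(1000, n_all), counts$feature_id))
      called <- de_features(call_de(res))
      mean(paste0("f", 1:n_de) %in% called)
    })
  }, numeric(1))
  expect_gte(mean(recov), 0.9)
})

test_that("strongly planted features top the p-value ranking", {
  withr::with_seed(199, {
    mu <- c(runif(20, 200, 1000), rlnorm(180, log(300), 0.5))
    lfc <- c(rep(c(3, -3), 10), rep(0, 180))
    base <- ifelse(lfc < 0, mu * 8, mu)
    cnt1 <- matrix(rnbinom(600, mu = rep(base, 3), size = 50), ncol = 3)
    cnt2 <- matrix(rnbinom(600, mu = rep(base * 2^lfc, 3), size = 50), ncol = 3)
  })
  counts <- dplyr::bind_cols(
    tibble::tibble(feature_id = paste0("f", 1:200)),
    tibble::as_tibble(setNames(as.data.frame(cbind(cnt1, cnt2)),
                               c(paste0("a", 1:3), paste0("b", 1:3))))
  )
  res <- de_test(counts, mk_groups(), setNames(rep(1000, 200), counts$feature_id))
  expect_true(all(res$feature_id[order(res$p_value)][1:10] %in% paste0("f", 1:20)))
})
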