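# Independent brute-force oracles used to cross-check the package's
# implementations, plus a cached copy of the default simulated dataset so
# multiple test files can reuse it.

# Exhaustive ORF enumeration: every ATG, first in-frame stop, stop included.
orf_oracle <- function(seq) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  codon_at <- function(i) paste0(chars[i], chars[i + 1], chars[i + 2])
  stops <- c("TAA", "TAG", "TGA")
  best <- c(start = 0L, len = 0L, frame = NA_integer_)
  if (n >= 6) {
    for (i in 1:(n - 5)) {
      if (codon_at(i) != "ATG") next
      j <- i + 3
      while (j + 2 <= n) {
        if (codon_at(j) %in% stops) {
          len <- j + 2 - i + 1
          if (len > best[["len"]]) {
            best <- c(start = i, len = len, frame = (i - 1L) %% 3L)
          }
          break
        }
        j <- j + 3
      }
    }
  }
  best
}

# Memoised top-down recursion for the optimal local-alignment score.
sw_oracle_score <- function(q, s, match = 2, mismatch = -1, gap = -2) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  memo <- matrix(NA_real_, n + 1, m + 1)
  H <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- max(0,
             H(i - 1, j - 1) + if (qc[i] == sc[j]) match else mismatch,
             H(i - 1, j) + gap,
             H(i, j - 1) + gap)
    memo[i + 1, j + 1] <<- v
    v
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) best <- max(best, H(i, j))
  best
}

# Step-up BH from its definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, n * p[o] / seq_len(n))
  q_sorted <- rev(cummin(rev(q_sorted)))
  out <- numeric(n)
  out[o] <- q_sorted
  out
}

# Exhaustive enumeration of all C(N, n) draws: P(X >= k).
hyper_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K) # successes are items 1..K
  mean(hits >= k)
}

# All-pairs closed-interval gap scan.
cis_oracle <- function(lnc, genes, window) {
  out <- list()
  for (i in seq_len(nrow(lnc))) for (j in seq_len(nrow(genes))) {
    if (lnc$chrom[i] != genes$chrom[j]) next
    if (lnc$start[i] <= genes$end[j] && genes$start[j] <= lnc$end[i]) {
      gap <- 0L
    } else if (lnc$start[i] > genes$end[j]) {
      gap <- lnc$start[i] - genes$end[j] - 1L
    } else {
      gap <- genes$start[j] - lnc$end[i] - 1L
    }
    if (gap < window) {
      out[[length(out) + 1]] <- data.frame(lncrna_id = lnc$lncrna_id[i],
                                           gene_id = genes$gene_id[j],
                                           gap_bp = gap)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(lncrna_id = character(), gene_id = character(), gap_bp = integer())
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Default simulated dataset, built once per test run.
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(.sim_cache$ds)) .sim_cache$ds <- simulate_dataset(sim_config())
  .sim_cache$ds
}

# The discovery + DE results on the default dataset, also cached.
default_analysis <- function() {
  if (is.null(.sim_cache$an)) {
    ds <- default_sim()
    disc <- discover_lncrnas(ds$candidates, ds$annotation, ds$seqs)
    de <- de_test(ds$counts, ds$groups, ds$lengths)
    lnc_ids <- disc$lncrnas$transcript_id
    dem <- call_de(de[!de$feature_id %in% lnc_ids, ])
    del <- call_de(de[de$feature_id %in% lnc_ids, ])
    .sim_cache$an <- list(ds = ds, disc = disc, dem = dem, del = del)
  }
  .sim_cache$an
}
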