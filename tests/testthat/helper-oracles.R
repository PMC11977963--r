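# Independent oracles and small fixture builders shared across test files.

# Product-limit survival by hand: product over distinct event times <= at of
# (1 - d_i / n_i), risk set counted from all animals still under observation.
km_oracle <- function(time, status, at) {
  ev_times <- sort(unique(time[status == 1]))
  vapply(at, function(a) {
    s <- 1
    for (t in ev_times[ev_times <= a]) {
      n_risk <- sum(time >= t)
      d <- sum(time == t & status == 1)
      s <- s * (1 - d / n_risk)
    }
    s
  }, numeric(1))
}

# Two-sided permutation p-value for the difference in means (t-statistic
# ordering, pooled variance), B random label shuffles.
perm_t_p <- function(x, y, B = 20000L) {
  pooled_t <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  obs <- abs(pooled_t(x, y))
  z <- c(x, y); n1 <- length(x)
  hits <- vapply(seq_len(B), function(i) {
    idx <- sample.int(length(z), n1)
    abs(pooled_t(z[idx], z[-idx])) >= obs
  }, logical(1))
  (1 + sum(hits)) / (B + 1)
}

# Exhaustive hypergeometric tail: enumerate every k-subset of a universe of
# size N and count those overlapping the m-set in at least ov elements.
hyper_tail_enum <- function(N, m, k, ov) {
  subsets <- utils::combn(N, k)
  in_set <- subsets <= m                 # successes are items 1..m
  mean(colSums(in_set) >= ov)
}

# Random toy annotation: a few genes with 2-4 exons on one chromosome.
random_annotation <- function(n_genes = 3L) {
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    o <- (g - 1L) * 5000L + 1L
    n_ex <- sample(2:4, 1)
    len <- sample(80:200, n_ex, replace = TRUE)
    gap <- sample(60:300, n_ex - 1, replace = TRUE)
    start <- o + cumsum(c(0L, len[-n_ex] + gap))
    data.frame(
      chrom = "chrI", start = start, end = start + len - 1L,
      strand = sample(c("+", "-"), 1),
      transcript_id = paste0("g", g, ".t1"), gene_id = paste0("g", g),
      stringsAsFactors = FALSE
    )
  }))
  gene_annotation(exons)
}

# Group stats straight from a ratio vector whose sample mean is exactly
# `target_mean` (symmetric spread), for worked-example arithmetic.
exact_mean_group <- function(target_mean, label, spread = 0.1, n = 5L) {
  dev <- seq(-1, 1, length.out = n) * spread
  group_from_ratios(target_mean + dev, label)
}
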