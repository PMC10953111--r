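# Independent brute-force oracles and genome-mirroring helpers shared across
# test files. Oracles deliberately avoid the implementation's code paths
# (cumulative sums, IRanges pileup, stats::quantile).

# direct shifted-sum evaluation of the difference-of-means filter
oracle_diff_filter <- function(cov, half_width = 75L) {
  n <- length(cov)
  out <- rep(NA_real_, n)
  idx <- seq.int(half_width + 1L, n - half_width)
  right <- numeric(length(idx))
  left <- numeric(length(idx))
  for (j in seq_len(half_width)) {
    right <- right + cov[idx + j]
    left <- left + cov[idx - j]
  }
  out[idx] <- (right - left) / (2 * half_width)
  out
}

# per-bp fragment counting by explicit accumulation
oracle_coverage <- function(frags, chrom_lengths) {
  vals <- lapply(chrom_lengths, function(L) numeric(L))
  for (i in seq_len(nrow(frags))) {
    chr <- frags$chrom[i]
    span <- (frags$start[i] + 1L):frags$end[i]
    vals[[chr]][span] <- vals[[chr]][span] + 1
  }
  vals
}

# linear interpolation of order statistics at h = (n - 1) q, from scratch
oracle_quantile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * q
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  s[lo] + (h - floor(h)) * (s[hi] - s[lo])
}

# genome mirror: position p -> L - 1 - p, interval [s, e) -> [L - e, L - s)
mirror_track <- function(track) {
  coverage_track(lapply(track$values, rev), normalized = track$normalized,
                 total_fragments = track$total_fragments)
}

mirror_genes <- function(genes, chrom_lengths) {
  L <- chrom_lengths[genes$chrom]
  gene_model(genes$gene_id, genes$chrom, L - genes$end, L - genes$start,
             ifelse(genes$strand == "+", "-", "+"))
}

mirror_pos <- function(pos, L) L - 1L - pos

# triangular coverage bump (linear flanks) centered at `center`
triangle_bump <- function(length_bp, center, height = 30, half_base = 80) {
  x <- seq_len(length_bp) - 1L
  pmax(0, height * (1 - abs(x - center) / half_base))
}

# gaussian-bump nucleosome array on a single chromosome
gaussian_array <- function(centers, length_bp, height = 30, sd = 20) {
  x <- seq_len(length_bp) - 1L
  v <- numeric(length_bp)
  for (cc in centers) v <- v + height * exp(-((x - cc)^2) / (2 * sd^2))
  v
}

# memoized default synthetic dataset + downstream calls shared by the
# acceptance tests (all derived from one fixed master seed)
.acc_cache <- new.env(parent = emptyenv())
acceptance_pipeline <- function(seed = 20240101L) {
  key <- paste0("s", seed)
  if (!is.null(.acc_cache[[key]])) return(.acc_cache[[key]])
  cfg <- sim_config(seed = seed)
  d <- simulate_dataset(cfg)
  peaks <- call_nucleosomes(d$mnase)
  calls <- call_plus_one_all(peaks, d$mnase, d$genes)
  occupancy <- call_all(d$chip, d$genes)
  res <- list(cfg = cfg, data = d, peaks = peaks, calls = calls,
              occupancy = occupancy)
  .acc_cache[[key]] <- res
  res
}
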