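# The synthetic-data generator: determinism, layout constraints, planted
# chromatin structure, and the statistical contracts of each emitter.

test_that("annotation generation is byte-deterministic and respects spacing", {
  cfg <- sim_config(n_genes = 100L, chrom_length = 400000L, seed = 1L)
  p1 <- withr::local_tempfile(fileext = ".gff3")
  p2 <- withr::local_tempfile(fileext = ".gff3")
  a1 <- generate_annotation(cfg, gff3_path = p1)
  a2 <- generate_annotation(cfg, gff3_path = p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(a1$genes, a2$genes)

  expect_equal(nrow(a1$genes), 100L)
  # divergent_fraction = 0.1 -> 10 pairs, 20 paired genes
  expect_equal(length(a1$divergent_partner), 20L)
  expect_equal(sum(!is.na(a1$divergent_partner)), 20L)

  # neighbouring transcription units >= 2 kb apart; within a pair the two
  # ATGs face each other across cfg$ndr_gap
  g <- a1$genes[order(a1$genes$chrom, a1$genes$start), ]
  partner <- a1$divergent_partner
  for (i in seq_len(nrow(g) - 1)) {
    if (g$chrom[i] != g$chrom[i + 1]) next
    gap <- g$start[i + 1] - g$end[i]
    paired <- !is.na(partner[g$gene_id[i]]) &&
      identical(unname(partner[g$gene_id[i]]), g$gene_id[i + 1])
    if (paired) expect_equal(gap, cfg$ndr_gap) else expect_gte(gap, 2000L)
  }
})

test_that("packing failure is detected", {
  cfg <- sim_config(n_genes = 500L, chrom_length = 50000L, n_chroms = 1L)
  expect_error(generate_annotation(cfg), "infeasible packing")
})

test_that("planted classes follow the multinomial proportions within 3 sigma", {
  cfg <- sim_config(n_genes = 1000L, n_chroms = 8L, chrom_length = 700000L,
                    seed = 3L)
  ann <- generate_annotation(cfg)
  truth <- plant_chromatin(ann, cfg)
  n <- nrow(truth)
  for (cl in names(cfg$class_proportions)) {
    p <- cfg$class_proportions[[cl]]
    expected <- n * p
    sigma <- sqrt(n * p * (1 - p))
    expect_lt(abs(sum(truth$class == cl) - expected), 3.5 * sigma,
              label = paste("count of", cl))
  }
})

test_that("H3K27me3 is planted in contiguous runs of at least 3 genes", {
  cfg <- sim_config(n_genes = 300L, n_chroms = 4L, chrom_length = 500000L,
                    seed = 4L)
  truth <- plant_chromatin(generate_annotation(cfg), cfg)
  truth <- truth[order(truth$chrom, truth$start), ]
  for (chr in unique(truth$chrom)) {
    r <- rle(truth$k27[truth$chrom == chr])
    runs <- r$lengths[r$values]
    if (length(runs) > 0) expect_gte(min(runs), 3L)
  }
})

test_that("an all-unmarked genome still gets +1 positions everywhere", {
  cfg <- sim_config(n_genes = 60L, chrom_length = 300000L,
                    class_proportions = c(H2AZ_K4 = 0, H2AZ_K27 = 0,
                                          K27_only = 0, H2AZ_only = 0,
                                          unmarked = 1), seed = 5L)
  truth <- plant_chromatin(generate_annotation(cfg), cfg)
  expect_false(any(truth$h2az | truth$k4 | truth$k27))
  expect_false(anyNA(truth$plus_one_true))
  expect_false(anyNA(truth$minus_one_true))
})

test_that("divergent pairs share their promoter nucleosome in the truth", {
  cfg <- sim_config(seed = 6L)
  ann <- generate_annotation(cfg)
  truth <- plant_chromatin(ann, cfg)
  paired <- truth[!is.na(truth$divergent_partner), ]
  idx <- match(paired$divergent_partner, truth$gene_id)
  expect_equal(paired$minus_one_true, truth$plus_one_true[idx])
  # and they share the chromatin class (one promoter, one state)
  expect_equal(paired$class, truth$class[idx])
})

test_that("MNase simulation is seed-stable and fragment lengths are on target", {
  cfg <- sim_config(n_genes = 40L, chrom_length = 200000L, n_chroms = 1L,
                    seed = 7L)
  truth <- plant_chromatin(generate_annotation(cfg), cfg)
  f1 <- simulate_mnase(truth, cfg)
  f2 <- simulate_mnase(truth, cfg)
  expect_identical(f1, f2)

  # central mass of the truncated normal after the 130-170 band-pass
  p_in <- (stats::pnorm(170.5, cfg$frag_len_mean, cfg$frag_len_sd) -
             stats::pnorm(129.5, cfg$frag_len_mean, cfg$frag_len_sd)) /
    (stats::pnorm(250, cfg$frag_len_mean, cfg$frag_len_sd) -
       stats::pnorm(100, cfg$frag_len_mean, cfg$frag_len_sd))
  kept <- filter_fragments_by_length(f1, 130L, 170L)
  frac <- nrow(kept) / nrow(f1)
  sigma <- sqrt(p_in * (1 - p_in) / nrow(f1))
  expect_lt(abs(frac - p_in), 3.5 * sigma + 0.002)

  # with no background, coverage piles up on planted dyads and the NDR
  # between +1 and -1 stays essentially empty
  cfg0 <- sim_config(n_genes = 5L, chrom_length = 60000L, n_chroms = 1L,
                     background_fraction = 0, seed = 8L)
  truth0 <- plant_chromatin(generate_annotation(cfg0), cfg0)
  f0 <- simulate_mnase(truth0, cfg0)
  cov0 <- fragments_to_coverage(f0, c(chr1 = cfg0$chrom_length))$values$chr1
  at_dyad <- cov0[truth0$plus_one_true + 1L]
  at_ndr <- cov0[(truth0$plus_one_true + truth0$minus_one_true) %/% 2 + 1L]
  expect_gt(mean(at_dyad), 0.6 * cfg0$mean_coverage)
  expect_lt(mean(at_ndr), 0.1 * mean(at_dyad))
})

test_that("ChIP tracks: flat when fold = 1, replicate means agree on truth", {
  cfg <- sim_config(n_genes = 30L, chrom_length = 150000L, n_chroms = 1L,
                    enrichment_fold = 1, seed = 9L)
  truth <- plant_chromatin(generate_annotation(cfg), cfg)
  reps <- simulate_chip(truth, cfg, "H2A.Z")
  base <- cfg$background_level * mark_config("H2A.Z")$threshold
  for (r in reps) {
    m <- mean(r$values$chr1)
    sigma <- sqrt(base / cfg$chip_granularity / length(r$values$chr1))
    expect_lt(abs(m - base), 4 * sigma)
    expect_true(r$normalized)
  }

  cfg3 <- sim_config(n_genes = 30L, chrom_length = 150000L, n_chroms = 1L,
                     seed = 10L)
  truth3 <- plant_chromatin(generate_annotation(cfg3), cfg3)
  reps3 <- simulate_chip(truth3, cfg3, "H2A.Z")
  expect_false(identical(reps3[[1]]$values$chr1, reps3[[2]]$values$chr1))
  marked <- truth3[truth3$h2az, ][1, ]
  win <- tss_window(marked[, c("chrom", "start", "end", "strand")], 200, 600,
                    cfg3$chrom_length)
  m1 <- mean(extract_window(reps3[[1]], win))
  m2 <- mean(extract_window(reps3[[2]], win))
  expect_lt(abs(m1 - m2) / m1, 0.1)

  expect_error(simulate_chip(truth3, cfg3, "H4K20me1"), "unknown mark")
})

test_that("expression simulation encodes the planted flips", {
  cfg <- sim_config(seed = 11L)
  truth <- plant_chromatin(generate_annotation(cfg), cfg)
  e1 <- simulate_expression(truth, cfg)
  e2 <- simulate_expression(truth, cfg)
  expect_identical(e1, e2)

  cls <- classify_de(e1$log2fc, e1$p)
  flips <- truth$flip
  if (sum(flips) > 0) expect_gte(mean(cls[flips] == "down"), 0.95)
  stable <- truth$class == "unmarked"
  expect_gte(mean(cls[stable] == "ns"), 0.95)
})

test_that("simulated BLAST hits recover the planted conservation classes", {
  cfg <- sim_config(n_genes = 60L, chrom_length = 300000L, seed = 12L)
  truth <- plant_chromatin(generate_annotation(cfg), cfg)
  blast <- simulate_blast_hits(truth, cfg)
  cls <- classify_conservation_all(blast)
  m <- match(truth$gene_id, cls$gene_id)
  agree <- mean(cls$conservation[m] == truth$conservation_true)
  expect_gte(agree, 0.95)
})
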