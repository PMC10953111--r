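# Per-gene joins: expression classes, co-occupancy, anchored matrices,
# conservation and the integrated gene table.

test_that("log2 RPKM follows its definition", {
  expect_equal(rpkm_log2(100, 1000, 1e6, pseudocount = 0), log2(100))
  expect_equal(rpkm_log2(0, 1000, 1e6, pseudocount = 1), 0)
  expect_equal(rpkm_log2(100, 1000, 1e6, 0),
               rpkm_log2(200, 1000, 2e6, 0))
  expect_error(rpkm_log2(10, 0, 1e6), "gene_length")
  expect_error(rpkm_log2(10, 1000, 0), "library_size")
})

test_that("DE classification includes the |log2fc| = 1 boundary", {
  expect_equal(classify_de(1.0, 0.005), "up")
  expect_equal(classify_de(-2.3, 1e-4), "down")
  expect_equal(classify_de(3.0, 0.02), "ns")
  expect_equal(classify_de(-1.0, 0.0099), "down")
  expect_equal(classify_de(0.99, 1e-9), "ns")
  expect_error(classify_de(1, NA), "present")
})

test_that("DE classes partition every gene with expression evidence", {
  set.seed(61)
  lfc <- stats::rnorm(500, 0, 2)
  p <- stats::runif(500)
  cls <- classify_de(lfc, p)
  expect_equal(sum(cls == "up") + sum(cls == "down") + sum(cls == "ns"), 500L)
})

test_that("venn regions are disjoint and sum to the union", {
  v <- venn_counts(c(1, 2, 3), c(2, 3, 4))
  expect_equal(v$AB, 2L)
  expect_equal(v$A_only, 1L)
  expect_equal(v$B_only, 1L)
  expect_equal(v$A_only + v$B_only + v$AB, v$total)

  expect_equal(venn_counts(c("a", "b"), c("c", "d"))$AB, 0L)

  set.seed(62)
  A <- sample(letters, 12); B <- sample(letters, 15); C <- sample(letters, 8)
  v3 <- venn_counts(A, B, C)
  expect_equal(sum(unlist(v3[setdiff(names(v3), "total")])), v3$total)
  expect_equal(v3$total, length(union(union(A, B), C)))
})

test_that("co-occupancy fraction is intersection over reference", {
  ref <- paste0("g", 1:100)
  expect_equal(co_occupancy_fraction(ref, ref[1:36]), 0.36)
  expect_equal(co_occupancy_fraction(ref[1:10], ref), 1.0)
  set.seed(63)
  a <- sample(letters, 10); b <- sample(letters, 13)
  expect_equal(co_occupancy_fraction(a, b), sum(a %in% b) / length(a))
  expect_error(co_occupancy_fraction(character(), ref), "empty")
})

test_that("enrichment matrix slices +1-anchored windows in orientation", {
  v <- as.numeric(1:10000)
  track <- coverage_track(list(chr1 = v))
  genes <- gene_model(c("long", "short"), "chr1", c(1900L, 5900L),
                      c(2400L, 6200L), c("+", "-"))
  calls <- data.frame(gene_id = c("long", "short"),
                      plus_one_pos = c(2000L, 6100L),
                      stringsAsFactors = FALSE)
  mat <- enrichment_matrix(track, calls, genes, flank_up = 1000L,
                           flank_down = 5000L)
  # rows sorted by ascending gene length: 300-bp gene first
  expect_equal(rownames(mat), c("short", "long"))
  expect_equal(mat["long", ], v[(2000 - 1000 + 1):(2000 + 5000)])
  # minus strand: same offsets walked leftwards
  expect_equal(mat["short", ], rev(v[1102:7101]))
  expect_equal(attr(mat, "n_excluded"), 0L)

  calls$plus_one_pos[2] <- NA_integer_
  mat1 <- enrichment_matrix(track, calls, genes, 100L, 100L)
  expect_equal(nrow(mat1), 1L)
  expect_equal(attr(mat1, "n_excluded"), 1L)

  # off-chromosome cells are NA
  calls2 <- data.frame(gene_id = "long", plus_one_pos = 400L)
  mat2 <- enrichment_matrix(track, calls2, genes[1, ], 1000L, 100L)
  expect_true(all(is.na(mat2[1, 1:600])))
  expect_false(anyNA(mat2[1, 601:1100]))
})

test_that("median profile bins columns and resists outlier rows", {
  mat <- matrix(5, nrow = 11, ncol = 84)
  expect_equal(median_profile(mat, 21L), rep(5, 4))
  mat[1, ] <- 1000
  expect_equal(median_profile(mat, 21L), rep(5, 4))
  mat[, 1:21] <- NA
  expect_equal(median_profile(mat, 21L), c(NA, 5, 5, 5))
  expect_error(median_profile(mat, 0L), "bin_width")
})

test_that("phased planted arrays leave their repeat in the median profile", {
  centers <- seq(500, 500 + 11 * 165, by = 165)
  cov <- gaussian_array(centers, 3000, height = 40, sd = 25)
  track <- coverage_track(list(chr1 = cov))
  genes <- gene_model(paste0("g", 1:5), "chr1", rep(480L, 5) + 0:4,
                      rep(2300L, 5) + 0:4, rep("+", 5))
  calls <- data.frame(gene_id = genes$gene_id, plus_one_pos = 500L)
  mat <- enrichment_matrix(track, calls, genes, flank_up = 0L,
                           flank_down = 1500L)
  prof <- median_profile(mat, 1L)
  tops <- which(diff(sign(diff(prof))) == -2) + 1L
  expect_true(all(abs(diff(tops) - 165) <= 2))
})

test_that("conservation classes follow the identity filter and hit cutoffs", {
  mk <- function(n, pident) data.frame(
    sseqid = paste0("s", seq_len(n)), pident = rep(pident, n))
  expect_equal(classify_conservation(mk(30, 80))$class, "low")
  expect_equal(classify_conservation(mk(350, 80))$class, "high")
  expect_equal(classify_conservation(mk(150, 80))$class, "intermediate")
  low_id <- classify_conservation(mk(100, 35))
  expect_equal(low_id$hit_count, 0L)
  expect_equal(low_id$class, "low")
  # duplicate subjects collapse
  dup <- data.frame(sseqid = rep("s1", 60), pident = 90)
  expect_equal(classify_conservation(dup)$hit_count, 1L)
  expect_error(classify_conservation(data.frame(x = 1)), "pident")
})

test_that("outfmt-6 parsing and per-query classification work end to end", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(
    vapply(1:60, function(i) sprintf(
      "gA\tsub%03d\t%.1f\t200\t5\t1\t1\t200\t1\t200\t1e-30\t250", i, 85.0),
      character(1)),
    "gB\tsubX\t35.0\t200\t5\t1\t1\t200\t1\t200\t1e-30\t250")
  writeLines(rows, path)
  blast <- read_blast_outfmt6(path)
  expect_equal(nrow(blast), 61L)
  cls <- classify_conservation_all(blast)
  expect_equal(cls$conservation[cls$gene_id == "gA"], "intermediate")
  expect_equal(cls$conservation[cls$gene_id == "gB"], "low")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gA\tonly-two-fields", bad)
  expect_error(read_blast_outfmt6(bad), "malformed")
})

test_that("the gene table joins all evidence and keeps missing rows", {
  genes <- gene_model(paste0("g", 1:10), "chr1",
                      seq(0L, 9000L, by = 1000L),
                      seq(500L, 9500L, by = 1000L), rep(c("+", "-"), 5))
  occupancy <- do.call(rbind, lapply(c("H2A.Z", "H3K4me3", "H3K27me3"),
    function(m) data.frame(gene_id = genes$gene_id, mark = m,
                           max_rep1 = 20, max_rep2 = 20,
                           positive = rep(c(TRUE, FALSE), 5),
                           negative_class = FALSE)))
  plusone <- data.frame(gene_id = genes$gene_id, chrom = "chr1",
                        strand = genes$strand,
                        plus_one_pos = c(NA, seq_len(9) * 100L),
                        bidirectional = FALSE)
  expression <- data.frame(gene_id = genes$gene_id[1:8],
                           rpkm_log2_wt = 5, rpkm_log2_kd = 5,
                           rpkm_log2_oe = 5,
                           log2fc = c(-3, -3, 0, 0, 2, 0, 0, 0),
                           p = c(1e-5, 1e-4, 0.5, 0.5, 1e-3, 0.9, 0.9, 0.9))
  conservation <- data.frame(gene_id = genes$gene_id, hit_count = 100L,
                             conservation = "intermediate")
  tab <- build_gene_table(genes, occupancy, plusone, expression, conservation)
  expect_equal(nrow(tab), 10L)
  expect_equal(sum(tab$de_class == "down", na.rm = TRUE), 2L)
  expect_equal(sum(tab$de_class == "up", na.rm = TRUE), 1L)
  expect_true(all(is.na(tab$de_class[9:10])))
  expect_false(tab$plus_one_present[1])
  expect_true(all(tab$plus_one_present[2:10]))
  # partition over genes with expression evidence
  with_expr <- !is.na(tab$de_class)
  expect_equal(sum(tab$de_class[with_expr] %in% c("up", "down", "ns")),
               sum(with_expr))

  dup_expr <- rbind(expression, expression[1, ])
  expect_error(build_gene_table(genes, occupancy, plusone, dup_expr),
               "duplicate")
})
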