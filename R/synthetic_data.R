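# Seed-reproducible synthetic genomes with known chromatin truth: annotation,
# planted nucleosome arrays with promoter NDRs, MNase fragments, replicate
# ChIP tracks for three marks (contiguous H3K27me3 domains), expression
# tables correlated with the planted states, and BLAST-like conservation
# evidence. Every component re-seeds its own stream from the master seed so
# modules can be regenerated independently and outputs are byte-identical
# across runs.

#' Simulation configuration
#'
#' Defaults emulate a compact fungal genome at mononucleosome resolution:
#' 165-bp nucleosome repeat, ~150-bp promoter NDRs, MNase fragment lengths
#' around 147 bp (truncated normal on \[100, 250\] before the 130--170
#' band-pass), 50x mean nucleosomal coverage with 10% uniform background,
#' and five chromatin classes whose proportions drive both the ChIP truth
#' and the expression states.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param n_genes total number of genes.
#' @param gene_length_range min/max gene length in bp.
#' @param nucleosome_repeat array repeat length in bp.
#' @param ndr_gap bp between the ATGs of a divergent gene pair (sets the NDR
#'   width between their shared promoter nucleosomes).
#' @param plus_one_offset planted +1 dyad, bp downstream of the ATG.
#' @param minus_one_offset planted -1 dyad, bp upstream of the ATG.
#' @param frag_len_mean,frag_len_sd MNase fragment-length distribution (bp).
#' @param frag_len_range truncation bounds for fragment lengths (bp).
#' @param mean_coverage expected fragments per nucleosome (~ peak coverage).
#' @param dyad_jitter_sd positional jitter of fragment centers (bp).
#' @param background_fraction fraction of fragments placed uniformly.
#' @param divergent_fraction fraction of genes heading a divergent pair
#'   (`round(divergent_fraction * n_genes)` pairs are laid out).
#' @param class_proportions named proportions over the chromatin classes
#'   `H2AZ_K4`, `H2AZ_K27`, `K27_only`, `H2AZ_only`, `unmarked`.
#' @param enrichment_fold planted ChIP enrichment over the background
#'   (fold 1 = indistinguishable from background; the default 6 over a
#'   0.5-threshold background puts marked windows at 3x the calling
#'   threshold).
#' @param background_level ChIP background, in units of the mark's calling
#'   threshold.
#' @param chip_granularity Poisson draws per CPM unit (noise resolution).
#' @param replicates ChIP replicates per mark.
#' @param p_expressed probability of being expressed in the wild type, per
#'   class.
#' @param p_flip probability that an expressed H2AZ_K27 gene is silenced
#'   under simulated H2A.Z depletion.
#' @param seed master seed (integer).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2L, chrom_length = 550000L, n_genes = 200L,
                       gene_length_range = c(500L, 3000L),
                       nucleosome_repeat = 165L, ndr_gap = 240L,
                       plus_one_offset = 30L, minus_one_offset = 230L,
                       frag_len_mean = 147, frag_len_sd = 8,
                       frag_len_range = c(100L, 250L),
                       mean_coverage = 50, dyad_jitter_sd = 10,
                       background_fraction = 0.1, divergent_fraction = 0.1,
                       class_proportions = c(H2AZ_K4 = 0.2, H2AZ_K27 = 0.1,
                                             K27_only = 0.3, H2AZ_only = 0.2,
                                             unmarked = 0.2),
                       enrichment_fold = 6, background_level = 0.5,
                       chip_granularity = 4, replicates = 2L,
                       p_expressed = c(H2AZ_K4 = 0.9, H2AZ_K27 = 0.9,
                                       K27_only = 0.1, H2AZ_only = 0.9,
                                       unmarked = 0.5),
                       p_flip = 0.9, seed = 1L) {
  stopifnot(abs(sum(class_proportions) - 1) < 1e-8,
            all(class_proportions >= 0),
            n_chroms >= 1, chrom_length > 0, n_genes >= 1,
            nucleosome_repeat > 0, mean_coverage > 0)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

.component_seed <- function(cfg, k) as.integer((cfg$seed %% 20000000L) + k)

#' Generate a synthetic gene annotation
#'
#' Genes are packed chromosome by chromosome with >= 2 kb between
#' neighbouring transcription units; a configured fraction is laid out as
#' divergent pairs whose ATGs face each other across a shared promoter NDR
#' (so one promoter nucleosome serves as +1 for one gene and -1 for the
#' other). Deterministic for a fixed seed.
#'
#' @param cfg a [sim_config].
#' @param gff3_path optional path; when given the annotation is written as
#'   GFF3.
#' @return A list: `genes` (a [gene_model]), `divergent_partner` (named
#'   character vector, partner gene id per paired gene).
#' @export
generate_annotation <- function(cfg, gff3_path = NULL) {
  set.seed(.component_seed(cfg, 101L))
  n_pairs <- round(cfg$divergent_fraction * cfg$n_genes)
  if (2L * n_pairs > cfg$n_genes)
    stop("generate_annotation: divergent_fraction too large for n_genes")
  margin <- 3000L
  spacing <- 2000L
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chroms))

  ids <- character(); chrom <- character()
  start <- integer(); end <- integer(); strand <- character()
  partner <- character()
  gi <- 0L
  # units to place: first n_pairs are divergent pairs, rest singles
  n_units <- cfg$n_genes - n_pairs
  unit_is_pair <- c(rep(TRUE, n_pairs), rep(FALSE, n_units - n_pairs))
  unit_is_pair <- sample(unit_is_pair)   # scatter pairs along the genome
  ci <- 1L
  cursor <- margin
  next_id <- function() { gi <<- gi + 1L; sprintf("g%04d", gi) }
  glen <- function() sample(seq(cfg$gene_length_range[1],
                                cfg$gene_length_range[2]), 1L)
  for (u in seq_len(n_units)) {
    need <- if (unit_is_pair[u]) 2L * cfg$gene_length_range[2] + cfg$ndr_gap
            else cfg$gene_length_range[2]
    while (cursor + need + margin > cfg$chrom_length) {
      ci <- ci + 1L
      if (ci > cfg$n_chroms)
        stop("generate_annotation: infeasible packing; enlarge the genome")
      cursor <- margin
    }
    if (unit_is_pair[u]) {
      lenA <- glen(); lenB <- glen()
      idA <- next_id(); idB <- next_id()
      # A on '-' transcribing leftwards, B on '+' rightwards; ATGs face
      # each other across ndr_gap bp
      ids <- c(ids, idA, idB)
      chrom <- c(chrom, chrom_names[ci], chrom_names[ci])
      start <- c(start, cursor, cursor + lenA + cfg$ndr_gap)
      end <- c(end, cursor + lenA, cursor + lenA + cfg$ndr_gap + lenB)
      strand <- c(strand, "-", "+")
      partner[idA] <- idB; partner[idB] <- idA
      cursor <- cursor + lenA + cfg$ndr_gap + lenB + spacing
    } else {
      len <- glen()
      id <- next_id()
      ids <- c(ids, id)
      chrom <- c(chrom, chrom_names[ci])
      start <- c(start, cursor)
      end <- c(end, cursor + len)
      strand <- c(strand, sample(c("+", "-"), 1L))
      cursor <- cursor + len + spacing
    }
  }
  genes <- gene_model(ids, chrom, start, end, strand)
  if (!is.null(gff3_path)) write_gff3(genes, gff3_path)
  list(genes = genes, divergent_partner = partner)
}

.atg_pos <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

# transcription-direction sign: downstream = +1 bp for '+', -1 bp for '-'
.dir_sign <- function(strand) ifelse(strand == "+", 1L, -1L)

#' Plant chromatin classes, nucleosome positions and expression states
#'
#' Assigns each gene one of five classes. H3K27me3-positive classes are laid
#' down as contiguous domains spanning runs of at least three adjacent genes
#' (facultative-heterochromatin style); the remaining genes receive the
#' euchromatic classes at the configured relative proportions. Every gene
#' gets planted +1 and -1 dyads (shared across divergent pairs). Expression
#' states follow the class rules: H3K4me3/H2A.Z genes are mostly expressed,
#' H3K27me3-only genes mostly silent, and expressed H2A.Z/H3K27me3 genes are
#' flagged to flip to silent under simulated H2A.Z depletion.
#'
#' @param annotation result of [generate_annotation].
#' @param cfg a [sim_config].
#' @return A `data.frame` truth table, one row per gene: gene coordinates,
#'   `class`, mark booleans (`h2az`, `k4`, `k27`), `divergent_partner`,
#'   `plus_one_true` / `minus_one_true` (0-based dyads),
#'   `expressed_wt`, `flip`, `conservation_true`.
#' @export
plant_chromatin <- function(annotation, cfg) {
  set.seed(.component_seed(cfg, 202L))
  genes <- annotation$genes
  n <- nrow(genes)
  prop <- cfg$class_proportions
  partner <- annotation$divergent_partner[genes$gene_id]

  # contiguous K27 domains over runs of >= 3 adjacent genes in genomic order
  ord <- order(genes$chrom, genes$start)
  target_k27 <- round((prop[["H2AZ_K27"]] + prop[["K27_only"]]) * n)
  in_k27_ord <- rep(FALSE, n)   # indexed by position in ord
  free <- rep(TRUE, n)
  while (sum(in_k27_ord) < target_k27 && any(free)) {
    run_len <- sample(3:6, 1L)
    anchor_pool <- which(free)
    a <- anchor_pool[sample.int(length(anchor_pool), 1L)]
    run <- a:min(a + run_len - 1L, n)
    ok <- free[run] & genes$chrom[ord[run]] == genes$chrom[ord[a]]
    run <- run[cumprod(ok) == 1]          # maximal contiguous free prefix
    if (length(run) < 3L) { free[a] <- FALSE; next }
    in_k27_ord[run] <- TRUE
    free[run] <- FALSE
  }
  in_k27 <- rep(FALSE, n)
  in_k27[ord] <- in_k27_ord

  # a divergent pair shares its promoter nucleosome, hence its chromatin
  # state: harmonize domain membership and draw one class per pair
  paired <- !is.na(partner)
  pidx <- match(partner, genes$gene_id)          # NA for singles
  in_k27[paired] <- in_k27[paired] | in_k27[pidx[paired]]

  p_h2az_in_k27 <- prop[["H2AZ_K27"]] / (prop[["H2AZ_K27"]] + prop[["K27_only"]])
  if (!is.finite(p_h2az_in_k27)) p_h2az_in_k27 <- 0
  eu_prop <- prop[c("H2AZ_K4", "H2AZ_only", "unmarked")]
  if (sum(eu_prop) == 0) eu_prop[] <- c(0, 0, 1)
  eu_prop <- eu_prop / sum(eu_prop)

  cls <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!is.na(cls[i])) next
    ci <- if (in_k27[i]) {
      if (stats::runif(1) < p_h2az_in_k27) "H2AZ_K27" else "K27_only"
    } else {
      sample(names(eu_prop), 1L, prob = eu_prop)
    }
    cls[i] <- ci
    if (paired[i]) cls[pidx[i]] <- ci
  }

  h2az <- cls %in% c("H2AZ_K4", "H2AZ_K27", "H2AZ_only")
  k4 <- cls == "H2AZ_K4"
  k27 <- in_k27

  atg <- .atg_pos(genes)
  dirs <- .dir_sign(genes$strand)
  plus_one <- atg + dirs * cfg$plus_one_offset
  minus_one <- atg - dirs * cfg$minus_one_offset
  # divergent pairs share promoter nucleosomes: the partner's +1 is this
  # gene's -1
  if (any(paired)) minus_one[paired] <- plus_one[pidx[paired]]

  expressed <- stats::runif(n) < cfg$p_expressed[cls]
  flip <- cls == "H2AZ_K27" & expressed & stats::runif(n) < cfg$p_flip

  cons <- ifelse(cls == "H2AZ_K4", "high",
                 ifelse(k27, "low", "intermediate"))

  truth <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, start = genes$start,
    end = genes$end, strand = genes$strand, class = cls,
    h2az = h2az, k4 = k4, k27 = k27,
    divergent_partner = unname(partner),
    plus_one_true = as.integer(plus_one),
    minus_one_true = as.integer(minus_one),
    expressed_wt = expressed, flip = flip,
    conservation_true = cons, stringsAsFactors = FALSE)
  truth
}

# All planted dyads: promoter +1/-1 plus the gene-body array walking
# downstream from the +1, plus a short upstream array beyond the -1 (skipped
# for divergent-pair genes, whose upstream side is the partner's array).
.planted_dyads <- function(truth, cfg) {
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    g <- truth[i, ]
    d <- .dir_sign(g$strand)
    body <- seq(from = g$plus_one_true,
                by = d * cfg$nucleosome_repeat,
                length.out = max(1L, (g$end - g$start) %/%
                                   cfg$nucleosome_repeat))
    body <- body[body >= min(g$start, g$plus_one_true) &
                   body <= max(g$end, g$plus_one_true)]
    up <- g$minus_one_true
    if (is.na(g$divergent_partner) || g$divergent_partner == "")
      up <- c(up, g$minus_one_true - d * cfg$nucleosome_repeat * (1:3))
    data.frame(chrom = g$chrom, dyad = c(body, up))
  })
  dy <- do.call(rbind, rows)
  unique(dy)
}

# truncated-normal lengths via inverse CDF (exact truncation, vectorized)
.rtnorm_len <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  round(stats::qnorm(u, mean, sd))
}

#' Simulate MNase fragments from the planted nucleosome truth
#'
#' Per planted dyad, a Poisson number of fragments (mean
#' `cfg$mean_coverage`) is drawn, centered on the dyad with Gaussian jitter;
#' fragment lengths follow the truncated normal of the config. A uniform
#' background fraction is added. Deterministic for a fixed seed.
#'
#' @param truth truth table from [plant_chromatin].
#' @param cfg a [sim_config].
#' @return A [fragment_set].
#' @export
simulate_mnase <- function(truth, cfg) {
  set.seed(.component_seed(cfg, 303L))
  dy <- .planted_dyads(truth, cfg)
  counts <- stats::rpois(nrow(dy), cfg$mean_coverage)
  chrom <- rep(dy$chrom, counts)
  center <- rep(dy$dyad, counts) +
    round(stats::rnorm(sum(counts), 0, cfg$dyad_jitter_sd))
  n_sig <- length(center)
  n_bg <- round(cfg$background_fraction / (1 - cfg$background_fraction) * n_sig)
  if (n_bg > 0) {
    bg_chrom <- sprintf("chr%d", sample.int(cfg$n_chroms, n_bg, replace = TRUE))
    bg_center <- sample.int(cfg$chrom_length - 400L, n_bg, replace = TRUE) + 200L
    chrom <- c(chrom, bg_chrom)
    center <- c(center, bg_center)
  }
  len <- .rtnorm_len(length(center), cfg$frag_len_mean, cfg$frag_len_sd,
                     cfg$frag_len_range[1], cfg$frag_len_range[2])
  start <- center - len %/% 2L
  end <- start + len
  keep <- start >= 0L & end <= cfg$chrom_length
  fragment_set(chrom[keep], start[keep], end[keep])
}

# contiguous enrichment intervals for a mark, per chromosome:
# per-gene ATG windows (mark geometry) unioned with the gene body, then
# bridged across runs of adjacent marked genes (K27-style domains)
.mark_intervals <- function(truth, cfg, mark_flag, up, down, bridge) {
  marked <- truth[truth[[mark_flag]], , drop = FALSE]
  if (nrow(marked) == 0) return(NULL)
  win_s <- integer(nrow(marked)); win_e <- integer(nrow(marked))
  for (i in seq_len(nrow(marked))) {
    w <- tss_window(marked[i, c("chrom", "start", "end", "strand")],
                    up, down, chrom_length = cfg$chrom_length)
    win_s[i] <- min(w$start, marked$start[i])
    win_e[i] <- max(w$end, marked$end[i])
  }
  iv <- data.frame(chrom = marked$chrom, start = win_s, end = win_e)
  iv <- iv[order(iv$chrom, iv$start), ]
  if (bridge) {
    # merge marked intervals separated by less than one intergenic spacing
    out <- iv[1, ]
    if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
      last <- nrow(out)
      if (iv$chrom[i] == out$chrom[last] &&
          iv$start[i] - out$end[last] <= 2500L) {
        out$end[last] <- max(out$end[last], iv$end[i])
      } else out <- rbind(out, iv[i, ])
    }
    iv <- out
  }
  iv
}

#' Simulate replicate ChIP coverage tracks for one mark
#'
#' Tracks are generated directly on the CPM scale: a flat background at
#' `background_level * threshold`, raised `enrichment_fold`-fold inside the
#' planted mark intervals (cosine-smoothed 50-bp edges), with
#' scaled-Poisson noise. H3K27me3 intervals are bridged across runs of
#' adjacent marked genes into contiguous domains; H2A.Z and H3K4me3 are
#' promoter-window shaped. Replicates share the truth and differ only in
#' noise.
#'
#' @param truth truth table from [plant_chromatin].
#' @param cfg a [sim_config].
#' @param mark `"H2A.Z"`, `"H3K4me3"` or `"H3K27me3"`.
#' @param configs mark configurations (defaults [default_mark_configs]).
#' @return List of `cfg$replicates` CPM [coverage_track]s.
#' @export
simulate_chip <- function(truth, cfg, mark, configs = default_mark_configs()) {
  flag <- switch(mark, "H2A.Z" = "h2az", "H3K4me3" = "k4",
                 "H3K27me3" = "k27",
                 stop("simulate_chip: unknown mark '", mark, "'"))
  mcfg <- configs[[mark]]
  iv <- .mark_intervals(truth, cfg, flag, mcfg$upstream, mcfg$downstream,
                        bridge = (mark == "H3K27me3"))
  base <- cfg$background_level * mcfg$threshold
  high <- base * cfg$enrichment_fold
  edge <- 50L
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chroms))
  lambda <- lapply(chrom_names, function(chr) {
    lam <- rep(base, cfg$chrom_length)
    if (!is.null(iv)) {
      sub <- iv[iv$chrom == chr, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        s <- max(sub$start[i], 0L); e <- min(sub$end[i], cfg$chrom_length)
        if (e <= s) next
        prof <- rep(1, e - s)
        w <- min(edge, length(prof) %/% 2L)
        if (w > 0) {
          ramp <- (1 - cos(pi * seq_len(w) / (w + 1))) / 2
          prof[seq_len(w)] <- ramp
          prof[(length(prof) - w + 1L):length(prof)] <- rev(ramp)
        }
        seg <- (s + 1L):e
        lam[seg] <- pmax(lam[seg], base + (high - base) * prof)
      }
    }
    lam
  })
  names(lambda) <- chrom_names
  mark_k <- switch(mark, "H2A.Z" = 1L, "H3K4me3" = 2L, "H3K27me3" = 3L)
  lapply(seq_len(cfg$replicates), function(r) {
    set.seed(.component_seed(cfg, 404L + 10L * mark_k + r))
    g <- cfg$chip_granularity
    values <- lapply(lambda, function(lam) stats::rpois(length(lam), lam * g) / g)
    coverage_track(values, normalized = TRUE)
  })
}

#' Simulate an expression table from the planted truth
#'
#' Emits per-gene log2 RPKM for the wild type, the simulated H2A.Z
#' depletion, and a simulated overexpression strain, plus the
#' depletion-vs-wild-type `log2fc` and `p`. Planted flips get a strong
#' negative fold change (around -3) and a small p-value; all other genes get
#' near-zero fold changes and non-significant p-values. Differential
#' expression is emitted at the `log2fc`/`p` level, not via a count-model
#' fit.
#'
#' @param truth truth table from [plant_chromatin].
#' @param cfg a [sim_config].
#' @return A `data.frame`: `gene_id`, `rpkm_log2_wt`, `rpkm_log2_kd`,
#'   `rpkm_log2_oe`, `log2fc`, `p`.
#' @export
simulate_expression <- function(truth, cfg) {
  set.seed(.component_seed(cfg, 505L))
  n <- nrow(truth)
  base <- ifelse(truth$expressed_wt, stats::rnorm(n, 6, 1),
                 pmax(0, stats::rnorm(n, 0.5, 0.4)))
  lfc <- ifelse(truth$flip, stats::rnorm(n, -3, 0.5), stats::rnorm(n, 0, 0.3))
  p <- ifelse(truth$flip, 10^stats::runif(n, -8, -3), stats::runif(n, 0.02, 1))
  data.frame(gene_id = truth$gene_id,
             rpkm_log2_wt = base,
             rpkm_log2_kd = pmax(0, base + lfc),
             rpkm_log2_oe = base + stats::rnorm(n, 0, 0.3),
             log2fc = lfc, p = p, stringsAsFactors = FALSE)
}

#' Simulate BLAST outfmt-6 hits matching the planted conservation classes
#'
#' Per gene, a Poisson number of distinct qualifying subjects (mean 30, 150
#' or 350 for low / intermediate / high) with identities above the 40%
#' filter, plus a handful of sub-threshold rows that the identity filter
#' must discard.
#'
#' @param truth truth table from [plant_chromatin].
#' @param cfg a [sim_config].
#' @return An outfmt-6 style `data.frame` (see [read_blast_outfmt6]).
#' @export
simulate_blast_hits <- function(truth, cfg) {
  set.seed(.component_seed(cfg, 606L))
  means <- c(low = 30, intermediate = 150, high = 350)
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    g <- truth$gene_id[i]
    n_hi <- stats::rpois(1, means[[truth$conservation_true[i]]])
    n_lo <- 5L
    k <- n_hi + n_lo
    if (k == 0) return(NULL)
    data.frame(qseqid = g,
               sseqid = sprintf("%s_s%04d", g, seq_len(k)),
               pident = c(stats::runif(n_hi, 45, 95),
                          stats::runif(n_lo, 20, 39)),
               length = 200L, mismatch = 10L, gapopen = 1L,
               qstart = 1L, qend = 200L, sstart = 1L, send = 200L,
               evalue = 1e-20, bitscore = 300,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a complete synthetic dataset
#'
#' Runs annotation, chromatin planting, MNase, ChIP, expression and
#' conservation simulation under one master seed. When `out_dir` is given,
#' writes GFF3, fragment BED, per-mark per-replicate bedGraphs, expression /
#' truth TSVs and a YAML config echo.
#'
#' @param cfg a [sim_config].
#' @param out_dir optional output directory.
#' @return A list: `cfg`, `genes`, `divergent_partner`, `truth`,
#'   `fragments` (length-filtered), `mnase` (raw [coverage_track]),
#'   `chip` (mark -> list of CPM tracks), `expression`, `blast`,
#'   `chrom_lengths`.
#' @export
simulate_dataset <- function(cfg = sim_config(), out_dir = NULL) {
  ann <- generate_annotation(cfg)
  truth <- plant_chromatin(ann, cfg)
  frags_all <- simulate_mnase(truth, cfg)
  frags <- filter_fragments_by_length(frags_all, 130L, 170L)
  chrom_lengths <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                                   sprintf("chr%d", seq_len(cfg$n_chroms)))
  mnase <- fragments_to_coverage(frags, chrom_lengths)
  marks <- c("H2A.Z", "H3K4me3", "H3K27me3")
  chip <- stats::setNames(lapply(marks, function(m) simulate_chip(truth, cfg, m)),
                          marks)
  expression <- simulate_expression(truth, cfg)
  blast <- simulate_blast_hits(truth, cfg)
  out <- list(cfg = cfg, genes = ann$genes,
              divergent_partner = ann$divergent_partner, truth = truth,
              fragments = frags, mnase = mnase, chip = chip,
              expression = expression, blast = blast,
              chrom_lengths = chrom_lengths)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gff3(ann$genes, file.path(out_dir, "genes.gff3"))
    write_bed_fragments(frags, file.path(out_dir, "mnase_fragments.bed"))
    write_bedgraph(mnase, file.path(out_dir, "mnase_coverage.bedgraph"))
    for (m in marks) for (r in seq_along(chip[[m]]))
      write_bedgraph(chip[[m]][[r]],
                     file.path(out_dir, sprintf("chip_%s_rep%d.bedgraph",
                                                gsub("[^A-Za-z0-9]", "", m), r)))
    utils::write.table(expression, file.path(out_dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(blast, file.path(out_dir, "blast_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    cfg_plain <- unclass(cfg)
    cfg_plain <- lapply(cfg_plain, function(x)
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)
    yaml::write_yaml(cfg_plain, file.path(out_dir, "sim_config.yaml"))
  }
  out
}
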