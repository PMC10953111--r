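# Per-gene integration of chromatin, expression and conservation evidence:
# the join behind the co-occupancy, DE-class, +1-anchored profile and
# conservation summaries.

#' Log2 RPKM
#'
#' `log2(count / (gene_length/1000) / (library_size/1e6) + pseudocount)`.
#' The pseudocount (default 1) keeps zero counts finite.
#'
#' @param count read count for the gene.
#' @param gene_length exonic length in bp (> 0).
#' @param library_size total library reads (> 0).
#' @param pseudocount added before taking log2.
#' @return log2 RPKM (vectorized over `count`/`gene_length`).
#' @export
rpkm_log2 <- function(count, gene_length, library_size, pseudocount = 1) {
  if (any(gene_length <= 0)) stop("rpkm_log2: gene_length must be > 0")
  if (any(library_size <= 0)) stop("rpkm_log2: library_size must be > 0")
  rpkm <- count / (gene_length / 1000) / (library_size / 1e6)
  log2(rpkm + pseudocount)
}

#' Classify differential expression
#'
#' `up` iff `log2fc >= 1` and `p < 0.01`; `down` iff `log2fc <= -1` and
#' `p < 0.01`; `ns` otherwise. The boundary `|log2fc| = 1` counts as
#' significant.
#'
#' @param log2fc log2 fold change(s).
#' @param p p-value(s) in `[0, 1]`.
#' @param lfc_cut absolute log2 fold-change cutoff (default 1).
#' @param p_cut p-value cutoff (default 0.01).
#' @return Character vector in `{"up", "down", "ns"}`.
#' @export
classify_de <- function(log2fc, p, lfc_cut = 1, p_cut = 0.01) {
  if (anyNA(p) || anyNA(log2fc))
    stop("classify_de: log2fc and p must be present")
  if (any(p < 0 | p > 1)) stop("classify_de: p must be in [0, 1]")
  out <- rep("ns", length(log2fc))
  out[log2fc >= lfc_cut & p < p_cut] <- "up"
  out[log2fc <= -lfc_cut & p < p_cut] <- "down"
  out
}

#' Venn region counts for two or three gene sets
#'
#' @param setA,setB,setC character vectors of gene ids (`setC` optional).
#' @return Named list of disjoint-region counts. Two sets:
#'   `A_only`, `B_only`, `AB`. Three sets: `A_only`, `B_only`, `C_only`,
#'   `AB_only`, `AC_only`, `BC_only`, `ABC`. Plus `total = |union|`.
#' @export
venn_counts <- function(setA, setB, setC = NULL) {
  A <- unique(as.character(setA)); B <- unique(as.character(setB))
  if (is.null(setC)) {
    ab <- intersect(A, B)
    out <- list(A_only = length(setdiff(A, B)),
                B_only = length(setdiff(B, A)),
                AB = length(ab))
    out$total <- length(union(A, B))
    return(out)
  }
  C <- unique(as.character(setC))
  inA <- function(x) x %in% A; inB <- function(x) x %in% B; inC <- function(x) x %in% C
  u <- union(union(A, B), C)
  key <- paste0(as.integer(inA(u)), as.integer(inB(u)), as.integer(inC(u)))
  cnt <- function(k) sum(key == k)
  list(A_only = cnt("100"), B_only = cnt("010"), C_only = cnt("001"),
       AB_only = cnt("110"), AC_only = cnt("101"), BC_only = cnt("011"),
       ABC = cnt("111"), total = length(u))
}

#' Fraction of a reference gene set carrying a mark
#'
#' `|reference ∩ mark| / |reference|` — e.g. the fraction of H2A.Z-marked
#' genes that lie in H3K27me3 domains.
#'
#' @param reference_set non-empty character vector of gene ids.
#' @param mark_set character vector of gene ids.
#' @return A fraction in `[0, 1]`.
#' @export
co_occupancy_fraction <- function(reference_set, mark_set) {
  ref <- unique(as.character(reference_set))
  if (length(ref) == 0) stop("co_occupancy_fraction: empty reference set")
  length(intersect(ref, unique(as.character(mark_set)))) / length(ref)
}

#' +1-anchored per-gene enrichment matrix
#'
#' Row g holds the per-bp coverage over
#' `[plus_one - flank_up, plus_one + flank_down)` read in transcription
#' orientation (so column 1 is always `flank_up` bp upstream of the +1
#' nucleosome). Rows are sorted by ascending gene length; positions off the
#' chromosome are `NA`. Genes without a +1 call are excluded; their count is
#' reported in the `"n_excluded"` attribute.
#'
#' @param track a [coverage_track].
#' @param calls per-gene call table from [call_plus_one_all].
#' @param genes a [gene_model] data frame.
#' @param flank_up,flank_down flank sizes in bp (defaults 1000 and 5000).
#' @return Numeric matrix, `rownames` = gene ids, with attribute
#'   `n_excluded`.
#' @export
enrichment_matrix <- function(track, calls, genes, flank_up = 1000L,
                              flank_down = 5000L) {
  m <- merge(genes, calls[, c("gene_id", "plus_one_pos")], by = "gene_id")
  n_excluded <- sum(is.na(m$plus_one_pos))
  m <- m[!is.na(m$plus_one_pos), , drop = FALSE]
  m <- m[order(m$end - m$start, m$gene_id), , drop = FALSE]
  width <- flank_up + flank_down
  mat <- matrix(NA_real_, nrow = nrow(m), ncol = width,
                dimnames = list(m$gene_id, NULL))
  offs <- seq.int(-flank_up, flank_down - 1L)
  for (i in seq_len(nrow(m))) {
    v <- track$values[[m$chrom[i]]]
    pos <- if (m$strand[i] == "+") m$plus_one_pos[i] + offs
           else m$plus_one_pos[i] - offs
    ok <- pos >= 0 & pos < length(v)
    row <- rep(NA_real_, width)
    row[ok] <- v[pos[ok] + 1L]
    mat[i, ] <- row
  }
  attr(mat, "n_excluded") <- n_excluded
  mat
}

#' Binned median profile of an anchored matrix
#'
#' Columns are grouped into consecutive bins of `bin_width` bp; each bin's
#' value is the median over all rows and positions in the bin, `NA` cells
#' ignored (an all-`NA` bin yields `NA`).
#'
#' @param mat matrix from [enrichment_matrix].
#' @param bin_width bin size in bp (default 21).
#' @return Numeric vector, one value per bin.
#' @export
median_profile <- function(mat, bin_width = 21L) {
  if (bin_width < 1) stop("median_profile: bin_width must be >= 1")
  nb <- ceiling(ncol(mat) / bin_width)
  vapply(seq_len(nb), function(b) {
    cols <- seq.int((b - 1L) * bin_width + 1L, min(b * bin_width, ncol(mat)))
    vals <- mat[, cols]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) NA_real_ else stats::median(vals)
  }, numeric(1))
}

#' Read BLAST tabular (outfmt 6) hits
#'
#' Standard 12-column tab-separated output: qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path path to the TSV.
#' @return A `data.frame` with those columns (zero rows for an empty file).
#' @export
read_blast_outfmt6 <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (file.size(path) == 0) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), 12), cols))
    return(df)
  }
  df <- tryCatch(
    utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                      col.names = cols),
    error = function(e) stop("malformed BLAST outfmt-6 table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!is.numeric(df$pident))
    stop("malformed BLAST outfmt-6 table: non-numeric percent identity")
  df
}

#' Conservation class from BLAST hit counts
#'
#' Hits are rows above the identity cutoff, counted as distinct subjects.
#' Fewer than `low_cut` hits is `low`, more than `high_cut` is `high`,
#' otherwise `intermediate`.
#'
#' @param blast_rows a `data.frame` with columns `sseqid` and `pident`
#'   (e.g. from [read_blast_outfmt6]), holding the hits of one query.
#' @param min_identity percent-identity cutoff (default 40; hits must exceed
#'   it).
#' @param low_cut,high_cut hit-count cutoffs (defaults 50 and 300).
#' @return A list with `class` (`"low"`, `"intermediate"`, `"high"`) and
#'   `hit_count`.
#' @export
classify_conservation <- function(blast_rows, min_identity = 40,
                                  low_cut = 50L, high_cut = 300L) {
  if (!all(c("sseqid", "pident") %in% names(blast_rows)))
    stop("classify_conservation: need sseqid and pident columns")
  keep <- blast_rows$pident > min_identity
  hits <- length(unique(blast_rows$sseqid[keep]))
  cls <- if (hits < low_cut) "low" else if (hits > high_cut) "high" else "intermediate"
  list(class = cls, hit_count = hits)
}

#' Conservation classes for every query in a BLAST table
#'
#' @param blast a full outfmt-6 `data.frame` (column `qseqid` keys genes).
#' @inheritParams classify_conservation
#' @return A `data.frame` with `gene_id`, `hit_count`, `conservation`.
#' @export
classify_conservation_all <- function(blast, min_identity = 40,
                                      low_cut = 50L, high_cut = 300L) {
  ids <- unique(blast$qseqid)
  rows <- lapply(ids, function(g) {
    r <- classify_conservation(blast[blast$qseqid == g, , drop = FALSE],
                               min_identity, low_cut, high_cut)
    data.frame(gene_id = g, hit_count = r$hit_count, conservation = r$class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Join all per-gene evidence into one chromatin table
#'
#' One row per annotated gene: occupancy flags for the three marks, +1
#' presence and bidirectionality, expression (log2 RPKM per strain, log2FC,
#' p, DE class) and conservation class. Genes missing from an evidence table
#' keep their row with `NA` in the corresponding columns.
#'
#' @param genes a [gene_model] data frame.
#' @param occupancy table from [call_all].
#' @param plusone_calls table from [call_plus_one_all].
#' @param expression `data.frame` with `gene_id`, optional
#'   `rpkm_log2_wt` / `rpkm_log2_kd` / `rpkm_log2_oe`, `log2fc`, `p`.
#' @param conservation optional table from [classify_conservation_all].
#' @return A `data.frame` of class `gene_chromatin_table`, plus a
#'   `"strata"` attribute with counts by (H2A.Z, H3K27me3, DE class).
#' @export
build_gene_table <- function(genes, occupancy, plusone_calls, expression,
                             conservation = NULL) {
  for (nm in list(genes = genes, plusone = plusone_calls,
                  expression = expression)) {
    if (anyDuplicated(nm$gene_id))
      stop("build_gene_table: duplicate gene_id within an input table")
  }
  tab <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = genes$start, end = genes$end,
                    strand = genes$strand, stringsAsFactors = FALSE)
  occ_flag <- function(mark, col = "positive") {
    sub <- occupancy[occupancy$mark == mark, , drop = FALSE]
    if (anyDuplicated(sub$gene_id))
      stop("build_gene_table: duplicate gene_id in occupancy for ", mark)
    sub[[col]][match(tab$gene_id, sub$gene_id)]
  }
  tab$H2A.Z <- occ_flag("H2A.Z")
  tab$H2A.Z_negative <- occ_flag("H2A.Z", "negative_class")
  tab$H3K4me3 <- occ_flag("H3K4me3")
  tab$H3K27me3 <- occ_flag("H3K27me3")
  i <- match(tab$gene_id, plusone_calls$gene_id)
  tab$plus_one_present <- !is.na(plusone_calls$plus_one_pos[i])
  tab$plus_one_present[is.na(i)] <- NA
  tab$bidirectional <- plusone_calls$bidirectional[i]
  j <- match(tab$gene_id, expression$gene_id)
  for (col in intersect(c("rpkm_log2_wt", "rpkm_log2_kd", "rpkm_log2_oe",
                          "log2fc", "p"), names(expression)))
    tab[[col]] <- expression[[col]][j]
  tab$de_class <- NA_character_
  has_expr <- !is.na(j)
  if (any(has_expr))
    tab$de_class[has_expr] <- classify_de(expression$log2fc[j[has_expr]],
                                          expression$p[j[has_expr]])
  if (!is.null(conservation)) {
    if (anyDuplicated(conservation$gene_id))
      stop("build_gene_table: duplicate gene_id in conservation table")
    k <- match(tab$gene_id, conservation$gene_id)
    tab$hit_count <- conservation$hit_count[k]
    tab$conservation <- conservation$conservation[k]
  }
  strata <- as.data.frame(table(
    H2A.Z = tab$H2A.Z, H3K27me3 = tab$H3K27me3, de_class = tab$de_class,
    useNA = "ifany"))
  attr(tab, "strata") <- strata
  class(tab) <- c("gene_chromatin_table", "data.frame")
  tab
}

#' Write the gene chromatin table as TSV
#' @param tab table from [build_gene_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
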