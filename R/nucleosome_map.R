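# Nucleosome map construction: differential-filter peak calling on MNase
# coverage, +1/-1-nucleosome and NDR detection, bidirectional-promoter flags.

#' Differential-filter parameters
#'
#' The peak caller convolves the coverage trace with an antisymmetric
#' difference-of-means kernel of size `2 * half_width + 1` (151 by default,
#' coefficient 1/150): the mean of the `half_width` positions to the right
#' minus the mean of the `half_width` positions to the left. Coverage maxima
#' then show up as descents of the filtered trace through zero.
#'
#' @param half_width half-width of the kernel in bp (default 75).
#' @return A list with `half_width`, `coeff`, `kernel_size`.
#' @export
filter_params <- function(half_width = 75L) {
  half_width <- as.integer(half_width)
  stopifnot(half_width >= 1)
  list(half_width = half_width, coeff = 1 / (2 * half_width),
       kernel_size = 2L * half_width + 1L)
}

#' Apply the differential filter to a per-bp coverage vector
#'
#' `f(i) = coeff * (sum_{j=1..hw} cov(i+j) - sum_{j=1..hw} cov(i-j))`.
#' Positions within `half_width` of either chromosome end are undefined and
#' returned as `NA`; no peak is ever called there.
#'
#' @param cov numeric per-bp coverage vector.
#' @param params a [filter_params] list.
#' @return Numeric vector of the same length, `NA` where undefined.
#' @export
differential_filter <- function(cov, params = filter_params()) {
  n <- length(cov)
  hw <- params$half_width
  if (n <= params$kernel_size)
    stop("coverage vector (", n, " bp) must be longer than the kernel (",
         params$kernel_size, " bp)")
  S <- c(0, cumsum(cov))                          # S[k+1] = sum cov[1..k]
  out <- rep(NA_real_, n)
  i <- seq.int(hw + 1L, n - hw)                   # defined positions (1-based)
  right <- S[i + hw + 1L] - S[i + 1L]             # cov[i+1 .. i+hw]
  left <- S[i] - S[i - hw]                        # cov[i-hw .. i-1]
  out[i] <- params$coeff * (right - left)
  out
}

#' Locate nucleosome peaks as descending zero-crossings
#'
#' A peak is called at every position where the filtered trace is `>= 0` and
#' the next position is `< 0` (on an exact-zero plateau this picks the last
#' index of the non-negative run, deterministically). The peak height is the
#' value of the original, unfiltered coverage at that position.
#'
#' @param filtered output of [differential_filter] (may contain `NA`).
#' @param cov the original coverage vector, aligned with `filtered`.
#' @param chrom chromosome name recorded in the output.
#' @return A `data.frame` with columns `chrom`, `pos` (0-based bp),
#'   `height`, ordered by `pos`.
#' @export
locate_peaks <- function(filtered, cov, chrom = "chr") {
  stopifnot(length(filtered) == length(cov))
  f <- filtered
  n <- length(f)
  a <- f[-n]
  b <- f[-1]
  hit <- which(!is.na(a) & !is.na(b) & a >= 0 & b < 0)
  data.frame(chrom = rep(chrom, length(hit)), pos = hit - 1L,
             height = cov[hit], stringsAsFactors = FALSE)
}

#' Call nucleosome peaks genome-wide
#'
#' Runs [differential_filter] and [locate_peaks] on every chromosome of a
#' coverage track.
#'
#' @param track a [coverage_track] (raw MNase coverage for the reads/bp
#'   height convention, or CPM for ChIP peak heights).
#' @param params a [filter_params] list.
#' @return A `data.frame` of peaks (`chrom`, `pos`, `height`).
#' @export
call_nucleosomes <- function(track, params = filter_params()) {
  out <- lapply(names(track$values), function(chr) {
    v <- track$values[[chr]]
    locate_peaks(differential_filter(v, params), v, chr)
  })
  do.call(rbind, out)
}

#' Parameters for +1-nucleosome / NDR detection
#'
#' Defaults follow the promoter-scan rules used throughout this package:
#' peaks below 20 reads/bp are discarded up front; starting 100 bp downstream
#' of the ATG the scan walks upstream (in transcription orientation) up to
#' 2 kb, looking for the first adjacent peak pair whose center-to-center
#' distance exceeds 200 bp, whose gene-side peak exceeds the height cutoff,
#' and whose inter-peak valley holds more than 20 bp below
#' `min + 0.1 * (max - min)` of the region's coverage.
#'
#' @param min_peak_height minimal peak height (reads/bp or CPM, matching the
#'   units of the coverage handed to the caller).
#' @param search_start_offset scan start, bp downstream of the ATG.
#' @param search_limit scan end, bp upstream of the ATG.
#' @param min_peak_distance minimal center-to-center peak distance (bp).
#' @param valley_rel_fraction relative depth defining "low" valley coverage.
#' @param min_valley_bp minimal number of low-coverage bp in the valley.
#' @return A parameter list.
#' @export
plus_one_params <- function(min_peak_height = 20, search_start_offset = 100L,
                            search_limit = 2000L, min_peak_distance = 200L,
                            valley_rel_fraction = 0.1, min_valley_bp = 20L) {
  stopifnot(min_peak_height > 0, search_start_offset > 0, search_limit > 0,
            min_peak_distance > 0, valley_rel_fraction > 0, min_valley_bp > 0)
  list(min_peak_height = min_peak_height,
       search_start_offset = as.integer(search_start_offset),
       search_limit = as.integer(search_limit),
       min_peak_distance = as.integer(min_peak_distance),
       valley_rel_fraction = valley_rel_fraction,
       min_valley_bp = as.integer(min_valley_bp))
}

# Transcription-orientation offset of 0-based positions relative to the ATG.
# For '+' the anchor is gene start; for '-' it is the last gene base
# (gene end - 1), so that mirroring the genome mirrors the offsets exactly.
.atg_offset <- function(pos, gene) {
  if (gene$strand == "+") pos - gene$start else (gene$end - 1L) - pos
}

#' Find the +1 nucleosome, -1 nucleosome and NDR of one gene
#'
#' Scans the height-filtered peak list upstream from `ATG + 100` (in
#' transcription orientation) for the first adjacent pair bounding a
#' qualifying nucleosome-depleted region; see [plus_one_params] for the three
#' acceptance rules. The gene-side flanking peak of that pair is the
#' +1 nucleosome, the far-side peak the -1 nucleosome, and the open interval
#' between their centers the NDR. A gene with no qualifying pair gets an
#' absent (NULL) call, not an error.
#'
#' @param peaks genome-wide peak table from [call_nucleosomes].
#' @param cov the unfiltered coverage: a [coverage_track] or, for a
#'   single-chromosome call, a numeric vector.
#' @param gene one gene (single-row [gene_model] or list).
#' @param params a [plus_one_params] list.
#' @return A list of class `plus_one_call`: `gene_id`, `chrom`, `strand`,
#'   `plus_one` / `minus_one` (each `NULL` or a list `pos`, `height`),
#'   `ndr` (`NULL` or a `genomic_window`), `bidirectional` (always `FALSE`
#'   here; see [flag_bidirectional]).
#' @export
find_plus_one <- function(peaks, cov, gene, params = plus_one_params()) {
  if (is.data.frame(gene)) { stopifnot(nrow(gene) == 1); gene <- as.list(gene) }
  v <- if (inherits(cov, "coverage_track")) cov$values[[gene$chrom]] else cov
  if (is.null(v)) stop("no coverage for chromosome ", gene$chrom)

  empty <- structure(list(gene_id = gene$gene_id, chrom = gene$chrom,
                          strand = gene$strand, plus_one = NULL,
                          minus_one = NULL, ndr = NULL,
                          bidirectional = FALSE),
                     class = "plus_one_call")

  p <- peaks[peaks$chrom == gene$chrom &
               peaks$height >= params$min_peak_height, , drop = FALSE]
  if (nrow(p) < 2) return(empty)
  off <- .atg_offset(p$pos, gene)
  ord <- order(off, decreasing = TRUE)           # downstream -> upstream
  p <- p[ord, , drop = FALSE]
  off <- off[ord]

  n <- nrow(p)
  for (k in seq_len(n - 1L)) {
    down <- k; up <- k + 1L
    if (off[down] > params$search_start_offset) next
    if (off[up] < -params$search_limit) break
    dist <- abs(p$pos[down] - p$pos[up])
    if (dist <= params$min_peak_distance) next
    if (p$height[down] <= params$min_peak_height) next
    lo <- min(p$pos[down], p$pos[up]); hi <- max(p$pos[down], p$pos[up])
    if (hi - lo < 2) next
    region <- v[(lo + 2L):hi]                    # strictly between centers
    thr <- min(region) + params$valley_rel_fraction * (max(region) - min(region))
    if (sum(region < thr) <= params$min_valley_bp) next
    ndr <- structure(list(chrom = gene$chrom, start = lo + 1L, end = hi,
                          strand = gene$strand, oriented = TRUE),
                     class = "genomic_window")
    out <- empty
    out$plus_one <- list(pos = p$pos[down], height = p$height[down])
    out$minus_one <- list(pos = p$pos[up], height = p$height[up])
    out$ndr <- ndr
    return(out)
  }
  empty
}

#' Find the -1 nucleosome of one gene
#'
#' The NDR-flanking nucleosome facing away from the gene start, i.e. the
#' far-side member of the same qualifying peak pair found by [find_plus_one].
#'
#' @inheritParams find_plus_one
#' @return `NULL` or a list with `pos` and `height`.
#' @export
find_minus_one <- function(peaks, cov, gene, params = plus_one_params()) {
  find_plus_one(peaks, cov, gene, params)$minus_one
}

#' Call +1/-1/NDR for every gene
#'
#' @param peaks genome-wide peak table from [call_nucleosomes].
#' @param track the unfiltered [coverage_track].
#' @param genes a [gene_model] data frame.
#' @param params a [plus_one_params] list.
#' @param bidirectional_tolerance bp tolerance for [flag_bidirectional];
#'   `NULL` skips flagging.
#' @return A `data.frame` with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `plus_one_pos`, `plus_one_height`, `minus_one_pos`, `minus_one_height`,
#'   `ndr_start`, `ndr_end`, `bidirectional` (absent calls are `NA`).
#' @export
call_plus_one_all <- function(peaks, track, genes, params = plus_one_params(),
                              bidirectional_tolerance = 50L) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    call <- find_plus_one(peaks, track, genes[i, ], params)
    data.frame(
      gene_id = call$gene_id, chrom = call$chrom, strand = call$strand,
      plus_one_pos = if (is.null(call$plus_one)) NA_integer_ else call$plus_one$pos,
      plus_one_height = if (is.null(call$plus_one)) NA_real_ else call$plus_one$height,
      minus_one_pos = if (is.null(call$minus_one)) NA_integer_ else call$minus_one$pos,
      minus_one_height = if (is.null(call$minus_one)) NA_real_ else call$minus_one$height,
      ndr_start = if (is.null(call$ndr)) NA_integer_ else call$ndr$start,
      ndr_end = if (is.null(call$ndr)) NA_integer_ else call$ndr$end,
      bidirectional = FALSE, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  if (!is.null(bidirectional_tolerance))
    calls <- flag_bidirectional(calls, tolerance = bidirectional_tolerance)
  calls
}

#' Flag +1 nucleosomes of bidirectional promoters
#'
#' Two divergently oriented genes share a promoter nucleosome when the -1
#' nucleosome of one coincides (within `tolerance`) with the +1 nucleosome of
#' the other; both calls are then flagged.
#'
#' @param calls per-gene call table from [call_plus_one_all].
#' @param tolerance positional tolerance in bp (default 50).
#' @return `calls` with the `bidirectional` column updated.
#' @export
flag_bidirectional <- function(calls, tolerance = 50L) {
  flag <- rep(FALSE, nrow(calls))
  has_m <- !is.na(calls$minus_one_pos)
  has_p <- !is.na(calls$plus_one_pos)
  for (i in which(has_m)) {
    j <- which(has_p &
                 calls$chrom == calls$chrom[i] &
                 calls$strand != calls$strand[i] &
                 calls$gene_id != calls$gene_id[i] &
                 abs(calls$plus_one_pos - calls$minus_one_pos[i]) <= tolerance)
    if (length(j) > 0) { flag[i] <- TRUE; flag[j] <- TRUE }
  }
  calls$bidirectional <- flag
  calls
}

#' Write a per-gene +1/-1/NDR table as TSV
#' @param calls table from [call_plus_one_all].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plus_one_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
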