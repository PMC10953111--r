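# Core containers and standard-format I/O.
#
# Internal coordinate convention: 0-based, half-open [start, end), so that
# interval arithmetic (lengths, overlaps, mirroring) needs no +/-1 bookkeeping.
# GFF3 (1-based inclusive) and the 1-based IRanges machinery are converted at
# the boundary.

#' Construct a gene model table
#'
#' A gene model is a data frame with one row per annotated gene, using 0-based
#' half-open coordinates and an explicit strand. The gene start on the coding
#' strand (`start` for `+`, `end` for `-`) is the ATG anchor used by all
#' promoter-window operations.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open span (`start < end`).
#' @param strand character vector, `"+"` or `"-"`.
#' @return A `data.frame` of class `gene_model` with columns
#'   `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @examples
#' gene_model("g1", "chr1", 100L, 200L, "+")
#' @export
gene_model <- function(gene_id, chrom, start, end, strand) {
  gene_id <- as.character(gene_id)
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  strand <- as.character(strand)
  n <- length(gene_id)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(strand) == 1L) strand <- rep(strand, n)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n,
            length(strand) == n)
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (any(start >= end))
    stop("gene_model requires start < end for all genes")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                   end = end, strand = strand, stringsAsFactors = FALSE)
  class(df) <- c("gene_model", "data.frame")
  df
}

#' Read gene models from a GFF3 file
#'
#' Imports `gene`-type features and converts their 1-based inclusive
#' coordinates to the internal 0-based half-open convention. The `ID`
#' attribute becomes `gene_id` and must be unique.
#'
#' @param path path to a GFF3 file.
#' @return A [gene_model] data frame (zero rows for an empty file).
#' @export
read_gff3 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("failed to parse GFF3 '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(gr) == 0)
    return(gene_model(character(), character(), integer(), integer(),
                      character()))
  if ("type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) == "gene"]
  if (length(gr) == 0)
    return(gene_model(character(), character(), integer(), integer(),
                      character()))
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(ids == ""))
    stop("GFF3 gene features must carry an ID attribute")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop("GFF3 gene features must be stranded")
  gene_model(ids, as.character(GenomicRanges::seqnames(gr)),
             BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr), strand)
}

#' Write gene models to a GFF3 file
#'
#' @param genes a [gene_model] data frame.
#' @param path output path.
#' @param source source field for column 2 (default `"nucposer"`).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "nucposer") {
  lines <- "##gff-version 3"
  if (nrow(genes) > 0) {
    lines <- c(lines, sprintf(
      "%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      genes$chrom, source, genes$start + 1L, genes$end,
      genes$strand, genes$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a fragment set
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @return A `data.frame` of class `fragment_set` with a `length` column.
#' @export
fragment_set <- function(chrom, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start >= end)) stop("fragments must satisfy start < end")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   length = end - start, stringsAsFactors = FALSE)
  class(df) <- c("fragment_set", "data.frame")
  df
}

#' Read fragments from a BED file
#'
#' BED is already 0-based half-open; only the first three columns are used.
#'
#' @param path path to a BED file.
#' @return A [fragment_set].
#' @export
read_bed_fragments <- function(path) {
  if (file.size(path) == 0)
    return(fragment_set(character(), integer(), integer()))
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  fragment_set(bed[[1]], bed[[2]], bed[[3]])
}

#' Write fragments as BED3
#'
#' @param frags a [fragment_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_fragments <- function(frags, path) {
  utils::write.table(frags[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Filter fragments by length
#'
#' Retains fragments with `lo <= length <= hi`, both bounds inclusive. The
#' mononucleosomal band used throughout this package is 130--170 bp.
#'
#' @param frags a [fragment_set].
#' @param lo,hi inclusive length bounds in bp.
#' @return The filtered [fragment_set].
#' @export
filter_fragments_by_length <- function(frags, lo = 130L, hi = 170L) {
  if (lo > hi) stop("filter_fragments_by_length: lo must be <= hi")
  keep <- frags$length >= lo & frags$length <= hi
  out <- frags[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fragment_set", "data.frame")
  out
}

#' Construct a coverage track
#'
#' A coverage track holds one non-negative per-bp numeric vector per
#' chromosome, plus the normalization state. Units are reads/bp when raw and
#' CPM/bp once [normalize_cpm] has been applied.
#'
#' @param values named list of per-bp numeric vectors, one per chromosome.
#' @param normalized logical; `TRUE` once CPM-scaled.
#' @param total_fragments fragment (or read-pair) count behind the track;
#'   the CPM denominator. `NA` if unknown.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, normalized = FALSE, total_fragments = NA_real_) {
  stopifnot(is.list(values), !is.null(names(values)))
  for (chr in names(values)) {
    v <- values[[chr]]
    if (!is.numeric(v)) stop("coverage values must be numeric (", chr, ")")
    if (any(v < 0, na.rm = TRUE)) stop("coverage values must be >= 0 (", chr, ")")
  }
  structure(list(values = values,
                 chrom_lengths = vapply(values, length, integer(1)),
                 normalized = isTRUE(normalized),
                 total_fragments = as.numeric(total_fragments)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$values), "chromosome(s),",
      sum(x$chrom_lengths), "bp total,",
      if (x$normalized) "CPM-normalized" else "raw", "\n")
  invisible(x)
}

#' Pile fragments up into per-bp coverage
#'
#' The value at position p is the number of fragments whose half-open span
#' contains p. Pileup is delegated to `IRanges::coverage`.
#'
#' @param frags a [fragment_set].
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return A raw (un-normalized) [coverage_track] with `total_fragments` set
#'   to `nrow(frags)`.
#' @export
fragments_to_coverage <- function(frags, chrom_lengths) {
  stopifnot(!is.null(names(chrom_lengths)))
  bad <- !(frags$chrom %in% names(chrom_lengths)) |
    frags$start < 0 |
    frags$end > chrom_lengths[frags$chrom]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("fragment outside chromosome bounds: %s:%d-%d",
                 frags$chrom[i], frags$start[i], frags$end[i]))
  }
  values <- lapply(names(chrom_lengths), function(chr) {
    f <- frags[frags$chrom == chr, , drop = FALSE]
    if (nrow(f) == 0) return(numeric(chrom_lengths[[chr]]))
    ir <- IRanges::IRanges(start = f$start + 1L, end = f$end)
    as.numeric(IRanges::coverage(ir, width = chrom_lengths[[chr]]))
  })
  names(values) <- names(chrom_lengths)
  coverage_track(values, normalized = FALSE, total_fragments = nrow(frags))
}

#' Normalize a coverage track to counts per million (CPM)
#'
#' Every per-bp value is multiplied by `1e6 / total_fragments`. The
#' denominator is supplied explicitly (filtered fragments for MNase, mapped
#' read pairs for ChIP). Normalizing an already-normalized track is an error.
#'
#' @param track a raw [coverage_track].
#' @param total_fragments positive count; defaults to the track's own
#'   `total_fragments`.
#' @return A CPM-normalized [coverage_track].
#' @export
normalize_cpm <- function(track, total_fragments = track$total_fragments) {
  if (track$normalized) stop("track is already CPM-normalized")
  if (is.na(total_fragments) || total_fragments <= 0)
    stop("total_fragments must be a positive count")
  scale <- 1e6 / total_fragments
  values <- lapply(track$values, function(v) v * scale)
  coverage_track(values, normalized = TRUE, total_fragments = total_fragments)
}

#' Read a bedGraph coverage file
#'
#' bedGraph intervals are 0-based half-open; positions not covered by any
#' interval get value 0. Chromosome lengths must be declared because bedGraph
#' carries none.
#'
#' @param path path to a bedGraph file.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param normalized logical; whether the file stores CPM values.
#' @param total_fragments optional CPM denominator to record.
#' @return A [coverage_track].
#' @export
read_bedgraph <- function(path, chrom_lengths, normalized = FALSE,
                          total_fragments = NA_real_) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  values <- lapply(names(chrom_lengths), function(chr) {
    v <- numeric(chrom_lengths[[chr]])
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
    if (length(sub) > 0) {
      w <- BiocGenerics::width(sub)
      idx <- sequence(w, from = BiocGenerics::start(sub))  # 1-based
      v[idx] <- rep(sub$score, w)
    }
    v
  })
  names(values) <- names(chrom_lengths)
  track <- coverage_track(values, normalized = FALSE,
                          total_fragments = total_fragments)
  track$normalized <- isTRUE(normalized)
  track
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are collapsed into intervals; zero runs are omitted.
#'
#' @param track a [coverage_track].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$values)) {
    r <- rle(track$values[[chr]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths        # 0-based starts
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", chr, starts[keep], ends[keep],
                         format(r$values[keep], digits = 15, trim = TRUE,
                                scientific = FALSE)),
                 con)
    }
  }
  invisible(path)
}

#' Strand-aware promoter window around the ATG
#'
#' For a `+` gene anchored at `start`, the window is
#' `[start - upstream, start + downstream)`; for a `-` gene anchored at `end`
#' it is the mirrored `[end - downstream, end + upstream)`. The window is
#' clipped to chromosome bounds when a length is supplied; a window that falls
#' entirely off the chromosome comes back empty (`start == end`).
#'
#' @param gene one gene: a single-row [gene_model] or a list with
#'   `chrom`, `start`, `end`, `strand`.
#' @param upstream,downstream non-negative extents in bp, measured in the
#'   direction of transcription.
#' @param chrom_length optional chromosome length for clipping.
#' @return A list of class `genomic_window` with `chrom`, `start`, `end`,
#'   `strand`, `oriented = TRUE`.
#' @export
tss_window <- function(gene, upstream, downstream, chrom_length = NULL) {
  if (upstream < 0 || downstream < 0)
    stop("upstream and downstream must be >= 0")
  if (is.data.frame(gene)) {
    stopifnot(nrow(gene) == 1)
    gene <- as.list(gene)
  }
  if (gene$strand == "+") {
    s <- gene$start - upstream
    e <- gene$start + downstream
  } else {
    s <- gene$end - downstream
    e <- gene$end + upstream
  }
  if (!is.null(chrom_length)) {
    s <- max(s, 0)
    e <- min(e, chrom_length)
  } else {
    s <- max(s, 0)
  }
  if (e < s) { s <- min(s, e) ; e <- s }
  structure(list(chrom = gene$chrom, start = as.integer(s),
                 end = as.integer(e), strand = gene$strand, oriented = TRUE),
            class = "genomic_window")
}

#' Is a window empty?
#' @param win a `genomic_window`.
#' @return logical.
#' @export
window_is_empty <- function(win) win$end <= win$start

#' Extract per-bp values over a window
#'
#' Values come back in transcription orientation when the window is oriented
#' and lies on the minus strand. Positions outside the chromosome are `NA`
#' (only possible when `clip = FALSE`).
#'
#' @param track a [coverage_track].
#' @param win a `genomic_window`.
#' @param clip if `TRUE` (default) the window is clipped to the chromosome;
#'   if `FALSE` out-of-bounds positions yield `NA`.
#' @return Numeric vector of per-bp values.
#' @export
extract_window <- function(track, win, clip = TRUE) {
  v <- track$values[[win$chrom]]
  if (is.null(v)) stop("window chromosome not in track: ", win$chrom)
  L <- length(v)
  s <- win$start; e <- win$end
  if (clip) { s <- max(s, 0); e <- min(e, L) }
  if (e <= s) return(numeric(0))
  pos <- seq.int(s, e - 1L)              # 0-based
  out <- rep(NA_real_, length(pos))
  ok <- pos >= 0 & pos < L
  out[ok] <- v[pos[ok] + 1L]
  if (isTRUE(win$oriented) && identical(win$strand, "-")) out <- rev(out)
  out
}

#' Read a two-column chromosome-sizes table
#' @param path TSV with columns chrom, length (no header).
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab[[2]]), as.character(tab[[1]]))
}
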