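# Threshold-based ChIP occupancy calling in strand-aware ATG windows.
#
# One mark = one window geometry + one CPM threshold + a replicate rule.
# A gene is positive for a mark when the maximum CPM coverage inside its
# window reaches the threshold in all required replicates.

#' Per-mark occupancy-calling configuration
#'
#' Defaults for the three marks analysed here:
#' \itemize{
#'   \item H2A.Z: 200 bp upstream / 600 bp downstream of the ATG,
#'     threshold 15 CPM in both replicates; genes below 7.5 CPM in every
#'     replicate form the explicit negative class.
#'   \item H3K4me3: 200 / 600, threshold 20 CPM, one replicate required.
#'   \item H3K27me3: 100 / 1000, threshold 15 CPM, one replicate required.
#' }
#'
#' @param mark_name one of `"H2A.Z"`, `"H3K4me3"`, `"H3K27me3"`, or any
#'   custom name when the geometry arguments are given explicitly.
#' @param upstream,downstream window extents in bp (transcription
#'   orientation); `NULL` takes the mark default.
#' @param threshold positive CPM threshold; `NULL` takes the mark default.
#' @param n_replicates_required replicates that must individually reach the
#'   threshold.
#' @param negative_threshold optional CPM level; genes whose window maxima in
#'   all replicates stay below it form an explicit mark-free class.
#' @param op comparison operator for the threshold, `">="` (default) or
#'   `">"`.
#' @return A list of class `mark_config`.
#' @export
mark_config <- function(mark_name, upstream = NULL, downstream = NULL,
                        threshold = NULL, n_replicates_required = NULL,
                        negative_threshold = NULL, op = ">=") {
  defaults <- list(
    "H2A.Z"    = list(upstream = 200L, downstream = 600L, threshold = 15,
                      n_replicates_required = 2L, negative_threshold = 7.5),
    "H3K4me3"  = list(upstream = 200L, downstream = 600L, threshold = 20,
                      n_replicates_required = 1L, negative_threshold = NULL),
    "H3K27me3" = list(upstream = 100L, downstream = 1000L, threshold = 15,
                      n_replicates_required = 1L, negative_threshold = NULL))
  d <- defaults[[mark_name]]
  if (is.null(d))
    d <- list(upstream = 200L, downstream = 600L, threshold = NULL,
              n_replicates_required = 1L, negative_threshold = NULL)
  cfg <- list(mark_name = mark_name,
              upstream = as.integer(upstream %||% d$upstream),
              downstream = as.integer(downstream %||% d$downstream),
              threshold = threshold %||% d$threshold,
              n_replicates_required =
                as.integer(n_replicates_required %||% d$n_replicates_required),
              negative_threshold = negative_threshold %||% d$negative_threshold,
              op = match.arg(op, c(">=", ">")))
  if (is.null(cfg$threshold) || cfg$threshold <= 0)
    stop("mark_config: threshold must be > 0")
  structure(cfg, class = "mark_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default configurations for the three marks
#' @return Named list of [mark_config] objects.
#' @export
default_mark_configs <- function() {
  marks <- c("H2A.Z", "H3K4me3", "H3K27me3")
  stats::setNames(lapply(marks, mark_config), marks)
}

#' Quantile-based threshold from peak heights
#'
#' Derives a calling threshold as a quantile of genome-wide peak heights
#' (e.g. the height below which 95% of detectable peaks fall). Quantiles use
#' linear interpolation of order statistics with `h = (n - 1) * q`
#' (`stats::quantile` type 7).
#'
#' @param peak_heights non-empty numeric vector of peak heights (CPM).
#' @param q quantile in (0, 1); default 0.95.
#' @return The threshold, a single number.
#' @export
quantile_threshold <- function(peak_heights, q = 0.95) {
  if (length(peak_heights) == 0)
    stop("quantile_threshold: empty peak-height list")
  if (q <= 0 || q >= 1) stop("quantile_threshold: q must be in (0, 1)")
  unname(stats::quantile(peak_heights, probs = q, type = 7, names = FALSE))
}

#' Maximum coverage over a window
#'
#' @param track a CPM-normalized [coverage_track].
#' @param win a `genomic_window` (clipped, non-empty).
#' @return The maximum per-bp value in the window.
#' @export
window_max <- function(track, win) {
  if (window_is_empty(win))
    stop("window_max: empty window (gene off chromosome?) on ", win$chrom)
  vals <- extract_window(track, win, clip = TRUE)
  if (length(vals) == 0)
    stop("window_max: empty window after clipping on ", win$chrom)
  max(vals, na.rm = TRUE)
}

#' Call one mark for one gene
#'
#' Positive iff the window maximum reaches `cfg$threshold` (under `cfg$op`)
#' in all `cfg$n_replicates_required` replicates. When the config sets a
#' `negative_threshold`, genes whose maxima in all replicates stay strictly
#' below it are additionally flagged as the mark-free class.
#'
#' @param tracks_per_replicate list of CPM [coverage_track]s, one per
#'   replicate.
#' @param gene one gene (single-row [gene_model] or list).
#' @param cfg a [mark_config].
#' @return A list of class `occupancy_call`: `gene_id`, `mark_name`,
#'   `max_cov_per_replicate`, `positive`, `negative_class`.
#' @export
call_mark <- function(tracks_per_replicate, gene, cfg) {
  if (length(tracks_per_replicate) < cfg$n_replicates_required)
    stop("call_mark: ", cfg$mark_name, " needs ", cfg$n_replicates_required,
         " replicate(s), got ", length(tracks_per_replicate))
  if (is.data.frame(gene)) { stopifnot(nrow(gene) == 1); gene <- as.list(gene) }
  chrom_len <- tracks_per_replicate[[1]]$chrom_lengths[[gene$chrom]]
  win <- tss_window(gene, cfg$upstream, cfg$downstream, chrom_length = chrom_len)
  maxima <- vapply(tracks_per_replicate, window_max, numeric(1), win = win)
  pass <- if (cfg$op == ">=") maxima >= cfg$threshold else maxima > cfg$threshold
  # replicate order must not matter: at least n_replicates_required of the
  # supplied replicates must pass ("both replicates" when 2 of 2 required)
  positive <- sum(pass) >= cfg$n_replicates_required
  negative_class <- FALSE
  if (!is.null(cfg$negative_threshold))
    negative_class <- all(maxima < cfg$negative_threshold)
  if (positive) negative_class <- FALSE
  structure(list(gene_id = gene$gene_id, mark_name = cfg$mark_name,
                 max_cov_per_replicate = unname(maxima),
                 positive = positive, negative_class = negative_class),
            class = "occupancy_call")
}

#' Call all marks for all genes
#'
#' @param tracks_by_mark named list; per mark, a list of replicate
#'   [coverage_track]s.
#' @param genes a [gene_model] data frame.
#' @param configs named list of [mark_config]s (default
#'   [default_mark_configs] restricted to the marks present).
#' @return A `data.frame` keyed by (`gene_id`, `mark`): columns `gene_id`,
#'   `mark`, `max_rep1`, `max_rep2` (`NA` for single-replicate marks),
#'   `positive`, `negative_class`.
#' @export
call_all <- function(tracks_by_mark, genes, configs = NULL) {
  if (is.null(configs)) configs <- default_mark_configs()[names(tracks_by_mark)]
  missing <- setdiff(names(configs), names(tracks_by_mark))
  if (length(missing) > 0)
    stop("call_all: no tracks for configured mark(s): ",
         paste(missing, collapse = ", "))
  rows <- list()
  for (mk in names(configs)) {
    cfg <- configs[[mk]]
    tracks <- tracks_by_mark[[mk]]
    for (i in seq_len(nrow(genes))) {
      cl <- call_mark(tracks, genes[i, ], cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = cl$gene_id, mark = cl$mark_name,
        max_rep1 = cl$max_cov_per_replicate[1],
        max_rep2 = if (length(cl$max_cov_per_replicate) > 1)
          cl$max_cov_per_replicate[2] else NA_real_,
        positive = cl$positive, negative_class = cl$negative_class,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write occupancy calls as TSV
#' @param calls table from [call_all].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occupancy_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
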