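#' Per-window value tracks
#'
#' A value track carries one number per window of a fixed-width genome
#' tiling: mean read depth, scaled damage, or a dimensionless fold ratio.
#' Windows dropped by [exclude_windows()] or flagged undefined by
#' [enrichment_fold()] simply disappear from / are `NA` in the table.
#'
#' @param grid A [make_windows()] grid (or any window-shaped interval set).
#' @param values Numeric vector, one value per window of `grid`.
#' @param label Sample label.
#' @param units Free-text unit description (`"depth"`, `"scaled"`, `"fold"`).
#' @return A data frame of class `value_track` with columns `chrom`, `start`,
#'   `end`, `value`.
#' @export
value_track <- function(grid, values, label = NA_character_, units = "depth") {
  stopifnot(inherits(grid, "interval_set"))
  if (length(values) != nrow(grid)) {
    stop("'values' must have one entry per window (",
         nrow(grid), " expected, ", length(values), " given)")
  }
  if (units == "depth" && any(values < 0, na.rm = TRUE)) {
    stop("coverage values must be >= 0")
  }
  df <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                   value = as.numeric(values), stringsAsFactors = FALSE)
  structure(df, label = label, units = units,
            window_size = attr(grid, "window_size"),
            layout = attr(grid, "layout"),
            class = c("value_track", "data.frame"))
}

#' @export
print.value_track <- function(x, ...) {
  lab <- attr(x, "label")
  cat("<value_track> ", nrow(x), " window(s)",
      if (!is.na(lab)) paste0(" [", lab, "]"),
      " units: ", attr(x, "units"), "\n", sep = "")
  v <- x$value
  cat(sprintf("  value range %.4g .. %.4g (mean %.4g, %d NA)\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)),
              mean(v, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

same_grid <- function(a, b) {
  nrow(a) == nrow(b) && all(a$chrom == b$chrom) &&
    all(a$start == b$start) && all(a$end == b$end)
}

track_windows <- function(x) {
  new_interval_set(data.frame(chrom = x$chrom, start = x$start, end = x$end,
                              name = NA_character_, score = x$value,
                              strand = ".", stringsAsFactors = FALSE),
                   label = attr(x, "label"), sorted = TRUE, merged = FALSE)
}

#' Mean read coverage per window
#'
#' Each read (interval) contributes its per-base depth; the window value is
#' total covered read-bases in the window divided by the window width, i.e.
#' the mean depth over the window. Coverage is accumulated with
#' `IRanges::coverage` and averaged with windowed views.
#'
#' @param reads An [interval_set()] of aligned reads (single-end records).
#' @param grid A [make_windows()] grid with a bound layout.
#' @return A [value_track()] of mean depths.
#' @export
window_mean_coverage <- function(reads, grid) {
  stopifnot(inherits(reads, "interval_set"), inherits(grid, "window_grid"))
  layout <- attr(grid, "layout")
  validate_against_layout(reads, layout)
  irl <- as_iranges_by_chrom(reads)
  sp <- split(seq_len(nrow(grid)), grid$chrom)
  vals <- numeric(nrow(grid))
  for (ch in names(sp)) {
    idx <- sp[[ch]]
    len <- chrom_length(layout, ch)
    cvg <- if (is.null(irl[[ch]])) {
      S4Vectors::Rle(0L, len)
    } else {
      IRanges::coverage(irl[[ch]], width = len)
    }
    v <- IRanges::Views(cvg, start = grid$start[idx] + 1, end = grid$end[idx])
    vals[idx] <- IRanges::viewMeans(v)
  }
  value_track(grid, vals, label = attr(reads, "label"), units = "depth")
}

#' Low-coverage scaling of damage tracks
#'
#' Computes the global scaling used to put damage samples on a common scale:
#' the per-window mean across all supplied tracks is ranked, the lowest
#' `q`-fraction of windows (default 10%; ties broken by genomic order) forms
#' the common low-damage bin set, and each sample is scaled by its own mean
#' depth over that common set. With `single_factor = TRUE` one factor -- the
#' across-sample mean over the low-damage set -- is applied to every sample
#' (the stricter reading of a single global factor).
#'
#' @param tracks Named list of [value_track()] objects sharing one grid.
#' @param q Fraction of windows forming the low-damage set (default 0.10).
#' @param single_factor Use one common factor for all samples?
#' @return Object of class `od_scaling`: `low_windows` (row indices),
#'   `factors` (named per sample), `q`, `single_factor`.
#' @export
compute_scaling <- function(tracks, q = 0.10, single_factor = FALSE) {
  if (!is.list(tracks) || !length(tracks)) stop("'tracks' must be a non-empty list")
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    names(tracks) <- vapply(seq_along(tracks), function(i) {
      lab <- attr(tracks[[i]], "label")
      if (is.na(lab)) paste0("sample", i) else lab
    }, "")
  }
  first <- tracks[[1L]]
  for (t in tracks) {
    if (!inherits(t, "value_track") || !same_grid(t, first)) {
      stop("all tracks must be value tracks on the same window grid")
    }
  }
  n <- nrow(first)
  if (n < 1) stop("grid has no windows")
  vals <- vapply(tracks, function(t) t$value, numeric(n))
  vals <- matrix(vals, nrow = n)
  means <- rowMeans(vals)
  k <- max(1L, floor(q * n))
  low <- sort(order(means, seq_len(n))[seq_len(k)])
  factors <- colMeans(vals[low, , drop = FALSE])
  if (single_factor) factors[] <- mean(factors)
  names(factors) <- names(tracks)
  if (any(factors <= 0)) {
    stop("zero-baseline: scaling factor is not positive for sample(s) ",
         paste(names(factors)[factors <= 0], collapse = ", "))
  }
  structure(list(low_windows = low, factors = factors, q = q,
                 single_factor = single_factor),
            class = "od_scaling")
}

#' @export
print.od_scaling <- function(x, ...) {
  cat("<od_scaling> low-damage set:", length(x$low_windows),
      "window(s) (q =", x$q, ")\n")
  cat("  factors:", paste(sprintf("%s=%.4g", names(x$factors), x$factors),
                          collapse = ", "),
      if (x$single_factor) "(single factor)", "\n")
  invisible(x)
}

#' Apply a scaling factor to a coverage track
#'
#' @param track A [value_track()].
#' @param scaling An [compute_scaling()] result.
#' @param sample Which factor to use; defaults to the track's label, falling
#'   back to the single factor when only one is present.
#' @return The scaled [value_track()] (units `"scaled"`).
#' @export
apply_scaling <- function(track, scaling, sample = NULL) {
  stopifnot(inherits(track, "value_track"), inherits(scaling, "od_scaling"))
  if (is.null(sample)) sample <- attr(track, "label")
  f <- if (!is.na(sample) && sample %in% names(scaling$factors)) {
    scaling$factors[[sample]]
  } else if (length(unique(scaling$factors)) == 1L) {
    scaling$factors[[1L]]
  } else {
    stop("no scaling factor for sample '", sample, "'")
  }
  out <- track
  out$value <- track$value / f
  attr(out, "units") <- "scaled"
  out
}

#' Per-window fold change of damage over input
#'
#' @param damage,input [value_track()] objects on the same grid (scaled).
#' @param epsilon Input values below this are treated as undefined: the
#'   window's fold is `NA` (never +/-Inf) and such windows are excluded from
#'   downstream ranking.
#' @return A [value_track()] of folds (units `"fold"`).
#' @export
enrichment_fold <- function(damage, input, epsilon = 1e-9) {
  stopifnot(inherits(damage, "value_track"), inherits(input, "value_track"))
  if (!same_grid(damage, input)) stop("damage and input are on different grids")
  fold <- damage$value / input$value
  fold[is.na(input$value) | input$value < epsilon] <- NA_real_
  out <- damage
  out$value <- fold
  attr(out, "units") <- "fold"
  attr(out, "label") <- paste0(attr(damage, "label"), "/", attr(input, "label"))
  out
}

#' Drop windows overlapping an exclusion track
#'
#' Any window sharing >= 1 bp with the exclusion set (e.g. centromeric
#' satellite annotations) is removed from the track.
#'
#' @param track A [value_track()].
#' @param exclusion An [interval_set()].
#' @return The [value_track()] without excluded windows.
#' @export
exclude_windows <- function(track, exclusion) {
  stopifnot(inherits(track, "value_track"), inherits(exclusion, "interval_set"))
  hit <- overlaps_any(track_windows(track), exclusion)
  out <- as.data.frame(track)[!hit, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, label = attr(track, "label"), units = attr(track, "units"),
            window_size = attr(track, "window_size"),
            layout = attr(track, "layout"),
            class = c("value_track", "data.frame"))
}

#' Select the top fraction of windows by value
#'
#' Returns the `ceiling(f * n)` highest-value windows (`NA` windows are
#' dropped first; ties at the cut are taken in genomic order up to the
#' count). Window values are carried in the score column.
#'
#' @param track A [value_track()] (typically folds from [enrichment_fold()]).
#' @param fraction Top fraction f, `0 < f <= 1` (default 0.01).
#' @return An [interval_set()] of the selected windows, genomically sorted.
#' @export
select_top_windows <- function(track, fraction = 0.01) {
  stopifnot(inherits(track, "value_track"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("'fraction' must be in (0, 1]")
  }
  keep <- !is.na(track$value)
  x <- track[keep, , drop = FALSE]
  n <- nrow(x)
  if (n == 0) stop("no defined windows to select from")
  k <- ceiling(fraction * n)
  o <- order(-x$value, seq_len(n))[seq_len(k)]
  sel <- x[sort(o), , drop = FALSE]
  interval_set(sel$chrom, sel$start, sel$end, score = sel$value,
               label = paste0("top", fraction * 100, "%"))
}

#' Read and write per-window values as bedGraph
#'
#' Four-column tab-separated bedGraph (0-based half-open). `track` lines and
#' `#` comments are skipped on read; reading is delegated to
#' `rtracklayer::import`.
#'
#' @param path File path.
#' @param label Sample label.
#' @return `read_bedgraph()` returns a data frame of class `value_track`
#'   (grid attributes unset; windows as stored in the file).
#' @export
read_bedgraph <- function(path, label = basename(path)) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  tmp <- tempfile(fileext = ".bedGraph")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines[keep], tmp)
  gr <- rtracklayer::import(tmp, format = "bedGraph")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   value = as.numeric(S4Vectors::mcols(gr)$score),
                   stringsAsFactors = FALSE)
  structure(df, label = label, units = "depth", window_size = NA_real_,
            layout = NULL, class = c("value_track", "data.frame"))
}

#' @rdname read_bedgraph
#' @param track A [value_track()] to write.
#' @param comments Header comment lines (without `#`).
#' @export
write_bedgraph <- function(track, path, comments = character()) {
  stopifnot(inherits(track, "value_track"))
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  if (length(comments)) writeLines(paste0("# ", comments), con)
  df <- data.frame(track$chrom,
                   format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE),
                   track$value)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
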