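#' Genomic interval sets
#'
#' The central container of the package: a set of genomic intervals in
#' BED-style 0-based half-open coordinates (`start` inclusive, `end`
#' exclusive). One-based inputs are NOT auto-detected -- convert before
#' construction. Optional BED6 columns (`name`, `score`, `strand`) are carried
#' through I/O but ignored by all interval algebra, which is strand-blind.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors, 0-based half-open; `0 <= start < end`.
#' @param name,score,strand Optional BED6 columns; `strand` one of
#'   `"+", "-", "."`.
#' @param label Optional provenance label (file of origin, sample name).
#' @param layout Optional [genome_layout()]; when given, intervals must fit
#'   their chromosome.
#' @return A data frame of class `interval_set` with attributes `label`,
#'   `sorted` and `merged`.
#' @examples
#' x <- interval_set("chr1", c(10, 15, 40), c(20, 30, 50))
#' merge_intervals(x)
#' @export
interval_set <- function(chrom = character(), start = numeric(),
                         end = numeric(), name = NA_character_,
                         score = NA_real_, strand = ".",
                         label = NA_character_, layout = NULL) {
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 0 || length(start) == 0 || length(end) == 0) n <- 0L
  chrom <- as.character(rep_len(chrom, n))
  start <- as.numeric(rep_len(start, n))
  end <- as.numeric(rep_len(end, n))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    b <- bad[1L]
    stop(sprintf("invalid interval %s:%s-%s (need 0 <= start < end)",
                 chrom[b], format(start[b], scientific = FALSE),
                 format(end[b], scientific = FALSE)))
  }
  strand <- as.character(rep_len(strand, n))
  if (n && !all(strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   name = as.character(rep_len(name, n)),
                   score = as.numeric(rep_len(score, n)),
                   strand = strand, stringsAsFactors = FALSE)
  x <- new_interval_set(df, label = label)
  if (!is.null(layout)) validate_against_layout(x, layout)
  x
}

new_interval_set <- function(df, label = NA_character_,
                             sorted = FALSE, merged = FALSE) {
  rownames(df) <- NULL
  structure(df,
            label = label, sorted = sorted, merged = merged,
            class = c("interval_set", "data.frame"))
}

#' @export
print.interval_set <- function(x, ...) {
  lab <- attr(x, "label")
  cat("<interval_set> ", nrow(x), " interval(s) on ",
      length(unique(x$chrom)), " chromosome(s)",
      if (!is.na(lab)) paste0(" [", lab, "]"), "\n", sep = "")
  flags <- c(if (isTRUE(attr(x, "sorted"))) "sorted",
             if (isTRUE(attr(x, "merged"))) "merged")
  if (length(flags)) cat("  flags:", paste(flags, collapse = ", "), "\n")
  cat("  total bp:", format(total_bp(x), big.mark = ","), "\n")
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat("... and", nrow(x) - 8, "more\n")
  invisible(x)
}

validate_against_layout <- function(x, layout) {
  len <- chrom_length(layout, x$chrom)
  bad <- which(x$end > len)
  if (length(bad)) {
    b <- bad[1L]
    stop(sprintf("interval %s:%s-%s exceeds chromosome length %s",
                 x$chrom[b], format(x$start[b], scientific = FALSE),
                 format(x$end[b], scientific = FALSE),
                 format(len[b], scientific = FALSE)))
  }
  invisible(x)
}

#' Number of intervals and total covered base pairs
#'
#' `total_bp()` counts each base once, i.e. it is the merged footprint.
#'
#' @param x An [interval_set()].
#' @return A single number.
#' @export
n_intervals <- function(x) nrow(x)

#' @rdname n_intervals
#' @export
total_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  m <- if (isTRUE(attr(x, "merged"))) x else merge_intervals(x)
  sum(m$end - m$start)
}

#' Sort an interval set by chromosome, start and end
#'
#' Chromosomes are ordered by the layout when one is given, lexicographically
#' otherwise.
#'
#' @param x An [interval_set()].
#' @param layout Optional [genome_layout()] fixing the chromosome order.
#' @return The sorted set with the `sorted` flag on.
#' @export
sort_intervals <- function(x, layout = NULL) {
  key <- if (!is.null(layout)) {
    match(x$chrom, layout$chrom)
  } else {
    match(x$chrom, sort(unique(x$chrom)))
  }
  o <- order(key, x$start, x$end)
  out <- new_interval_set(as.data.frame(x)[o, , drop = FALSE],
                          label = attr(x, "label"),
                          sorted = TRUE, merged = isTRUE(attr(x, "merged")))
  out
}

# ---- IRanges bridge (internal) ----------------------------------------------
# 0-based half-open [start, end) maps to 1-based closed [start + 1, end].

as_iranges_by_chrom <- function(x) {
  if (nrow(x) == 0) return(list())
  sp <- split(seq_len(nrow(x)), x$chrom)
  lapply(sp, function(i) IRanges::IRanges(start = x$start[i] + 1,
                                          end = x$end[i]))
}

iranges_to_df <- function(irl) {
  if (!length(irl)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  chroms <- sort(names(irl))
  parts <- lapply(chroms, function(ch) {
    ir <- irl[[ch]]
    data.frame(chrom = rep(ch, length(ir)),
               start = as.numeric(IRanges::start(ir)) - 1,
               end = as.numeric(IRanges::end(ir)),
               name = NA_character_, score = NA_real_, strand = ".",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

# ---- Core algebra -----------------------------------------------------------

#' Merge overlapping intervals
#'
#' Combines overlapping intervals per chromosome into a minimal disjoint set.
#' Book-ended intervals (one ending exactly where the next starts) are joined
#' by default, matching the behaviour of the standard BED merging tools; set
#' `book_ended = FALSE` to join only intervals sharing at least one base.
#'
#' @param x An [interval_set()].
#' @param book_ended Join intervals separated by a zero-length gap?
#' @return A sorted, merged [interval_set()] covering the same bases.
#' @export
merge_intervals <- function(x, book_ended = TRUE) {
  stopifnot(inherits(x, "interval_set"))
  irl <- as_iranges_by_chrom(x)
  gap <- if (book_ended) 1L else 0L
  red <- lapply(irl, IRanges::reduce, min.gapwidth = gap)
  new_interval_set(iranges_to_df(red), label = attr(x, "label"),
                   sorted = TRUE, merged = TRUE)
}

#' Intersect two interval sets
#'
#' "Overlap" throughout the package means sharing at least one base; no
#' minimum-fraction rule is applied.
#'
#' @param a,b [interval_set()] objects.
#' @param mode `"regions"` returns the per-base intersection as an interval
#'   set; `"bp"` the total number of shared bases; `"count"` the number of
#'   `a` records (as given, unmerged) overlapping at least one `b` record,
#'   each counted once.
#' @return An [interval_set()] or a single number, per `mode`.
#' @export
intersect_intervals <- function(a, b, mode = c("regions", "bp", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "interval_set"), inherits(b, "interval_set"))
  if (mode == "count") {
    irb <- as_iranges_by_chrom(b)
    total <- 0L
    if (nrow(a)) {
      sp <- split(seq_len(nrow(a)), a$chrom)
      for (ch in names(sp)) {
        if (is.null(irb[[ch]])) next
        ira <- IRanges::IRanges(a$start[sp[[ch]]] + 1, a$end[sp[[ch]]])
        total <- total + sum(IRanges::countOverlaps(ira, irb[[ch]]) > 0L)
      }
    }
    return(as.numeric(total))
  }
  ira <- lapply(as_iranges_by_chrom(a), IRanges::reduce, min.gapwidth = 1L)
  irb <- lapply(as_iranges_by_chrom(b), IRanges::reduce, min.gapwidth = 1L)
  common <- intersect(names(ira), names(irb))
  res <- lapply(common, function(ch) IRanges::intersect(ira[[ch]], irb[[ch]]))
  names(res) <- common
  res <- res[vapply(res, length, 1L) > 0L]
  if (mode == "bp") {
    return(sum(vapply(res, function(ir) sum(as.numeric(IRanges::width(ir))), 1)))
  }
  new_interval_set(iranges_to_df(res), sorted = TRUE, merged = TRUE)
}

#' Subtract one interval set from another
#'
#' @param a,b [interval_set()] objects.
#' @param mode `"per-base"` clips the portions of `a` covered by `b`
#'   (coordinate subtraction on the merged footprint of `a`);
#'   `"any-overlap"` drops every whole `a` record that shares at least one
#'   base with `b` and keeps the remaining records untouched. The whole-record
#'   rule is the one used for track partitioning and centromeric-satellite
#'   exclusion.
#' @return An [interval_set()].
#' @export
subtract_intervals <- function(a, b, mode = c("per-base", "any-overlap")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "interval_set"), inherits(b, "interval_set"))
  if (mode == "any-overlap") {
    if (nrow(a) == 0) return(a)
    irb <- as_iranges_by_chrom(b)
    keep <- rep(TRUE, nrow(a))
    sp <- split(seq_len(nrow(a)), a$chrom)
    for (ch in names(sp)) {
      if (is.null(irb[[ch]])) next
      idx <- sp[[ch]]
      ira <- IRanges::IRanges(a$start[idx] + 1, a$end[idx])
      keep[idx] <- IRanges::countOverlaps(ira, irb[[ch]]) == 0L
    }
    out <- new_interval_set(as.data.frame(a)[keep, , drop = FALSE],
                            label = attr(a, "label"),
                            sorted = isTRUE(attr(a, "sorted")), merged = FALSE)
    return(out)
  }
  ira <- lapply(as_iranges_by_chrom(a), IRanges::reduce, min.gapwidth = 1L)
  irb <- as_iranges_by_chrom(b)
  res <- lapply(names(ira), function(ch) {
    if (is.null(irb[[ch]])) ira[[ch]]
    else IRanges::setdiff(ira[[ch]], IRanges::reduce(irb[[ch]]))
  })
  names(res) <- names(ira)
  res <- res[vapply(res, length, 1L) > 0L]
  new_interval_set(iranges_to_df(res), label = attr(a, "label"),
                   sorted = TRUE, merged = TRUE)
}

#' Extend intervals symmetrically, clamped to chromosome ends
#'
#' Each interval becomes `[max(0, start - flank), min(len, end + flank))`.
#' This is the operation used to widen 1-bp break records into peaks of a
#' target mean width (a 1-bp record with `flank = 133` becomes 267 bp wide
#' away from chromosome edges). The output is not auto-merged.
#'
#' @param x An [interval_set()].
#' @param flank Non-negative number of bases to add on each side.
#' @param layout A [genome_layout()]; all chromosomes of `x` must be present.
#' @return An [interval_set()] with the same records, widened.
#' @export
extend_clamped <- function(x, flank, layout) {
  stopifnot(inherits(x, "interval_set"), inherits(layout, "genome_layout"))
  if (!is.numeric(flank) || length(flank) != 1L || is.na(flank) || flank < 0) {
    stop("'flank' must be a single non-negative number")
  }
  if (nrow(x) == 0) return(x)
  len <- chrom_length(layout, x$chrom)
  out <- as.data.frame(x)
  out$start <- pmax(0, x$start - flank)
  out$end <- pmin(len, x$end + flank)
  new_interval_set(out, label = attr(x, "label"),
                   sorted = isTRUE(attr(x, "sorted")), merged = FALSE)
}

# ---- Window grids -----------------------------------------------------------

#' Tile a genome into fixed-width windows
#'
#' Windows start at 0 on every chromosome; the trailing window is truncated at
#' the chromosome end, so widths always sum exactly to the genome length.
#' Windows never span chromosomes.
#'
#' @param layout A [genome_layout()].
#' @param window_size Window width W in bp (>= 1).
#' @return An [interval_set()] of class `window_grid` carrying the layout and
#'   `window_size` as attributes, in layout chromosome order.
#' @export
make_windows <- function(layout, window_size) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(window_size) || length(window_size) != 1L ||
      is.na(window_size) || window_size < 1) {
    stop("'window_size' must be a single number >= 1")
  }
  window_size <- floor(window_size)
  parts <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    s <- seq(0, len - 1, by = window_size)
    data.frame(chrom = layout$chrom[i], start = s,
               end = pmin(s + window_size, len),
               name = NA_character_, score = NA_real_, strand = ".",
               stringsAsFactors = FALSE)
  })
  out <- new_interval_set(do.call(rbind, parts), sorted = TRUE, merged = TRUE)
  attr(out, "layout") <- layout
  attr(out, "window_size") <- window_size
  class(out) <- c("window_grid", class(out))
  out
}

#' Flag windows touched by each track
#'
#' One logical per (window, track): `TRUE` iff the track overlaps the window
#' by at least one base. The result feeds [membership_counts()] for
#' UpSet-style exclusive set counting over binarized windows.
#'
#' @param grid A [make_windows()] grid.
#' @param tracks A named list of [interval_set()] objects.
#' @return Logical matrix, rows = windows (in grid order), columns = tracks.
#' @export
binarize_windows <- function(grid, tracks) {
  stopifnot(inherits(grid, "window_grid"))
  if (!is.list(tracks) || length(tracks) == 0) {
    stop("'tracks' must be a non-empty list of interval sets")
  }
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    names(tracks) <- paste0("track", seq_along(tracks))
  }
  sp <- split(seq_len(nrow(grid)), grid$chrom)
  mat <- matrix(FALSE, nrow = nrow(grid), ncol = length(tracks),
                dimnames = list(NULL, names(tracks)))
  for (k in seq_along(tracks)) {
    irt <- as_iranges_by_chrom(tracks[[k]])
    for (ch in names(sp)) {
      if (is.null(irt[[ch]])) next
      idx <- sp[[ch]]
      irw <- IRanges::IRanges(grid$start[idx] + 1, grid$end[idx])
      mat[idx, k] <- IRanges::countOverlaps(irw, irt[[ch]]) > 0L
    }
  }
  mat
}

#' Exclusive (UpSet-style) membership counts over binarized windows
#'
#' Partitions the flagged windows into exclusive track combinations: each
#' window with at least one flag is counted in exactly one combination (the
#' full set of tracks flagging it). Also reports, per track, the fraction of
#' its flagged windows shared with at least one other track.
#'
#' @param mat Logical matrix from [binarize_windows()].
#' @return A list of class `membership_counts`: `combinations` (named integer
#'   vector, names like `"a&b"`), `n_flagged`, `per_track` (data frame with
#'   flagged-window counts and shared fractions).
#' @export
membership_counts <- function(mat) {
  if (!is.matrix(mat) || !is.logical(mat) || ncol(mat) < 1) {
    stop("'mat' must be a logical matrix with >= 1 column")
  }
  if (is.null(colnames(mat))) colnames(mat) <- paste0("track", seq_len(ncol(mat)))
  any_flag <- rowSums(mat) > 0
  sub <- mat[any_flag, , drop = FALSE]
  combo <- apply(sub, 1L, function(r) paste(colnames(mat)[r], collapse = "&"))
  counts <- sort(table(combo), decreasing = TRUE)
  combinations <- stats::setNames(as.integer(counts), names(counts))
  flagged <- colSums(mat)
  shared <- vapply(seq_len(ncol(mat)), function(k) {
    f <- mat[, k]
    if (!any(f)) return(NA_real_)
    sum(f & rowSums(mat[, -k, drop = FALSE]) > 0) / sum(f)
  }, 1)
  structure(list(
    combinations = combinations,
    n_flagged = sum(any_flag),
    per_track = data.frame(track = colnames(mat),
                           n_windows = as.integer(flagged),
                           frac_shared = shared,
                           stringsAsFactors = FALSE)
  ), class = "membership_counts")
}

#' @export
print.membership_counts <- function(x, ...) {
  cat("<membership_counts> ", x$n_flagged, " flagged window(s), ",
      length(x$combinations), " exclusive combination(s)\n", sep = "")
  print(x$combinations)
  print(x$per_track, row.names = FALSE)
  invisible(x)
}
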