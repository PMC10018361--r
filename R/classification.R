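#' Merge replicate peak files with satellite exclusion
#'
#' Takes the union of the replicate peak sets, merges overlapping/book-ended
#' records, then removes every merged peak that overlaps the exclusion track
#' by >= 1 bp (whole-record removal -- the rule used for centromeric
#' satellite filtering, where partially assembled satellite arrays would
#' otherwise bias the peak set).
#'
#' @param peak_sets List of [interval_set()] objects (replicates/stages).
#' @param exclusion Optional [interval_set()] of regions to exclude.
#' @param label Provenance label for the merged set.
#' @return A merged [interval_set()].
#' @export
merge_replicates <- function(peak_sets, exclusion = NULL, label = "merged") {
  if (!is.list(peak_sets) || !length(peak_sets)) {
    stop("'peak_sets' must be a non-empty list")
  }
  for (p in peak_sets) stopifnot(inherits(p, "interval_set"))
  pooled <- do.call(rbind, lapply(peak_sets, as.data.frame))
  merged <- merge_intervals(new_interval_set(pooled))
  if (!is.null(exclusion)) {
    merged <- subtract_intervals(merged, exclusion, mode = "any-overlap")
  }
  attr(merged, "label") <- label
  merged
}

#' Extend 1-bp break records to a target mean width
#'
#' Point-break records (1-bp resolution break maps) are widened to match the
#' mean width of broad peaks from a lower-resolution assay so the two can be
#' compared: flank = `floor((target - 1) / 2)` on each side via
#' [extend_clamped()] (267 bp target gives the +/-133 bp extension). For even
#' targets one extra base is added downstream. Records near chromosome ends
#' are clamped and come out narrower.
#'
#' @param points An [interval_set()] of 1-bp records. Wider records trigger a
#'   warning and are extended symmetrically anyway.
#' @param target_width Target width in bp (e.g. 267).
#' @param layout A [genome_layout()].
#' @return An [interval_set()] of widened records.
#' @export
extend_point_breaks <- function(points, target_width, layout) {
  stopifnot(inherits(points, "interval_set"))
  if (!is.numeric(target_width) || target_width < 1) {
    stop("'target_width' must be >= 1")
  }
  w <- points$end - points$start
  if (any(w != 1)) {
    warning(sum(w != 1), " record(s) are not 1 bp wide; extending symmetrically anyway")
  }
  flank <- floor((target_width - 1) / 2)
  out <- extend_clamped(points, flank, layout)
  extra <- target_width - (1 + 2 * flank)   # 1 for even targets
  if (extra > 0) {
    len <- chrom_length(layout, out$chrom)
    out$end <- pmin(len, out$end + extra)
  }
  out
}

#' Classify breaks as set-specific or shared with references
#'
#' For each named reference set, the count and fraction of query peaks
#' overlapping it (>= 1 bp); peaks overlapping no reference are "specific".
#' Used to split a break map into cell-type-specific and shared locations.
#'
#' @param query An [interval_set()] of peaks.
#' @param references Named list of [interval_set()] objects.
#' @return Object of class `classification_result`: `total`, `per_reference`
#'   (data frame of counts/fractions), `n_specific`, `frac_specific`,
#'   `specific` (logical per query record).
#' @export
classify_breaks <- function(query, references) {
  stopifnot(inherits(query, "interval_set"))
  if (nrow(query) == 0) stop("'query' must be non-empty")
  if (!is.list(references) || !length(references) ||
      is.null(names(references)) || any(!nzchar(names(references)))) {
    stop("'references' must be a non-empty named list")
  }
  hits <- vapply(references, function(r) overlaps_any(query, r),
                 logical(nrow(query)))
  hits <- matrix(hits, nrow = nrow(query),
                 dimnames = list(NULL, names(references)))
  any_hit <- rowSums(hits) > 0
  per_ref <- data.frame(reference = colnames(hits),
                        n_overlap = colSums(hits),
                        frac_overlap = colSums(hits) / nrow(query),
                        stringsAsFactors = FALSE)
  rownames(per_ref) <- NULL
  structure(list(
    total = nrow(query),
    per_reference = per_ref,
    n_specific = sum(!any_hit),
    frac_specific = sum(!any_hit) / nrow(query),
    specific = !any_hit
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result> ", x$total, " query peak(s)\n", sep = "")
  cat(sprintf("  specific (no reference overlap): %d (%.1f%%)\n",
              x$n_specific, 100 * x$frac_specific))
  df <- x$per_reference
  df$frac_overlap <- sprintf("%.1f%%", 100 * df$frac_overlap)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-chromosome peak summaries
#'
#' For each chromosome: length, merged covered bp, coverage percent, peak
#' count and peaks per Mb; optionally the merged bp of a repeat track per
#' chromosome (for repeat-content regressions). The genome-wide peaks-per-Mb
#' figure uses total peak count over total genome length.
#'
#' @param peaks An [interval_set()] (merged internally if needed).
#' @param layout A [genome_layout()].
#' @param repeats Optional repeat annotation [interval_set()].
#' @return A data frame of class `chromosome_summary` with one row per
#'   layout chromosome and a `genome_wide` attribute (list with
#'   `total_peaks`, `covered_bp`, `coverage_pct`, `peaks_per_mb`).
#' @export
chromosome_summary <- function(peaks, layout, repeats = NULL) {
  stopifnot(inherits(peaks, "interval_set"), inherits(layout, "genome_layout"))
  m <- if (isTRUE(attr(peaks, "merged"))) peaks else merge_intervals(peaks)
  validate_against_layout(m, layout)
  cov_by <- tapply(m$end - m$start, m$chrom, sum)
  cnt_by <- table(m$chrom)
  df <- data.frame(chrom = layout$chrom, length = layout$length,
                   stringsAsFactors = FALSE)
  df$covered_bp <- as.numeric(cov_by[df$chrom])
  df$covered_bp[is.na(df$covered_bp)] <- 0
  df$coverage_pct <- 100 * df$covered_bp / df$length
  df$n_peaks <- as.numeric(cnt_by[df$chrom])
  df$n_peaks[is.na(df$n_peaks)] <- 0
  df$peaks_per_mb <- df$n_peaks * 1e6 / df$length
  if (!is.null(repeats)) {
    rm_ <- merge_intervals(repeats)
    rep_by <- tapply(rm_$end - rm_$start, rm_$chrom, sum)
    df$repeat_bp <- as.numeric(rep_by[df$chrom])
    df$repeat_bp[is.na(df$repeat_bp)] <- 0
    df$repeat_pct <- 100 * df$repeat_bp / df$length
  }
  structure(df,
            genome_wide = list(
              total_peaks = sum(df$n_peaks),
              covered_bp = sum(df$covered_bp),
              coverage_pct = 100 * sum(df$covered_bp) / genome_size(layout),
              peaks_per_mb = sum(df$n_peaks) * 1e6 / genome_size(layout)),
            class = c("chromosome_summary", "data.frame"))
}

#' @export
print.chromosome_summary <- function(x, ...) {
  gw <- attr(x, "genome_wide")
  cat(sprintf("<chromosome_summary> %d chromosome(s); genome-wide: %s peaks, %.2f%% coverage, %.1f peaks/Mb\n",
              nrow(x), format(gw$total_peaks, big.mark = ","),
              gw$coverage_pct, gw$peaks_per_mb))
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Regression of peak coverage on repeat content
#'
#' Ordinary least squares of per-chromosome peak coverage (%) on repeat
#' coverage (%), as used to ask whether break density tracks chromosomal
#' repeat content. Requires >= 3 chromosomes with repeat data.
#'
#' @param summary A [chromosome_summary()] computed with a repeat track.
#' @return List with `r_squared`, `slope`, `p_value` (two-sided, for the
#'   slope), `n` and the underlying `lm` fit.
#' @export
repeat_content_correlation <- function(summary) {
  stopifnot(inherits(summary, "chromosome_summary"))
  if (is.null(summary$repeat_pct)) {
    stop("summary lacks repeat content; rerun chromosome_summary() with 'repeats'")
  }
  df <- as.data.frame(summary)[!is.na(summary$repeat_pct), , drop = FALSE]
  if (nrow(df) < 3) stop("need >= 3 chromosomes with repeat content")
  fit <- stats::lm(coverage_pct ~ repeat_pct, data = df)
  if (stats::var(df$coverage_pct) < 1e-12) {
    # constant response: nothing to explain
    return(list(r_squared = 0, slope = 0, p_value = NA_real_,
                n = nrow(df), fit = fit))
  }
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2L])
  p <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2L, 4L] else NA_real_
  list(r_squared = sm$r.squared, slope = slope, p_value = p,
       n = nrow(df), fit = fit)
}
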