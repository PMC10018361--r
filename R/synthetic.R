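#' @name synthetic_data
#' @title Seeded synthetic-data generators
#'
#' @description
#' Generators producing desk-scale analogues of the real inputs: random
#' multi-chromosome genomes, sequences with planted tandem repeats, break
#' sets with planted region-association structure, and per-window coverage
#' tracks with planted damage enrichment. Every generator is deterministic
#' under a fixed seed, and each returns the ground truth needed to verify
#' the corresponding analysis stage.
NULL

#' Generate a random genome
#'
#' I.i.d. bases at the stated GC fraction.
#'
#' @param lengths Named numeric vector of chromosome lengths (names become
#'   chromosome names; unnamed vectors get `chr1..chrN`).
#' @param gc GC fraction in `[0, 1]` (default 0.42, mouse-like).
#' @param seed Optional integer seed.
#' @return List of class `synthetic_genome`: `layout` ([genome_layout()]),
#'   `seqs` (named character), `gc`, `seed`.
#' @export
make_genome <- function(lengths, gc = 0.42, seed = NULL) {
  if (is.null(names(lengths))) {
    names(lengths) <- paste0("chr", seq_along(lengths))
  }
  if (gc < 0 || gc > 1) stop("'gc' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lengths, function(len) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, "")
  structure(list(layout = genome_layout(names(lengths), unname(lengths)),
                 seqs = seqs, gc = gc,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome>", nrow(x$layout), "chromosome(s),",
      format(genome_size(x$layout), big.mark = ","), "bp, GC", x$gc, "\n")
  invisible(x)
}

#' Plant tandem-repeat blocks into a genome
#'
#' Writes `n` non-overlapping blocks of exactly `units` copies of `unit`
#' into the sequence, at least `min_spacing` bp apart. IUPAC codes in the
#' unit are instantiated randomly per copy (so `"NA"` yields TA/CA/GA/AA
#' mosaics). The bases flanking each block are set to non-matching bases so
#' every planted block is a maximal run, making exact-boundary recovery
#' testable.
#'
#' @param genome A [make_genome()] result.
#' @param n Number of blocks.
#' @param unit Repeat unit (IUPAC), e.g. `"CA"`.
#' @param units Copies per block (exact).
#' @param min_spacing Minimum distance between blocks (>= 2 * unit length).
#' @param seed Optional integer seed.
#' @return The modified `synthetic_genome` with a `truth` element: an
#'   [interval_set()] of the planted blocks (unit counts as scores).
#' @export
plant_tandem_repeats <- function(genome, n, unit, units, min_spacing = 100,
                                 seed = NULL) {
  stopifnot(inherits(genome, "synthetic_genome"))
  mask <- pattern_mask(unit)
  u <- nchar(unit)
  if (min_spacing < 2 * u) stop("'min_spacing' must be >= 2 * unit length")
  if (!is.null(seed)) set.seed(seed)
  block_w <- units * u
  need <- block_w + 2 * u      # block plus run-breaking flanks
  layout <- genome$layout
  placed <- list()
  # rejection-sample non-overlapping placements, chromosome picked by length
  occupied <- lapply(stats::setNames(layout$chrom, layout$chrom),
                     function(ch) matrix(numeric(0), ncol = 2))
  tries <- 0L
  while (length(placed) < n) {
    tries <- tries + 1L
    if (tries > 1000L * max(1L, n)) {
      stop("cannot place ", n, " blocks without overlap; genome too small")
    }
    ci <- sample.int(nrow(layout), 1L, prob = layout$length)
    ch <- layout$chrom[ci]
    len <- layout$length[ci]
    if (len < need + 2) next
    s <- floor(stats::runif(1) * (len - need + 1)) + u  # block start, 0-based
    occ <- occupied[[ch]]
    lo <- s - u - min_spacing
    hi <- s + block_w + u + min_spacing
    if (nrow(occ) && any(occ[, 2] > lo & occ[, 1] < hi)) next
    occupied[[ch]] <- rbind(occ, c(s - u, s + block_w + u))
    placed[[length(placed) + 1L]] <- list(chrom = ch, start = s)
  }
  # base choices per IUPAC symbol
  choices <- lapply(strsplit(toupper(unit), "")[[1L]], function(sym) {
    b <- c("A", "C", "G", "T")
    b[bitwAnd(IUPAC_BITS[[sym]], c(1L, 2L, 4L, 8L)) > 0L]
  })
  seqs <- genome$seqs
  truth <- list()
  for (pl in placed) {
    block <- vapply(seq_len(units), function(i) {
      paste(vapply(choices, function(cc) cc[sample.int(length(cc), 1L)], ""),
            collapse = "")
    }, "")
    block <- paste(block, collapse = "")
    # run-breaking flanks: for the left flank, mismatch the last non-N unit
    # symbol; for the right, mismatch the first; both within one unit length
    syms <- strsplit(toupper(unit), "")[[1L]]
    non_n <- which(syms != "N")
    if (!length(non_n)) stop("cannot break runs of an all-N unit")
    jl <- non_n[length(non_n)]; jr <- non_n[1L]
    left <- strsplit(substr(seqs[[pl$chrom]], pl$start - u + 1, pl$start), "")[[1L]]
    left[jl] <- iupac_nonmatching_base(syms[jl])
    right <- strsplit(substr(seqs[[pl$chrom]], pl$start + nchar(block) + 1,
                             pl$start + nchar(block) + u), "")[[1L]]
    right[jr] <- iupac_nonmatching_base(syms[jr])
    seqs[[pl$chrom]] <- paste0(
      substr(seqs[[pl$chrom]], 1, pl$start - u),
      paste(left, collapse = ""), block, paste(right, collapse = ""),
      substr(seqs[[pl$chrom]], pl$start + nchar(block) + u + 1,
             nchar(seqs[[pl$chrom]])))
    truth[[length(truth) + 1L]] <- data.frame(
      chrom = pl$chrom, start = pl$start, end = pl$start + nchar(block),
      stringsAsFactors = FALSE)
  }
  genome$seqs <- seqs
  tr <- if (length(truth)) {
    df <- do.call(rbind, truth)
    sort_intervals(interval_set(df$chrom, df$start, df$end,
                                name = paste0("(", toupper(unit), ")n"),
                                score = units, label = "planted"))
  } else {
    interval_set(label = "planted")
  }
  genome$truth <- tr
  genome
}

#' Simulate break placements with tunable feature association
#'
#' Each break is placed independently: with probability `rho` its start is
#' drawn uniformly within `proximity` bp of a randomly chosen feature
#' interval, otherwise uniformly on the genome (chromosomes weighted by
#' length). Widths are drawn from a log-normal matched to observed broad-peak
#' statistics (median 213 bp, truncated below at 146 bp) unless overridden.
#' `rho = 0` gives a feature-independent null set.
#'
#' @param layout A [genome_layout()].
#' @param n Number of breaks.
#' @param features Optional [interval_set()] the breaks are attracted to.
#' @param rho Attraction probability in `[0, 1]`.
#' @param proximity Distance d (bp) around a feature within which attracted
#'   breaks land.
#' @param width_meanlog,width_sdlog,width_min Log-normal width parameters.
#'   Set `width_sdlog = 0` (with `width_min = 1`, `width_meanlog = 0`) for
#'   1-bp point breaks.
#' @param seed Optional integer seed.
#' @return List of class `synthetic_breaks`: `breaks` ([interval_set()]),
#'   `truth` (list with the parameters, the seed and the per-break
#'   `attracted` flag).
#' @export
simulate_breaks <- function(layout, n, features = NULL, rho = 0,
                            proximity = 1000,
                            width_meanlog = log(213), width_sdlog = 0.45,
                            width_min = 146, seed = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  if (rho < 0 || rho > 1) stop("'rho' must be in [0, 1]")
  if (rho > 0 && (is.null(features) || nrow(features) == 0)) {
    stop("'features' must be non-empty when rho > 0")
  }
  if (!is.null(seed)) set.seed(seed)
  w <- pmax(width_min, round(stats::rlnorm(n, width_meanlog, width_sdlog)))
  w <- pmin(w, min(layout$length))
  attracted <- stats::runif(n) < rho
  chrom <- character(n)
  start <- numeric(n)
  n_bg <- sum(!attracted)
  if (n_bg) {
    ci <- sample.int(nrow(layout), n_bg, replace = TRUE, prob = layout$length)
    chrom[!attracted] <- layout$chrom[ci]
    len <- layout$length[ci]
    start[!attracted] <- floor(stats::runif(n_bg) * (len - w[!attracted] + 1))
  }
  n_at <- sum(attracted)
  if (n_at) {
    fi <- sample.int(nrow(features), n_at, replace = TRUE)
    fch <- features$chrom[fi]
    len <- chrom_length(layout, fch)
    lo <- pmax(0, features$start[fi] - proximity)
    hi <- pmin(len - w[attracted], features$end[fi] + proximity)
    hi <- pmax(hi, lo)  # tiny chromosomes: clamp
    chrom[attracted] <- fch
    start[attracted] <- lo + floor(stats::runif(n_at) * (hi - lo + 1))
  }
  breaks <- interval_set(chrom, start, start + w, label = "simulated-breaks",
                         layout = layout)
  structure(list(
    breaks = breaks,
    truth = list(n = n, rho = rho, proximity = proximity,
                 attracted = attracted,
                 width = list(meanlog = width_meanlog, sdlog = width_sdlog,
                              min = width_min),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  ), class = "synthetic_breaks")
}

#' Simulate damage and input coverage tracks
#'
#' The input track fluctuates around `base_depth` with multiplicative
#' gamma-distributed noise (mean 1, coefficient of variation `dispersion`);
#' the damage track additionally carries a `fold`-times enrichment in the
#' designated windows. Both tracks are strictly positive.
#'
#' @param grid A [make_windows()] grid.
#' @param enriched Integer indices of enriched windows (rows of `grid`).
#' @param fold Enrichment fold (>= 1).
#' @param base_depth Baseline mean depth.
#' @param dispersion Noise coefficient of variation (> 0). The default 0.1
#'   matches the bin-level overdispersion typical of whole-genome coverage
#'   averaged over 50-kb windows, where counting noise is negligible and
#'   residual variation comes from mappability and GC effects.
#' @param seed Optional integer seed.
#' @return List of class `synthetic_coverage`: `damage` and `input`
#'   ([value_track()] objects), `enriched`, `fold`, `seed`.
#' @export
simulate_coverage_tracks <- function(grid, enriched = integer(), fold = 1,
                                     base_depth = 30, dispersion = 0.1,
                                     seed = NULL) {
  stopifnot(inherits(grid, "interval_set"))
  if (fold < 1) stop("'fold' must be >= 1")
  if (dispersion <= 0) stop("'dispersion' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(grid)
  shape <- 1 / dispersion^2
  noise <- function() stats::rgamma(n, shape = shape, rate = shape)
  input_v <- base_depth * noise()
  mult <- rep(1, n)
  mult[enriched] <- fold
  damage_v <- base_depth * mult * noise()
  structure(list(
    damage = value_track(grid, damage_v, label = "damage"),
    input = value_track(grid, input_v, label = "input"),
    enriched = sort(unique(as.integer(enriched))),
    fold = fold,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  ), class = "synthetic_coverage")
}
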