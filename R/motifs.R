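#' @name motif_scanning
#' @title Motif scanners for break-prone sequence classes
#'
#' @description
#' Targeted scanners for the sequence families implicated in chromatin-
#' remodelling-associated DNA fragility: short tandem repeats such as (CA)n
#' and the degenerate (NA)n, alternating purine--pyrimidine (RY)k runs (the
#' Z-DNA-prone class; R = A/G, Y = C/T), and IUPAC consensus motifs such as
#' the topoisomerase II cleavage consensus `RNYNNCNNGYNGKTNYNY`.
#'
#' Matching semantics: IUPAC ambiguity codes in the *pattern* match their
#' base sets; in the *sequence* only A/C/G/T are informative and every other
#' symbol is treated as N, which matches the pattern symbol N only. This
#' keeps assembly gaps (N runs) from producing artefactual hits.
NULL

IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)

pattern_mask <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  if (!length(chars)) stop("motif pattern must be non-empty")
  m <- unname(IUPAC_BITS[chars])
  if (anyNA(m)) {
    stop("invalid IUPAC symbol in motif pattern: ",
         paste(unique(chars[is.na(m)]), collapse = ", "))
  }
  # sequence N carries a private bit (16) so that only pattern N matches it
  m[chars == "N"] <- 31L
  m
}

sequence_bits <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  b <- unname(c(A = 1L, C = 2L, G = 4L, T = 8L)[v])
  b[is.na(b)] <- 16L
  b
}

# a base that a given IUPAC symbol cannot match (used to break planted runs)
iupac_nonmatching_base <- function(sym) {
  mask <- pattern_mask(sym)
  bases <- c("A", "C", "G", "T")
  free <- bases[bitwAnd(mask, c(1L, 2L, 4L, 8L)) == 0L]
  if (!length(free)) stop("symbol '", sym, "' matches every base")
  free[1L]
}

#' Specify a motif to scan for
#'
#' @param kind `"tandem-unit"` (k+ consecutive copies of a short unit, e.g.
#'   CA or the degenerate NA), `"alternating-RY"` (k+ purine--pyrimidine
#'   dinucleotide alternations) or `"iupac-consensus"` (fixed-length IUPAC
#'   pattern).
#' @param pattern The repeat unit or consensus pattern (IUPAC text). Ignored
#'   for `"alternating-RY"`.
#' @param min_units Minimum unit count k for the repeat kinds. There is no
#'   silent default for tandem scans: choose k explicitly.
#' @param strand `"plus"` or `"both"`. Defaults follow field practice:
#'   plus-only for repeat tracks, both strands for consensus motifs.
#' @return A list of class `motif_spec`.
#' @export
motif_spec <- function(kind = c("tandem-unit", "alternating-RY", "iupac-consensus"),
                       pattern = NULL, min_units = NULL, strand = NULL) {
  kind <- match.arg(kind)
  if (kind != "alternating-RY") {
    if (is.null(pattern)) stop("'pattern' is required for kind ", kind)
    pattern_mask(pattern)  # validates
    pattern <- toupper(pattern)
  }
  if (kind != "iupac-consensus") {
    if (is.null(min_units)) stop("'min_units' (k) is required for kind ", kind)
    if (min_units < 1) stop("'min_units' must be >= 1")
  }
  if (is.null(strand)) strand <- if (kind == "iupac-consensus") "both" else "plus"
  strand <- match.arg(strand, c("plus", "both"))
  structure(list(kind = kind, pattern = pattern,
                 min_units = if (is.null(min_units)) NA_integer_ else as.integer(min_units),
                 strand = strand),
            class = "motif_spec")
}

#' Scan sequences with a motif specification
#'
#' Dispatches to [scan_tandem_repeats()], [scan_alternating_ry()] or
#' [scan_iupac()] according to the spec.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @param spec A [motif_spec()].
#' @return An [interval_set()] of motif hits.
#' @export
scan_motif <- function(seqs, spec) {
  stopifnot(inherits(spec, "motif_spec"))
  switch(spec$kind,
         "tandem-unit" = scan_tandem_repeats(seqs, spec$pattern, spec$min_units,
                                             strand = spec$strand),
         "alternating-RY" = scan_alternating_ry(seqs, spec$min_units),
         "iupac-consensus" = scan_iupac(seqs, spec$pattern, strand = spec$strand))
}

# positions (1-based) where the unit/pattern matches the sequence
match_positions <- function(bits, mask) {
  L <- length(mask)
  M <- length(bits)
  if (M < L) return(logical(0))
  ok <- bitwAnd(mask[1L], bits[seq_len(M - L + 1L)]) > 0L
  if (L > 1L) for (j in 2L:L) {
    ok <- ok & bitwAnd(mask[j], bits[j:(j + M - L)]) > 0L
  }
  ok
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

motif_hits_set <- function(rows, label) {
  if (!length(rows)) {
    out <- interval_set(label = label)
    return(out)
  }
  df <- do.call(rbind, rows)
  x <- interval_set(df$chrom, df$start, df$end, name = df$name,
                    score = df$score, strand = df$strand, label = label)
  sort_intervals(x)
}

#' Scan for maximal tandem repeats of a short unit
#'
#' Reports maximal runs of at least `min_units` consecutive copies of `unit`
#' (IUPAC codes allowed in the unit, so `"NA"` finds TA/CA/GA/AA mosaics).
#' Runs are found in every phase of the unit length; where runs in different
#' phases overlap, the longest (earliest on ties) is kept, so each locus
#' yields one maximal hit whose width is `units * nchar(unit)`. The unit
#' count is stored in the score column.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @param unit Repeat unit, e.g. `"CA"` or `"NA"`.
#' @param min_units Minimum number of consecutive units k (required; no
#'   silent default).
#' @param strand `"plus"` (default, the convention for repeat tracks) or
#'   `"both"`, which also scans the reverse complement and reports
#'   minus-strand hits in plus coordinates.
#' @return An [interval_set()] of hits with unit counts as scores.
#' @export
scan_tandem_repeats <- function(seqs, unit, min_units, strand = c("plus", "both")) {
  strand <- match.arg(strand)
  mask <- pattern_mask(unit)
  u <- length(mask)
  if (missing(min_units) || is.null(min_units) || min_units < 1) {
    stop("'min_units' (k) must be supplied and >= 1")
  }
  k <- as.integer(min_units)
  name <- paste0("(", toupper(unit), ")n")
  rows <- list()
  scan_one <- function(seq, chrom, strd, M_plus) {
    bits <- sequence_bits(seq)
    M <- length(bits)
    ok <- match_positions(bits, mask)
    runs <- list()
    for (p in seq_len(u) - 1L) {
      pos <- seq.int(p + 1L, by = u, length.out = max(0L, (length(ok) - p + u - 1L) %/% u))
      pos <- pos[pos <= length(ok)]
      if (!length(pos)) next
      r <- rle(ok[pos])
      ends_i <- cumsum(r$lengths)
      starts_i <- ends_i - r$lengths + 1L
      good <- which(r$values & r$lengths >= k)
      for (g in good) {
        units <- r$lengths[g]
        s0 <- pos[starts_i[g]] - 1L            # 0-based
        runs[[length(runs) + 1L]] <- c(s0, units)
      }
    }
    if (!length(runs)) return(NULL)
    m <- do.call(rbind, runs)
    # keep longest runs first, drop overlapping shorter alternatives
    o <- order(-m[, 2L], m[, 1L])
    m <- m[o, , drop = FALSE]
    kept <- matrix(numeric(0), ncol = 2L)
    for (r in seq_len(nrow(m))) {
      s0 <- m[r, 1L]; e0 <- s0 + m[r, 2L] * u
      if (nrow(kept) == 0 || all(e0 <= kept[, 1L] | s0 >= kept[, 2L])) {
        kept <- rbind(kept, c(s0, e0))
      }
    }
    s0 <- kept[, 1L]; e0 <- kept[, 2L]
    if (strd == "-") {  # map from revcomp coordinates back to plus
      tmp <- M_plus - e0
      e0 <- M_plus - s0
      s0 <- tmp
    }
    data.frame(chrom = chrom, start = s0, end = e0, name = name,
               score = (e0 - s0) / u, strand = strd, stringsAsFactors = FALSE)
  }
  for (ch in names(seqs)) {
    M <- nchar(seqs[[ch]])
    r <- scan_one(seqs[[ch]], ch, "+", M)
    if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    if (strand == "both") {
      r <- scan_one(revcomp(seqs[[ch]]), ch, "-", M)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  }
  motif_hits_set(rows, label = name)
}

#' Scan for alternating purine--pyrimidine (RY)k runs
#'
#' Finds maximal stretches in which adjacent bases alternate between purines
#' (A/G) and pyrimidines (C/T) -- the Z-DNA-prone class -- and reports those
#' with at least `min_units` dinucleotide alternations. The unit count is
#' `floor(stretch bp / 2)`; a trailing unpaired base of an odd-length stretch
#' is excluded from the reported interval. Scanning is plus-strand only: the
#' reverse complement of an alternating run is itself alternating, so the
#' same genomic stretches would be reported again.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @param min_units Minimum number of RY unit pairs k (e.g. 9 or 26).
#' @return An [interval_set()] of runs with unit counts as scores.
#' @export
scan_alternating_ry <- function(seqs, min_units) {
  if (missing(min_units) || min_units < 1) stop("'min_units' must be >= 1")
  k <- as.integer(min_units)
  rows <- list()
  for (ch in names(seqs)) {
    v <- strsplit(toupper(seqs[[ch]]), "", fixed = TRUE)[[1L]]
    cls <- integer(length(v))                 # 1 = purine, 2 = pyrimidine
    cls[v %in% c("A", "G")] <- 1L
    cls[v %in% c("C", "T")] <- 2L
    if (length(v) < 2L) next
    alt <- cls[-length(cls)] != 0L & cls[-1L] != 0L &
      cls[-length(cls)] != cls[-1L]
    r <- rle(alt)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    good <- which(r$values)
    for (g in good) {
      bp <- r$lengths[g] + 1L                 # adjacent-pair run -> bases
      units <- bp %/% 2L
      if (units < k) next
      s0 <- starts_i[g] - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = s0, end = s0 + 2L * units,
        name = "(RY)n", score = units, strand = "+",
        stringsAsFactors = FALSE)
    }
  }
  motif_hits_set(rows, label = "(RY)n")
}

#' Scan for a fixed-length IUPAC consensus motif
#'
#' Every window of pattern length matching at all positions is reported.
#' With `strand = "both"` (the default, as consensus motifs are searched on
#' both strands) the reverse complement of the sequence is scanned too and
#' minus-strand hits are reported in plus coordinates.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @param pattern IUPAC consensus, e.g. `"RNYNNCNNGYNGKTNYNY"`.
#' @param strand `"both"` (default) or `"plus"`.
#' @return An [interval_set()] of hits (score 1 per hit).
#' @export
scan_iupac <- function(seqs, pattern, strand = c("both", "plus")) {
  strand <- match.arg(strand)
  mask <- pattern_mask(pattern)
  L <- length(mask)
  rows <- list()
  for (ch in names(seqs)) {
    seq <- seqs[[ch]]
    M <- nchar(seq)
    ok <- match_positions(sequence_bits(seq), mask)
    s0 <- which(ok) - 1L
    if (length(s0)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = s0, end = s0 + L, name = toupper(pattern),
        score = 1, strand = "+", stringsAsFactors = FALSE)
    }
    if (strand == "both") {
      okm <- match_positions(sequence_bits(revcomp(seq)), mask)
      p0 <- which(okm) - 1L
      if (length(p0)) {
        s0m <- M - p0 - L
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = s0m, end = s0m + L, name = toupper(pattern),
          score = 1, strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  motif_hits_set(rows, label = toupper(pattern))
}

#' Fraction of peaks containing a motif, and the converse
#'
#' `peak_motif_fraction()` is the fraction of peaks overlapping at least one
#' motif hit by >= 1 bp (e.g. "the (CA)n motif is present in 43.2% of
#' peaks"); `motif_overlap_fraction()` swaps the roles (e.g. "17.2% of all
#' (CA)n repeats overlap peaks").
#'
#' @param peaks,hits [interval_set()] objects.
#' @return A fraction in `[0, 1]`.
#' @export
peak_motif_fraction <- function(peaks, hits) {
  stopifnot(inherits(peaks, "interval_set"), inherits(hits, "interval_set"))
  if (nrow(peaks) == 0) stop("fraction undefined: empty peak set")
  sum(overlaps_any(peaks, hits)) / nrow(peaks)
}

#' @rdname peak_motif_fraction
#' @export
motif_overlap_fraction <- function(hits, peaks) {
  stopifnot(inherits(peaks, "interval_set"), inherits(hits, "interval_set"))
  if (nrow(hits) == 0) stop("fraction undefined: empty hit set")
  sum(overlaps_any(hits, peaks)) / nrow(hits)
}
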