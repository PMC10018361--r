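# Independent oracles used across the suite.
#
# Interval algebra is checked against a per-base boolean-array model: each
# chromosome is a logical vector, operations are plain vector logic, and
# intervals are recovered as runs of TRUE. Motif scanners are checked against
# naive character-by-character sliding-window loops. Permutation nulls are
# checked against exhaustive enumeration of all placements on small toys.

# ---- per-base interval model ------------------------------------------------

oracle_mask <- function(x, lens) {
  masks <- lapply(lens, function(l) logical(l))
  for (i in seq_len(nrow(x))) {
    ch <- x$chrom[i]
    masks[[ch]][(x$start[i] + 1):x$end[i]] <- TRUE
  }
  masks
}

mask_to_df <- function(masks) {
  out <- lapply(sort(names(masks)), function(ch) {
    r <- rle(masks[[ch]])
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = s[keep], end = e[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(chrom = character(), start = numeric(),
                               end = numeric(), stringsAsFactors = FALSE)
  else out
}

oracle_merge <- function(x, lens) mask_to_df(oracle_mask(x, lens))

oracle_intersect_regions <- function(a, b, lens) {
  ma <- oracle_mask(a, lens); mb <- oracle_mask(b, lens)
  mask_to_df(Map(`&`, ma, mb))
}

oracle_intersect_bp <- function(a, b, lens) {
  ma <- oracle_mask(a, lens); mb <- oracle_mask(b, lens)
  sum(vapply(names(ma), function(ch) sum(ma[[ch]] & mb[[ch]]), 1))
}

oracle_count_hits <- function(a, b, lens) {
  mb <- oracle_mask(b, lens)
  hits <- vapply(seq_len(nrow(a)), function(i) {
    any(mb[[a$chrom[i]]][(a$start[i] + 1):a$end[i]])
  }, TRUE)
  sum(hits)
}

oracle_subtract_perbase <- function(a, b, lens) {
  ma <- oracle_mask(a, lens); mb <- oracle_mask(b, lens)
  mask_to_df(Map(function(x, y) x & !y, ma, mb))
}

oracle_subtract_drop <- function(a, b, lens) {
  mb <- oracle_mask(b, lens)
  keep <- vapply(seq_len(nrow(a)), function(i) {
    !any(mb[[a$chrom[i]]][(a$start[i] + 1):a$end[i]])
  }, TRUE)
  as.data.frame(a)[keep, c("chrom", "start", "end"), drop = FALSE]
}

# random interval set on a small named-length genome
random_iset <- function(lens, n) {
  ch <- sample(names(lens), n, replace = TRUE)
  w <- sample.int(200, n, replace = TRUE)
  w <- pmin(w, lens[ch])
  s <- floor(runif(n) * (lens[ch] - w + 1))
  interval_set(ch, s, s + w)
}

coords_df <- function(x) {
  df <- as.data.frame(x)[, c("chrom", "start", "end")]
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

expect_same_regions <- function(x, df) {
  expect_equal(coords_df(x), {
    d <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
}

# ---- naive motif oracles ----------------------------------------------------

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = c("T"), U = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T", "N"))

naive_char_match <- function(seq_char, pat_char) {
  if (!seq_char %in% c("A", "C", "G", "T")) seq_char <- "N"
  if (seq_char == "N") return(pat_char == "N")
  seq_char %in% IUPAC_SETS[[pat_char]]
}

naive_window_match <- function(chars, pos, pat) {
  all(vapply(seq_along(pat), function(j) {
    naive_char_match(chars[pos + j - 1L], pat[j])
  }, TRUE))
}

naive_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ch <- strsplit(toupper(seq), "")[[1L]]
  ch[!ch %in% names(comp)] <- "N"
  paste(rev(comp[ch]), collapse = "")
}

naive_scan_iupac_plus <- function(seq, pattern) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  pat <- strsplit(toupper(pattern), "")[[1L]]
  L <- length(pat); M <- length(chars)
  if (M < L) return(integer(0))
  which(vapply(seq_len(M - L + 1L), function(p) {
    naive_window_match(chars, p, pat)
  }, TRUE)) - 1L
}

# maximal per-phase tandem runs >= k units, longest-first non-overlapping
naive_scan_tandem <- function(seq, unit, k) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  pat <- strsplit(toupper(unit), "")[[1L]]
  u <- length(pat); M <- length(chars)
  runs <- NULL
  for (p in seq_len(u) - 1L) {
    i <- p + 1L
    while (i + u - 1L <= M) {
      if (naive_window_match(chars, i, pat)) {
        units <- 1L
        while (i + (units + 1L) * u - 1L <= M &&
               naive_window_match(chars, i + units * u, pat)) {
          units <- units + 1L
        }
        if (units >= k) runs <- rbind(runs, c(i - 1L, units))
        i <- i + units * u
      } else i <- i + u
    }
  }
  if (is.null(runs)) {
    return(data.frame(start = numeric(), end = numeric(), units = numeric()))
  }
  runs <- runs[order(-runs[, 2L], runs[, 1L]), , drop = FALSE]
  kept <- NULL
  for (r in seq_len(nrow(runs))) {
    s <- runs[r, 1L]; e <- s + runs[r, 2L] * u
    if (is.null(kept) || all(e <= kept[, 1L] | s >= kept[, 2L])) {
      kept <- rbind(kept, c(s, e))
    }
  }
  kept <- kept[order(kept[, 1L]), , drop = FALSE]
  data.frame(start = kept[, 1L], end = kept[, 2L],
             units = (kept[, 2L] - kept[, 1L]) / u)
}

naive_scan_ry <- function(seq, k) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  cls <- ifelse(chars %in% c("A", "G"), 1L,
                ifelse(chars %in% c("C", "T"), 2L, 0L))
  M <- length(cls)
  out <- NULL
  i <- 1L
  while (i <= M) {
    if (cls[i] == 0L) { i <- i + 1L; next }
    j <- i
    while (j < M && cls[j + 1L] != 0L && cls[j + 1L] != cls[j]) j <- j + 1L
    bp <- j - i + 1L
    units <- bp %/% 2L
    if (units >= k) out <- rbind(out, c(i - 1L, i - 1L + 2L * units, units))
    i <- j + 1L
  }
  if (is.null(out)) {
    return(data.frame(start = numeric(), end = numeric(), units = numeric()))
  }
  data.frame(start = out[, 1L], end = out[, 2L], units = out[, 3L])
}

random_sequence <- function(len, n_frac = 0.02) {
  b <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  nn <- floor(n_frac * len)
  if (nn > 0) b[sample.int(len, nn)] <- "N"
  paste(b, collapse = "")
}

# ---- exact placement-enumeration expectation --------------------------------

# expected statistic of a query under uniform placement on one chromosome,
# enumerating every start for every query interval independently
exact_expected_stat <- function(query, reference, len, statistic) {
  mref <- logical(len)
  for (i in seq_len(nrow(reference))) {
    mref[(reference$start[i] + 1):reference$end[i]] <- TRUE
  }
  cum <- c(0, cumsum(mref))
  total <- 0
  for (i in seq_len(nrow(query))) {
    w <- query$end[i] - query$start[i]
    starts <- 0:(len - w)
    ov <- cum[starts + w + 1] - cum[starts + 1]
    total <- total + if (statistic == "count") mean(ov > 0) else mean(ov)
  }
  total
}
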