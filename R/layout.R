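#' Genome layout (chromosome sizes)
#'
#' A genome layout anchors all coordinates in the package: an ordered table of
#' chromosome names and lengths, as found in a standard `chrom.sizes` file.
#' Interval sets and window grids are validated against it.
#'
#' @param chrom Character vector of unique, non-empty chromosome names.
#' @param length Numeric vector of chromosome lengths in base pairs (>= 1).
#'   Stored as doubles so whole-genome totals never overflow 32-bit integers.
#' @return A data frame of class `genome_layout` with columns `chrom` and
#'   `length`, preserving the input order.
#' @examples
#' gl <- genome_layout(c("chr1", "chr2"), c(2e6, 1e6))
#' genome_size(gl)
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (base::length(chrom) != base::length(length)) {
    stop("'chrom' and 'length' must have the same length")
  }
  if (any(!nzchar(chrom)) || anyNA(chrom)) {
    stop("chromosome names must be non-empty")
  }
  if (anyDuplicated(chrom)) {
    stop("duplicated chromosome name: ", chrom[anyDuplicated(chrom)])
  }
  if (anyNA(length) || any(length < 1) || any(length != floor(length))) {
    stop("chromosome lengths must be positive integers")
  }
  structure(
    data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
    class = c("genome_layout", "data.frame")
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", nrow(x), " chromosome(s), ",
      format(genome_size(x), big.mark = ","), " bp\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more\n")
  invisible(x)
}

#' Total genome size of a layout
#' @param layout A [genome_layout()].
#' @return Total length in base pairs.
#' @export
genome_size <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(layout$length)
}

#' Look up chromosome lengths in a layout
#' @param layout A [genome_layout()].
#' @param chrom Character vector of chromosome names.
#' @return Numeric vector of lengths; errors on unknown chromosomes.
#' @export
chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(i)]), collapse = ", "))
  }
  layout$length[i]
}

#' Read and write chrom.sizes files
#'
#' `chrom.sizes` is the two-column tab-separated table (name, length) used by
#' the UCSC toolchain. Comment lines starting with `#` are skipped on read.
#'
#' @param path File path.
#' @return `read_chrom_sizes()` returns a [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_layout(df$chrom, df$length)
}

#' @rdname read_chrom_sizes
#' @param layout A [genome_layout()] to write.
#' @export
write_chrom_sizes <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  utils::write.table(as.data.frame(layout), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Optional "chr" prefix normalisation; exact matching stays the default
# everywhere, this helper is opt-in.

#' Toggle the "chr" prefix on chromosome names
#'
#' Chromosome matching in this package is exact text matching. When two data
#' sources disagree about the UCSC `chr` prefix, normalise one of them
#' explicitly with this helper.
#'
#' @param x Character vector of chromosome names, a [genome_layout()] or an
#'   [interval_set()].
#' @param add If `TRUE` ensure the `chr` prefix is present, otherwise strip it.
#' @return Object of the same type with renamed chromosomes.
#' @export
normalize_chrom_prefix <- function(x, add = TRUE) {
  fix <- function(nm) {
    has <- startsWith(nm, "chr")
    if (add) ifelse(has, nm, paste0("chr", nm)) else ifelse(has, substring(nm, 4), nm)
  }
  if (is.character(x)) return(fix(x))
  if (inherits(x, "genome_layout")) return(genome_layout(fix(x$chrom), x$length))
  if (inherits(x, "interval_set")) {
    x$chrom <- fix(x$chrom)
    return(x)
  }
  stop("unsupported type for chromosome renaming")
}
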