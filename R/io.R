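#' Read a BED3/BED6 file into an interval set
#'
#' Tab-separated, headerless BED as written by the common peak callers and
#' genome-arithmetic tools. `track`/`browser` lines and `#` comments are
#' skipped. Coordinates stay 0-based half-open. Parsing is delegated to
#' `rtracklayer::import` after comment filtering.
#'
#' @param path BED file path.
#' @param label Provenance label; defaults to the file name.
#' @param layout Optional [genome_layout()] to validate against.
#' @return An [interval_set()].
#' @export
read_bed <- function(path, label = basename(path), layout = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  tmp <- tempfile(fileext = ".bed")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines[keep], tmp)
  if (!any(keep)) {
    return(interval_set(label = label))
  }
  gr <- rtracklayer::import(tmp, format = "BED")
  md <- S4Vectors::mcols(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  x <- interval_set(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    name = if ("name" %in% names(md)) as.character(md$name) else NA_character_,
    score = if ("score" %in% names(md)) as.numeric(md$score) else NA_real_,
    strand = strand,
    label = label
  )
  if (!is.null(layout)) validate_against_layout(x, layout)
  x
}

#' Write an interval set as BED
#'
#' Writes BED3 when no record has a name, score or strand, BED6 otherwise.
#' Optional `#`-prefixed header comments (skipped by [read_bed()]) can carry
#' provenance.
#'
#' @param x An [interval_set()].
#' @param path Output path.
#' @param comments Character vector of header comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, comments = character()) {
  stopifnot(inherits(x, "interval_set"))
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  if (length(comments)) writeLines(paste0("# ", comments), con)
  bed6 <- nrow(x) > 0 &&
    (any(!is.na(x$name)) || any(!is.na(x$score)) || any(x$strand != "."))
  df <- data.frame(chrom = x$chrom,
                   start = format(x$start, scientific = FALSE, trim = TRUE),
                   end = format(x$end, scientific = FALSE, trim = TRUE),
                   stringsAsFactors = FALSE)
  if (bed6) {
    df$name <- ifelse(is.na(x$name), ".", x$name)
    df$score <- ifelse(is.na(x$score), 0, x$score)
    df$strand <- x$strand
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a multi-record FASTA file
#'
#' @param path FASTA path (plain text; line wrapping and lower case allowed).
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
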