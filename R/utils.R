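#' @importFrom stats rbinom rlnorm rnorm runif setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

# Coordinate conventions: 0-based half-open everywhere internally;
# 1-based inclusive "ref:start..end" (GenBank style) at human-facing edges.

#' Parse a 1-based inclusive region string into 0-based half-open coordinates
#'
#' Accepts the GenBank-style dialect used in locus tables, e.g.
#' `"DQ537336.1:29,265..35,054"`. Thousands separators are ignored.
#'
#' @param x character vector of `"ref:start..end"` strings (1-based inclusive).
#' @return data.frame with columns `reference_id`, `start`, `end`
#'   (0-based half-open).
#' @examples
#' parse_region("chr1:101..200")  # start 100, end 200
#' @export
parse_region <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  m <- regmatches(x, regexec("^(.+):([0-9,]+)\\.\\.([0-9,]+)$", x))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) {
    stop("malformed region string(s): ", paste(x[bad], collapse = ", "),
         " (expected \"ref:start..end\", 1-based inclusive)")
  }
  ref <- vapply(m, `[[`, "", 2L)
  s1 <- as.integer(gsub(",", "", vapply(m, `[[`, "", 3L)))
  e1 <- as.integer(gsub(",", "", vapply(m, `[[`, "", 4L)))
  if (any(s1 < 1L) || any(e1 < s1)) {
    stop("region coordinates must satisfy 1 <= start <= end")
  }
  data.frame(reference_id = ref, start = s1 - 1L, end = e1,
             stringsAsFactors = FALSE)
}

#' Format 0-based half-open coordinates as a 1-based inclusive region string
#'
#' @param reference_id character reference name(s).
#' @param start,end integer 0-based half-open interval(s).
#' @return character vector `"ref:start..end"` (1-based inclusive).
#' @export
format_region <- function(reference_id, start, end) {
  stopifnot(all(end > start), all(start >= 0))
  sprintf("%s:%s..%s", reference_id,
          formatC(start + 1L, format = "d", big.mark = ","),
          formatC(end, format = "d", big.mark = ","))
}

# Uppercase a DNA string and check the alphabet. `allow` is the permitted set.
.check_dna <- function(seq, allow = c("A", "C", "G", "T", "N"),
                       what = "sequence") {
  seq <- toupper(as.character(seq))
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1L]])
  bad <- setdiff(chars, allow)
  if (length(bad) > 0L) {
    stop("non-DNA characters in ", what, ": ",
         paste(bad, collapse = ", "))
  }
  seq
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Atomic write: write via a tempfile in the destination directory, then rename.
.atomic_write <- function(writer, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}

#' Write a BED file (0-based half-open) for a set of intervals
#'
#' @param intervals data.frame with columns `reference_id`, `start`, `end` and
#'   optionally `name` and `score`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("reference_id", "start", "end") %in% names(intervals)))
  df <- data.frame(chrom = intervals$reference_id,
                   start = as.integer(intervals$start),
                   end = as.integer(intervals$end))
  if (!is.null(intervals$name)) df$name <- intervals$name
  if (!is.null(intervals$score)) {
    if (is.null(df$name)) df$name <- "."
    df$score <- intervals$score
  }
  .atomic_write(function(tmp) {
    write.table(df, tmp, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }, path)
}

# Overlap length of [s1,e1) with [s2,e2)
.overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}
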