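# Read QC and enrichment accounting for Cas9-targeted nanopore runs:
# mean-quality filtering, N50, on-target read classification, per-locus
# depth, genome-wide coverage and the enrichment rate.

#' Construct a target locus
#'
#' @param name locus label (e.g. a gene name).
#' @param region either a 1-based inclusive `"ref:start..end"` string or a
#'   list/data.frame row with `reference_id`, `start`, `end` already 0-based
#'   half-open.
#' @return object of class `target_locus` with fields `name`, `reference_id`,
#'   `start`, `end` (0-based half-open).
#' @examples
#' target_locus("Glu-1By", "DQ537336.1:29,265..35,054")
#' @export
target_locus <- function(name, region) {
  if (is.character(region) && length(region) == 1L) {
    region <- parse_region(region)
  }
  stopifnot(all(c("reference_id", "start", "end") %in% names(region)))
  start <- as.integer(region$start[1L])
  end <- as.integer(region$end[1L])
  if (end <= start || start < 0L) stop("locus interval must be non-empty")
  structure(list(name = name, reference_id = region$reference_id[1L],
                 start = start, end = end),
            class = "target_locus")
}

#' @export
print.target_locus <- function(x, ...) {
  cat(sprintf("<target_locus> %s  %s (%d bp)\n", x$name,
              format_region(x$reference_id, x$start, x$end),
              x$end - x$start))
  invisible(x)
}

#' Read FASTQ and filter reads by mean quality
#'
#' The per-read quality is computed from the mean per-base error probability,
#' `Q = -10 log10(mean(10^(-q_i/10)))`, matching basecaller-reported read
#' Qscores; a read is retained iff `Q > min_q` (strict, as in "Qscore > 8").
#'
#' @param fastq path to an (uncompressed or gzipped) FASTQ file.
#' @param min_q minimum mean read quality (exclusive); default 8.
#' @return list with `stats` (class `read_stats`: `n_reads`, `total_bases`,
#'   `n50`, `min_qscore_applied`), `ids`, `lengths` and `mean_q` of the
#'   retained reads.
#' @export
filter_reads_by_qscore <- function(fastq, min_q = 8) {
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq",
                                        with.qualities = TRUE)
  if (length(reads) == 0L) {
    stats <- structure(list(n_reads = 0L, total_bases = 0L, n50 = 0L,
                            min_qscore_applied = min_q),
                       class = "read_stats")
    return(list(stats = stats, ids = character(), lengths = integer(),
                mean_q = numeric()))
  }
  quals <- as.character(S4Vectors::mcols(reads)$qualities)
  mean_q <- vapply(quals, function(q) {
    phred <- utf8ToInt(q) - 33L
    if (any(phred < 0L)) stop("invalid Phred+33 quality string")
    -10 * log10(mean(10^(-phred / 10)))
  }, 0, USE.NAMES = FALSE)
  keep <- mean_q > min_q
  ids <- sub("\\s.*$", "", names(reads))[keep]
  lens <- Biostrings::width(reads)[keep]
  stats <- structure(list(
    n_reads = sum(keep),
    total_bases = sum(lens),
    n50 = if (sum(keep) > 0L) compute_n50(lens) else 0L,
    min_qscore_applied = min_q), class = "read_stats")
  list(stats = stats, ids = ids, lengths = lens, mean_q = mean_q[keep])
}

#' @export
print.read_stats <- function(x, ...) {
  cat(sprintf("<read_stats> %d reads, %.3f Mb, N50 = %d bp (Q > %g)\n",
              x$n_reads, x$total_bases / 1e6, x$n50, x$min_qscore_applied))
  invisible(x)
}

#' Compute the N50 of a set of read lengths
#'
#' The largest length `L` such that reads of length >= `L` together contain
#' at least half the total yield.
#'
#' @param lengths positive integer vector of read lengths.
#' @return integer N50 (always one of the input lengths).
#' @examples
#' compute_n50(c(10, 2, 2, 2))  # 10
#' @export
compute_n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("cannot compute N50 of an empty length set")
  stopifnot(all(lengths > 0))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

# Read primary alignments from SAM or BAM into a GAlignments with qnames.
# SAM input is converted on the fly via Rsamtools.
.read_primary_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  } else {
    bam <- path
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flag, what = "qname"),
    use.names = FALSE)
}

.check_locus_ref <- function(aln, locus) {
  if (!locus$reference_id %in% GenomeInfoDb::seqlevels(aln)) {
    stop("reference \"", locus$reference_id,
         "\" absent from alignment header")
  }
}

#' Classify reads as on-target per locus
#'
#' A read is on-target for a locus iff its primary alignment overlaps the
#' locus interval by at least `min_overlap_bp` reference bases. Unmapped,
#' secondary and supplementary records are ignored.
#'
#' @param alignments path to a SAM/BAM file, or a `GAlignments` object with a
#'   `qname` metadata column.
#' @param loci list of [target_locus()] objects (or a single one).
#' @param min_overlap_bp minimum reference overlap in bp; default 200
#'   (excludes adapter-level touches at nanopore read lengths).
#' @return named list (one element per locus) of unique on-target read names.
#' @export
classify_on_target <- function(alignments, loci, min_overlap_bp = 200L) {
  if (inherits(loci, "target_locus")) loci <- list(loci)
  aln <- if (is.character(alignments)) {
    .read_primary_alignments(alignments)
  } else alignments
  res <- lapply(loci, function(locus) {
    .check_locus_ref(aln, locus)
    gr <- GenomicRanges::GRanges(
      locus$reference_id,
      IRanges::IRanges(locus$start + 1L, locus$end))
    hits <- GenomicRanges::findOverlaps(
      GenomicAlignments::granges(aln), gr,
      minoverlap = as.integer(min_overlap_bp))
    unique(S4Vectors::mcols(aln)$qname[S4Vectors::queryHits(hits)])
  })
  names(res) <- vapply(loci, `[[`, "", "name")
  res
}

#' Mean sequencing depth over a target locus
#'
#' Depth at a position counts primary-alignment read bases covering it:
#' deletions in the read do not cover, insertions do not add.
#'
#' @inheritParams classify_on_target
#' @param locus a [target_locus()].
#' @return mean depth (x) as a single numeric.
#' @export
mean_target_depth <- function(alignments, locus) {
  aln <- if (is.character(alignments)) {
    .read_primary_alignments(alignments)
  } else alignments
  .check_locus_ref(aln, locus)
  # drop.D.ranges = TRUE: deleted reference bases are not covered
  cov <- GenomicRanges::coverage(
    GenomicAlignments::grglist(aln, drop.D.ranges = TRUE))
  rc <- cov[[locus$reference_id]]
  n <- locus$end - locus$start
  if (length(rc) < locus$end) {
    rc <- c(rc, S4Vectors::Rle(0L, locus$end - length(rc)))
  }
  sum(as.numeric(rc[(locus$start + 1L):locus$end])) / n
}

#' Genome-wide coverage implied by total sequenced bases
#'
#' @param total_bases total retained read bases (bp), aligned or not.
#' @param genome_size haploid genome size (bp); must be positive.
#' @return coverage in x (`total_bases / genome_size`).
#' @examples
#' genome_coverage(547e6, 24e9)  # ~0.02x
#' @export
genome_coverage <- function(total_bases, genome_size) {
  if (!is.numeric(genome_size) || genome_size <= 0) {
    stop("genome_size must be positive")
  }
  stopifnot(total_bases >= 0)
  total_bases / genome_size
}

#' Enrichment rate of a target locus
#'
#' Fold-excess of on-target mean depth over the genome-wide coverage expected
#' from the total yield: `mean_depth / genome_coverage`.
#'
#' @param mean_depth mean on-target depth (x).
#' @param genome_coverage genome-wide coverage (x); must be positive.
#' @return enrichment rate (x).
#' @export
enrichment_rate <- function(mean_depth, genome_coverage) {
  if (!is.numeric(genome_coverage) || any(genome_coverage <= 0)) {
    stop("genome_coverage must be positive")
  }
  stopifnot(all(mean_depth >= 0))
  mean_depth / genome_coverage
}

#' Fraction of all reads that are on-target
#'
#' @param per_locus_reads named list of on-target read-name sets, as returned
#'   by [classify_on_target()].
#' @param n_total_reads total number of (retained) reads; must be positive.
#' @return fraction in `[0, 1]`: unique on-target reads across all loci over
#'   the total.
#' @export
on_target_fraction <- function(per_locus_reads, n_total_reads) {
  stopifnot(n_total_reads > 0)
  n_on <- length(unique(unlist(per_locus_reads, use.names = FALSE)))
  n_on / n_total_reads
}

#' Per-locus enrichment report
#'
#' Combines on-target classification, per-locus mean depth, genome-wide
#' coverage and the enrichment rate into one table.
#'
#' @inheritParams classify_on_target
#' @param total_bases total retained read bases (bp).
#' @param genome_size haploid genome size (bp).
#' @return data.frame (class `enrichment_report`) with one row per locus:
#'   `locus`, `region`, `n_on_target_reads`, `mean_depth`, `genome_coverage`,
#'   `enrichment_rate`.
#' @export
enrichment_report <- function(alignments, loci, total_bases, genome_size,
                              min_overlap_bp = 200L) {
  if (inherits(loci, "target_locus")) loci <- list(loci)
  aln <- if (is.character(alignments)) {
    .read_primary_alignments(alignments)
  } else alignments
  cov <- genome_coverage(total_bases, genome_size)
  on <- classify_on_target(aln, loci, min_overlap_bp)
  depth <- vapply(loci, function(l) mean_target_depth(aln, l), 0)
  out <- data.frame(
    locus = names(on),
    region = vapply(loci, function(l)
      format_region(l$reference_id, l$start, l$end), ""),
    n_on_target_reads = lengths(on),
    mean_depth = depth,
    genome_coverage = cov,
    enrichment_rate = enrichment_rate(depth, cov),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("enrichment_report", class(out))
  out
}

#' Write an enrichment report as TSV
#'
#' @param report data.frame from [enrichment_report()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_enrichment_report <- function(report, path) {
  .atomic_write(function(tmp) {
    write.table(report, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}
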