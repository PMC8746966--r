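# Conversion of per-read, reference-anchored cytosine methylation calls
# (DeepSignal-plant-style tables) into standard SAM MM:Z / ML:B:C
# base-modification tags, plus a decoder used as a round-trip oracle.
#
# MM grammar used here: "C+m?,d1,d2,...;" where d_i counts the SKIPPED
# canonical bases (C) in the read's original-orientation sequence between
# the previous listed C (exclusive) and this one (exclusive). Skip mode '?'
# declares unlisted Cs as "no call", which matches the sparse per-read
# calls this pipeline consumes. ML holds floor(prob*256) capped at 255.

# Named column layouts for caller tables. Positions are 0-based reference
# coordinates in the deepsignal_plant dialect.
.meth_dialects <- list(
  deepsignal_plant = c(chrom = 1L, pos = 2L, strand = 3L, pos_in_strand = 4L,
                       read_id = 5L, read_strand = 6L, prob_unmeth = 7L,
                       prob_meth = 8L, label = 9L, kmer = 10L)
)

#' Parse a per-read methylation call table
#'
#' @param path tab-separated call table, no header, one call per row.
#' @param dialect named column layout; currently `"deepsignal_plant"`
#'   (chrom, pos, strand, pos_in_strand, read name, read strand,
#'   prob_unmeth, prob_meth, label, k-mer; positions 0-based).
#' @return data.frame with columns `read_id`, `reference_id`, `ref_pos`
#'   (0-based), `ref_strand`, `prob_meth`, `context`, `called_label`.
#'   Rows with a probability outside `[0, 1]` are dropped with a warning;
#'   the number dropped is attached as attribute `n_malformed`.
#' @export
parse_meth_calls <- function(path, dialect = "deepsignal_plant") {
  if (!dialect %in% names(.meth_dialects)) {
    stop("unknown call-table dialect: ", dialect)
  }
  lay <- .meth_dialects[[dialect]]
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < max(lay)) {
    stop("call table has ", ncol(tab), " columns; dialect \"", dialect,
         "\" needs at least ", max(lay))
  }
  out <- data.frame(
    read_id = as.character(tab[[lay["read_id"]]]),
    reference_id = as.character(tab[[lay["chrom"]]]),
    ref_pos = as.integer(tab[[lay["pos"]]]),
    ref_strand = as.character(tab[[lay["strand"]]]),
    prob_meth = as.numeric(tab[[lay["prob_meth"]]]),
    context = as.character(tab[[lay["kmer"]]]),
    called_label = as.integer(tab[[lay["label"]]]),
    stringsAsFactors = FALSE)
  bad <- !is.finite(out$prob_meth) | out$prob_meth < 0 | out$prob_meth > 1 |
    is.na(out$ref_pos) | out$ref_pos < 0
  if (any(bad)) {
    warning(sum(bad), " malformed call row(s) rejected")
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_malformed") <- sum(bad)
  out
}

# Split a CIGAR string into op lengths and op letters.
.cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*") stop("missing CIGAR")
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (length(toks) == 0L || nchar(paste(toks, collapse = "")) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar)
  }
  list(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}

#' Map reference positions to read positions through a CIGAR
#'
#' Walks the alignment and returns, for each requested reference position,
#' the corresponding 0-based position in the read's ORIGINAL orientation
#' (i.e. the sequence as basecalled, before any reverse-complementing by the
#' aligner), or `NA` when the position falls in a deletion/skip or outside
#' the aligned span.
#'
#' @param cigar CIGAR string (ops M/I/D/N/S/H/P/=/X).
#' @param aln_start 0-based reference start of the alignment.
#' @param is_reverse logical; TRUE when the read aligned to the minus strand.
#' @param read_length length of the read sequence as stored (SEQ field).
#' @param ref_positions sorted integer vector of 0-based reference positions.
#' @return integer vector parallel to `ref_positions` (`NA` = not mappable).
#' @examples
#' ref_to_read_positions("10M", 100, FALSE, 10, c(102))          # 2
#' ref_to_read_positions("10M", 100, TRUE, 10, c(102))           # 7
#' ref_to_read_positions("2S4M1D4M", 50, FALSE, 10, c(54, 55))   # NA, 6
#' @export
ref_to_read_positions <- function(cigar, aln_start, is_reverse, read_length,
                                  ref_positions) {
  ops <- .cigar_ops(cigar)
  read_length <- as.integer(read_length)
  aln_start <- as.integer(aln_start)
  qlen <- sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
  if (qlen != read_length) {
    stop("CIGAR implies query length ", qlen, " but read_length is ",
         read_length)
  }
  out <- rep(NA_integer_, length(ref_positions))
  r <- as.integer(aln_start)  # next reference position consumed
  q <- 0L                     # next query (SEQ) position consumed
  for (i in seq_along(ops$op)) {
    len <- ops$len[i]
    op <- ops$op[i]
    if (op %in% c("M", "=", "X")) {
      hit <- which(ref_positions >= r & ref_positions < r + len)
      if (length(hit) > 0L) out[hit] <- q + (ref_positions[hit] - r)
      r <- r + len
      q <- q + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      r <- r + len  # reference consumed, no read base: positions stay NA
    }
    # H and P consume neither SEQ nor reference
  }
  if (is_reverse) {
    mapped <- !is.na(out)
    out[mapped] <- read_length - 1L - out[mapped]
  }
  out
}

#' Encode base-modification positions as SAM MM/ML tag values
#'
#' @param read_seq read sequence in ORIGINAL orientation (as basecalled).
#' @param mod_positions strictly increasing 0-based indices into
#'   `read_seq`; each must hold the canonical `base`.
#' @param probs modification probabilities in `[0, 1]`, parallel to
#'   `mod_positions`.
#' @param base canonical base letter; default `"C"`.
#' @param code modification code; default `"m"` (5mC).
#' @param skip_mode `"?"` (unlisted canonical bases carry no call) or `"."`.
#' @return `list(mm = "C+m?,...;", ml = integer ML values)`, or
#'   `list(mm = NULL, ml = NULL)` when there are no positions.
#' @examples
#' encode_mm("ACGCA", 3L, 1.0)            # MM "C+m?,1;", ML 255
#' encode_mm("CCCC", c(0L, 3L), c(.5, .25))  # MM "C+m?,0,2;", ML 128, 64
#' @export
encode_mm <- function(read_seq, mod_positions, probs, base = "C",
                      code = "m", skip_mode = "?") {
  if (length(mod_positions) == 0L) return(list(mm = NULL, ml = NULL))
  stopifnot(length(probs) == length(mod_positions),
            all(probs >= 0 & probs <= 1),
            !is.unsorted(mod_positions, strictly = TRUE))
  chars <- strsplit(toupper(read_seq), "", fixed = TRUE)[[1L]]
  on_base <- chars[mod_positions + 1L] == base
  if (!all(on_base)) {
    stop("modification position(s) ",
         paste(mod_positions[!on_base], collapse = ", "),
         " do not hold base ", base,
         " (upstream coordinate-mapping inconsistency)")
  }
  base_idx <- which(chars == base) - 1L          # 0-based positions of `base`
  rank <- match(mod_positions, base_idx)          # 1-based rank among bases
  deltas <- diff(c(0L, rank)) - 1L                # skipped bases in between
  list(
    mm = paste0(base, "+", code, skip_mode, ",",
                paste(deltas, collapse = ","), ";"),
    ml = as.integer(pmin(floor(probs * 256), 255))
  )
}

#' Decode SAM MM/ML tag values back to read positions and probabilities
#'
#' Inverse of [encode_mm()] up to ML quantisation (probabilities are
#' recovered as `(ml + 0.5) / 256`, the midpoint of the encoded bin).
#'
#' @param read_seq read sequence in original orientation.
#' @param mm_tag MM tag value (may contain several `;`-terminated items;
#'   only `base+code` items matching `base`/`code` are decoded).
#' @param ml_values integer ML values parallel to the listed positions.
#' @param base,code canonical base and modification code to decode.
#' @return `list(positions = 0-based indices, probs = numeric)`.
#' @export
decode_mm <- function(read_seq, mm_tag, ml_values = NULL, base = "C",
                      code = "m") {
  if (is.null(mm_tag) || !nzchar(mm_tag)) {
    return(list(positions = integer(), probs = numeric()))
  }
  items <- strsplit(mm_tag, ";", fixed = TRUE)[[1L]]
  chars <- strsplit(toupper(read_seq), "", fixed = TRUE)[[1L]]
  positions <- integer()
  n_before <- 0L  # ML values consumed by preceding items
  for (item in items) {
    if (!nzchar(item)) next
    m <- regexec("^([ACGTUN])([-+])([a-zA-Z0-9]+)([.?]?)(,.*)?$", item)[[1L]]
    if (m[1L] == -1L) stop("malformed MM item: ", item)
    parts <- regmatches(item, regexec(
      "^([ACGTUN])([-+])([a-zA-Z0-9]+)([.?]?)(,.*)?$", item))[[1L]]
    delta_str <- parts[6L]
    deltas <- if (is.na(delta_str) || !nzchar(delta_str)) integer() else
      as.integer(strsplit(sub("^,", "", delta_str), ",", fixed = TRUE)[[1L]])
    if (parts[2L] != base || parts[4L] != code) {
      n_before <- n_before + length(deltas)
      next
    }
    base_idx <- which(chars == base) - 1L
    rank <- cumsum(deltas + 1L)
    if (length(rank) > 0L && max(rank) > length(base_idx)) {
      stop("MM deltas walk past the last ", base, " in the read")
    }
    positions <- base_idx[rank]
    probs <- if (is.null(ml_values)) {
      rep(NA_real_, length(positions))
    } else {
      (ml_values[n_before + seq_along(positions)] + 0.5) / 256
    }
    return(list(positions = positions, probs = probs))
  }
  list(positions = integer(), probs = numeric())
}

# --- SAM record tagging ------------------------------------------------

# Index parsed calls by read id for fast lookup.
.index_calls <- function(calls) {
  split(calls[, c("reference_id", "ref_pos", "prob_meth")],
        calls$read_id)
}

#' Add MM/ML methylation tags to alignment records
#'
#' Re-implements the call-table-to-tags conversion: for every primary
#' alignment with at least one call that maps onto a read-base `C`
#' (in original orientation), MM:Z and ML:B:C tags are written. All other
#' records pass through unchanged. Re-running on already tagged output
#' replaces, rather than duplicates, the tags.
#'
#' @param alignments input SAM (or BAM) path.
#' @param calls data.frame from [parse_meth_calls()].
#' @param out output path; `.sam` writes SAM text, `.bam` converts via
#'   Rsamtools.
#' @param emit_ml logical; set FALSE to write MM only.
#' @return invisibly, a summary data.frame (one row per tagged read:
#'   `read_id`, `n_calls`, `n_tagged`, `n_unmapped_pos`, `n_not_c`).
#' @export
tag_alignments <- function(alignments, calls, out, emit_ml = TRUE) {
  sam_in <- alignments
  if (grepl("\\.bam$", alignments, ignore.case = TRUE)) {
    sam_in <- Rsamtools::asSam(alignments, tempfile(), overwrite = TRUE)
  }
  idx <- .index_calls(calls)
  lines <- readLines(sam_in)
  is_header <- startsWith(lines, "@")
  body <- lines[!is_header]
  log <- list()
  out_body <- vapply(body, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    flag <- as.integer(f[2L])
    qname <- f[1L]
    # only primary, mapped records with a stored sequence are tagged
    if (bitwAnd(flag, 0x4L) != 0L || bitwAnd(flag, 0x900L) != 0L ||
        f[10L] == "*" || is.null(idx[[qname]])) {
      return(line)
    }
    cl <- idx[[qname]]
    cl <- cl[cl$reference_id == f[3L], , drop = FALSE]
    if (nrow(cl) == 0L) return(line)
    cl <- cl[order(cl$ref_pos), , drop = FALSE]
    cl <- cl[!duplicated(cl$ref_pos), , drop = FALSE]
    seq_stored <- f[10L]
    read_len <- nchar(seq_stored)
    is_rev <- bitwAnd(flag, 0x10L) != 0L
    seq_orig <- if (is_rev) .revcomp(seq_stored) else seq_stored
    read_pos <- ref_to_read_positions(f[6L], as.integer(f[4L]) - 1L,
                                      is_rev, read_len, cl$ref_pos)
    mappable <- !is.na(read_pos)
    chars <- strsplit(toupper(seq_orig), "", fixed = TRUE)[[1L]]
    on_c <- mappable
    on_c[mappable] <- chars[read_pos[mappable] + 1L] == "C"
    ord <- order(read_pos[on_c])
    pos <- read_pos[on_c][ord]
    prb <- cl$prob_meth[on_c][ord]
    log[[qname]] <<- data.frame(
      read_id = qname, n_calls = nrow(cl), n_tagged = length(pos),
      n_unmapped_pos = sum(!mappable), n_not_c = sum(mappable & !on_c),
      stringsAsFactors = FALSE)
    # idempotence: strip any existing MM/ML before re-tagging
    keep <- !grepl("^(MM|ML):", f[-(1:11)])
    f <- c(f[1:11], f[-(1:11)][keep])
    if (length(pos) == 0L) return(paste(f, collapse = "\t"))
    tags <- encode_mm(seq_orig, pos, prb)
    f <- c(f, paste0("MM:Z:", tags$mm))
    if (emit_ml) {
      f <- c(f, paste0("ML:B:C,", paste(tags$ml, collapse = ",")))
    }
    paste(f, collapse = "\t")
  }, "", USE.NAMES = FALSE)
  res_lines <- c(lines[is_header], out_body)
  if (grepl("\\.bam$", out, ignore.case = TRUE)) {
    tmp_sam <- tempfile(fileext = ".sam")
    writeLines(res_lines, tmp_sam)
    Rsamtools::asBam(tmp_sam, sub("\\.bam$", "", out, ignore.case = TRUE),
                     overwrite = TRUE, indexDestination = FALSE)
  } else {
    .atomic_write(function(tmp) writeLines(res_lines, tmp), out)
  }
  summary <- do.call(rbind, c(unname(log), list(NULL)))
  if (is.null(summary)) {
    summary <- data.frame(read_id = character(), n_calls = integer(),
                          n_tagged = integer(), n_unmapped_pos = integer(),
                          n_not_c = integer(), stringsAsFactors = FALSE)
  }
  invisible(summary)
}
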