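# Independent brute-force oracles and fixture builders. These deliberately
# use naive, step-by-step computations so they share no code path with the
# package implementations they check.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}

# --- protospacer oracle: scan every offset, compare characters -----------

iupac_match <- function(pattern_char, base_char) {
  tab <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  base_char %in% tab[[pattern_char]]
}

oracle_scan_guide <- function(ref, spacer, pam = "NGG") {
  n <- nchar(ref)
  w <- nchar(spacer) + nchar(pam)
  hits <- data.frame(position = integer(), strand = character())
  check_at <- function(seq, i) {  # 1-based window start in `seq`
    win <- substr(seq, i, i + w - 1L)
    if (substr(win, 1L, nchar(spacer)) != spacer) return(FALSE)
    pam_part <- strsplit(substr(win, nchar(spacer) + 1L, w), "")[[1L]]
    all(mapply(iupac_match, strsplit(pam, "")[[1L]], pam_part))
  }
  for (i in seq_len(n - w + 1L)) {
    if (check_at(ref, i)) {
      hits <- rbind(hits, data.frame(position = (i - 1L) + 17L,
                                     strand = "+"))
    }
  }
  rc <- revcomp_chr(ref)
  for (i in seq_len(n - w + 1L)) {
    if (check_at(rc, i)) {
      # rc window [i, i+w) maps to forward [n - (i-1) - w, n - (i-1));
      # cut 3 bp 5' of PAM on the minus strand
      fwd_start <- n - (i - 1L) - w
      hits <- rbind(hits, data.frame(position = fwd_start + nchar(pam) + 3L,
                                     strand = "-"))
    }
  }
  hits[order(hits$position), , drop = FALSE]
}

# --- CIGAR aligned-pair walk oracle -------------------------------------

# expand a CIGAR one base at a time into (ref_pos, query_pos) pairs
oracle_aligned_pairs <- function(cigar, aln_start) {
  lens <- as.integer(strsplit(gsub("[MIDNSHP=X]", " ", cigar), " +")[[1L]])
  ops <- strsplit(gsub("[0-9]+", "", cigar), "")[[1L]]
  ref <- aln_start
  qry <- 0L
  pairs_ref <- integer()
  pairs_qry <- integer()
  for (i in seq_along(ops)) {
    for (b in seq_len(lens[i])) {
      op <- ops[i]
      if (op %in% c("M", "=", "X")) {
        pairs_ref <- c(pairs_ref, ref)
        pairs_qry <- c(pairs_qry, qry)
        ref <- ref + 1L
        qry <- qry + 1L
      } else if (op %in% c("I", "S")) {
        qry <- qry + 1L
      } else if (op %in% c("D", "N")) {
        ref <- ref + 1L
      }
    }
  }
  data.frame(ref = pairs_ref, qry = pairs_qry)
}

oracle_ref_to_read <- function(cigar, aln_start, is_reverse, read_length,
                               ref_positions) {
  pairs <- oracle_aligned_pairs(cigar, aln_start)
  out <- pairs$qry[match(ref_positions, pairs$ref)]
  if (is_reverse) out <- ifelse(is.na(out), NA, read_length - 1L - out)
  as.integer(out)
}

# random plausible CIGAR: optional soft clips at the ends, alternating
# match-like and indel ops in between, <= 50 ops
random_cigar <- function() {
  n_core <- sample(1:20, 1)
  ops <- character()
  lens <- integer()
  prev_indel <- TRUE  # force a match-type op first
  for (i in seq_len(n_core)) {
    if (prev_indel) {
      op <- sample(c("M", "=", "X"), 1)
      prev_indel <- FALSE
    } else {
      op <- sample(c("M", "=", "X", "I", "D"), 1)
      prev_indel <- op %in% c("I", "D")
    }
    ops <- c(ops, op)
    lens <- c(lens, sample(1:12, 1))
  }
  if (prev_indel) {  # end on a match-type op
    ops <- c(ops, "M")
    lens <- c(lens, sample(1:12, 1))
  }
  if (runif(1) < 0.4) {
    ops <- c("S", ops)
    lens <- c(sample(1:8, 1), lens)
  }
  if (runif(1) < 0.4) {
    ops <- c(ops, "S")
    lens <- c(lens, sample(1:8, 1))
  }
  list(cigar = paste0(lens, ops, collapse = ""),
       read_length = sum(lens[ops %in% c("M", "I", "S", "=", "X")]),
       ref_span = sum(lens[ops %in% c("M", "D", "N", "=", "X")]))
}

# --- CpG island brute-force oracle --------------------------------------

# enumerate every qualifying interval (length >= min_len, GC > gc_min,
# obs/exp CpG > oe_min); merge into strict-overlap components; report the
# longest qualifying interval per component (leftmost on ties)
oracle_cpg_islands <- function(seq, min_len = 200L, gc_min = 0.5,
                               oe_min = 0.6) {
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  if (n < min_len) return(data.frame(start = integer(), end = integer()))
  isC <- cumsum(chars == "C")
  isG <- cumsum(chars == "G")
  isN <- cumsum(chars == "N")
  cg <- cumsum(c(chars[-n] == "C" & chars[-1L] == "G", FALSE))
  cnt <- function(cs, s, e) cs[e] - ifelse(s > 1, cs[pmax(s - 1, 1)], 0)
  best_start <- integer()
  best_end <- integer()
  for (s0 in 0:(n - min_len)) {
    ends <- (s0 + min_len):n             # candidate 0-based half-open ends
    len <- ends - s0
    nc <- cnt(isC, s0 + 1, ends)
    ng <- cnt(isG, s0 + 1, ends)
    nn <- cnt(isN, s0 + 1, ends)
    ncg <- cnt(cg, s0 + 1, ends - 1)     # CG starts strictly before end
    gc_ok <- (len - nn) > 0 & (nc + ng) / pmax(len - nn, 1) > gc_min
    exp_cg <- nc * ng / len
    oe_ok <- exp_cg > 0 & ncg / ifelse(exp_cg > 0, exp_cg, 1) > oe_min
    ok <- which(gc_ok & oe_ok)
    if (length(ok) > 0L) {
      best_start <- c(best_start, s0)
      best_end <- c(best_end, max(ends[ok]))
    }
  }
  if (length(best_start) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  # strict-overlap components over the per-start maximal intervals
  comp <- integer(length(best_start))
  cur <- 1L
  comp[1L] <- 1L
  cur_end <- best_end[1L]
  for (i in seq_along(best_start)[-1L]) {
    if (best_start[i] < cur_end) {
      comp[i] <- cur
      cur_end <- max(cur_end, best_end[i])
    } else {
      cur <- cur + 1L
      comp[i] <- cur
      cur_end <- best_end[i]
    }
  }
  out <- lapply(split(seq_along(comp), comp), function(ix) {
    lens <- best_end[ix] - best_start[ix]
    j <- ix[which.max(lens)]             # which.max takes the leftmost tie
    data.frame(start = best_start[j], end = best_end[j])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# sequence generator for island tests: AT-rich background with occasional
# GC/CpG-enriched patches so that islands actually occur
random_island_seq <- function(n) {
  blocks <- character()
  got <- 0L
  while (got < n) {
    len <- sample(100:400, 1)
    if (runif(1) < 0.35) {
      block <- paste(ifelse(runif(len) < 0.25, "CG",
                            sample(c("A", "C", "G", "T"), len, replace = TRUE,
                                   prob = c(.2, .3, .3, .2))),
                     collapse = "")
    } else {
      block <- random_dna(len, gc = 0.35)
    }
    blocks <- c(blocks, block)
    got <- got + nchar(block)
  }
  substr(paste(blocks, collapse = ""), 1L, n)
}

# --- pileup oracle -------------------------------------------------------

# per-position depth over [start0, end0) from raw SAM lines, primary only,
# deletions not covering
oracle_pileup_depth <- function(sam_path, ref_id, start0, end0) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  depth <- integer(end0 - start0)
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1L]]
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 0x4) != 0 || bitwAnd(flag, 0x900) != 0) next
    if (f[3L] != ref_id) next
    pairs <- oracle_aligned_pairs(f[6L], as.integer(f[4L]) - 1L)
    hit <- pairs$ref[pairs$ref >= start0 & pairs$ref < end0]
    if (length(hit) > 0L) {
      depth[hit - start0 + 1L] <- depth[hit - start0 + 1L] + 1L
    }
  }
  depth
}

# --- tiny fixture writers ------------------------------------------------

write_sam_fixture <- function(path, records, ref_id = "ref", ref_len = 10000L) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", ref_id, ref_len))
  writeLines(c(hdr, records), path)
}

sam_record <- function(qname, flag, ref, pos1, cigar, seq,
                       qual = strrep("I", nchar(seq)), extra = NULL) {
  rec <- paste(qname, flag, ref, pos1, 60, cigar, "*", 0, 0, seq, qual,
               sep = "\t")
  if (!is.null(extra)) rec <- paste(rec, extra, sep = "\t")
  rec
}

write_fastq_fixture <- function(path, ids, seqs, quals) {
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), path)
}

write_calls_fixture <- function(path, df) {
  # df: read_id, reference_id, ref_pos, ref_strand, prob_meth
  tab <- data.frame(chrom = df$reference_id, pos = df$ref_pos,
                    strand = df$ref_strand,
                    pos_in_strand = df$ref_pos, read_id = df$read_id,
                    read_strand = "+", prob_unmeth = 1 - df$prob_meth,
                    prob_meth = df$prob_meth,
                    label = as.integer(df$prob_meth >= 0.5), kmer = "NNCNN")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

# small default simulation used by several tests (cheap, audited once)
small_sim_config <- function(seed = 11, ...) {
  args <- list(seed = seed, ref_length = 20000L, locus_start = 6000L,
               locus_length = 3000L, promoter_length = 800L,
               island_offset = 1200L, island_length = 250L,
               repeat_offset = 1800L, repeat_unit = 60L, repeat_copies = 15L,
               genome_size = 6e6, coverage_x = 0.02, target_depth = 10)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}
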