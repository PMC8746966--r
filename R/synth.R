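# Deterministic synthetic-data generator emulating a Cas9-targeted nanopore
# enrichment experiment on a large-genome target: a reference carrying a
# promoter / gene-body / CpG-island / low-complexity-repeat architecture,
# cut-to-cut on-target reads at nCATS-like depth plus diffuse off-target
# background, caller-style per-read methylation tables, and optional
# two-haplotype structure — all with machine-readable ground truth.
#
# RNG contract: one integer seed; make_reference() seeds with `seed`,
# simulate_reads() with `seed + 1`, simulate_meth_calls() with `seed + 2`,
# so each stage is individually reproducible.

#' Build a simulation configuration
#'
#' Defaults emulate the target-enrichment regime of a multi-kilobase seed
#' storage gene in a very large (multi-gigabase) cereal genome: 15x target
#' depth (within the observed 5-17x band), ~3 kb nanopore-like read lengths
#' and 0.02x genome-wide coverage. The nominal genome size is scaled down
#' 1000-fold (24 Gb -> 24 Mb) to keep background read counts tractable;
#' coverage, depth and enrichment arithmetic are unaffected by this scaling
#' (the on-target read *fraction*, which scales with genome size, is
#' correspondingly higher than in a real 24 Gb run).
#'
#' @param seed integer seed governing all randomness (mandatory).
#' @param genome_size nominal genome size (bp) used in coverage accounting.
#' @param ref_length length of the simulated reference window (bp).
#' @param locus_start,locus_length target locus placement (0-based).
#' @param promoter_length promoter length at the locus 5' end (bp).
#' @param island_offset,island_length designed CpG island (locus offsets).
#' @param repeat_offset,repeat_unit,repeat_copies designed tandem
#'   low-complexity tract (locus offset, unit bp, copy number).
#' @param guide_up,guide_down spacers (20 nt) cutting at the locus
#'   boundaries; defaults are published glutenin-panel spacers.
#' @param target_depth on-target depth (x); also the on-target read count
#'   since each read spans cut-to-cut.
#' @param coverage_x genome-wide coverage (x) implied by total yield.
#' @param read_length_mean,read_length_sd lognormal background read-length
#'   model (bp).
#' @param qscore_mean,qscore_sd per-read mean quality model.
#' @param sub_rate,indel_rate per-base substitution / indel rates.
#' @param end_jitter max inward jitter (bp) at cut-fragment read ends.
#' @param meth_probs list with elements `promoter` and `body`, each a named
#'   vector of true methylation probabilities for `CpG`, `CHG`, `CHH`.
#' @param meth_high,meth_low,meth_sd emission model for caller
#'   probabilities: methylated sites emit `N(meth_high, meth_sd)`,
#'   unmethylated `N(meth_low, meth_sd)`, clipped to `[0, 1]`.
#' @param haplotype_mode logical; TRUE simulates a two-allele locus.
#' @param n_snps heterozygous SNPs distinguishing the two alleles.
#' @param hap_meth_probs optional list `HP1`/`HP2`, each shaped like
#'   `meth_probs`, for allele-specific methylation; default both alleles
#'   share `meth_probs`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genome_size = 24e6,
                       ref_length = 60000L,
                       locus_start = 20000L,
                       locus_length = 6000L,
                       promoter_length = 1500L,
                       island_offset = 2500L,
                       island_length = 300L,
                       repeat_offset = 3500L,
                       repeat_unit = 60L,
                       repeat_copies = 30L,
                       guide_up = "GGGCCCTGTGCGGTTCGCAC",
                       guide_down = "CCCTCCATCCGACACATTAT",
                       target_depth = 15,
                       coverage_x = 0.02,
                       read_length_mean = 3000,
                       read_length_sd = 2500,
                       qscore_mean = 12,
                       qscore_sd = 2,
                       sub_rate = 0.02,
                       indel_rate = 0,
                       end_jitter = 50L,
                       meth_probs = list(
                         promoter = c(CpG = 0.1, CHG = 0.05, CHH = 0.02),
                         body = c(CpG = 0.8, CHG = 0.1, CHH = 0.05)),
                       meth_high = 0.9, meth_low = 0.1, meth_sd = 0.05,
                       haplotype_mode = FALSE,
                       n_snps = 20L,
                       hap_meth_probs = NULL) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(seed == round(seed), target_depth > 0, coverage_x > 0,
            island_offset + island_length <= locus_length,
            repeat_offset + repeat_unit * repeat_copies <= locus_length,
            locus_start + locus_length < ref_length,
            all(unlist(meth_probs) >= 0), all(unlist(meth_probs) <= 1))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

.sample_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# CpG-island-like sequence: frequent CG dinucleotides in a GC-rich base
.sample_island <- function(n) {
  out <- character()
  len <- 0L
  while (len < n) {
    if (runif(1) < 0.3) {
      out <- c(out, "CG")
      len <- len + 2L
    } else {
      b <- sample(c("A", "C", "G", "T"), 1, prob = c(.2, .3, .3, .2))
      out <- c(out, b)
      len <- len + 1L
    }
  }
  substr(paste(out, collapse = ""), 1L, n)
}

.splice <- function(seq, at0, replacement) {
  # overwrite seq at 0-based offset `at0` with `replacement`
  paste0(substr(seq, 1L, at0),
         replacement,
         substr(seq, at0 + nchar(replacement) + 1L, nchar(seq)))
}

#' Generate the synthetic reference and its architecture
#'
#' Builds a reference window containing a target locus with promoter, gene
#' body, designed CpG island and tandem low-complexity repeat tract, and
#' plants the two guide protospacer+PAM sites so that the predicted blunt
#' cuts fall exactly at the locus boundaries. The result is self-audited:
#' the designed island must be re-detected by [find_cpg_islands()], the
#' repeat tract by [dotplot_matches()], and each guide must cut exactly
#' once.
#'
#' @param config a [sim_config()].
#' @param audit logical; set FALSE to skip the self-audit (faster).
#' @return list of class `sim_reference`: `id`, `seq`, `architecture`
#'   (BED-like data.frame), `guides` (list of [guide_rna()]),
#'   `cut_sites` (`c(start, end)` of the excised fragment), `snps`
#'   (data.frame, empty unless haplotype mode), `config`.
#' @export
make_reference <- function(config, audit = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$ref_length
  ls <- config$locus_start
  ll <- config$locus_length
  le <- ls + ll
  seq <- .sample_dna(n, gc = 0.4)
  # designed architecture inside the locus
  island0 <- ls + config$island_offset
  seq <- .splice(seq, island0, .sample_island(config$island_length))
  unit <- .sample_dna(config$repeat_unit, gc = 0.5)
  tract <- strrep(unit, config$repeat_copies)
  rep0 <- ls + config$repeat_offset
  seq <- .splice(seq, rep0, tract)
  # guide sites: upstream forward guide cuts at `ls` (cut = spacer_start+17),
  # downstream reverse guide cuts at `le` (cut = forward PAM end + 3)
  g_up <- guide_rna("guide_up", config$guide_up, "NGG", "F")
  g_dn <- guide_rna("guide_down", config$guide_down, "NGG", "R")
  seq <- .splice(seq, ls - 17L, paste0(g_up$spacer, "TGG"))
  seq <- .splice(seq, le - 6L, .revcomp(paste0(g_dn$spacer, "TGG")))
  # optional heterozygous SNPs for the second allele
  snps <- data.frame(pos = integer(), ref = character(), alt = character())
  if (isTRUE(config$haplotype_mode) && config$n_snps > 0L) {
    cand <- setdiff((ls + 100L):(le - 100L),
                    c((ls - 20L):(ls + 20L), (le - 20L):(le + 20L)))
    pos <- sort(sample(cand, config$n_snps))
    refb <- substring(seq, pos + 1L, pos + 1L)
    altb <- vapply(refb, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, "", USE.NAMES = FALSE)
    snps <- data.frame(pos = pos, ref = refb, alt = altb,
                       stringsAsFactors = FALSE)
  }
  arch <- data.frame(
    reference_id = "refA",
    start = c(ls, ls, ls + config$promoter_length, island0, rep0),
    end = c(le, ls + config$promoter_length, le,
            island0 + config$island_length, rep0 + nchar(tract)),
    name = c("locus", "promoter", "body", "cpg_island", "repeat_tract"),
    stringsAsFactors = FALSE)
  ref <- structure(list(id = "refA", seq = seq, architecture = arch,
                        guides = list(g_up, g_dn),
                        cut_sites = c(start = ls, end = le),
                        snps = snps, config = config),
                   class = "sim_reference")
  if (audit) .audit_reference(ref)
  ref
}

# generator self-audit: the designed architecture must be recoverable by
# the package's own detectors, and the guide panel must cut exactly once
# per guide at the intended positions.
.audit_reference <- function(ref) {
  cfg <- ref$config
  locus_seq <- substr(ref$seq, cfg$locus_start + 1L,
                      cfg$locus_start + cfg$locus_length)
  isl <- find_cpg_islands(locus_seq)
  want <- c(cfg$island_offset, cfg$island_offset + cfg$island_length)
  if (nrow(isl) == 0L ||
      !any(.overlap_len(isl$start, isl$end, want[1], want[2]) >=
             0.5 * cfg$island_length)) {
    stop("reference self-audit: designed CpG island not re-detected")
  }
  dp <- dotplot_matches(locus_seq)
  tract_end <- cfg$repeat_offset + cfg$repeat_unit * cfg$repeat_copies
  if (nrow(dp$segments) == 0L ||
      !any(.overlap_len(dp$segments$start, dp$segments$end,
                        cfg$repeat_offset, tract_end) >=
             0.8 * (tract_end - cfg$repeat_offset))) {
    stop("reference self-audit: designed repeat tract not re-detected")
  }
  for (g in ref$guides) {
    cuts <- find_protospacers(c(refA = ref$seq), g)
    if (nrow(cuts) != 1L) {
      stop("reference self-audit: guide ", g$name, " has ", nrow(cuts),
           " cut sites (expected 1)")
    }
  }
  cuts <- rbind(find_protospacers(c(refA = ref$seq), ref$guides[[1L]]),
                find_protospacers(c(refA = ref$seq), ref$guides[[2L]]))
  frag <- predict_fragments(cuts, data.frame(upstream = "guide_up",
                                             downstream = "guide_down"))
  if (nrow(frag) != 1L || frag$start != cfg$locus_start ||
      frag$end != cfg$locus_start + cfg$locus_length) {
    stop("reference self-audit: predicted fragment does not match the locus")
  }
  invisible(TRUE)
}

# substitute bases (and optionally indels) into a reference span; returns
# the read sequence plus its CIGAR relative to the span start.
.mutate_read <- function(span_seq, sub_rate, indel_rate) {
  chars <- strsplit(span_seq, "", fixed = TRUE)[[1L]]
  m <- length(chars)
  nsub <- rbinom(1L, m, sub_rate)
  if (nsub > 0L) {
    at <- sample.int(m, nsub)
    chars[at] <- vapply(chars[at], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, "", USE.NAMES = FALSE)
  }
  if (indel_rate <= 0) {
    return(list(seq = paste(chars, collapse = ""),
                cigar = paste0(m, "M")))
  }
  # indels: per reference base, ins/del events at indel_rate/2 each,
  # event length 1-3 bp
  ops_len <- integer()
  ops_op <- character()
  out <- character()
  i <- 1L
  run_m <- 0L
  push <- function(len, op) {
    if (len > 0L) {
      if (length(ops_op) > 0L && ops_op[length(ops_op)] == op) {
        ops_len[length(ops_len)] <<- ops_len[length(ops_len)] + len
      } else {
        ops_len <<- c(ops_len, len)
        ops_op <<- c(ops_op, op)
      }
    }
  }
  while (i <= m) {
    u <- runif(1)
    if (u < indel_rate / 2) {            # deletion
      push(run_m, "M"); run_m <- 0L
      dlen <- min(sample.int(3L, 1L), m - i + 1L)
      push(dlen, "D")
      i <- i + dlen
    } else if (u < indel_rate) {         # insertion after current base
      out <- c(out, chars[i])
      run_m <- run_m + 1L
      push(run_m, "M"); run_m <- 0L
      ilen <- sample.int(3L, 1L)
      out <- c(out, sample(c("A", "C", "G", "T"), ilen, replace = TRUE))
      push(ilen, "I")
      i <- i + 1L
    } else {
      out <- c(out, chars[i])
      run_m <- run_m + 1L
      i <- i + 1L
    }
  }
  push(run_m, "M")
  list(seq = paste(out, collapse = ""),
       cigar = paste0(ops_len, ops_op, collapse = ""))
}

#' Simulate nCATS-like reads over a synthetic reference
#'
#' On-target reads span cut site to cut site with small inward end jitter
#' (Cas9-released fragments); background reads have lognormal lengths and
#' uniform placement outside the locus (off-target reads in a huge genome
#' essentially never hit a kilobase-scale target). Background yield is set
#' so that total yield over the nominal genome size equals the configured
#' genome-wide coverage.
#'
#' @param config a [sim_config()].
#' @param reference a `sim_reference` from [make_reference()].
#' @return list of class `sim_reads`: `reads` (data.frame: `read_id`,
#'   `flag`, `pos` 0-based, `cigar`, `seq` (SEQ, reference orientation),
#'   `qual`, `strand`, `origin`, `haplotype`, `length`), `truth`
#'   (per-read origin table plus configured/realised yield numbers).
#' @export
simulate_reads <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"),
            inherits(reference, "sim_reference"))
  if (config$target_depth <= 0) stop("target depth must be positive")
  set.seed(config$seed + 1L)
  ls <- config$locus_start
  le <- ls + config$locus_length
  n <- config$ref_length
  n_on <- round(config$target_depth)
  hap <- if (isTRUE(config$haplotype_mode)) {
    rep_len(c("HP1", "HP2"), n_on)
  } else rep("unassigned", n_on)
  rows <- vector("list", 0L)
  mk_qual <- function(len) {
    q <- round(max(2, min(40, rnorm(1, config$qscore_mean, config$qscore_sd))))
    strrep(intToUtf8(q + 33L), len)
  }
  for (i in seq_len(n_on)) {
    s0 <- ls + sample.int(config$end_jitter + 1L, 1L) - 1L
    e0 <- le - (sample.int(config$end_jitter + 1L, 1L) - 1L)
    span <- substr(reference$seq, s0 + 1L, e0)
    if (nrow(reference$snps) > 0L && hap[i] == "HP2") {
      inside <- reference$snps[reference$snps$pos >= s0 &
                                 reference$snps$pos < e0, , drop = FALSE]
      for (j in seq_len(nrow(inside))) {
        substr(span, inside$pos[j] - s0 + 1L, inside$pos[j] - s0 + 1L) <-
          inside$alt[j]
      }
    }
    mut <- .mutate_read(span, config$sub_rate, config$indel_rate)
    rev <- runif(1) < 0.5
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = sprintf("on_%03d", i), flag = if (rev) 16L else 0L,
      pos = s0, cigar = mut$cigar, seq = mut$seq,
      qual = mk_qual(nchar(mut$seq)), strand = if (rev) "-" else "+",
      origin = "on_target", haplotype = hap[i],
      stringsAsFactors = FALSE)
  }
  # background reads outside the locus until the yield budget is spent
  total_yield <- config$coverage_x * config$genome_size
  on_bases <- sum(nchar(vapply(rows, `[[`, "", "seq")))
  bg_budget <- max(0, total_yield - on_bases)
  meanlog <- log(config$read_length_mean^2 /
                   sqrt(config$read_length_mean^2 + config$read_length_sd^2))
  sdlog <- sqrt(log(1 + (config$read_length_sd / config$read_length_mean)^2))
  got <- 0
  b <- 0L
  while (got < bg_budget) {
    len <- max(200L, round(rlnorm(1, meanlog, sdlog)))
    left_room <- ls - len
    right_room <- (n - le) - len
    if (left_room < 0 && right_room < 0) {
      len <- max(200L, min(ls, n - le) - 1L)
      left_room <- ls - len
      right_room <- (n - le) - len
    }
    side_left <- runif(1) < left_room / max(1, left_room + right_room)
    s0 <- if (side_left && left_room >= 0) {
      sample.int(left_room + 1L, 1L) - 1L
    } else {
      le + sample.int(max(1L, right_room + 1L), 1L) - 1L
    }
    span <- substr(reference$seq, s0 + 1L, s0 + len)
    mut <- .mutate_read(span, config$sub_rate, config$indel_rate)
    rev <- runif(1) < 0.5
    b <- b + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = sprintf("bg_%05d", b), flag = if (rev) 16L else 0L,
      pos = s0, cigar = mut$cigar, seq = mut$seq,
      qual = mk_qual(nchar(mut$seq)), strand = if (rev) "-" else "+",
      origin = "background", haplotype = "unassigned",
      stringsAsFactors = FALSE)
    got <- got + len
  }
  reads <- do.call(rbind, rows)
  reads$length <- nchar(reads$seq)
  reads <- reads[order(reads$pos), , drop = FALSE]
  rownames(reads) <- NULL
  truth <- list(
    per_read = reads[, c("read_id", "pos", "strand", "origin", "haplotype",
                         "length")],
    n_on_target = n_on,
    total_bases = sum(reads$length),
    true_coverage = sum(reads$length) / config$genome_size,
    true_enrichment = config$target_depth / config$coverage_x,
    fragment = c(start = ls, end = le))
  structure(list(reads = reads, truth = truth, reference_id = reference$id,
                 config = config),
            class = "sim_reads")
}

#' Write simulated reads as SAM
#'
#' @param sim a `sim_reads` object.
#' @param reference the `sim_reference` used to simulate.
#' @param path output `.sam` path.
#' @return the path, invisibly.
#' @export
write_sim_sam <- function(sim, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", reference$id,
                   reference$config$ref_length))
  r <- sim$reads
  hp_tag <- ifelse(r$haplotype %in% c("HP1", "HP2"),
                   paste0("\tHP:i:", sub("HP", "", r$haplotype)), "")
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s%s",
                 r$read_id, r$flag, reference$id, r$pos + 1L, r$cigar,
                 r$seq, r$qual, hp_tag)
  .atomic_write(function(tmp) writeLines(c(hdr, rec), tmp), path)
}

#' Write simulated reads as FASTQ (original read orientation)
#'
#' @inheritParams write_sim_sam
#' @param path output `.fastq` path.
#' @return the path, invisibly.
#' @export
write_sim_fastq <- function(sim, path) {
  r <- sim$reads
  seqs <- ifelse(r$strand == "-",
                 vapply(r$seq, .revcomp, "", USE.NAMES = FALSE), r$seq)
  quals <- ifelse(r$strand == "-",
                  vapply(r$qual, function(q) {
                    paste(rev(strsplit(q, "")[[1L]]), collapse = "")
                  }, "", USE.NAMES = FALSE), r$qual)
  .atomic_write(function(tmp) {
    writeLines(paste0("@", r$read_id, "\n", seqs, "\n+\n", quals), tmp)
  }, path)
}

# cytosine site table for the locus: position, strand, context, region
# class and true methylation probability (per haplotype when configured)
.locus_sites <- function(config, reference) {
  ls <- config$locus_start
  le <- ls + config$locus_length
  chars <- strsplit(substr(reference$seq, ls + 1L, le), "", fixed = TRUE)[[1L]]
  pos_c <- ls + which(chars == "C") - 1L
  pos_g <- ls + which(chars == "G") - 1L
  sites <- rbind(
    data.frame(pos = pos_c, strand = "+", stringsAsFactors = FALSE),
    data.frame(pos = pos_g, strand = "-", stringsAsFactors = FALSE))
  sites <- sites[order(sites$pos, sites$strand), , drop = FALSE]
  sites$context <- context_classify(reference$seq, sites$pos, sites$strand)
  sites$region <- ifelse(sites$pos < ls + config$promoter_length,
                         "promoter", "body")
  km <- substring(reference$seq, sites$pos - 1L, sites$pos + 3L)
  minus <- sites$strand == "-"
  if (any(minus)) {
    rc <- chartr("ACGT", "TGCA", km[minus])
    km[minus] <- vapply(strsplit(rc, "", fixed = TRUE), function(x) {
      paste(rev(x), collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  sites$kmer <- km
  prob_for <- function(probs) {
    mapply(function(reg, ctx) probs[[reg]][[ctx]],
           sites$region, sites$context)
  }
  if (!is.null(config$hap_meth_probs)) {
    sites$p_true_hp1 <- prob_for(config$hap_meth_probs$HP1)
    sites$p_true_hp2 <- prob_for(config$hap_meth_probs$HP2)
    sites$p_true <- (sites$p_true_hp1 + sites$p_true_hp2) / 2
  } else {
    sites$p_true <- prob_for(config$meth_probs)
    sites$p_true_hp1 <- sites$p_true
    sites$p_true_hp2 <- sites$p_true
  }
  rownames(sites) <- NULL
  sites
}

#' Simulate caller-style per-read methylation calls
#'
#' For every reference cytosine (both strands) of the target locus covered
#' by an on-target read, the true methylation state is drawn Bernoulli from
#' the site's regional truth probability and a caller probability is
#' emitted from the clipped-normal emission model. Output follows the
#' deepsignal_plant table dialect consumed by [parse_meth_calls()].
#'
#' @param config a [sim_config()].
#' @param reference a `sim_reference`.
#' @param sim a `sim_reads` object.
#' @return list of class `sim_calls`: `calls` (data.frame in dialect column
#'   order), `site_truth` (per-site table with true probabilities).
#' @export
simulate_meth_calls <- function(config, reference, sim) {
  stopifnot(inherits(sim, "sim_reads"))
  set.seed(config$seed + 2L)
  sites <- .locus_sites(config, reference)
  on <- sim$reads[sim$reads$origin == "on_target", , drop = FALSE]
  clamp01 <- function(x) pmin(1, pmax(0, x))
  res <- vector("list", nrow(on))
  for (i in seq_len(nrow(on))) {
    span_end <- on$pos[i] +
      GenomicAlignments::cigarWidthAlongReferenceSpace(on$cigar[i])
    s <- sites[sites$pos >= on$pos[i] & sites$pos < span_end, , drop = FALSE]
    if (nrow(s) == 0L) next
    p <- if (on$haplotype[i] == "HP2") s$p_true_hp2 else s$p_true_hp1
    state <- rbinom(nrow(s), 1L, p)
    prob <- clamp01(rnorm(nrow(s),
                          ifelse(state == 1L, config$meth_high,
                                 config$meth_low), config$meth_sd))
    res[[i]] <- data.frame(
      chrom = reference$id, pos = s$pos, strand = s$strand,
      pos_in_strand = ifelse(s$strand == "+", s$pos,
                             config$ref_length - 1L - s$pos),
      read_id = on$read_id[i], read_strand = on$strand[i],
      prob_unmeth = 1 - prob, prob_meth = prob,
      label = as.integer(prob >= 0.5), kmer = s$kmer,
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, c(res, list(NULL)))
  structure(list(calls = calls, site_truth = sites, config = config),
            class = "sim_calls")
}

#' Write simulated calls in the deepsignal_plant table dialect
#'
#' @param simcalls a `sim_calls` object.
#' @param path output TSV path (no header, dialect column order).
#' @return the path, invisibly.
#' @export
write_sim_calls <- function(simcalls, path) {
  .atomic_write(function(tmp) {
    write.table(simcalls$calls, tmp, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }, path)
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: reference + reads + methylation calls, optionally
#' written to a directory (`reference.fa`, `architecture.bed`, `reads.sam`,
#' `reads.fastq`, `calls.tsv`, `read_haplotypes.tsv`,
#' `ground_truth.json`).
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list with `reference`, `sim` (reads), `simcalls` and `truth`.
#' @export
simulate_ncats <- function(config, out_dir = NULL) {
  reference <- make_reference(config)
  sim <- simulate_reads(config, reference)
  simcalls <- simulate_meth_calls(config, reference, sim)
  truth <- c(sim$truth,
             list(site_truth = simcalls$site_truth,
                  architecture = reference$architecture,
                  seed = config$seed))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    .atomic_write(function(tmp) {
      writeLines(c(paste0(">", reference$id), reference$seq), tmp)
    }, file.path(out_dir, "reference.fa"))
    write_bed(reference$architecture, file.path(out_dir, "architecture.bed"))
    write_sim_sam(sim, reference, file.path(out_dir, "reads.sam"))
    write_sim_fastq(sim, file.path(out_dir, "reads.fastq"))
    write_sim_calls(simcalls, file.path(out_dir, "calls.tsv"))
    hp <- sim$reads[, c("read_id", "haplotype")]
    .atomic_write(function(tmp) {
      write.table(hp, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    }, file.path(out_dir, "read_haplotypes.tsv"))
    .atomic_write(function(tmp) {
      jsonlite::write_json(
        list(per_read = truth$per_read,
             n_on_target = truth$n_on_target,
             total_bases = truth$total_bases,
             true_coverage = truth$true_coverage,
             true_enrichment = truth$true_enrichment,
             fragment = as.list(truth$fragment),
             seed = config$seed),
        tmp, auto_unbox = TRUE, digits = NA)
    }, file.path(out_dir, "ground_truth.json"))
  }
  list(reference = reference, sim = sim, simcalls = simcalls, truth = truth)
}
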