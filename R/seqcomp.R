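# Sequence-composition characterisation: CpG-island detection with the
# classical >=200 bp / GC > 50% / CpG observed-to-expected > 0.6 criteria,
# and exact k-mer self-similarity (dot plot) repeat delineation.

# Per-interval composition via prefix sums. Returns closures over the
# sequence so repeated interval queries are O(1).
.comp_index <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  cs_c <- cumsum(chars == "C")
  cs_g <- cumsum(chars == "G")
  cs_n <- cumsum(chars == "N")
  is_cg <- if (n >= 2L) {
    chars[-n] == "C" & chars[-1L] == "G"
  } else logical(0)
  cs_cg <- cumsum(is_cg)  # cs_cg[i]: CG dinucleotides starting at <= i
  rng <- function(cs, s, e) {  # sum over 1-based [s, e], vectorised
    cs[e] - ifelse(s > 1L, cs[pmax(s - 1L, 1L)], 0)
  }
  list(
    n = n,
    # all stats for 0-based half-open [s0, e0)
    stats = function(s0, e0) {
      s <- s0 + 1L
      e <- e0
      len <- e0 - s0
      n_c <- rng(cs_c, s, e)
      n_g <- rng(cs_g, s, e)
      n_n <- rng(cs_n, s, e)
      n_cg <- ifelse(len >= 2L, rng(cs_cg, s, pmax(e - 1L, s)), 0)
      eff <- len - n_n
      gc <- ifelse(eff > 0, (n_c + n_g) / eff, 0)
      exp_cg <- n_c * n_g / len
      oe <- ifelse(exp_cg > 0, n_cg / exp_cg, 0)
      list(length = len, gc_fraction = gc, obs_exp_cpg = oe)
    })
}

#' Detect CpG islands
#'
#' Classical criteria: length >= `min_length`, GC fraction > `gc_min`,
#' observed/expected CpG > `oe_min`, where expected CpG is
#' `count(C) * count(G) / length`. The detector enumerates, for every
#' start position, the longest qualifying interval (up to `max_length`),
#' groups overlapping qualifying intervals, and reports the longest
#' interval of each group (leftmost on ties). This is exact maximal-
#' interval detection, not a windowed approximation: a sliding-window
#' screen can miss qualifying intervals none of whose fixed-size windows
#' qualify. `N` bases never count as C/G and are excluded from the GC
#' denominator.
#'
#' @param seq uppercase DNA (character, or `DNAString`).
#' @param min_length minimum island length (bp); default 200.
#' @param gc_min GC-fraction threshold (exclusive); default 0.5.
#' @param oe_min observed/expected CpG threshold (exclusive); default 0.6.
#' @param max_length longest island considered (bp); default 2000, well
#'   above typical plant gene-body islands. Bounds the quadratic scan.
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `length`, `gc_fraction`, `obs_exp_cpg`; islands sorted and
#'   non-overlapping. Zero rows when the sequence is shorter than
#'   `min_length` or nothing qualifies.
#' @export
find_cpg_islands <- function(seq, min_length = 200L, gc_min = 0.5,
                             oe_min = 0.6, max_length = 2000L) {
  seq <- .check_dna(seq)
  n <- nchar(seq)
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      gc_fraction = numeric(), obs_exp_cpg = numeric())
  if (n < min_length) return(empty)
  ix <- .comp_index(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  cs_c <- c(0, cumsum(chars == "C"))
  cs_g <- c(0, cumsum(chars == "G"))
  cs_n <- c(0, cumsum(chars == "N"))
  cs_cg <- c(0, cumsum(chars[-n] == "C" & chars[-1L] == "G"), 0)
  # per start, the longest qualifying end (scan lengths ascending so later
  # hits overwrite shorter ones); the GC criterion is the cheap prescreen,
  # O/E is evaluated only on GC-passing starts
  best_end <- rep(NA_integer_, n - min_length + 1L)
  for (len in seq.int(min_length, min(n, max_length))) {
    i1 <- seq_len(n - len + 1L)           # 1-based interval starts
    i2 <- i1 + len
    nc <- cs_c[i2] - cs_c[i1]
    ng <- cs_g[i2] - cs_g[i1]
    nn <- cs_n[i2] - cs_n[i1]
    gc_ok <- which((nc + ng) > gc_min * (len - nn) & (len - nn) > 0L)
    if (length(gc_ok) == 0L) next
    ncg <- cs_cg[i2[gc_ok] - 1L] - cs_cg[i1[gc_ok]]
    exp_cg <- nc[gc_ok] * ng[gc_ok] / len
    hit <- gc_ok[exp_cg > 0 & ncg > oe_min * exp_cg]
    if (length(hit) > 0L) best_end[hit] <- (hit - 1L) + len
  }
  qs <- which(!is.na(best_end)) - 1L       # qualifying 0-based starts
  if (length(qs) == 0L) return(empty)
  ends <- best_end[qs + 1L]
  # group strictly overlapping intervals; report the longest per group
  comp <- integer(length(qs))
  comp[1L] <- 1L
  cur_end <- ends[1L]
  for (i in seq_along(qs)[-1L]) {
    if (qs[i] < cur_end) {
      comp[i] <- comp[i - 1L]
      cur_end <- max(cur_end, ends[i])
    } else {
      comp[i] <- comp[i - 1L] + 1L
      cur_end <- ends[i]
    }
  }
  pick <- vapply(split(seq_along(comp), comp), function(ixs) {
    ixs[which.max(ends[ixs] - qs[ixs])]
  }, 0L)
  st <- ix$stats(qs[pick], ends[pick])
  out <- data.frame(start = qs[pick], end = ends[pick], length = st$length,
                    gc_fraction = st$gc_fraction,
                    obs_exp_cpg = st$obs_exp_cpg)
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

#' Exact k-mer self-similarity matches and repeat segments
#'
#' Tabulates every exact k-mer self-match off the main diagonal, on both
#' strands, and reports maximal repeat segments: runs of bases covered by at
#' least `min_density` matching k-mers, merged across gaps of at most
#' `max_offset_merge` bp.
#'
#' @param seq uppercase DNA (character or `DNAString`).
#' @param k k-mer size; must be >= 8. Default 15. K-mers containing `N` are
#'   skipped.
#' @param max_offset_merge merge gap (bp) between covered runs; default 30.
#' @param min_density minimum per-base match count inside a segment;
#'   default 1.
#' @param min_segment_length segments shorter than this are dropped;
#'   default `2 * k`, which suppresses isolated chance matches.
#' @return list with `matches` (data.frame `i`, `j`, `strand`; 0-based
#'   k-mer start coordinates, `strand` `"-"` for reverse-complement matches)
#'   and `segments` (data.frame `start`, `end`, `length`,
#'   `self_match_density` = mean per-base match coverage).
#' @export
dotplot_matches <- function(seq, k = 15L, max_offset_merge = 30L,
                            min_density = 1, min_segment_length = 2L * k) {
  seq <- .check_dna(seq)
  stopifnot(k >= 8L)
  n <- nchar(seq)
  empty <- list(matches = data.frame(i = integer(), j = integer(),
                                     strand = character()),
                segments = data.frame(start = integer(), end = integer(),
                                      length = integer(),
                                      self_match_density = numeric()))
  if (k > n) return(empty)
  starts <- 1:(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  valid <- !grepl("N", kmers, fixed = TRUE)
  rc <- .revcomp(seq)
  kmers_rc_of_fwd <- substring(rc, starts, starts + k - 1L)
  # reverse-complement k-mer starting (0-based) at forward position p
  # is the rc-string k-mer starting at n - k - p
  pairs <- list()
  # forward-forward: all ordered pairs of equal k-mers, i != j
  grp <- split((starts - 1L)[valid], kmers[valid])
  grp <- grp[lengths(grp) > 1L]
  for (g in grp) {
    cmb <- expand.grid(i = g, j = g)
    cmb <- cmb[cmb$i != cmb$j, , drop = FALSE]
    pairs[[length(pairs) + 1L]] <-
      data.frame(i = cmb$i, j = cmb$j, strand = "+")
  }
  # forward-reverse: forward k-mer at i equals reverse complement of the
  # k-mer at j (i may equal j for palindromes; still off-diagonal in the
  # reverse frame)
  fwd_map <- split((starts - 1L)[valid], kmers[valid])
  rc_pos0 <- n - k - (starts - 1L)          # forward 0-based start of rc k-mer
  rc_map <- split(rc_pos0[valid[rc_pos0 + 1L]],
                  kmers_rc_of_fwd[valid[rc_pos0 + 1L]])
  shared <- intersect(names(fwd_map), names(rc_map))
  for (km in shared) {
    cmb <- expand.grid(i = fwd_map[[km]], j = rc_map[[km]])
    if (nrow(cmb) > 0L) {
      pairs[[length(pairs) + 1L]] <-
        data.frame(i = cmb$i, j = cmb$j, strand = "-")
    }
  }
  matches <- do.call(rbind, c(pairs, list(NULL)))
  if (is.null(matches) || nrow(matches) == 0L) return(empty)
  matches <- matches[order(matches$i, matches$j), , drop = FALSE]
  rownames(matches) <- NULL
  # per-base coverage by the i-side k-mer windows
  cov <- integer(n)
  for (r in seq_len(nrow(matches))) {
    idx <- (matches$i[r] + 1L):(matches$i[r] + k)
    cov[idx] <- cov[idx] + 1L
  }
  covered <- cov >= min_density
  segs <- empty$segments
  if (any(covered)) {
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts_run <- ends - r$lengths + 1L
    runs <- data.frame(start = starts_run[r$values] - 1L,
                       end = ends[r$values])
    # merge runs separated by small gaps
    merged <- runs[1L, , drop = FALSE]
    if (nrow(runs) > 1L) {
      for (q in 2:nrow(runs)) {
        if (runs$start[q] - merged$end[nrow(merged)] <= max_offset_merge) {
          merged$end[nrow(merged)] <- runs$end[q]
        } else {
          merged <- rbind(merged, runs[q, ])
        }
      }
    }
    segs <- data.frame(
      start = merged$start, end = merged$end,
      length = merged$end - merged$start,
      self_match_density = vapply(seq_len(nrow(merged)), function(q) {
        mean(cov[(merged$start[q] + 1L):merged$end[q]])
      }, 0))
    segs <- segs[segs$length >= min_segment_length, , drop = FALSE]
    rownames(segs) <- NULL
  }
  list(matches = matches, segments = segs)
}

#' Complement of repeat segments within a sequence span
#'
#' @param seq_length sequence length (bp), or the sequence itself.
#' @param repeat_segments data.frame with `start`, `end` (0-based half-open),
#'   e.g. from [dotplot_matches()]`$segments`.
#' @param upstream_only if TRUE, return only the interval upstream of the
#'   first repeat segment.
#' @return data.frame of unique (non-repeat) intervals `start`, `end`.
#' @export
unique_region <- function(seq_length, repeat_segments,
                          upstream_only = FALSE) {
  if (is.character(seq_length)) seq_length <- nchar(seq_length)
  segs <- repeat_segments[order(repeat_segments$start), , drop = FALSE]
  gaps <- data.frame(start = integer(), end = integer())
  cursor <- 0L
  for (i in seq_len(nrow(segs))) {
    if (segs$start[i] > cursor) {
      gaps <- rbind(gaps, data.frame(start = cursor, end = segs$start[i]))
    }
    cursor <- max(cursor, segs$end[i])
  }
  if (cursor < seq_length) {
    gaps <- rbind(gaps, data.frame(start = cursor, end = seq_length))
  }
  if (upstream_only && nrow(segs) > 0L) {
    gaps <- gaps[gaps$end <= segs$start[1L], , drop = FALSE]
  }
  rownames(gaps) <- NULL
  gaps
}
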