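# Guide panel geometry: protospacer/PAM location, SpCas9 blunt-cut
# prediction and excised-fragment enumeration.
#
# SpCas9 geometry: the 20-nt protospacer is immediately followed by the PAM
# (default NGG); the blunt double-strand break falls 3 bp 5' of the PAM,
# i.e. between protospacer positions 17 and 18.

#' Construct a guide RNA description
#'
#' @param name short label for the guide (e.g. `"Glu-1By_F1"`).
#' @param spacer 20-nt DNA spacer sequence, A/C/G/T only.
#' @param pam_pattern PAM in IUPAC notation; default `"NGG"` (SpCas9).
#' @param orientation intended orientation, `"F"` or `"R"`, as used in guide
#'   design tables. Informational only: both strands are always searched.
#' @return an object of class `guide_rna`.
#' @examples
#' g <- guide_rna("Bx_F1", "AAAACGTCCATGCATAAGTA")
#' @export
guide_rna <- function(name, spacer, pam_pattern = "NGG", orientation = "F") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  spacer <- .check_dna(spacer, allow = c("A", "C", "G", "T"), what = "spacer")
  if (nchar(spacer) != 20L) {
    stop("spacer must be exactly 20 nt, got ", nchar(spacer))
  }
  if (!is.character(pam_pattern) || !nzchar(pam_pattern)) {
    stop("pam_pattern must be a non-empty IUPAC string")
  }
  pam_pattern <- toupper(pam_pattern)
  iupac <- strsplit("ACGTRYSWKMBDHVN", "")[[1L]]
  if (!all(strsplit(pam_pattern, "")[[1L]] %in% iupac)) {
    stop("pam_pattern contains non-IUPAC characters")
  }
  orientation <- match.arg(orientation, c("F", "R"))
  structure(list(name = name, spacer = spacer, pam_pattern = pam_pattern,
                 intended_orientation = orientation),
            class = "guide_rna")
}

#' @export
print.guide_rna <- function(x, ...) {
  cat(sprintf("<guide_rna> %s  %s-%s (%s)\n", x$name, x$spacer,
              x$pam_pattern, x$intended_orientation))
  invisible(x)
}

#' Read a guide table (TSV: name, spacer, orientation)
#'
#' @param path TSV file with columns `name`, `spacer` and optionally
#'   `orientation`; a header line is expected.
#' @param pam_pattern PAM applied to every guide.
#' @return list of [guide_rna()] objects.
#' @export
read_guides <- function(path, pam_pattern = "NGG") {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "spacer") %in% names(tab)))
  ori <- if ("orientation" %in% names(tab)) tab$orientation else "F"
  ori <- rep_len(ori, nrow(tab))
  lapply(seq_len(nrow(tab)), function(i) {
    guide_rna(tab$name[i], tab$spacer[i], pam_pattern, ori[i])
  })
}

# Coerce references to a named character vector of uppercase DNA.
.as_reference_set <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    seqs <- as.character(reference)
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  } else if (methods::is(reference, "DNAString")) {
    seqs <- c(ref = as.character(reference))
  } else if (is.character(reference)) {
    seqs <- reference
    if (is.null(names(seqs))) {
      names(seqs) <- if (length(seqs) == 1L) "ref" else
        paste0("seq", seq_along(seqs))
    }
  } else {
    stop("reference must be a character vector, DNAString or DNAStringSet")
  }
  vapply(seqs, .check_dna, "", what = "reference")
}

# All protospacer+PAM occurrences of one guide in one sequence.
# Returns 0-based: site span [site_start, site_end), cut position, strand.
.scan_guide <- function(seq, guide) {
  subject <- Biostrings::DNAString(seq)
  pat_fwd <- Biostrings::DNAString(paste0(guide$spacer, guide$pam_pattern))
  p <- nchar(guide$pam_pattern)
  fixed <- c(pattern = FALSE, subject = TRUE)  # IUPAC in pattern only
  hits_f <- Biostrings::matchPattern(pat_fwd, subject, fixed = fixed)
  hits_r <- Biostrings::matchPattern(Biostrings::reverseComplement(pat_fwd),
                                     subject, fixed = fixed)
  f_start <- BiocGenerics::start(hits_f) - 1L   # 0-based site start
  r_start <- BiocGenerics::start(hits_r) - 1L
  data.frame(
    site_start = c(f_start, r_start),
    site_end   = c(f_start + 20L + p, r_start + 20L + p),
    # + strand: cut 3 bp 5' of PAM = protospacer start + 17
    # - strand: forward-coordinate PAM half-open end + 3
    position   = c(f_start + 17L, r_start + p + 3L),
    strand     = rep(c("+", "-"), c(length(f_start), length(r_start))),
    stringsAsFactors = FALSE
  )
}

#' Locate protospacer+PAM sites and predicted Cas9 cut positions
#'
#' Finds every exact occurrence of the guide spacer immediately followed by a
#' PAM match, on both strands of each reference, and reports the blunt-cut
#' coordinate (3 bp 5' of the PAM). Positions are 0-based: a cut at position
#' `p` falls between bases `p-1` and `p`.
#'
#' @param reference named character vector, `DNAString` or `DNAStringSet`.
#' @param guide a [guide_rna()] object.
#' @return data.frame of cut sites with columns `reference_id`, `position`,
#'   `strand`, `guide_name`, plus the matched `site_start`/`site_end` span
#'   (protospacer+PAM, 0-based half-open). Zero rows when nothing matches.
#' @examples
#' ref <- paste0(strrep("A", 100), "AAAACGTCCATGCATAAGTA", "CGG",
#'               strrep("T", 50))
#' find_protospacers(c(chr = ref), guide_rna("g1", "AAAACGTCCATGCATAAGTA"))
#' @export
find_protospacers <- function(reference, guide) {
  stopifnot(inherits(guide, "guide_rna"))
  seqs <- .as_reference_set(reference)
  out <- lapply(names(seqs), function(id) {
    hits <- .scan_guide(seqs[[id]], guide)
    if (nrow(hits) == 0L) return(NULL)
    cbind(data.frame(reference_id = id, stringsAsFactors = FALSE), hits,
          data.frame(guide_name = guide$name, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, c(out, list(NULL)))
  if (is.null(out)) {
    out <- data.frame(reference_id = character(), site_start = integer(),
                      site_end = integer(), position = integer(),
                      strand = character(), guide_name = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$reference_id, out$position),
      c("reference_id", "position", "strand", "guide_name",
        "site_start", "site_end")]
}

#' Predict excised target fragments from paired guide cuts
#'
#' For each (upstream guide, downstream guide) pair, one fragment is produced
#' per combination of an upstream cut and a downstream cut with
#' `upstream < downstream` on the same reference.
#'
#' @param cut_sites data.frame from [find_protospacers()] (rows for all guides
#'   of interest, possibly rbind-ed).
#' @param pairing data.frame with columns `upstream` and `downstream` naming
#'   guides, one row per intended pair.
#' @return data.frame of fragments (`reference_id`, `start`, `end`, `length`,
#'   `guide_up`, `guide_down`), 0-based half-open, sorted by start. Empty with
#'   a warning when no combination is properly ordered.
#' @export
predict_fragments <- function(cut_sites, pairing) {
  stopifnot(is.data.frame(pairing),
            all(c("upstream", "downstream") %in% names(pairing)))
  frags <- list()
  any_candidates <- FALSE
  for (i in seq_len(nrow(pairing))) {
    gu <- pairing$upstream[i]
    gd <- pairing$downstream[i]
    cu <- cut_sites[cut_sites$guide_name == gu, , drop = FALSE]
    cd <- cut_sites[cut_sites$guide_name == gd, , drop = FALSE]
    if (nrow(cu) == 0L || nrow(cd) == 0L) {
      stop("pair (", gu, ", ", gd, "): at least one cut site per guide ",
           "is required")
    }
    shared <- intersect(unique(cu$reference_id), unique(cd$reference_id))
    if (length(shared) == 0L) {
      stop("pair (", gu, ", ", gd, "): cuts lie on different references")
    }
    for (ref in shared) {
      pu <- cu$position[cu$reference_id == ref]
      pd <- cd$position[cd$reference_id == ref]
      combos <- expand.grid(u = pu, d = pd)
      any_candidates <- TRUE
      combos <- combos[combos$u < combos$d, , drop = FALSE]
      if (nrow(combos) > 0L) {
        frags[[length(frags) + 1L]] <- data.frame(
          reference_id = ref, start = combos$u, end = combos$d,
          length = combos$d - combos$u, guide_up = gu, guide_down = gd,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(frags, list(NULL)))
  if (is.null(out)) {
    if (any_candidates) {
      warning("no properly ordered (upstream < downstream) cut combination; ",
              "returning zero fragments")
    }
    out <- data.frame(reference_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      guide_up = character(), guide_down = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$reference_id, out$start, out$end), , drop = FALSE]
}

#' Count exact protospacer+PAM occurrences outside declared target intervals
#'
#' A simplified exact-match off-target census (no mismatch tolerance, no
#' scoring): every protospacer+PAM occurrence on either strand whose matched
#' span does not overlap any declared target interval is counted.
#'
#' @param reference named character vector, `DNAString` or `DNAStringSet`.
#' @param guide a [guide_rna()] object.
#' @param targets data.frame with columns `reference_id`, `start`, `end`
#'   (0-based half-open) declaring on-target intervals.
#' @return integer count (>= 0).
#' @export
offtarget_exact_count <- function(reference, guide, targets) {
  stopifnot(is.data.frame(targets),
            all(c("reference_id", "start", "end") %in% names(targets)))
  sites <- find_protospacers(reference, guide)
  if (nrow(sites) == 0L) return(0L)
  off <- vapply(seq_len(nrow(sites)), function(i) {
    t <- targets[targets$reference_id == sites$reference_id[i], ,
                 drop = FALSE]
    if (nrow(t) == 0L) return(TRUE)
    all(.overlap_len(sites$site_start[i], sites$site_end[i],
                     t$start, t$end) == 0L)
  }, NA)
  sum(off)
}
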