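# Per-read and per-site methylation summaries over target regions:
# read x site matrices, per-site frequencies, cytosine sequence context,
# promoter-vs-gene-body contrast and haplotype-split profiles.

#' Build a read x site methylation matrix for a region
#'
#' Calls are binarised at a single threshold: an entry is methylated iff
#' `prob >= binarize_threshold` (ties count as methylated, matching an
#' argmax caller label at 0.5). Sites are (position, strand) pairs; sites
#' with zero coverage are excluded.
#'
#' @param calls data.frame from [parse_meth_calls()].
#' @param region a [target_locus()] or a `"ref:start..end"` string
#'   (1-based inclusive).
#' @param binarize_threshold probability cut; default 0.5.
#' @return object of class `meth_matrix`: list with `region`, `sites`
#'   (data.frame `pos`, `strand`), `read_ids`, `probs` and `states`
#'   (read x site matrices; states 1 = methylated, 0 = unmethylated,
#'   NA = missing).
#' @export
build_matrix <- function(calls, region, binarize_threshold = 0.5) {
  if (is.character(region)) {
    region <- target_locus(region, region)
  }
  stopifnot(inherits(region, "target_locus"),
            binarize_threshold >= 0, binarize_threshold <= 1)
  cl <- calls[calls$reference_id == region$reference_id &
                calls$ref_pos >= region$start &
                calls$ref_pos < region$end, , drop = FALSE]
  if (nrow(cl) == 0L) {
    empty <- matrix(numeric(), 0L, 0L)
    return(structure(list(region = region,
                          sites = data.frame(pos = integer(),
                                             strand = character()),
                          read_ids = character(), probs = empty,
                          states = empty, threshold = binarize_threshold),
                     class = "meth_matrix"))
  }
  site_key <- paste0(cl$ref_pos, cl$ref_strand)
  sites <- unique(data.frame(pos = cl$ref_pos, strand = cl$ref_strand,
                             key = site_key, stringsAsFactors = FALSE))
  sites <- sites[order(sites$pos, sites$strand), , drop = FALSE]
  reads <- sort(unique(cl$read_id))
  probs <- matrix(NA_real_, length(reads), nrow(sites),
                  dimnames = list(reads, sites$key))
  # last call wins on (read, site) duplicates
  probs[cbind(match(cl$read_id, reads), match(site_key, sites$key))] <-
    cl$prob_meth
  states <- ifelse(is.na(probs), NA_integer_,
                   as.integer(probs >= binarize_threshold))
  structure(list(region = region,
                 sites = data.frame(pos = sites$pos, strand = sites$strand,
                                    stringsAsFactors = FALSE),
                 read_ids = reads, probs = probs, states = states,
                 threshold = binarize_threshold),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("<meth_matrix> %s: %d reads x %d sites (threshold %.2f)\n",
              x$region$name, length(x$read_ids), nrow(x$sites), x$threshold))
  invisible(x)
}

#' Per-site methylation frequency and coverage
#'
#' @param matrix a `meth_matrix` from [build_matrix()].
#' @return data.frame of class `region_profile`: `pos`, `strand`, `n_meth`,
#'   `n_unmeth`, `coverage` (non-missing calls) and `frequency`
#'   (`n_meth / coverage`; `NA` when no read covers the site).
#' @export
site_frequency <- function(matrix) {
  stopifnot(inherits(matrix, "meth_matrix"))
  if (nrow(matrix$sites) == 0L) {
    out <- data.frame(pos = integer(), strand = character(),
                      n_meth = integer(), n_unmeth = integer(),
                      coverage = integer(), frequency = numeric())
  } else {
    n_meth <- colSums(matrix$states == 1L, na.rm = TRUE)
    n_unmeth <- colSums(matrix$states == 0L, na.rm = TRUE)
    cov <- n_meth + n_unmeth
    out <- data.frame(pos = matrix$sites$pos, strand = matrix$sites$strand,
                      n_meth = as.integer(n_meth),
                      n_unmeth = as.integer(n_unmeth),
                      coverage = as.integer(cov),
                      frequency = ifelse(cov > 0, n_meth / cov, NA_real_),
                      row.names = NULL)
  }
  class(out) <- c("region_profile", class(out))
  out
}

#' Classify the cytosine sequence context (CpG / CHG / CHH)
#'
#' Standard plant trinucleotide contexts read 5'->3' on the strand carrying
#' the cytosine. Bases running off the end of the sequence are treated as
#' non-G (context falls back to CHH/CHG accordingly).
#'
#' @param reference_seq reference sequence (character).
#' @param pos 0-based position(s) holding the cytosine (a `C` on `+`, a `G`
#'   on `-` in forward-strand letters).
#' @param strand `"+"` or `"-"`, recycled along `pos`.
#' @return character vector in `c("CpG", "CHG", "CHH")`.
#' @examples
#' context_classify("ACGT", 1, "+")   # CpG
#' context_classify("ACAGT", 1, "+")  # CHG
#' @export
context_classify <- function(reference_seq, pos, strand = "+") {
  chars <- strsplit(toupper(reference_seq), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  strand <- rep_len(strand, length(pos))
  at <- function(i) ifelse(i >= 0L & i < n, chars[i + 1L], "")
  base <- at(pos)
  ok <- (strand == "+" & base == "C") | (strand == "-" & base == "G")
  if (!all(ok)) {
    stop("position(s) ", paste(pos[!ok], collapse = ", "),
         " do not hold a cytosine on strand ",
         paste(unique(strand[!ok]), collapse = "/"))
  }
  # next two bases 5'->3' on the cytosine's strand, in forward letters:
  # + strand: pos+1, pos+2 compared against G
  # - strand: pos-1, pos-2 compared against C (G on the minus strand)
  n1 <- ifelse(strand == "+", at(pos + 1L) == "G", at(pos - 1L) == "C")
  n2 <- ifelse(strand == "+", at(pos + 2L) == "G", at(pos - 2L) == "C")
  ifelse(n1, "CpG", ifelse(n2, "CHG", "CHH"))
}

#' Contrast promoter and gene-body methylation
#'
#' Means of per-site frequencies over two disjoint intervals, with an
#' optional permutation test (site-to-interval labels reshuffled,
#' two-sided on |difference|). The permutation test is a quantitative
#' extension beyond a purely visual promoter/body comparison.
#'
#' @param profile a `region_profile` from [site_frequency()].
#' @param promoter_interval,body_interval numeric `c(start, end)` 0-based
#'   half-open intervals (or `"ref:a..b"` strings), disjoint.
#' @param n_permutations number of label permutations; 0 skips the test.
#' @return object of class `gbm_contrast`: `promoter_mean`, `body_mean`,
#'   `difference` (body - promoter), `n_promoter_sites`, `n_body_sites`,
#'   `p_value` (NA when not permuted).
#' @export
gbm_contrast <- function(profile, promoter_interval, body_interval,
                         n_permutations = 0L) {
  as_iv <- function(x) {
    if (is.character(x)) {
      r <- parse_region(x)
      c(r$start, r$end)
    } else as.numeric(x)
  }
  pr <- as_iv(promoter_interval)
  bd <- as_iv(body_interval)
  if (.overlap_len(pr[1], pr[2], bd[1], bd[2]) > 0) {
    stop("promoter and body intervals must be disjoint")
  }
  f <- profile$frequency
  in_pr <- profile$pos >= pr[1] & profile$pos < pr[2] & !is.na(f)
  in_bd <- profile$pos >= bd[1] & profile$pos < bd[2] & !is.na(f)
  if (sum(in_pr) == 0L) stop("promoter interval contains no covered sites")
  if (sum(in_bd) == 0L) stop("body interval contains no covered sites")
  pm <- mean(f[in_pr])
  bm <- mean(f[in_bd])
  obs <- bm - pm
  p <- NA_real_
  if (n_permutations > 0L) {
    vals <- c(f[in_pr], f[in_bd])
    n_p <- sum(in_pr)
    perm <- vapply(seq_len(n_permutations), function(i) {
      lab <- sample.int(length(vals), n_p)
      mean(vals[-lab]) - mean(vals[lab])
    }, 0)
    p <- (1 + sum(abs(perm) >= abs(obs))) / (n_permutations + 1)
  }
  structure(list(promoter_mean = pm, body_mean = bm, difference = obs,
                 n_promoter_sites = sum(in_pr), n_body_sites = sum(in_bd),
                 p_value = p),
            class = "gbm_contrast")
}

#' @export
print.gbm_contrast <- function(x, ...) {
  cat(sprintf(
    "<gbm_contrast> promoter %.3f (%d sites) | body %.3f (%d sites) | diff %+.3f",
    x$promoter_mean, x$n_promoter_sites, x$body_mean, x$n_body_sites,
    x$difference))
  if (!is.na(x$p_value)) cat(sprintf(" | perm p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}

#' Split a methylation matrix into per-haplotype profiles
#'
#' @param matrix a `meth_matrix`.
#' @param read_to_haplotype named character vector (read id -> `"HP1"`,
#'   `"HP2"` or `"unassigned"`), or a data.frame with columns `read_id`,
#'   `haplotype`. Reads of the matrix missing from the mapping are treated
#'   as unassigned; mapping entries for unknown read ids are ignored with a
#'   warning.
#' @return named list of `region_profile` data.frames (`HP1`, `HP2`,
#'   `unassigned`; empty profiles when a group has no reads).
#' @export
split_by_haplotype <- function(matrix, read_to_haplotype) {
  stopifnot(inherits(matrix, "meth_matrix"))
  if (is.data.frame(read_to_haplotype)) {
    read_to_haplotype <- setNames(as.character(read_to_haplotype$haplotype),
                                  read_to_haplotype$read_id)
  }
  unknown <- setdiff(names(read_to_haplotype), matrix$read_ids)
  if (length(unknown) > 0L) {
    warning(length(unknown),
            " read id(s) in the haplotype mapping are absent from the ",
            "matrix and were ignored")
  }
  hp <- read_to_haplotype[matrix$read_ids]
  hp[is.na(hp)] <- "unassigned"
  groups <- c("HP1", "HP2", "unassigned")
  out <- lapply(groups, function(g) {
    sub <- matrix
    keep <- which(hp == g)
    sub$read_ids <- matrix$read_ids[keep]
    sub$probs <- matrix$probs[keep, , drop = FALSE]
    sub$states <- matrix$states[keep, , drop = FALSE]
    site_frequency(sub)
  })
  names(out) <- groups
  out
}

#' Write a per-site profile as bedGraph or TSV
#'
#' bedGraph rows carry the methylation frequency; sites with no coverage are
#' skipped in bedGraph output and kept (frequency `NA`) in TSV.
#'
#' @param profile a `region_profile`.
#' @param reference_id reference name for the bedGraph rows.
#' @param path output path.
#' @param format `"bedgraph"` or `"tsv"`.
#' @return the path, invisibly.
#' @export
write_site_profile <- function(profile, reference_id, path,
                               format = c("bedgraph", "tsv")) {
  format <- match.arg(format)
  .atomic_write(function(tmp) {
    if (format == "bedgraph") {
      keep <- !is.na(profile$frequency)
      df <- data.frame(reference_id, profile$pos[keep],
                       profile$pos[keep] + 1L, profile$frequency[keep])
      write.table(df, tmp, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    } else {
      write.table(cbind(reference_id = reference_id, profile), tmp,
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }, path)
}

#' Write a read x site methylation matrix as TSV
#'
#' @param matrix a `meth_matrix`.
#' @param path output path; rows are reads, columns are `pos(strand)` sites,
#'   entries are probabilities (`NA` = missing).
#' @return the path, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "meth_matrix"))
  .atomic_write(function(tmp) {
    df <- as.data.frame(matrix$probs)
    df <- cbind(read_id = rownames(matrix$probs), df)
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}
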