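# MM/ML tag encoding/decoding, CIGAR coordinate mapping, SAM tagging.

test_that("call-table parsing maps the dialect columns and rejects bad rows", {
  tsv <- tempfile(fileext = ".tsv")
  write_calls_fixture(tsv, data.frame(
    read_id = c("r1", "r2", "r3"), reference_id = "chr",
    ref_pos = c(10L, 20L, 30L), ref_strand = "+",
    prob_meth = c(0.9, 0.1, 0.5)))
  calls <- parse_meth_calls(tsv)
  expect_identical(nrow(calls), 3L)
  expect_identical(calls$read_id, c("r1", "r2", "r3"))
  expect_equal(calls$prob_meth, c(0.9, 0.1, 0.5))
  expect_identical(attr(calls, "n_malformed"), 0L)

  # a probability outside [0, 1] drops only that row, with a warning
  lines <- readLines(tsv)
  bad <- sub("\t0.9\t", "\t1.3\t", lines[1])
  bad <- sub("0.1\t0.9", "-0.3\t1.3", lines[1])
  writeLines(c(bad, lines[2:3]), tsv)
  expect_warning(calls2 <- parse_meth_calls(tsv), "malformed")
  expect_identical(nrow(calls2), 2L)
  expect_identical(attr(calls2, "n_malformed"), 1L)

  expect_error(parse_meth_calls(tsv, dialect = "nope"), "unknown")
})

test_that("reference-to-read mapping handles clips, deletions and strand flips", {
  expect_identical(ref_to_read_positions("10M", 100, FALSE, 10, 102L), 2L)
  expect_identical(ref_to_read_positions("2S4M1D4M", 50, FALSE, 10,
                                         c(54L, 55L)), c(NA_integer_, 6L))
  expect_identical(ref_to_read_positions("10M", 100, TRUE, 10, 102L), 7L)
  expect_error(ref_to_read_positions("10M", 0, FALSE, 8, 1L), "length")
  expect_error(ref_to_read_positions("*", 0, FALSE, 8, 1L), "CIGAR")
})

test_that("coordinate mapping agrees with the aligned-pair walk oracle on random CIGARs", {
  set.seed(99)
  for (i in 1:300) {
    rc <- random_cigar()
    start <- sample(0:5000, 1)
    rev <- runif(1) < 0.5
    # probe positions: inside, at the edges and outside the span
    probes <- sort(unique(c(
      sample(start:(start + rc$ref_span + 10), 8, replace = TRUE),
      start - 1L, start, start + rc$ref_span - 1L, start + rc$ref_span)))
    got <- ref_to_read_positions(rc$cigar, start, rev, rc$read_length,
                                 probes)
    want <- oracle_ref_to_read(rc$cigar, start, rev, rc$read_length,
                               probes)
    expect_identical(got, want)
  }
})

test_that("MM encoding matches hand-derived delta examples", {
  expect_identical(encode_mm("ACGCA", 3L, 1.0),
                   list(mm = "C+m?,1;", ml = 255L))
  expect_identical(encode_mm("CCCC", c(0L, 3L), c(0.5, 0.25)),
                   list(mm = "C+m?,0,2;", ml = c(128L, 64L)))
  expect_identical(encode_mm("ACGT", integer(), numeric()),
                   list(mm = NULL, ml = NULL))
  expect_error(encode_mm("ACGCA", 2L, 0.5), "do not hold")
})

test_that("decode(encode(x)) recovers positions exactly and probs within 1/256", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(20:80, 1)
    seq <- random_dna(n, gc = runif(1, 0.3, 0.7))
    cpos <- which(strsplit(seq, "")[[1]] == "C") - 1L
    if (length(cpos) == 0L) next
    k <- sample.int(length(cpos), 1)
    pos <- sort(cpos[sample.int(length(cpos), k)])
    probs <- runif(k)
    enc <- encode_mm(seq, pos, probs)
    dec <- decode_mm(seq, enc$mm, enc$ml)
    expect_identical(dec$positions, pos)
    expect_true(all(abs(dec$probs - probs) < 1 / 256))
  }
})

test_that("tampering with one delta shifts downstream positions", {
  seq <- "CCACCACC"
  enc <- encode_mm(seq, c(0L, 3L, 6L), c(0.9, 0.9, 0.9))
  dec_ok <- decode_mm(seq, enc$mm, enc$ml)
  tampered <- sub("C\\+m\\?,0", "C+m?,1", enc$mm)
  dec_bad <- decode_mm(seq, tampered, enc$ml)
  expect_false(identical(dec_ok$positions, dec_bad$positions))
  # skipping one extra C pushes the first listed position from C0 to C1
  expect_identical(dec_bad$positions[1], 1L)
})

test_that("empty or foreign MM tags decode to nothing", {
  expect_identical(decode_mm("ACGT", "")$positions, integer())
  expect_identical(decode_mm("ACGT", NULL)$positions, integer())
  # an A+a item is skipped and its ML values are not consumed for C+m
  expect_identical(decode_mm("ACGT", "A+a?,0;", 5L)$positions, integer())
  expect_error(decode_mm("ACGT", "Z~x"), "malformed")
})

# build a small SAM + calls fixture around a known reference
tagging_fixture <- function(dir = tempfile()) {
  dir.create(dir)
  set.seed(55)
  ref <- random_dna(500, gc = 0.5)
  sam <- file.path(dir, "in.sam")
  reads <- list(
    fwd = list(flag = 0L, pos1 = 101L, cigar = "100M"),
    rev = list(flag = 16L, pos1 = 201L, cigar = "100M"),
    del = list(flag = 0L, pos1 = 301L, cigar = "40M10D50M"),
    nocall1 = list(flag = 0L, pos1 = 11L, cigar = "60M"),
    nocall2 = list(flag = 0L, pos1 = 401L, cigar = "60M"))
  recs <- vapply(names(reads), function(id) {
    r <- reads[[id]]
    span <- ""
    # reconstruct SEQ from the reference through the CIGAR
    lens <- as.integer(strsplit(gsub("[A-Z]", " ", r$cigar), " +")[[1]])
    ops <- strsplit(gsub("[0-9]+", "", r$cigar), "")[[1]]
    p <- r$pos1
    for (j in seq_along(ops)) {
      if (ops[j] == "M") {
        span <- paste0(span, substr(ref, p, p + lens[j] - 1L))
        p <- p + lens[j]
      } else if (ops[j] == "D") {
        p <- p + lens[j]
      }
    }
    sam_record(id, r$flag, "chr", r$pos1, r$cigar, span)
  }, "")
  write_sam_fixture(sam, recs, ref_id = "chr", ref_len = 600L)
  list(dir = dir, ref = ref, sam = sam, reads = reads)
}

test_that("tagging adds MM/ML only to reads with mappable calls and round-trips", {
  fx <- tagging_fixture()
  chars <- strsplit(fx$ref, "")[[1]]
  # forward reads can encode + strand C calls; the reverse-aligned read
  # presents - strand cytosines (reference G positions) as C
  c_in <- function(a, b) (which(chars == "C") - 1L)[
    which(chars == "C") - 1L >= a & which(chars == "C") - 1L < b]
  g_in <- function(a, b) (which(chars == "G") - 1L)[
    which(chars == "G") - 1L >= a & which(chars == "G") - 1L < b]
  calls <- rbind(
    data.frame(read_id = "fwd", reference_id = "chr",
               ref_pos = head(c_in(100, 200), 5), ref_strand = "+",
               prob_meth = 0.9),
    data.frame(read_id = "rev", reference_id = "chr",
               ref_pos = head(g_in(200, 300), 4), ref_strand = "-",
               prob_meth = 0.8),
    data.frame(read_id = "del", reference_id = "chr",
               ref_pos = head(c_in(300, 400), 6), ref_strand = "+",
               prob_meth = 0.7))
  calls$context <- "NNCNN"
  calls$called_label <- 1L
  out <- file.path(fx$dir, "out.sam")
  summary <- tag_alignments(fx$sam, calls, out)
  expect_identical(sort(summary$read_id), c("del", "fwd", "rev"))
  lines <- readLines(out)
  body <- lines[!startsWith(lines, "@")]
  mm <- regmatches(body, regexpr("MM:Z:[^\t]+", body))
  tagged <- grepl("MM:Z:", body)
  names(tagged) <- vapply(strsplit(body, "\t"), `[[`, "", 1L)
  expect_true(all(tagged[c("fwd", "rev", "del")]))
  expect_false(any(tagged[c("nocall1", "nocall2")]))
  # untagged records are byte-identical to the input
  in_body <- readLines(fx$sam)
  in_body <- in_body[!startsWith(in_body, "@")]
  expect_identical(body[!tagged], in_body[!tagged])

  # round trip: decode the reverse-strand read's tag; positions must land
  # on C in original orientation and probabilities match the calls
  rev_line <- body[startsWith(body, "rev")]
  f <- strsplit(rev_line, "\t")[[1]]
  mm_val <- sub("^MM:Z:", "", grep("^MM:Z:", f, value = TRUE))
  ml_val <- as.integer(strsplit(
    sub("^ML:B:C,", "", grep("^ML:B:C", f, value = TRUE)), ",")[[1]])
  seq_orig <- revcomp_chr(f[10])
  dec <- decode_mm(seq_orig, mm_val, ml_val)
  oc <- strsplit(seq_orig, "")[[1]][dec$positions + 1L]
  expect_true(all(oc == "C"))
  expect_true(all(abs(dec$probs - 0.8) < 1 / 256))
  expect_identical(length(dec$positions), 4L)
})

test_that("calls at deleted or non-C positions are dropped with counters", {
  fx <- tagging_fixture()
  chars <- strsplit(fx$ref, "")[[1]]
  # 'del' read: CIGAR 40M10D50M at pos1 301 -> ref [340, 350) is deleted
  del_c <- (which(chars == "C") - 1L)
  del_c <- del_c[del_c >= 340 & del_c < 350]
  expect_gt(length(del_c), 0L)  # the seeded fixture has Cs in this window
  calls <- data.frame(read_id = "del", reference_id = "chr",
                      ref_pos = del_c, ref_strand = "+", prob_meth = 0.9,
                      context = "NNCNN", called_label = 1L)
  out <- tempfile(fileext = ".sam")
  summary <- tag_alignments(fx$sam, calls, out)
  expect_identical(summary$n_unmapped_pos, length(del_c))
  expect_identical(summary$n_tagged, 0L)
  body <- readLines(out)
  expect_false(any(grepl("MM:Z:", body[grepl("^del\t", body)])))
})

test_that("tagging is idempotent: re-running replaces rather than duplicates", {
  fx <- tagging_fixture()
  chars <- strsplit(fx$ref, "")[[1]]
  cpos <- (which(chars == "C") - 1L)
  cpos <- head(cpos[cpos >= 100 & cpos < 200], 3)
  calls <- data.frame(read_id = "fwd", reference_id = "chr",
                      ref_pos = cpos, ref_strand = "+", prob_meth = 0.6,
                      context = "NNCNN", called_label = 1L)
  out1 <- tempfile(fileext = ".sam")
  out2 <- tempfile(fileext = ".sam")
  tag_alignments(fx$sam, calls, out1)
  tag_alignments(out1, calls, out2)
  expect_identical(readLines(out1), readLines(out2))
  line <- grep("^fwd\t", readLines(out2), value = TRUE)
  expect_identical(lengths(regmatches(line, gregexpr("MM:Z:", line))), 1L)
})

test_that("every tagged position lands on C across a simulated data set", {
  cfg <- small_sim_config(seed = 17)
  res <- simulate_ncats(cfg, out_dir = tempfile())
  calls <- data.frame(
    read_id = res$simcalls$calls$read_id,
    reference_id = res$simcalls$calls$chrom,
    ref_pos = res$simcalls$calls$pos,
    ref_strand = res$simcalls$calls$strand,
    prob_meth = res$simcalls$calls$prob_meth,
    context = res$simcalls$calls$kmer,
    called_label = res$simcalls$calls$label)
  sam <- file.path(tempdir(), "sim_tag_in.sam")
  write_sim_sam(res$sim, res$reference, sam)
  out <- tempfile(fileext = ".sam")
  tag_alignments(sam, calls, out)
  body <- readLines(out)
  body <- body[!startsWith(body, "@")]
  tagged <- body[grepl("MM:Z:", body)]
  expect_gt(length(tagged), 0L)
  for (line in tagged) {
    f <- strsplit(line, "\t")[[1]]
    mm_val <- sub("^MM:Z:", "", grep("^MM:Z:", f, value = TRUE))
    ml_val <- as.integer(strsplit(
      sub("^ML:B:C,", "", grep("^ML:B:C", f, value = TRUE)), ",")[[1]])
    seq_orig <- if (bitwAnd(as.integer(f[2]), 16L) != 0L) {
      revcomp_chr(f[10])
    } else f[10]
    dec <- decode_mm(seq_orig, mm_val, ml_val)
    expect_true(all(strsplit(seq_orig, "")[[1]][dec$positions + 1L] == "C"))
  }
})
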