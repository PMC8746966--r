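# Synthetic-data generator: determinism, architecture self-audit, read
# regime, call emission, ground-truth consistency.

test_that("configuration validation catches impossible architectures", {
  expect_error(sim_config(), "mandatory")
  expect_error(small_sim_config(island_offset = 2900L,
                                island_length = 300L))
  expect_error(small_sim_config(target_depth = 0))
  expect_error(small_sim_config(coverage_x = 0))
  expect_error(small_sim_config(meth_probs = list(
    promoter = c(CpG = 1.4, CHG = 0, CHH = 0),
    body = c(CpG = 0.8, CHG = 0.1, CHH = 0.05))))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 5)
  a <- make_reference(cfg, audit = FALSE)
  b <- make_reference(cfg, audit = FALSE)
  expect_identical(a$seq, b$seq)
  ra <- simulate_reads(cfg, a)
  rb <- simulate_reads(cfg, b)
  expect_identical(ra$reads, rb$reads)
  ca <- simulate_meth_calls(cfg, a, ra)
  cb <- simulate_meth_calls(cfg, b, rb)
  expect_identical(ca$calls, cb$calls)
  # different seed -> different sequence
  expect_false(identical(
    make_reference(small_sim_config(seed = 6), audit = FALSE)$seq, a$seq))
})

test_that("written outputs are byte-identical across runs with the same seed", {
  d1 <- tempfile()
  d2 <- tempfile()
  simulate_ncats(small_sim_config(seed = 9), d1)
  simulate_ncats(small_sim_config(seed = 9), d2)
  for (f in c("reference.fa", "reads.sam", "reads.fastq", "calls.tsv",
              "architecture.bed", "ground_truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("the designed architecture passes its own detectors", {
  cfg <- small_sim_config(seed = 12)
  ref <- make_reference(cfg)  # audit = TRUE would stop() on failure
  locus_seq <- substr(ref$seq, cfg$locus_start + 1,
                      cfg$locus_start + cfg$locus_length)
  isl <- find_cpg_islands(locus_seq)
  expect_gte(nrow(isl), 1L)
  dp <- dotplot_matches(locus_seq)
  expect_gte(nrow(dp$segments), 1L)
  # guide cuts delimit exactly the locus
  cuts <- rbind(find_protospacers(c(refA = ref$seq), ref$guides[[1]]),
                find_protospacers(c(refA = ref$seq), ref$guides[[2]]))
  frag <- predict_fragments(cuts, data.frame(upstream = "guide_up",
                                             downstream = "guide_down"))
  expect_identical(frag$start, cfg$locus_start)
  expect_identical(frag$length, cfg$locus_length)
})

test_that("simulated reads realise the configured depth and coverage regime", {
  cfg <- small_sim_config(seed = 23)
  ref <- make_reference(cfg, audit = FALSE)
  sim <- simulate_reads(cfg, ref)
  dir <- tempfile()
  dir.create(dir)
  sam <- file.path(dir, "reads.sam")
  write_sim_sam(sim, ref, sam)
  locus <- target_locus("L", list(reference_id = "refA",
                                  start = cfg$locus_start,
                                  end = cfg$locus_start + cfg$locus_length))
  d <- mean_target_depth(sam, locus)
  expect_lt(abs(d - cfg$target_depth), 2)
  # total yield close to the coverage budget
  expect_lt(abs(sim$truth$true_coverage - cfg$coverage_x) / cfg$coverage_x,
            0.15)
  # on-target classification recovers exactly the on-target reads
  on <- classify_on_target(sam, locus)
  truth_on <- sim$reads$read_id[sim$reads$origin == "on_target"]
  expect_setequal(on$L, truth_on)
})

test_that("zero error rate reproduces the reference exactly; errors perturb it", {
  cfg <- small_sim_config(seed = 19, sub_rate = 0, target_depth = 3)
  ref <- make_reference(cfg, audit = FALSE)
  sim <- simulate_reads(cfg, ref)
  on <- sim$reads[sim$reads$origin == "on_target", ]
  for (i in seq_len(nrow(on))) {
    span <- substr(ref$seq, on$pos[i] + 1, on$pos[i] + nchar(on$seq[i]))
    expect_identical(on$seq[i], span)
    expect_identical(on$cigar[i], paste0(nchar(on$seq[i]), "M"))
  }
  cfg2 <- small_sim_config(seed = 19, sub_rate = 0.05, target_depth = 3)
  sim2 <- simulate_reads(cfg2, make_reference(cfg2, audit = FALSE))
  on2 <- sim2$reads[sim2$reads$origin == "on_target", ]
  mism <- vapply(seq_len(nrow(on2)), function(i) {
    span <- substr(ref$seq, on2$pos[i] + 1, on2$pos[i] + nchar(on2$seq[i]))
    a <- strsplit(span, "")[[1]]
    b <- strsplit(on2$seq[i], "")[[1]]
    mean(a != b)
  }, 0)
  expect_gt(mean(mism), 0.02)
  expect_lt(mean(mism), 0.10)
})

test_that("indel mode produces CIGARs consistent with read lengths", {
  cfg <- small_sim_config(seed = 37, indel_rate = 0.01, target_depth = 5)
  ref <- make_reference(cfg, audit = FALSE)
  sim <- simulate_reads(cfg, ref)
  has_indel <- grepl("[ID]", sim$reads$cigar)
  expect_gt(sum(has_indel), 0)
  for (i in seq_len(nrow(sim$reads))) {
    qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(sim$reads$cigar[i])
    expect_identical(qlen, nchar(sim$reads$seq[i]))
  }
  # the SAM remains readable by the alignment machinery
  sam <- tempfile(fileext = ".sam")
  write_sim_sam(sim, ref, sam)
  locus <- target_locus("L", list(reference_id = "refA",
                                  start = cfg$locus_start,
                                  end = cfg$locus_start + cfg$locus_length))
  expect_gt(mean_target_depth(sam, locus), 1)
})

test_that("call emission matches regional truth and separates states cleanly", {
  cfg <- small_sim_config(seed = 41)
  res <- simulate_ncats(cfg)
  calls <- res$simcalls$calls
  truth <- res$truth$site_truth
  # every call sits on a known site with matching strand
  key_calls <- paste(calls$pos, calls$strand)
  key_sites <- paste(truth$pos, truth$strand)
  expect_true(all(key_calls %in% key_sites))
  # probabilities are bimodal around the emission model modes
  expect_true(all(calls$prob_meth >= 0 & calls$prob_meth <= 1))
  expect_gt(mean(calls$prob_meth > 0.5 & calls$prob_meth < 0.99 |
                   calls$prob_meth < 0.5), 0.99)
  # a fully methylated override drives site frequencies to ~1
  cfg_hi <- small_sim_config(seed = 43, meth_probs = list(
    promoter = c(CpG = 1, CHG = 1, CHH = 1),
    body = c(CpG = 1, CHG = 1, CHH = 1)))
  res_hi <- simulate_ncats(cfg_hi)
  calls_hi <- with(res_hi$simcalls$calls, data.frame(
    read_id = read_id, reference_id = chrom, ref_pos = pos,
    ref_strand = strand, prob_meth = prob_meth, context = kmer,
    called_label = label, stringsAsFactors = FALSE))
  locus <- target_locus("L", list(reference_id = "refA",
                                  start = cfg$locus_start,
                                  end = cfg$locus_start + cfg$locus_length))
  prof <- site_frequency(build_matrix(calls_hi, locus))
  expect_gt(mean(prof$frequency, na.rm = TRUE), 0.98)
})

test_that("frequency recovery tightens with depth (0.8 truth, depth 50)", {
  cfg <- small_sim_config(seed = 47, target_depth = 50,
                          coverage_x = 0.05,
                          meth_probs = list(
                            promoter = c(CpG = 0.8, CHG = 0.8, CHH = 0.8),
                            body = c(CpG = 0.8, CHG = 0.8, CHH = 0.8)))
  res <- simulate_ncats(cfg)
  calls <- with(res$simcalls$calls, data.frame(
    read_id = read_id, reference_id = chrom, ref_pos = pos,
    ref_strand = strand, prob_meth = prob_meth, context = kmer,
    called_label = label, stringsAsFactors = FALSE))
  locus <- target_locus("L", list(reference_id = "refA",
                                  start = cfg$locus_start,
                                  end = cfg$locus_start + cfg$locus_length))
  prof <- site_frequency(build_matrix(calls, locus))
  prof <- prof[prof$coverage >= 40, ]
  # per-site binomial noise at depth 50 keeps 95%+ of sites within 0.15,
  # and the region mean estimates the truth to within ~2 binomial SEs
  expect_gte(mean(abs(prof$frequency - 0.8) <= 0.15), 0.95)
  expect_lt(abs(mean(prof$frequency) - 0.8), 0.02)
})
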