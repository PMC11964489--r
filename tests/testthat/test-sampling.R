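test_that("a perfect read yields one candidate event per k-mer window", {
  m <- random_kmer_model(5, seed = 3)
  set.seed(21)
  seq <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
               collapse = "")
  pr <- perfect_read(seq, m)
  ev <- events_for_read(pr$rec, pr$aln, sampling_config(k = 5))
  expect_equal(nrow(ev), nchar(seq) - 5 + 1)
  expect_true(all(ev$duration == 30L))
  expect_true(all(ev$pass))
  # labels are the sliding windows in order
  wins <- substring(seq, 1:(nchar(seq) - 4), 5:nchar(seq))
  expect_equal(ev$kmer, wins)
})

test_that("move_offset shifts labels relative to events by whole bases", {
  m <- random_kmer_model(5, seed = 3)
  set.seed(22)
  seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  pr <- perfect_read(seq, m)
  ev0 <- events_for_read(pr$rec, pr$aln, sampling_config(k = 5))
  ev2 <- events_for_read(pr$rec, pr$aln,
                         sampling_config(k = 5, move_offset = 2L))
  expect_equal(nrow(ev2), nrow(ev0))
  # event (segment) i of the offset run equals event i+2 of the baseline
  # (the last two anchors fall beyond the baseline's window range), while
  # labels stay the window sequence
  n2 <- nrow(ev2)
  expect_equal(ev2$mean[1:(n2 - 2L)], ev0$mean[3:n2])
  wins <- substring(seq, 1:(nchar(seq) - 4), 5:nchar(seq))
  expect_equal(ev2$kmer, wins)
})

test_that("reads shorter than k yield no events", {
  m <- random_kmer_model(5, seed = 3)
  pr <- perfect_read("ACG", random_kmer_model(3, seed = 3))
  ev <- events_for_read(pr$rec, pr$aln, sampling_config(k = 5))
  expect_equal(nrow(ev), 0L)
})

test_that("dwell filter bounds are strict, matching the sampling rule", {
  cfg <- sampling_config(k = 5, min_dur = 20L, max_dur = 40L)
  expect_false(passes_filters(20L, 0, cfg))
  expect_false(passes_filters(40L, 0, cfg))
  expect_true(passes_filters(30L, 0, cfg))
  # exhaustive sweep: accepted set is exactly 21..39
  durs <- 1:60
  expect_equal(durs[passes_filters(durs, rep(0, 60), cfg)], 21:39)
  # inclusive variant widens by one on each side
  cfg_inc <- sampling_config(k = 5, inclusive_dur = TRUE)
  expect_equal(durs[passes_filters(durs, rep(0, 60), cfg_inc)], 20:40)
})

test_that("stddev filter drops unstable events when enabled", {
  cfg_off <- sampling_config(k = 5)
  cfg_on <- sampling_config(k = 5, max_event_stddev = 0.5)
  expect_true(passes_filters(30L, 9.9, cfg_off))
  expect_false(passes_filters(30L, 0.6, cfg_on))
  expect_true(passes_filters(30L, 0.4, cfg_on))
})

test_that("events overlapping indel neighborhoods are dropped", {
  m <- random_kmer_model(3, seed = 3)
  set.seed(23)
  seq <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
               collapse = "")
  pr <- perfect_read(seq, m, dwell = 30L)
  # corrupt: delete base 10 (its samples become an insertion)
  ops <- pr$aln$ops
  ops$kind[11] <- "DELETION"
  ops$length[11] <- 1L
  ops <- rbind(ops[1:11, ], data.frame(kind = "INSERTION", length = 30L),
               ops[12:nrow(ops), ])
  aln <- ss_alignment(ss_ops(ops$kind, ops$length))
  ev <- events_for_read(pr$rec, aln, sampling_config(k = 3, indel_skip = 2L))
  # excluded bases are 8..12 (deletion at 10 +/- 2), so windows 6..12 are
  # dropped: window w covers bases w..w+2
  wins <- substring(seq, 1:(nchar(seq) - 2), 3:nchar(seq))
  kept <- setdiff(0:(nchar(seq) - 3), 6:12)
  expect_equal(ev$kmer, wins[kept + 1L])
  # with skip 0 only windows touching the deleted base itself vanish
  ev0 <- events_for_read(pr$rec, aln, sampling_config(k = 3, indel_skip = 0L))
  kept0 <- setdiff(0:(nchar(seq) - 3), 8:10)
  expect_equal(ev0$kmer, wins[kept0 + 1L])
})

test_that("accumulator caps stored samples per k-mer in stream order", {
  ev <- data.table::data.table(
    read_id = "r", kmer = "AAAAA", mean = as.numeric(1:6000),
    stddev = 0.1, duration = 30L, pass = TRUE
  )
  acc <- accumulate_events(ev, sampling_config(k = 5, num_samples = 5000L))
  expect_equal(nrow(acc$samples), 5000L)
  expect_equal(acc$samples$mean, as.numeric(1:5000))
  expect_equal(unname(acc$counts["AAAAA"]), 6000L)
})

test_that("strict counter mode counts rejected observations against the cap", {
  # 10 observations, first 4 fail filters; cap 6
  ev <- data.table::data.table(
    read_id = "r", kmer = "AA", mean = as.numeric(1:10),
    stddev = 0.1, duration = c(rep(50L, 4), rep(30L, 6)), pass = FALSE
  )
  ev[, pass := passes_filters(duration, stddev, sampling_config(k = 2))]
  cfg_stored <- sampling_config(k = 2, num_samples = 6L)
  cfg_strict <- sampling_config(k = 2, num_samples = 6L,
                                strict_counter = TRUE)
  expect_equal(nrow(accumulate_events(ev, cfg_stored)$samples), 6L)
  # strict: only observations 5 and 6 are both passing and under the cap
  expect_equal(accumulate_events(ev, cfg_strict)$samples$mean, c(5, 6))
})

test_that("per-k-mer tallies match brute force on an interleaved stream", {
  set.seed(9)
  ev <- data.table::data.table(
    read_id = "r",
    kmer = sample(c("ACGTA", "TTTTT"), 500, replace = TRUE),
    mean = rnorm(500), stddev = 0.1, duration = 30L, pass = TRUE
  )
  cfg <- sampling_config(k = 5, num_samples = 100L)
  acc <- accumulate_events(ev, cfg)
  for (km in c("ACGTA", "TTTTT")) {
    expect_equal(unname(acc$counts[km]), sum(ev$kmer == km))
    expect_equal(acc$samples[kmer == km, mean],
                 head(ev[kmer == km, mean], 100L))
  }
  # invariant: nothing stored violates the filters; total under global cap
  expect_true(all(passes_filters(acc$samples$duration, acc$samples$stddev,
                                 cfg)))
  expect_lte(nrow(acc$samples), 4^5 * 100L)
})

test_that("completeness report counts k-mers by stored depth", {
  ev <- data.table::data.table(
    read_id = "r",
    kmer = rep(c("AA", "AC", "AG"), times = c(150, 80, 1)),
    mean = 0, stddev = 0.1, duration = 30L, pass = TRUE
  )
  acc <- accumulate_events(ev, sampling_config(k = 2, num_samples = 5000L))
  rep <- completeness_report(acc, depths = c(1L, 100L))
  expect_equal(rep$n_kmers, c(3L, 1L))
  expect_equal(rep$fraction, c(3, 1) / 16)

  empty <- accumulate_events(
    data.table::data.table(read_id = character(), kmer = character(),
                           mean = numeric(), stddev = numeric(),
                           duration = integer(), pass = logical()),
    sampling_config(k = 2))
  expect_equal(completeness_report(empty, depths = 1L)$n_kmers, 0L)
})

test_that("rna mode reverses traversal but keeps 5'->3' labels", {
  m <- random_kmer_model(3, seed = 3)
  set.seed(24)
  seq <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
  n <- nchar(seq)
  # simulate in rna mode: traversal is the reversed sequence
  sim <- simulate_dataset(sim_config(m, coverage = "random", n_reads = 1,
                                     read_length = n, rna_mode = TRUE,
                                     seed = 4))
  rec <- sim$reads[[1]]; aln <- sim$alignments[[1]]
  ev <- events_for_read(rec, aln, sampling_config(k = 3, rna_mode = TRUE))
  rseq <- rec$sequence
  wins <- substring(rseq, 1:(nchar(rseq) - 2), 3:nchar(rseq))
  # every label is a genuine 5'->3' window of the read
  expect_true(all(ev$kmer %in% wins))
  # label multiset equals the reversed-traversal expectation: all windows
  expect_equal(sort(ev$kmer), sort(wins))
  # event means recover the model levels (noise is small at dwell ~30)
  err <- ev$mean - unname(
    (m$levels[ev$kmer] * 20 + 100 -
       median(raw_to_pa(rec))) / mad(raw_to_pa(rec), constant = 1))
  expect_lt(max(abs(err)), 0.2)
})

test_that("sample_events skips inconsistent reads and counts them", {
  m <- random_kmer_model(3, seed = 3)
  pr <- perfect_read(paste(rep("ACGT", 10), collapse = ""), m)
  good <- pr$rec
  # alignment that overruns the signal
  bad_aln <- ss_alignment(ss_ops(rep("MATCH", 40), rep(1000L, 40)))
  reads <- list(good = good)
  reads$good$read_id <- "good"
  acc1 <- sample_events(list(good = reads$good),
                        list(good = pr$aln), sampling_config(k = 3))
  expect_gt(nrow(acc1$samples), 0)
  acc2 <- sample_events(list(good = reads$good),
                        list(good = bad_aln), sampling_config(k = 3))
  expect_equal(nrow(acc2$samples), 0L)
  expect_equal(unname(acc2$skipped["inconsistent"]), 1L)
  acc3 <- sample_events(list(good = reads$good), list(),
                        sampling_config(k = 3))
  expect_equal(unname(acc3$skipped["no_alignment"]), 1L)
})
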