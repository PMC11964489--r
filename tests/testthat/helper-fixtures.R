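# Shared fixture builders. Everything is generated in code; no data files.

# independent cursor simulator for ss expansion: walks the ops one unit at
# a time, used as the oracle for ss_to_segments
oracle_expand_ss <- function(ops, signal_start = 0L, seq_start = 0L) {
  sig <- signal_start
  base <- seq_start
  rows <- list()
  for (i in seq_len(nrow(ops))) {
    kind <- ops$kind[i]
    len <- ops$length[i]
    if (kind == "MATCH") {
      rows[[length(rows) + 1L]] <- data.frame(base = base, start = sig,
                                              end = sig + len)
      sig <- sig + len
      base <- base + 1L
    } else if (kind == "DELETION") {
      base <- base + len
    } else {
      sig <- sig + len
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(base = integer(), start = integer(), end = integer())
}

# random valid op list for round-trip fuzzing
random_ops <- function(n) {
  kinds <- sample(c("MATCH", "DELETION", "INSERTION"), n, replace = TRUE,
                  prob = c(0.7, 0.15, 0.15))
  poremodel::ss_ops(kinds, sample(1:50, n, replace = TRUE))
}

# a tiny perfect read: every base one MATCH run of constant dwell, signal
# generated from a supplied k-mer model with zero noise
perfect_read <- function(seq, model, dwell = 30L, pa_mean = 100, pa_sd = 20,
                         digitisation = 4096, range_pA = 600) {
  k <- model$k
  n <- nchar(seq)
  win <- pmin(0:(n - 1L), n - k)
  kmers <- substring(seq, win + 1L, win + k)
  z <- rep(unname(model$levels[kmers]), each = dwell)
  pa <- z * pa_sd + pa_mean
  raw <- pa * digitisation / range_pA
  list(
    rec = poremodel::read_record("perfect", raw, digitisation, range_pA,
                                 offset = 0, sampling_rate = 4000,
                                 sequence = seq),
    aln = poremodel::ss_alignment(poremodel::ss_ops(rep("MATCH", n),
                                                    rep(dwell, n)))
  )
}

# small complete model with distinct levels, handy for io round-trips
toy_model <- function(k = 2, seed = 99) {
  poremodel::random_kmer_model(k, seed = seed)
}
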