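## Signal simulator: reads, raw current traces and exact ground-truth ss
## alignments generated from a known k-mer model, so sampling, model
## building, significance detection and the F1 metric can all be exercised
## with no external data.

#' De Bruijn sequence over the DNA alphabet
#'
#' Returns a linear sequence whose sliding k-mer windows cover every one of
#' the `4^k` k-mers exactly once (a cyclic de Bruijn sequence of order `k`,
#' linearized by appending its first `k - 1` characters). Used by the
#' simulator to reach a target per-k-mer depth with the minimum number of
#' bases.
#'
#' By default the classic lexicographic (Lyndon-word) sequence is
#' returned. That sequence is globally balanced but locally skewed (it
#' opens A-rich and closes T-rich), which interacts badly with per-read
#' median/MAD normalization when it is chunked into reads; passing a
#' `seed` instead draws a uniformly shuffled sequence via a random Euler
#' tour of the de Bruijn graph, whose windows of a few kilobases are
#' composition-balanced like real reads.
#'
#' @param k window length.
#' @param alphabet ordered base set.
#' @param seed `NULL` for the lexicographic sequence; an integer for a
#'   seeded random Euler-tour sequence.
#' @return character scalar of length `4^k + k - 1`.
#' @export
de_bruijn_sequence <- function(k, alphabet = MODEL_ALPHABET, seed = NULL) {
  stopifnot(k >= 1L)
  if (!is.null(seed)) return(de_bruijn_random(k, alphabet, seed))
  n <- length(alphabet)
  a <- integer(k + 1L)                 # 1-based scratch, classic recursion
  seq_idx <- integer(0)
  env <- environment()
  db <- function(t, p) {
    if (t > k) {
      if (k %% p == 0L) {
        env$seq_idx <- c(env$seq_idx, env$a[2:(p + 1L)])
      }
    } else {
      env$a[t + 1L] <- env$a[t - p + 1L]
      db(t + 1L, p)
      j0 <- env$a[t - p + 1L] + 1L
      if (j0 <= n - 1L) {
        for (j in j0:(n - 1L)) {
          env$a[t + 1L] <- j
          db(t + 1L, t)
        }
      }
    }
  }
  db(1L, 1L)
  cyc <- paste(alphabet[seq_idx + 1L], collapse = "")
  paste0(cyc, substr(cyc, 1L, k - 1L))
}

## random de Bruijn sequence: Euler tour with shuffled edge order over the
## graph whose nodes are (k-1)-mers and whose edges append one base
de_bruijn_random <- function(k, alphabet = MODEL_ALPHABET, seed = 1L) {
  n <- length(alphabet)
  old_seed <- globalenv()$.Random.seed
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  if (k == 1L) return(paste(sample(alphabet), collapse = ""))
  n_nodes <- as.integer(n^(k - 1L))
  n_edges <- n_nodes * n
  ## per-node random order over outgoing bases (column = node)
  ord <- apply(matrix(runif(n * n_nodes), nrow = n), 2L, order) - 1L
  dim(ord) <- c(n, n_nodes)
  next_edge <- rep(1L, n_nodes)
  stack <- integer(n_edges + 1L)
  stack[1L] <- 0L
  top <- 1L
  path <- integer(n_edges + 1L)
  np <- 0L
  while (top > 0L) {
    u <- stack[top]
    if (next_edge[u + 1L] <= n) {
      b <- ord[next_edge[u + 1L], u + 1L]
      next_edge[u + 1L] <- next_edge[u + 1L] + 1L
      v <- (u * n + b) %% n_nodes
      top <- top + 1L
      stack[top] <- v
    } else {
      np <- np + 1L
      path[np] <- u
      top <- top - 1L
    }
  }
  nodes <- rev(path[seq_len(np)])      # Euler circuit: n_edges + 1 nodes
  ## each edge contributes the last char of its target node; the cyclic
  ## windows of that string are exactly the k-mers of the tour's edges
  cyc <- paste(alphabet[nodes[-1L] %% n + 1L], collapse = "")
  paste0(cyc, substr(cyc, 1L, k - 1L))
}

#' Synthetic truth models
#'
#' `positional_kmer_model()` builds a model whose level is an additive
#' function of the bases at chosen positions: `level = sum_i weights[i] *
#' effect(base_i) + noise`. Positions with zero weight carry no signal and
#' are not significant; positions with weight well above the noise are.
#' `random_kmer_model()` draws independent levels, giving a model where
#' every position discriminates.
#'
#' @param k k-mer length.
#' @param weights numeric length-`k` vector of per-position weights
#'   (0 = position has no influence).
#' @param base_effects named numeric vector over A,C,G,T (default centred,
#'   unit-spaced).
#' @param level_noise_sd standard deviation of the i.i.d. noise added to
#'   each k-mer's level.
#' @param event_sd per-k-mer within-event spread stored in the model's
#'   stddev column (recycled).
#' @param seed RNG seed.
#' @return complete `kmer_model` in normalized space.
#' @export
positional_kmer_model <- function(k, weights,
                                  base_effects = c(A = -1.5, C = -0.5,
                                                   G = 0.5, T = 1.5),
                                  level_noise_sd = 0, event_sd = 0.25,
                                  seed = 1L) {
  stopifnot(length(weights) == k)
  kmers <- all_kmers(k)
  mat <- matrix(base_effects[unlist(strsplit(kmers, ""), use.names = FALSE)],
                ncol = k, byrow = TRUE)
  levels <- as.numeric(mat %*% weights)
  if (level_noise_sd > 0) {
    old <- globalenv()$.Random.seed
    set.seed(seed)
    levels <- levels + rnorm(length(levels), 0, level_noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  kmer_model(stats::setNames(levels, kmers),
             stats::setNames(rep_len(event_sd, length(kmers)), kmers),
             space = "normalized")
}

#' @rdname positional_kmer_model
#' @param level_sd spread of the independent levels.
#' @export
random_kmer_model <- function(k, level_sd = 1, event_sd = 0.25, seed = 1L) {
  kmers <- all_kmers(k)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  levels <- rnorm(length(kmers), 0, level_sd)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  kmer_model(stats::setNames(levels, kmers),
             stats::setNames(rep_len(event_sd, length(kmers)), kmers),
             space = "normalized")
}

#' Simulation configuration
#'
#' @param truth_model complete `kmer_model` in normalized space; its levels
#'   set the per-event mean and its stddev column the per-sample Gaussian
#'   noise (0.25 normalized units when absent).
#' @param coverage `"random"` (uniform random sequences of `n_reads` x
#'   `read_length`) or `"debruijn"` (chunked de Bruijn cycles so every
#'   k-mer is observed `depth` times with minimal bases).
#' @param n_reads number of reads (`"random"` mode, default 10). In
#'   `"debruijn"` mode an optional read budget: when set, simulation stops
#'   with an error (stating the required read count) if the depth target
#'   cannot be met within it.
#' @param read_length bases per read.
#' @param depth target observations per k-mer (`"debruijn"` mode).
#' @param dwell_mean,dwell_sd,dwell_min,dwell_max integer truncated-normal
#'   dwell distribution in samples per base (defaults 30, 5, 20, 40: ~30
#'   samples/base as for RNA004 at 130 bases/s and 4 kHz, bounded by the
#'   default sampler filter window).
#' @param rna_mode simulate 3'->5' signal order (direct RNA).
#' @param pa_mean,pa_sd global current mean/spread in pA used to place the
#'   normalized levels on the pA scale.
#' @param digitisation,range_pA,offset,sampling_rate ADC calibration
#'   written into each read record (defaults mirror a PromethION RNA004
#'   flow cell: 2048 levels over 299.43 pA at 4 kHz).
#' @param seed RNG seed; a given seed reproduces the dataset bit-exactly.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(truth_model, coverage = c("random", "debruijn"),
                       n_reads = NULL, read_length = 2000L, depth = 1L,
                       dwell_mean = 30, dwell_sd = 5,
                       dwell_min = 20L, dwell_max = 40L,
                       rna_mode = FALSE, pa_mean = 100, pa_sd = 20,
                       digitisation = 2048, range_pA = 299.432068,
                       offset = 0, sampling_rate = 4000, seed = 1L) {
  coverage <- match.arg(coverage)
  stopifnot(inherits(truth_model, "kmer_model"),
            truth_model$space == "normalized",
            read_length >= truth_model$k, depth >= 1L,
            dwell_min <= dwell_mean, dwell_mean <= dwell_max, pa_sd > 0)
  if (model_completeness(truth_model) < 1) {
    stop("truth model must be complete (all 4^k k-mers)")
  }
  structure(
    list(truth_model = truth_model, coverage = coverage,
         n_reads = if (!is.null(n_reads)) as.integer(n_reads),
         read_length = as.integer(read_length), depth = as.integer(depth),
         dwell_mean = dwell_mean, dwell_sd = dwell_sd,
         dwell_min = as.integer(dwell_min), dwell_max = as.integer(dwell_max),
         rna_mode = isTRUE(rna_mode), pa_mean = pa_mean, pa_sd = pa_sd,
         digitisation = digitisation, range_pA = range_pA, offset = offset,
         sampling_rate = sampling_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

## integer truncated-normal dwell times via inverse-CDF sampling
sample_dwells <- function(n, cfg) {
  lo <- pnorm(cfg$dwell_min, cfg$dwell_mean, cfg$dwell_sd)
  hi <- pnorm(cfg$dwell_max, cfg$dwell_mean, cfg$dwell_sd)
  as.integer(round(qnorm(runif(n, lo, hi), cfg$dwell_mean, cfg$dwell_sd)))
}

## split a long template into reads of read_length overlapping by k-1 so
## no k-mer window is lost at a boundary
chunk_template <- function(template, read_length, k) {
  n <- nchar(template)
  step <- read_length - (k - 1L)
  starts <- seq(1L, max(1L, n - k + 1L), by = step)
  vapply(starts, function(s) substr(template, s, min(n, s + read_length - 1L)),
         "")
}

#' Simulate a read set from a truth model
#'
#' Each base of each read emits a truncated-normal number of signal samples
#' drawn from `Normal(level(kmer), stddev(kmer))` in normalized units,
#' where the k-mer is the window anchored at that base (signal order; for
#' RNA the traversal runs 3'->5'). Normalized samples are placed on the pA
#' scale with the configured global mean/spread and quantized to ADC counts
#' with the configured calibration, so the forward pipeline (pA conversion,
#' median/MAD normalization) sees realistic input. The emitted ss string
#' reconstructs the segmentation exactly.
#'
#' @param cfg `sim_config`.
#' @return list with `reads` (named list of `read_record`, sequences
#'   included), `alignments` (named list of `ss_alignment`, exact ground
#'   truth), `truth_model`, and `globals` (the `scaling_params` used to
#'   place levels on the pA scale).
#' @export
simulate_dataset <- function(cfg) {
  old_seed <- globalenv()$.Random.seed
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)

  model <- cfg$truth_model
  k <- model$k
  sds <- if (is.null(model$stddev))
    stats::setNames(rep(0.25, length(model$levels)), names(model$levels))
  else model$stddev

  if (cfg$coverage == "debruijn") {
    ## random Euler-tour sequence: locally composition-balanced, so
    ## per-read median/MAD normalization is stable across chunked reads
    cycle <- de_bruijn_sequence(k, seed = cfg$seed)
    core <- substr(cycle, 1L, n_kmers(k))         # cyclic part
    template <- paste0(strrep(core, cfg$depth), substr(cycle, 1L, k - 1L))
    seqs <- chunk_template(template, cfg$read_length, k)
    if (!is.null(cfg$n_reads) && length(seqs) > cfg$n_reads) {
      stop(sprintf(
        "depth %d needs %d reads of length %d (budget %d); raise n_reads or read_length",
        cfg$depth, length(seqs), cfg$read_length, cfg$n_reads))
    }
  } else {
    if (is.null(cfg$n_reads)) cfg$n_reads <- 10L
    seqs <- vapply(seq_len(cfg$n_reads), function(i) {
      paste(sample(MODEL_ALPHABET, cfg$read_length, replace = TRUE),
            collapse = "")
    }, "")
  }

  reads <- vector("list", length(seqs))
  alns <- vector("list", length(seqs))
  ids <- sprintf("sim_read_%04d", seq_along(seqs))
  for (i in seq_along(seqs)) {
    seq <- seqs[i]
    n <- nchar(seq)
    trav <- if (cfg$rna_mode)
      paste(rev(strsplit(seq, "")[[1L]]), collapse = "") else seq
    win_start <- pmin(0:(n - 1L), n - k)          # window per traversal base
    wins <- substring(trav, win_start + 1L, win_start + k)
    if (cfg$rna_mode) {
      wins <- vapply(strsplit(wins, ""),
                     function(ch) paste(rev(ch), collapse = ""), "")
    }
    dwell <- sample_dwells(n, cfg)
    mu <- rep(unname(model$levels[wins]), dwell)
    sdv <- rep(unname(sds[wins]), dwell)
    z <- rnorm(length(mu), mu, sdv)
    pa <- z * cfg$pa_sd + cfg$pa_mean
    raw <- round(pa * cfg$digitisation / cfg$range_pA - cfg$offset)
    reads[[i]] <- read_record(
      read_id = ids[i], raw = raw, digitisation = cfg$digitisation,
      range_pA = cfg$range_pA, offset = cfg$offset,
      sampling_rate = cfg$sampling_rate, sequence = seq
    )
    alns[[i]] <- ss_alignment(ss_ops(rep("MATCH", n), dwell))
  }
  names(reads) <- ids
  names(alns) <- ids
  list(reads = reads, alignments = alns, truth_model = model,
       globals = scaling_params(cfg$pa_mean, cfg$pa_sd))
}

#' Write a simulated dataset to fixture files
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if missing); writes `signals.tsv`
#'   (TSV signal container), `reads.fasta`, and `alignments.paf` with ss
#'   tags.
#' @return named character vector of the three paths.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- file.path(dir, "signals.tsv")
  fa <- file.path(dir, "reads.fasta")
  paf <- file.path(dir, "alignments.paf")
  write_signal_tsv(sim$reads, sig)
  seqs <- vapply(sim$reads, `[[`, "", "sequence")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, names(sim$reads))), fa)
  write_paf_ss(sim$alignments,
               signal_lens = vapply(sim$reads, function(r) length(r$raw), 0),
               seq_lens = nchar(seqs), path = paf)
  c(signals = sig, fasta = fa, paf = paf)
}

#' Corrupt a ground-truth alignment
#'
#' Introduces indel operations and boundary jitter into a pure-match
#' alignment so indel masking and sub-perfect F1 paths can be exercised.
#' Signal consumption is preserved: a deleted base's samples become an
#' insertion run, and an inserted run is split off the tail of a match.
#'
#' @param aln `ss_alignment` of MATCH ops only.
#' @param ins_rate per-base probability of splitting off an insertion.
#' @param del_rate per-base probability of deleting the base.
#' @param jitter max samples moved across each match-match boundary.
#' @param seed RNG seed.
#' @return corrupted `ss_alignment`.
#' @export
corrupt_alignment <- function(aln, ins_rate = 0, del_rate = 0, jitter = 0L,
                              seed = 1L) {
  stopifnot(all(aln$ops$kind == "MATCH"))
  old_seed <- globalenv()$.Random.seed
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  lens <- aln$ops$length
  n <- length(lens)
  if (jitter > 0L && n > 1L) {
    for (i in seq_len(n - 1L)) {
      d <- sample(seq(-jitter, jitter), 1L)
      d <- max(min(d, lens[i + 1L] - 1L), -(lens[i] - 1L))
      lens[i] <- lens[i] + d
      lens[i + 1L] <- lens[i + 1L] - d
    }
  }
  kinds <- character(); out_lens <- integer()
  for (i in seq_len(n)) {
    u <- runif(1)
    if (u < del_rate) {
      kinds <- c(kinds, "DELETION", "INSERTION")
      out_lens <- c(out_lens, 1L, lens[i])
    } else if (u < del_rate + ins_rate && lens[i] > 1L) {
      split <- sample(seq_len(lens[i] - 1L), 1L)
      kinds <- c(kinds, "MATCH", "INSERTION")
      out_lens <- c(out_lens, lens[i] - split, split)
    } else {
      kinds <- c(kinds, "MATCH")
      out_lens <- c(out_lens, lens[i])
    }
  }
  ss_alignment(ss_ops(kinds, out_lens), signal_start = aln$signal_start,
               seq_start = aln$seq_start,
               seq_is_reference = aln$seq_is_reference)
}
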