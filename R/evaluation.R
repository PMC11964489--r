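## Model and alignment evaluation: Pearson correlation between models and
## a tolerance-based F1 over one-to-one signal-point-to-base mappings.

#' Signal-point mapping from an ss alignment
#'
#' Expands an alignment into a per-sample map: MATCH samples map to their
#' base, INSERTION samples and samples outside the alignment are unmapped.
#'
#' @param aln `ss_alignment`.
#' @param signal_len total signal samples.
#' @return integer vector of length `signal_len`: 0-based base index per
#'   sample, `NA` where unmapped.
#' @export
mapping_from_ss <- function(aln, signal_len) {
  seg <- ss_to_segments(aln, signal_len = signal_len, seq_len = Inf)
  map <- rep(NA_integer_, signal_len)
  if (nrow(seg)) {
    lens <- seg$end - seg$start
    idx <- sequence(lens) - 1L + rep(seg$start, lens)   # 0-based samples
    map[idx + 1L] <- rep(seg$base, lens)
  }
  map
}

#' Tolerance-based F1 of a signal-point mapping against ground truth
#'
#' Classifies every signal point: both mapped with base distance within
#' `tolerance` is a true positive; query mapped where truth is unmapped, or
#' mapped beyond tolerance, a false positive; truth mapped but query
#' unmapped, a false negative; both unmapped, a true negative. Precision,
#' recall and F1 follow; F1 is 0 when precision + recall is 0.
#'
#' @param query,truth integer mappings as from [mapping_from_ss()] (`NA` =
#'   unmapped), equal length.
#' @param tolerance allowed base distance for a true positive (default 1:
#'   a signal point mapped one base left or right of the correct base still
#'   counts).
#' @return object of class `f1_result`: counts `tp`, `fp`, `fn`, `tn` and
#'   `precision`, `recall`, `f1`.
#' @export
f1_score <- function(query, truth, tolerance = 1L) {
  if (length(query) != length(truth)) {
    stop("query and truth mappings differ in length (",
         length(query), " vs ", length(truth), ")")
  }
  qm <- !is.na(query); tm <- !is.na(truth)
  close_enough <- qm & tm & abs(query - truth) <= tolerance
  tp <- sum(close_enough)
  fp <- sum(qm) - tp
  fn <- sum(!qm & tm)
  tn <- sum(!qm & !tm)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall, f1 = f1),
            class = "f1_result")
}

#' @export
print.f1_result <- function(x, ...) {
  cat(sprintf("<f1_result> TP=%d FP=%d FN=%d TN=%d  P=%.4f R=%.4f F1=%.4f\n",
              x$tp, x$fp, x$fn, x$tn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Pooled and per-read F1 over aligned read sets
#'
#' @param query_alns,truth_alns named lists of `ss_alignment` sharing ids.
#' @param signal_lens named integer vector of per-read signal lengths.
#' @param tolerance base tolerance, as in [f1_score()].
#' @return list with `pooled` (`f1_result` over the concatenated points,
#'   the micro-average) and `per_read` (data.frame of per-read scores).
#' @export
f1_over_reads <- function(query_alns, truth_alns, signal_lens, tolerance = 1L) {
  ids <- intersect(names(query_alns), names(truth_alns))
  if (length(ids) == 0L) stop("no shared read ids between query and truth")
  q_all <- integer(); t_all <- integer()
  per <- lapply(ids, function(id) {
    q <- mapping_from_ss(query_alns[[id]], signal_lens[[id]])
    t <- mapping_from_ss(truth_alns[[id]], signal_lens[[id]])
    q_all <<- c(q_all, q); t_all <<- c(t_all, t)
    r <- f1_score(q, t, tolerance)
    data.frame(read_id = id, tp = r$tp, fp = r$fp, fn = r$fn, tn = r$tn,
               precision = r$precision, recall = r$recall, f1 = r$f1)
  })
  list(pooled = f1_score(q_all, t_all, tolerance),
       per_read = do.call(rbind, per))
}

#' Pearson correlation between two k-mer models
#'
#' Computed over the intersection of k-mer keys; models must share `k`
#' (collapse the larger one first, see [collapse_model()]). Affine
#' transforms of either model (e.g. the pA transform) leave the value
#' unchanged.
#'
#' @param a,b `kmer_model` of equal `k`.
#' @return list with `pearson` and `n_shared`.
#' @export
model_correlation <- function(a, b) {
  if (a$k != b$k) {
    stop("models have different k (", a$k, " vs ", b$k,
         "); collapse the larger model first")
  }
  shared <- intersect(names(a$levels), names(b$levels))
  if (length(shared) < 3L) stop("fewer than 3 shared k-mers")
  list(pearson = cor(a$levels[shared], b$levels[shared]),
       n_shared = length(shared))
}

#' Model quality as a function of sampling depth
#'
#' Repeats the simulate-and-rebuild pipeline at increasing per-k-mer
#' stored-sample depths and reports, per depth, the Pearson correlation of
#' the rebuilt model against the truth and the k-mer coverage. Correlation
#' rises with depth and saturates once each k-mer has on the order of a
#' hundred stored samples.
#'
#' @param truth_model complete `kmer_model` (normalized space) to simulate
#'   from and compare against.
#' @param depths integer vector of target stored samples per k-mer.
#' @param cfg `sampling_config` for the rebuild.
#' @param read_length,seed passed to [simulate_dataset()].
#' @return data.frame: `depth`, `pearson`, `n_kmers_covered`,
#'   `min_stored`, `median_stored`.
#' @export
depth_sweep <- function(truth_model, depths, cfg = sampling_config(k = truth_model$k),
                        read_length = 4000L, seed = 1L) {
  rows <- lapply(seq_along(depths), function(i) {
    d <- depths[i]
    sim <- simulate_dataset(sim_config(
      truth_model = truth_model, coverage = "debruijn", depth = d,
      read_length = read_length, rna_mode = cfg$rna_mode,
      seed = seed + i - 1L))
    built <- build_kmer_model(sim$reads, sim$alignments, cfg)
    per_kmer <- built$accumulator$samples[, .N, by = kmer]
    data.frame(
      depth = d,
      pearson = model_correlation(built$model, truth_model)$pearson,
      n_kmers_covered = nrow(per_kmer),
      min_stored = min(per_kmer$N),
      median_stored = median(per_kmer$N)
    )
  })
  do.call(rbind, rows)
}
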