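## Event sampling: walk each read's ss alignment, cut the normalized signal
## into one event per k-mer window (the window's anchor base's segment),
## filter by dwell time / stability / indel neighborhood, and accumulate up
## to a cap of stored samples per k-mer.

#' Event-sampling configuration
#'
#' @param k k-mer length.
#' @param num_samples cap on samples collected per k-mer (default 5000).
#' @param move_offset whole-base shift between each event and the k-mer
#'   window it is labelled with; aligns the segment register to the model's
#'   significant-base register.
#' @param min_dur,max_dur dwell-time bounds in samples; events pass when
#'   `min_dur < duration < max_dur` (strict; set `inclusive_dur = TRUE` for
#'   closed bounds).
#' @param max_event_stddev drop events whose within-event standard
#'   deviation (normalized units) exceeds this; `NULL` disables the filter.
#' @param indel_skip bases excluded on each side of an alignment indel
#'   (default 2); events whose k-mer window overlaps an excluded base are
#'   dropped.
#' @param rna_mode `TRUE` for direct RNA: the signal runs 3'->5', so base
#'   traversal is reversed to match signal order; emitted k-mer strings stay
#'   written 5'->3'.
#' @param scaling `"med-mad"` (per-read median/MAD normalization of the pA
#'   signal) or `"none"`.
#' @param inclusive_dur use closed dwell bounds.
#' @param strict_counter count every candidate observation against the cap
#'   (so late qualifying events of a saturated k-mer are skipped even when
#'   earlier ones failed filters) instead of capping stored samples only.
#' @param min_read_length skip reads shorter than this many bases.
#' @return object of class `sampling_config`.
#' @export
sampling_config <- function(k = 5L, num_samples = 5000L, move_offset = 0L,
                            min_dur = 20L, max_dur = 40L,
                            max_event_stddev = NULL, indel_skip = 2L,
                            rna_mode = FALSE, scaling = c("med-mad", "none"),
                            inclusive_dur = FALSE, strict_counter = FALSE,
                            min_read_length = 0L) {
  scaling <- match.arg(scaling)
  stopifnot(k >= 1L, num_samples >= 1L, min_dur < max_dur, indel_skip >= 0L,
            move_offset >= 0L, move_offset < k)
  structure(
    list(k = as.integer(k), num_samples = as.integer(num_samples),
         move_offset = as.integer(move_offset),
         min_dur = as.integer(min_dur), max_dur = as.integer(max_dur),
         max_event_stddev = max_event_stddev,
         indel_skip = as.integer(indel_skip), rna_mode = isTRUE(rna_mode),
         scaling = scaling, inclusive_dur = isTRUE(inclusive_dur),
         strict_counter = isTRUE(strict_counter),
         min_read_length = as.integer(min_read_length)),
    class = "sampling_config"
  )
}

#' Dwell/stability filter for one event
#'
#' @param duration event length in samples.
#' @param stddev within-event standard deviation (normalized units).
#' @param cfg `sampling_config`.
#' @return logical vector (vectorized over events).
#' @export
passes_filters <- function(duration, stddev, cfg) {
  ok <- if (cfg$inclusive_dur) {
    duration >= cfg$min_dur & duration <= cfg$max_dur
  } else {
    duration > cfg$min_dur & duration < cfg$max_dur
  }
  if (!is.null(cfg$max_event_stddev)) {
    ok <- ok & stddev <= cfg$max_event_stddev
  }
  ok
}

## Per-read candidate events as a data.table(kmer, mean, stddev, duration,
## pass). Normalization is applied here; event statistics come from prefix
## sums so cost is linear in signal length.
events_for_read_dt <- function(rec, aln, cfg) {
  seq <- rec$sequence
  if (is.null(seq)) stop("read ", rec$read_id, " has no sequence")
  n <- nchar(seq)
  if (n < cfg$k || n < cfg$min_read_length) return(NULL)

  sig <- raw_to_pa(rec)
  if (cfg$scaling == "med-mad") sig <- med_mad_normalize(sig)

  seg <- ss_to_segments(aln, signal_len = length(sig), seq_len = n)
  ## traversal order: index into the ss alignment's base numbering, which
  ## follows signal order; for RNA that is the reversed sequence
  trav <- if (cfg$rna_mode) paste(rev(strsplit(seq, "")[[1L]]), collapse = "") else seq

  w <- 0:(n - cfg$k)                      # window starts, traversal coords
  anchor <- w + cfg$move_offset
  labels <- substring(trav, w + 1L, w + cfg$k)
  if (cfg$rna_mode) {
    labels <- vapply(strsplit(labels, ""),
                     function(ch) paste(rev(ch), collapse = ""), "")
  }

  seg_of_base <- rep(NA_integer_, n)
  seg_of_base[seg$base + 1L] <- seq_len(nrow(seg))
  si <- seg_of_base[anchor + 1L]
  keep <- !is.na(si)

  if (cfg$indel_skip >= 0L && any(aln$ops$kind != "MATCH")) {
    excl <- mask_indel_neighborhood(aln, cfg$indel_skip)
    excl <- excl[excl >= 0L & excl < n]
    if (length(excl)) {
      bad <- logical(n)
      bad[excl + 1L] <- TRUE
      cum_bad <- c(0L, cumsum(bad))
      ## window w covers traversal bases w .. w+k-1
      overlaps <- (cum_bad[w + cfg$k + 1L] - cum_bad[w + 1L]) > 0L
      keep <- keep & !overlaps
    }
  }
  if (!any(keep)) return(NULL)

  si <- si[keep]
  labels <- labels[keep]
  st <- seg$start[si]; en <- seg$end[si]
  dur <- en - st
  cs <- c(0, cumsum(sig))
  cs2 <- c(0, cumsum(sig^2))
  ev_sum <- cs[en + 1L] - cs[st + 1L]
  ev_sum2 <- cs2[en + 1L] - cs2[st + 1L]
  ev_mean <- ev_sum / dur
  ev_var <- pmax(0, (ev_sum2 - dur * ev_mean^2) / pmax(dur - 1L, 1L))
  ev_sd <- sqrt(ev_var)

  dt <- data.table::data.table(
    read_id = rec$read_id, kmer = labels, mean = ev_mean, stddev = ev_sd,
    duration = as.integer(dur)
  )
  dt[, pass := passes_filters(duration, stddev, cfg)]
  dt[!grepl("N", kmer, fixed = TRUE)]
}

#' Candidate events for one read
#'
#' Enumerates the sliding k-mer windows of the read, pairs each with the
#' signal segment of its anchor base (shifted by `move_offset`), computes
#' event mean / standard deviation / duration on the normalized signal, and
#' flags which events pass the dwell and stability filters. Windows
#' overlapping an indel neighborhood are removed.
#'
#' @param rec `read_record` with a sequence.
#' @param aln `ss_alignment` for the read.
#' @param cfg `sampling_config`.
#' @return data.table with columns `read_id`, `kmer`, `mean`, `stddev`,
#'   `duration`, `pass`; zero rows when the read is shorter than `k`.
#' @export
events_for_read <- function(rec, aln, cfg = sampling_config()) {
  out <- events_for_read_dt(rec, aln, cfg)
  if (is.null(out)) {
    out <- data.table::data.table(
      read_id = character(), kmer = character(), mean = numeric(),
      stddev = numeric(), duration = integer(), pass = logical()
    )
  }
  out[]
}

#' Accumulate events into per-k-mer samples
#'
#' Applies the cap: at most `cfg$num_samples` events stored per k-mer, in
#' stream order. By default the cap counts stored (post-filter) samples;
#' with `cfg$strict_counter` every candidate observation advances the
#' per-k-mer counter and storage stops once the counter reaches the cap.
#'
#' @param events data.table of candidate events (rows from
#'   [events_for_read()], concatenated in stream order).
#' @param cfg `sampling_config`.
#' @return object of class `kmer_accumulator`: stored samples, per-k-mer
#'   observation counts, and the config.
#' @export
accumulate_events <- function(events, cfg = sampling_config()) {
  events <- data.table::as.data.table(events)
  if (nrow(events) == 0L) {
    stored <- data.table::data.table(
      read_id = character(), kmer = character(), mean = numeric(),
      stddev = numeric(), duration = integer(), pass = logical()
    )
    counts <- integer()
  } else {
    counts_dt <- events[, .N, by = kmer]
    counts <- stats::setNames(counts_dt$N, counts_dt$kmer)
    if (cfg$strict_counter) {
      events[, obs_idx := seq_len(.N), by = kmer]
      stored <- events[pass & obs_idx <= cfg$num_samples][, obs_idx := NULL]
    } else {
      stored <- events[pass == TRUE]
      stored[, obs_idx := seq_len(.N), by = kmer]
      stored <- stored[obs_idx <= cfg$num_samples][, obs_idx := NULL]
    }
  }
  structure(list(samples = stored, counts = counts, cfg = cfg),
            class = "kmer_accumulator")
}

#' @export
print.kmer_accumulator <- function(x, ...) {
  cat(sprintf("<kmer_accumulator> k=%d: %d stored samples over %d k-mers\n",
              x$cfg$k, nrow(x$samples),
              data.table::uniqueN(x$samples$kmer)))
  invisible(x)
}

#' Completeness report for an accumulator
#'
#' @param acc `kmer_accumulator`.
#' @param depths stored-sample depths to report coverage at.
#' @return data.frame: for each depth, the number and fraction of the
#'   `4^k` possible k-mers with at least that many stored samples.
#' @export
completeness_report <- function(acc, depths = c(1L, 100L, acc$cfg$num_samples)) {
  per_kmer <- acc$samples[, .N, by = kmer]
  total <- n_kmers(acc$cfg$k)
  data.frame(
    depth = depths,
    n_kmers = vapply(depths, function(d) sum(per_kmer$N >= d), 0L),
    fraction = vapply(depths, function(d) sum(per_kmer$N >= d) / total, 0)
  )
}

#' Sample events across a read set
#'
#' Runs [events_for_read()] per read and [accumulate_events()] over the
#' concatenated stream. Reads whose sequence is missing, shorter than `k`,
#' or inconsistent with their alignment are skipped and counted.
#'
#' @param reads named list of `read_record`.
#' @param alignments named list of `ss_alignment`, keyed like `reads`.
#' @param cfg `sampling_config`.
#' @param verbose print per-filter rejection counts.
#' @return `kmer_accumulator` with an extra `skipped` field (named counts of
#'   skipped reads by reason).
#' @export
sample_events <- function(reads, alignments, cfg = sampling_config(),
                          verbose = FALSE) {
  chunks <- vector("list", length(reads))
  skipped <- c(no_alignment = 0L, too_short = 0L, inconsistent = 0L)
  for (i in seq_along(reads)) {
    rec <- reads[[i]]
    aln <- alignments[[rec$read_id]]
    if (is.null(aln)) { skipped["no_alignment"] <- skipped["no_alignment"] + 1L; next }
    if (is.null(rec$sequence) || nchar(rec$sequence) < max(cfg$k, cfg$min_read_length)) {
      skipped["too_short"] <- skipped["too_short"] + 1L; next
    }
    res <- tryCatch(events_for_read_dt(rec, aln, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      skipped["inconsistent"] <- skipped["inconsistent"] + 1L; next
    }
    chunks[[i]] <- res
  }
  events <- data.table::rbindlist(chunks[!vapply(chunks, is.null, TRUE)])
  acc <- accumulate_events(events, cfg)
  acc$skipped <- skipped
  if (verbose) {
    rej <- if (nrow(events)) sum(!events$pass) else 0L
    message(sprintf("sampled %d events (%d rejected by filters), skipped reads: %s",
                    nrow(acc$samples), rej,
                    paste(names(skipped), skipped, sep = "=", collapse = ", ")))
  }
  acc
}
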