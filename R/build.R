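## From accumulated events to a finished k-mer model.

#' Summarise an accumulator into a k-mer model
#'
#' Per k-mer, the model level is the mean (or median) of the stored event
#' means. The spread column is, by default, the mean of the per-event
#' standard deviations; `spread = "sd_of_means"` instead uses the standard
#' deviation of the event means, and `"mad_of_means"` their raw MAD.
#' K-mers with no stored samples are omitted (never imputed); coverage is
#' visible through [completeness_report()].
#'
#' @param acc `kmer_accumulator`.
#' @param stat central tendency over event means: `"mean"` or `"median"`.
#' @param spread `"mean_event_sd"`, `"sd_of_means"`, or `"mad_of_means"`.
#' @return `kmer_model` in normalized space.
#' @export
summarize_accumulator <- function(acc, stat = c("mean", "median"),
                                  spread = c("mean_event_sd", "sd_of_means",
                                             "mad_of_means")) {
  stat <- match.arg(stat)
  spread <- match.arg(spread)
  s <- acc$samples
  if (nrow(s) == 0L) stop("accumulator holds no samples")
  center_f <- if (stat == "mean") mean else median
  spread_f <- switch(spread,
    mean_event_sd = function(m, sds) mean(sds),
    sd_of_means = function(m, sds) if (length(m) > 1L) sd(m) else 0,
    mad_of_means = function(m, sds) mad(m, constant = 1)
  )
  agg <- s[, .(level = center_f(mean), sdv = spread_f(mean, stddev)),
           by = kmer]
  kmer_model(stats::setNames(agg$level, agg$kmer),
             stats::setNames(agg$sdv, agg$kmer),
             space = "normalized")
}

#' Transform a normalized model to picoamps
#'
#' Applies `pA = normalized_level * global_stddev + global_mean` to every
#' level. The transform is affine, so Pearson correlations between models
#' are unchanged. Spread values are left in normalized units; use
#' [rescale_stddev()] for the heuristic spread column.
#'
#' @param model `kmer_model` in normalized space.
#' @param params `scaling_params` with the dataset's global pA mean and
#'   standard deviation.
#' @return `kmer_model` in pA space.
#' @export
to_pa <- function(model, params) {
  if (model$space != "normalized") stop("model is already in pA space")
  if (is.null(params$global_mean) || is.null(params$global_stddev)) {
    stop("scaling params lack global mean/stddev")
  }
  if (params$global_stddev <= 0) stop("global stddev must be positive")
  kmer_model(model$levels * params$global_stddev + params$global_mean,
             model$stddev, space = "pA")
}

#' Invert the pA transform
#' @inheritParams to_pa
#' @export
from_pa <- function(model, params) {
  if (model$space != "pA") stop("model is not in pA space")
  kmer_model((model$levels - params$global_mean) / params$global_stddev,
             model$stddev, space = "normalized")
}

#' Rescale model spreads onto a heuristic interval
#'
#' Normalized per-k-mer spreads span a broader range than downstream
#' event-aligners expect; this maps them linearly (min-max) onto
#' `[lo, hi]`, preserving their order. All-equal spreads map to the
#' interval midpoint.
#'
#' @param model `kmer_model` with spreads.
#' @param lo,hi target interval (default 2.5 to 4, the range typical pore
#'   models quote in pA).
#' @return `kmer_model` with rescaled spreads.
#' @export
rescale_stddev <- function(model, lo = 2.5, hi = 4.0) {
  if (is.null(model$stddev)) stop("model has no spread column to rescale")
  s <- model$stddev
  rng <- range(s)
  out <- if (rng[1L] == rng[2L]) {
    rep((lo + hi) / 2, length(s))
  } else {
    lo + (s - rng[1L]) / (rng[2L] - rng[1L]) * (hi - lo)
  }
  kmer_model(model$levels, stats::setNames(out, names(s)), space = model$space)
}

#' Build a k-mer model from reads and alignments
#'
#' End-to-end driver: sample events ([sample_events()]), summarise
#' ([summarize_accumulator()]), and optionally transform to pA with globals
#' estimated from the read set ([estimate_globals()]) and rescale spreads.
#'
#' @param reads named list of `read_record`.
#' @param alignments named list of `ss_alignment`.
#' @param cfg `sampling_config`.
#' @param stat,spread passed to [summarize_accumulator()].
#' @param pa transform levels to picoamps.
#' @param rescale_spread apply [rescale_stddev()] to the spread column.
#' @return list with `model` (`kmer_model`), `accumulator`, `globals`
#'   (`scaling_params` or `NULL`), and `completeness` (data.frame).
#' @export
build_kmer_model <- function(reads, alignments, cfg = sampling_config(),
                             stat = "mean", spread = "mean_event_sd",
                             pa = FALSE, rescale_spread = pa) {
  acc <- sample_events(reads, alignments, cfg)
  model <- summarize_accumulator(acc, stat = stat, spread = spread)
  globals <- NULL
  if (pa) {
    globals <- estimate_globals(reads, method = cfg$scaling)
    model <- to_pa(model, globals)
  }
  if (rescale_spread) model <- rescale_stddev(model)
  list(model = model, accumulator = acc, globals = globals,
       completeness = completeness_report(acc))
}
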