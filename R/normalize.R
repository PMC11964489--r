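## Per-read signal normalization and dataset-level scaling parameters.

#' Median/MAD normalize a signal
#'
#' Subtracts the median and divides by the median absolute deviation. The
#' raw MAD is used by default (no Gaussian consistency factor): the factor
#' only rescales an affine space that the later pA transform re-fits anyway.
#'
#' @param x numeric signal (pA), length >= 2.
#' @param consistency if `TRUE`, multiply the MAD by 1.4826 so it estimates
#'   a Gaussian standard deviation.
#' @return normalized numeric vector with median 0 and MAD 1.
#' @export
med_mad_normalize <- function(x, consistency = FALSE) {
  stopifnot(length(x) >= 2L)
  m <- median(x)
  s <- mad(x, center = m, constant = if (consistency) 1.4826 else 1)
  if (s == 0) stop("degenerate signal: MAD is zero")
  (x - m) / s
}

#' Dataset-level scaling parameters
#'
#' Holds the global mean and standard deviation (in pA) used to transform a
#' normalized model back to real-world current values.
#'
#' @param global_mean,global_stddev pooled pA mean and standard deviation.
#' @param method normalization method the model was built under.
#' @return object of class `scaling_params`.
#' @export
scaling_params <- function(global_mean, global_stddev,
                           method = c("med-mad", "none")) {
  method <- match.arg(method)
  stopifnot(is.finite(global_mean), is.finite(global_stddev))
  structure(list(method = method, global_mean = global_mean,
                 global_stddev = global_stddev),
            class = "scaling_params")
}

#' @export
print.scaling_params <- function(x, ...) {
  cat(sprintf("<scaling_params> %s: mean=%.3f pA, stddev=%.3f pA\n",
              x$method, x$global_mean, x$global_stddev))
  invisible(x)
}

#' Estimate global scaling parameters from a read set
#'
#' Pools the pA-converted samples of all reads and takes their mean and
#' standard deviation.
#'
#' @param reads list of `read_record`.
#' @param method recorded normalization method.
#' @return `scaling_params`.
#' @export
estimate_globals <- function(reads, method = "med-mad") {
  if (length(reads) == 0L) stop("cannot estimate globals from an empty read set")
  pooled <- unlist(lapply(reads, raw_to_pa), use.names = FALSE)
  scaling_params(mean(pooled), sd(pooled), method = method)
}
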