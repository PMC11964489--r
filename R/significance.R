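## Which base positions inside a k-mer drive the current level?
##
## For each position, the model's levels are partitioned by the base at
## that position into four "1-mer" level collections. If the four
## collections look alike (high pairwise histogram correlation), the
## position does not discriminate; if they differ, it is significant. A
## large model can then be collapsed onto the contiguous significant
## positions by group-averaging.

#' Partition a model's levels by the base at each position
#'
#' @param model `kmer_model`.
#' @return list of length `k`; element `i` is a list with `base_index`
#'   (0-based) and `levels`, a list mapping each base to the numeric vector
#'   of levels of all k-mers carrying that base at position `i`
#'   (`4^(k-1)` values for a complete model).
#' @export
build_positional_models <- function(model) {
  kmers <- names(model$levels)
  lv <- unname(model$levels)
  lapply(seq_len(model$k), function(i) {
    b <- substring(kmers, i, i)
    if (!all(b %in% model$alphabet)) {
      stop("k-mer base outside alphabet at position ", i - 1L)
    }
    list(base_index = i - 1L,
         levels = lapply(stats::setNames(nm = model$alphabet),
                         function(a) lv[b == a]))
  })
}

#' Histogram similarity of two level collections
#'
#' Builds `num_bins` evenly spaced numbers spanning the pooled range of the
#' two collections (read as bin edges, giving `num_bins - 1` bins; set
#' `bins_as_count = TRUE` for `num_bins` bins), histograms both collections
#' on the shared bins, and returns the Pearson correlation of the two count
#' vectors.
#'
#' @param x,y non-empty numeric vectors of current levels.
#' @param num_bins number of evenly spaced bin edges (default 10).
#' @param bins_as_count treat `num_bins` as the bin count instead.
#' @return Pearson coefficient in `[-1, 1]`; 1 (with a warning) when either
#'   count vector has zero variance, i.e. both shapes are degenerate.
#' @export
histogram_similarity <- function(x, y, num_bins = 10L, bins_as_count = FALSE) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  n_edges <- if (bins_as_count) num_bins + 1L else num_bins
  if (n_edges < 3L) stop("need at least 2 bins")
  rng <- range(c(x, y))
  if (rng[1L] == rng[2L]) {
    warning("degenerate level range; similarity defined as 1")
    return(1)
  }
  edges <- seq(rng[1L], rng[2L], length.out = n_edges)
  bin_counts <- function(v) {
    idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(idx, nbins = n_edges - 1L)
  }
  cx <- bin_counts(x); cy <- bin_counts(y)
  if (sd(cx) == 0 || sd(cy) == 0) {
    warning("zero variance in histogram counts; similarity defined as 1")
    return(1)
  }
  cor(cx, cy)
}

#' Detect significant base positions of a k-mer model
#'
#' For each position, the 12 ordered base pairs (A,C,G,T choose 2, both
#' orders) are compared by [histogram_similarity()]; a position whose mean
#' pairwise similarity falls below `threshold` is significant. Returns the
#' full per-position report.
#'
#' @param model `kmer_model`.
#' @param num_bins bin-edge count per comparison (default 10).
#' @param threshold mean-similarity cutoff (default 0.96).
#' @param bins_as_count see [histogram_similarity()].
#' @return object of class `significance_report`: data.frame `per_index`
#'   (`index`, `mean_similarity`, `significant`), `significant_indices`
#'   (ascending 0-based), `threshold`, `num_bins`.
#' @export
significant_indices <- function(model, num_bins = 10L, threshold = 0.96,
                                bins_as_count = FALSE) {
  if (model_completeness(model) < 1) {
    warning(sprintf("model covers %d of %.0f %d-mers; proceeding on available k-mers",
                    length(model$levels), n_kmers(model$k), model$k))
  }
  pos <- build_positional_models(model)
  mean_sim <- vapply(pos, function(p) {
    sims <- numeric()
    for (a in model$alphabet) {
      for (b in setdiff(model$alphabet, a)) {
        sims <- c(sims, suppressWarnings(
          histogram_similarity(p$levels[[a]], p$levels[[b]],
                               num_bins = num_bins,
                               bins_as_count = bins_as_count)))
      }
    }
    mean(sims)
  }, 0)
  per_index <- data.frame(index = seq_along(pos) - 1L,
                          mean_similarity = mean_sim,
                          significant = mean_sim < threshold)
  structure(
    list(per_index = per_index,
         significant_indices = per_index$index[per_index$significant],
         threshold = threshold, num_bins = num_bins),
    class = "significance_report"
  )
}

#' @export
print.significance_report <- function(x, ...) {
  cat(sprintf("<significance_report> threshold=%.2f, bins=%d\n",
              x$threshold, x$num_bins))
  print(x$per_index, row.names = FALSE)
  cat("significant indices:",
      if (length(x$significant_indices))
        paste(x$significant_indices, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Write a significance report as TSV
#' @param report `significance_report`.
#' @param path file path.
#' @export
write_significance_report <- function(report, path) {
  utils::write.table(report$per_index, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Collapse a model onto a contiguous subset of positions
#'
#' Each reduced k-mer's level is the mean of the levels of all parent
#' k-mers sharing that subsequence at `keep_indices` (`4^(k-k')` parents
#' per child for a complete model). Used to compare models of different k:
#' a 9-mer model collapsed to its central 5 positions is comparable with a
#' 5-mer model.
#'
#' @param model `kmer_model`.
#' @param keep_indices contiguous ascending 0-based positions to keep.
#' @return `kmer_model` with `k = length(keep_indices)`; spreads, when
#'   present, are group-averaged the same way.
#' @export
collapse_model <- function(model, keep_indices) {
  keep_indices <- sort(as.integer(keep_indices))
  if (length(keep_indices) == 0L) stop("keep_indices is empty")
  if (any(keep_indices < 0L) || any(keep_indices >= model$k)) {
    stop("keep_indices out of range [0, k)")
  }
  if (length(keep_indices) > 1L && any(diff(keep_indices) != 1L)) {
    stop("keep_indices must be contiguous (register would be ambiguous)")
  }
  lo <- keep_indices[1L] + 1L
  hi <- keep_indices[length(keep_indices)] + 1L
  child <- substring(names(model$levels), lo, hi)
  levels <- tapply(model$levels, child, mean)
  stddev <- if (!is.null(model$stddev)) {
    s <- tapply(model$stddev, child, mean)
    stats::setNames(as.numeric(s), names(s))
  }
  kmer_model(stats::setNames(as.numeric(levels), names(levels)), stddev,
             space = model$space)
}

#' Per-position, per-base level distributions for plotting
#'
#' @param model `kmer_model`.
#' @return data.frame with columns `index` (0-based position), `base`,
#'   `level`, one row per (position, k-mer).
#' @export
density_profile <- function(model) {
  pos <- build_positional_models(model)
  data.table::rbindlist(lapply(pos, function(p) {
    data.table::rbindlist(lapply(names(p$levels), function(a) {
      data.table::data.table(index = p$base_index, base = a,
                             level = p$levels[[a]])
    }))
  })) |> as.data.frame()
}

#' Density plot of per-position base discrimination
#'
#' One panel per k-mer position; overlapping per-base level densities. A
#' position whose four curves separate discriminates the bases and will be
#' reported significant by [significant_indices()].
#'
#' @param model `kmer_model`.
#' @return a ggplot object.
#' @export
plot_density_profile <- function(model) {
  d <- density_profile(model)
  ggplot2::ggplot(d, ggplot2::aes(x = level, colour = base, fill = base)) +
    ggplot2::geom_density(alpha = 0.25) +
    ggplot2::facet_wrap(~index, labeller = ggplot2::label_both) +
    ggplot2::labs(x = sprintf("current level (%s)", model$space),
                  y = "density") +
    ggplot2::theme_minimal()
}
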