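## k-mer model tables: '#'-prefixed header lines, then tab-separated columns
## kmer, level_mean[, level_stdv]. The same dialect ONT and downstream
## event-aligners consume; some published models carry means only.

MODEL_ALPHABET <- c("A", "C", "G", "T")

#' Construct a k-mer model
#'
#' @param levels named numeric vector: expected current level per k-mer.
#'   Names must all have the same length `k` over `{A,C,G,T}`.
#' @param stddev optional named numeric vector of per-k-mer spreads, same
#'   names as `levels`.
#' @param space `"normalized"` (median/MAD units) or `"pA"` (picoamps).
#' @param alphabet ordered base set; fixed to ACGT (U is mapped to T on
#'   ingest everywhere in the package).
#' @return object of class `kmer_model` with fields `k`, `alphabet`,
#'   `levels`, `stddev`, `space`.
#' @export
kmer_model <- function(levels, stddev = NULL, space = c("normalized", "pA"),
                       alphabet = MODEL_ALPHABET) {
  space <- match.arg(space)
  kmers <- names(levels)
  if (is.null(kmers) || any(!nzchar(kmers))) stop("levels must be named by k-mer")
  if (anyDuplicated(kmers)) stop("duplicate k-mer keys in model")
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop("k-mer keys have mixed lengths: ",
                            paste(k, collapse = ", "))
  if (!all(grepl(sprintf("^[%s]+$", paste(alphabet, collapse = "")), kmers))) {
    stop("k-mer keys contain bases outside the alphabet")
  }
  if (!is.null(stddev)) {
    if (!identical(sort(names(stddev)), sort(kmers))) {
      stop("stddev names must match level names")
    }
    stddev <- stddev[kmers]
  }
  ord <- order(kmers)
  structure(
    list(k = as.integer(k), alphabet = alphabet,
         levels = levels[ord], stddev = if (!is.null(stddev)) stddev[ord],
         space = space),
    class = "kmer_model"
  )
}

#' @export
print.kmer_model <- function(x, ...) {
  cat(sprintf("<kmer_model> k=%d, %d/%d k-mers (%.1f%% complete), space=%s%s\n",
              x$k, length(x$levels), n_kmers(x$k),
              100 * model_completeness(x), x$space,
              if (is.null(x$stddev)) ", means only" else ""))
  invisible(x)
}

#' @export
as.data.frame.kmer_model <- function(x, ...) {
  d <- data.frame(kmer = names(x$levels), level_mean = unname(x$levels),
                  stringsAsFactors = FALSE)
  if (!is.null(x$stddev)) d$level_stdv <- unname(x$stddev)
  d
}

#' Number of possible k-mers and model size ratios
#'
#' `n_kmers(k)` is `4^k`; `model_size_ratio(k_large, k_small)` is the factor
#' by which the larger model's k-mer count exceeds the smaller's — e.g. a
#' 9-mer model holds `4^9 / 4^5 = 256` times more k-mers than a 5-mer model.
#'
#' @param k,k_large,k_small k-mer lengths.
#' @export
n_kmers <- function(k) 4^k

#' @rdname n_kmers
#' @export
model_size_ratio <- function(k_large, k_small) {
  n_kmers(k_large) / n_kmers(k_small)
}

#' Fraction of possible k-mers present in a model
#' @param model `kmer_model`.
#' @export
model_completeness <- function(model) {
  length(model$levels) / n_kmers(model$k)
}

#' All k-mers of length k in lexicographic order
#' @param k k-mer length.
#' @param alphabet ordered base set.
#' @export
all_kmers <- function(k, alphabet = MODEL_ALPHABET) {
  if (k == 0L) return("")
  grids <- rev(expand.grid(rep(list(alphabet), k), stringsAsFactors = FALSE))
  out <- do.call(paste0, grids)
  sort(out)
}

#' Expected signal samples per base
#'
#' At a translocation speed of `bases_per_sec` and an acquisition rate of
#' `sampling_rate` Hz, each base dwells for `floor(sampling_rate /
#' bases_per_sec)` samples on average — 30 for the RNA004 chemistry
#' (130 bases/s at 4 kHz).
#'
#' @param bases_per_sec translocation speed.
#' @param sampling_rate signal acquisition rate in Hz.
#' @export
expected_dwell <- function(bases_per_sec = 130, sampling_rate = 4000) {
  floor(sampling_rate / bases_per_sec)
}

#' Read / write k-mer model tables
#'
#' Tab-separated files with optional `#`-prefixed header lines, columns
#' `kmer`, `level_mean` and optionally `level_stdv`. `write_kmer_model()`
#' emits k-mers in lexicographic order plus provenance headers (`#k`,
#' `#scaling`, `#globals` when known); the two functions round-trip.
#'
#' @param path file path.
#' @param model `kmer_model`.
#' @param globals optional [scaling_params()] recorded in the header.
#' @return `read_kmer_model()` returns a `kmer_model`.
#' @export
read_kmer_model <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  body <- lines[!hdr & nzchar(lines)]
  if (length(body) == 0L) stop("model file has no data rows: ", path)
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  ## tolerate a column-name row
  if (identical(tolower(fields[[1L]][1L]), "kmer")) {
    fields <- fields[-1L]; ncol <- ncol[-1L]
    if (length(fields) == 0L) stop("model file has no data rows: ", path)
  }
  if (length(unique(ncol)) != 1L) {
    stop("ragged model file: rows with ", paste(unique(ncol), collapse = "/"),
         " columns")
  }
  if (ncol[1L] < 2L) stop("model file needs at least kmer and level columns")
  kmers <- toupper(vapply(fields, `[[`, "", 1L))
  kmers <- chartr("U", "T", kmers)
  levels <- as.numeric(vapply(fields, `[[`, "", 2L))
  if (anyNA(levels)) stop("non-numeric level_mean in model file")
  names(levels) <- kmers
  stddev <- NULL
  if (ncol[1L] >= 3L) {
    stddev <- as.numeric(vapply(fields, `[[`, "", 3L))
    if (anyNA(stddev)) stop("non-numeric level_stdv in model file")
    names(stddev) <- kmers
  }
  space_line <- grep("^#scaling\\t", lines, value = TRUE)
  space <- if (length(space_line) && grepl("pA", space_line)) "pA" else "normalized"
  kmer_model(levels, stddev, space = space)
}

#' @rdname read_kmer_model
#' @export
write_kmer_model <- function(model, path, globals = NULL) {
  hdr <- c(sprintf("#k\t%d", model$k),
           sprintf("#scaling\t%s", model$space),
           sprintf("#tool-version\tporemodel-%s",
                   as.character(utils::packageVersion("poremodel"))))
  if (!is.null(globals)) {
    hdr <- c(hdr, sprintf("#globals\tmean=%.6f\tstddev=%.6f",
                          globals$global_mean, globals$global_stddev))
  }
  d <- as.data.frame(model)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(d, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
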