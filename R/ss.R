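## ss format: run-length encoding of a signal-to-sequence alignment.
## "7,2D3,4I,5" = 7 signal samples matched, 2 bases deleted, 3 samples
## matched, 4 signal samples inserted, 5 samples matched. Bare integers are
## matches (signal samples for one base), nD deletes n bases, nI skips n
## signal samples. Commas between runs are optional on input; emitted on
## output.

SS_KINDS <- c("MATCH", "DELETION", "INSERTION")

#' Construct an ss operation table
#'
#' @param kind character vector over `"MATCH"`, `"DELETION"`, `"INSERTION"`.
#' @param length positive integer vector; `MATCH`/`INSERTION` lengths count
#'   signal samples, `DELETION` lengths count bases.
#' @return data.frame with columns `kind`, `length`.
#' @export
ss_ops <- function(kind = character(), length = integer()) {
  kind <- as.character(kind)
  length <- as.integer(length)
  stopifnot(length(kind) == length(length))
  if (!all(kind %in% SS_KINDS)) {
    stop("unknown ss op kind: ", paste(setdiff(kind, SS_KINDS), collapse = ", "))
  }
  if (any(length <= 0L)) stop("ss op lengths must be positive")
  data.frame(kind = kind, length = length, stringsAsFactors = FALSE)
}

#' Construct a signal-to-sequence alignment
#'
#' Bundles an ss operation table with its anchoring coordinates. All
#' coordinates are 0-based; signal intervals derived from the alignment are
#' half-open.
#'
#' @param ops data.frame from [ss_ops()] or [parse_ss()].
#' @param signal_start 0-based index of the first raw-signal sample consumed.
#' @param seq_start 0-based index of the first base consumed.
#' @param seq_is_reference logical; `TRUE` when bases index a reference
#'   rather than the basecalled read.
#' @return object of class `ss_alignment`.
#' @export
ss_alignment <- function(ops, signal_start = 0L, seq_start = 0L,
                         seq_is_reference = FALSE) {
  if (is.character(ops)) ops <- parse_ss(ops)
  ops <- ss_ops(ops$kind, ops$length)
  stopifnot(signal_start >= 0L, seq_start >= 0L)
  structure(
    list(ops = ops, signal_start = as.integer(signal_start),
         seq_start = as.integer(seq_start),
         seq_is_reference = isTRUE(seq_is_reference)),
    class = "ss_alignment"
  )
}

#' @export
print.ss_alignment <- function(x, ...) {
  cat("<ss_alignment> ", serialize_ss(x$ops),
      "  signal_start=", x$signal_start,
      " seq_start=", x$seq_start,
      if (x$seq_is_reference) " (reference)" else " (read)", "\n", sep = "")
  invisible(x)
}

#' Parse an ss operation string
#'
#' Accepts the grammar `(INT | INT"D" | INT"I")*` with optional commas
#' between runs, as emitted by upstream signal-alignment tools.
#'
#' @param text single character string, e.g. `"7,2D3,4I,5"`.
#' @return data.frame of operations as from [ss_ops()]; zero rows for `""`.
#' @examples
#' parse_ss("7,2D3,4I,5")
#' @export
parse_ss <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) return(ss_ops())
  n <- nchar(text)
  kinds <- character(); lens <- integer()
  pos <- 1L
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regexpr("^([0-9]+)([DI]?),?", rest, perl = TRUE)
    if (m == -1L) {
      stop(sprintf("malformed ss token at byte offset %d: '%s'", pos - 1L,
                   substr(text, pos, min(n, pos + 9L))))
    }
    tok <- regmatches(rest, m)
    digits <- sub("^([0-9]+).*$", "\\1", tok)
    suffix <- sub("^[0-9]+([DI]?),?$", "\\1", tok)
    len <- suppressWarnings(as.integer(digits))
    if (is.na(len)) {
      stop(sprintf("unreadable ss run length at byte offset %d", pos - 1L))
    }
    if (len == 0L) {
      stop(sprintf("zero-length ss op at byte offset %d", pos - 1L))
    }
    kinds <- c(kinds, switch(suffix, D = "DELETION", I = "INSERTION", "MATCH"))
    lens <- c(lens, len)
    pos <- pos + attr(m, "match.length")
  }
  ss_ops(kinds, lens)
}

#' Serialize an ss operation table to its string form
#'
#' Inverse of [parse_ss()]: match runs are emitted as bare integers,
#' deletions as `nD`, insertions as `nI`, comma-separated.
#'
#' @param ops data.frame of operations (or an `ss_alignment`).
#' @return single character string; `""` for an empty op list.
#' @export
serialize_ss <- function(ops) {
  if (inherits(ops, "ss_alignment")) ops <- ops$ops
  n <- nrow(ops)
  if (n == 0L) return("")
  suffix <- c(MATCH = "", DELETION = "D", INSERTION = "I")[ops$kind]
  ## upstream emitters separate runs with commas except after a deletion,
  ## whose trailing letter already delimits it: 7,2D3,4I,5
  sep <- c(ifelse(ops$kind[-n] == "DELETION", "", ","), "")
  paste0(ops$length, suffix, sep, collapse = "")
}

#' Expand an alignment to per-base signal segments
#'
#' Walks the operation list with a signal cursor and a base cursor: each
#' MATCH run assigns its signal samples to the current base (one run per
#' base, matching move-table semantics); DELETION advances the base cursor
#' without producing an interval; INSERTION advances the signal cursor
#' without touching a base.
#'
#' @param aln `ss_alignment`.
#' @param signal_len total raw-signal samples available.
#' @param seq_len total bases available.
#' @return data.frame with 0-based `base` index and half-open signal
#'   interval `[start, end)`, one row per matched base, sorted.
#' @export
ss_to_segments <- function(aln, signal_len, seq_len) {
  ops <- aln$ops
  is_match <- ops$kind == "MATCH"
  is_del <- ops$kind == "DELETION"
  is_ins <- ops$kind == "INSERTION"
  ## signal consumed by MATCH and INSERTION runs; bases by MATCH (1 each)
  ## and DELETION (length each)
  sig_adv <- ifelse(is_del, 0L, ops$length)
  base_adv <- ifelse(is_match, 1L, ifelse(is_del, ops$length, 0L))
  sig_end <- aln$signal_start + cumsum(sig_adv)
  base_end <- aln$seq_start + cumsum(base_adv)
  if (length(sig_end) && tail(sig_end, 1L) > signal_len) {
    stop("ss alignment overruns signal: needs ", tail(sig_end, 1L),
         " samples, have ", signal_len)
  }
  if (length(base_end) && tail(base_end, 1L) > seq_len) {
    stop("ss alignment overruns sequence: needs ", tail(base_end, 1L),
         " bases, have ", seq_len)
  }
  sig_start <- sig_end - sig_adv
  base_start <- base_end - base_adv
  data.frame(
    base = base_start[is_match],
    start = sig_start[is_match],
    end = sig_end[is_match]
  )
}

#' Base indices near alignment indels
#'
#' Bases within `skip` positions of a deletion run, or within `skip` bases
#' on either side of an insertion boundary, carry unreliable segment
#' boundaries; events overlapping them are dropped by the sampler.
#'
#' @param aln `ss_alignment`.
#' @param skip non-negative integer neighborhood half-width in bases.
#' @return sorted integer vector of excluded 0-based base indices (possibly
#'   negative / beyond the sequence; callers intersect with valid range).
#' @export
mask_indel_neighborhood <- function(aln, skip = 2L) {
  stopifnot(skip >= 0L)
  ops <- aln$ops
  base_adv <- ifelse(ops$kind == "MATCH", 1L,
                     ifelse(ops$kind == "DELETION", ops$length, 0L))
  base_end <- aln$seq_start + cumsum(base_adv)
  base_start <- base_end - base_adv
  excl <- integer()
  for (i in seq_len(nrow(ops))) {
    if (ops$kind[i] == "DELETION") {
      excl <- c(excl, seq(base_start[i] - skip, base_end[i] - 1L + skip))
    } else if (ops$kind[i] == "INSERTION" && skip > 0L) {
      ## boundary sits between base_start-1 and base_start
      excl <- c(excl, seq(base_start[i] - skip, base_start[i] + skip - 1L))
    }
  }
  sort(unique(excl))
}

#' Convert a basecaller move table to an ss alignment
#'
#' The move table marks, at a fixed stride of raw samples, the neural-net
#' steps at which a new base was emitted. Each maximal run of steps starting
#' at a 1-move becomes one MATCH of `run_length * stride` samples; no
#' deletion or insertion ops can arise.
#'
#' @param stride samples per step (>= 1).
#' @param moves integer 0/1 vector; `moves[1]` must be 1.
#' @param trim_offset samples skipped before the first step (alignment
#'   `signal_start`).
#' @param signal_len total samples in the read; consumption is checked.
#' @return `ss_alignment` anchored at `trim_offset`.
#' @export
move_table_to_ss <- function(stride, moves, trim_offset = 0L,
                             signal_len = stride * length(moves) + trim_offset) {
  stopifnot(stride >= 1L, trim_offset >= 0L)
  if (length(moves) == 0L) stop("move table is empty")
  if (!all(moves %in% c(0L, 1L))) stop("moves must be 0/1")
  if (moves[1L] != 1L) stop("move table must start with a 1-move")
  if (stride * length(moves) + trim_offset > signal_len) {
    stop("move table overruns signal length")
  }
  run_len <- diff(c(which(moves == 1L), length(moves) + 1L))
  ss_alignment(ss_ops(rep("MATCH", length(run_len)), run_len * stride),
               signal_start = trim_offset)
}
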