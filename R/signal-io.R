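## Raw-signal records and the external formats that carry them.
##
## Signals travel in a plain-text TSV container: one row per read with the
## calibration fields every ADC-to-pA conversion needs (the same header
## semantics SLOW5-family containers use) and the raw samples comma-packed.
## Columns: read_id, digitisation, offset, range, sampling_rate, raw_signal
## [, sequence].

#' Construct a raw-signal read record
#'
#' @param read_id read identifier.
#' @param raw integer vector of ADC samples.
#' @param digitisation ADC levels spanning `range_pA` (e.g. 2048).
#' @param range_pA full-scale current range in picoamps.
#' @param offset ADC offset added before scaling.
#' @param sampling_rate acquisition rate in Hz.
#' @param sequence optional basecalled/reference sequence, 5'->3'; `U` is
#'   mapped to `T` on ingest.
#' @return object of class `read_record`.
#' @export
read_record <- function(read_id, raw, digitisation, range_pA, offset = 0,
                        sampling_rate = 4000, sequence = NULL) {
  stopifnot(length(raw) > 0L, digitisation > 0, range_pA > 0,
            sampling_rate > 0)
  if (!is.null(sequence)) {
    sequence <- chartr("Uu", "Tt", toupper(sequence))
    if (!grepl("^[ACGTN]*$", sequence)) {
      stop("sequence contains characters outside {A,C,G,T,U,N}")
    }
  }
  structure(
    list(read_id = as.character(read_id), raw = as.numeric(raw),
         digitisation = as.numeric(digitisation),
         range_pA = as.numeric(range_pA), offset = as.numeric(offset),
         sampling_rate = as.numeric(sampling_rate), sequence = sequence),
    class = "read_record"
  )
}

#' @export
print.read_record <- function(x, ...) {
  cat(sprintf("<read_record> %s: %d samples @ %g Hz%s\n", x$read_id,
              length(x$raw), x$sampling_rate,
              if (!is.null(x$sequence))
                sprintf(", %d bases", nchar(x$sequence)) else ""))
  invisible(x)
}

#' Convert raw ADC samples to picoamps
#'
#' `pA = (raw + offset) * range_pA / digitisation`, the standard calibration
#' carried in nanopore signal container headers.
#'
#' @param rec `read_record`.
#' @return numeric vector of pA values, same length as `rec$raw`.
#' @export
raw_to_pa <- function(rec) {
  (rec$raw + rec$offset) * rec$range_pA / rec$digitisation
}

#' Read / write the TSV signal container
#'
#' One row per read: `read_id`, `digitisation`, `offset`, `range`,
#' `sampling_rate`, comma-separated `raw_signal`, optional `sequence`.
#' Header line starts with `#`.
#'
#' @param path file path.
#' @param reads list of `read_record`.
#' @return `read_signal_tsv()` returns a named list of `read_record`.
#' @export
read_signal_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) == 0L) return(list())
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 6L) stop("signal TSV row has ", length(f),
                             " fields; need >= 6")
    raw <- as.numeric(strsplit(f[6L], ",", fixed = TRUE)[[1L]])
    if (anyNA(raw)) stop("non-numeric raw sample in read ", f[1L])
    read_record(
      read_id = f[1L], raw = raw,
      digitisation = as.numeric(f[2L]), offset = as.numeric(f[3L]),
      range_pA = as.numeric(f[4L]), sampling_rate = as.numeric(f[5L]),
      sequence = if (length(f) >= 7L && nzchar(f[7L])) f[7L]
    )
  })
  stats::setNames(out, vapply(out, `[[`, "", "read_id"))
}

#' @rdname read_signal_tsv
#' @export
write_signal_tsv <- function(reads, path) {
  hdr <- "#read_id\tdigitisation\toffset\trange\tsampling_rate\traw_signal\tsequence"
  rows <- vapply(reads, function(r) {
    paste(r$read_id, r$digitisation, r$offset, r$range_pA, r$sampling_rate,
          paste(r$raw, collapse = ","),
          if (is.null(r$sequence)) "" else r$sequence,
          sep = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read sequences from FASTA/FASTQ
#'
#' Thin wrapper over Biostrings; names are truncated at the first
#' whitespace and `U` is mapped to `T`.
#'
#' @param path FASTA or FASTQ file (format detected from extension).
#' @return named character vector of sequences.
#' @export
read_sequences <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  set <- Biostrings::readBStringSet(path, format = fmt)
  seqs <- chartr("Uu", "Tt", toupper(as.character(set)))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Read / write PAF alignments carrying ss tags
#'
#' Minimal PAF support for signal-to-sequence alignments: the 12 mandatory
#' columns plus an `ss:Z:` tag holding the run-length alignment string. The
#' query is the signal (sample coordinates), the target the sequence (base
#' coordinates), both 0-based half-open per PAF convention.
#'
#' @param path file path.
#' @param alignments named list of `ss_alignment` keyed by read id.
#' @param signal_lens,seq_lens named integer vectors giving, per read id,
#'   total samples and total bases (used for the PAF length columns).
#' @return `read_paf_ss()` returns a named list of `ss_alignment`.
#' @export
read_paf_ss <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L) stop("PAF row has fewer than 12 columns")
    ss_tag <- grep("^ss:Z:", f[-(1:12)], value = TRUE)
    if (length(ss_tag) != 1L) {
      stop("PAF row for ", f[1L], " lacks a single ss:Z: tag")
    }
    ops <- parse_ss(sub("^ss:Z:", "", ss_tag))
    out[[f[1L]]] <- ss_alignment(
      ops,
      signal_start = as.integer(f[3L]),
      seq_start = as.integer(f[8L]),
      seq_is_reference = !identical(f[6L], f[1L])
    )
  }
  out
}

#' @rdname read_paf_ss
#' @export
write_paf_ss <- function(alignments, signal_lens, seq_lens, path) {
  rows <- vapply(names(alignments), function(id) {
    a <- alignments[[id]]
    ops <- a$ops
    sig_used <- sum(ops$length[ops$kind != "DELETION"])
    base_used <- sum(ifelse(ops$kind == "MATCH", 1L,
                            ifelse(ops$kind == "DELETION", ops$length, 0L)))
    paste(id, signal_lens[[id]], a$signal_start, a$signal_start + sig_used,
          "+", id, seq_lens[[id]], a$seq_start, a$seq_start + base_used,
          base_used, base_used, 255,
          paste0("ss:Z:", serialize_ss(ops)),
          sep = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}

#' Read basecaller move tables from SAM/BAM
#'
#' Extracts the move-table auxiliary tag (`mv:B:c`, first element the
#' stride, remainder the per-step 0/1 moves) and the trimmed-samples tag
#' (`ts:i`, 0 when absent) and converts each to an ss alignment via
#' [move_table_to_ss()]. SAM input is converted through Rsamtools.
#'
#' @param path SAM or BAM file.
#' @return named list with, per read, `stride`, `moves`, `trim_offset` and
#'   the derived `ss_alignment` (`$aln`).
#' @export
read_sam_moves <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = "qname", tag = c("mv", "ts"))
  )[[1L]]
  out <- list()
  for (i in seq_along(res$qname)) {
    mv <- res$tag$mv[[i]]
    if (is.null(mv)) next
    ts <- res$tag$ts[[i]]
    ts <- if (is.null(ts) || is.na(ts)) 0L else as.integer(ts)
    stride <- as.integer(mv[1L])
    moves <- as.integer(mv[-1L])
    out[[res$qname[i]]] <- list(
      stride = stride, moves = moves, trim_offset = ts,
      aln = move_table_to_ss(stride, moves, trim_offset = ts)
    )
  }
  out
}
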