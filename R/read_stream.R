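#' Read FASTQ records for one sample
#'
#' Reads at most `max_records` records from a FASTQ file (plain or gzipped,
#' autodetected) in file order.  Quality strings are ignored: no quality
#' filtering is applied anywhere in the pipeline.
#'
#' @param path Path to a FASTQ file (`.gz` accepted).
#' @param max_records Cap on the number of records read (default 2.5e6).
#' @return Named character vector of read sequences; names are the FASTQ
#'   record ids.  `length()` of the result is `L = min(records, max_records)`.
#' @export
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII"), fq)
#' stream_reads(fq)
stream_reads <- function(path, max_records = 2.5e6) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 nrec = as.integer(max_records),
                                 with.qualities = FALSE),
    error = function(e) {
      bad <- locate_malformed_fastq(path)
      if (!is.na(bad))
        stop("malformed FASTQ record at record index ", bad, " in ", path,
             call. = FALSE)
      stop(conditionMessage(e), call. = FALSE)
    })
  seqs <- as.character(x)
  names(seqs) <- names(x)
  seqs
}

# First malformed 4-line record (1-based index), or NA if none found.
locate_malformed_fastq <- function(path) {
  con <- gzfile(path, open = "rt")  # gzfile reads plain files transparently
  on.exit(close(con))
  i <- 0L
  repeat {
    block <- readLines(con, n = 4L)
    if (length(block) == 0L) return(NA_integer_)
    i <- i + 1L
    if (length(block) < 4L ||
        !startsWith(block[1L], "@") ||
        !startsWith(block[3L], "+") ||
        nchar(block[2L]) != nchar(block[4L]))
      return(i)
  }
}

#' Anchor/target k-mer tuples of a single read
#'
#' Slides a window of stride 1 along the read.  For every anchor position
#' `p` (0-based) with `p + k <= len`, the downstream target is
#' `seq[p+k+g, p+2k+g)` and the upstream target is `seq[p-k-g, p-g)`; each
#' is emitted only when it fits inside the read.  Any window (anchor or
#' target) containing a non-ACGT base is skipped.
#'
#' @param sequence A single DNA string.
#' @param k K-mer length (default 27).
#' @param g Gap between anchor and target (default 0).
#' @return A list with `pairs` (data.frame: `anchor`, `direction` in
#'   `"up"`/`"down"`, `target`) and `anchor_counts` (named integer vector of
#'   within-read occurrence counts over all valid anchor windows).
#' @export
#' @examples
#' extract_pairs(strrep("ACGT", 20), k = 27)$pairs[1:2, ]
extract_pairs <- function(sequence, k = 27, g = 0) {
  stopifnot(length(sequence) == 1, k >= 1, g >= 0)
  res <- cpp_extract_pairs(as.character(sequence), as.integer(k),
                           as.integer(g))
  list(pairs = data.frame(anchor = res$anchor, direction = res$direction,
                          target = res$target, stringsAsFactors = FALSE),
       anchor_counts = res$anchor_counts)
}
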