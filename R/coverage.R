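## Per-position read-start and read-depth profiles.

#' Count read starts and depth per position
#'
#' The method's primitive statistics: for every transcript position,
#' `starts[i]` is the number of retained reads whose 5'-most aligned base is
#' `i`, and `depth[i]` the number of reads spanning `i` (a read `[start,
#' end]` covers every position in between, inclusive). A read starting at
#' `i` covers `i`, so `starts[i] <= depth[i]` everywhere.
#'
#' @param reads A `data.frame(transcript_id, start, end)` of 1-based,
#'   inclusive read records. Reference names may be collapsed-duplicate
#'   aliases; they are resolved through the alias map.
#' @param ts A [transcript_set()].
#' @return A `CoverageSet`: a named list (by surviving transcript id) of
#'   lists with integer vectors `starts` and `depth` of length `L`.
#' @export
count_reads <- function(reads, ts) {
  stopifnot(is.data.frame(reads),
            all(c("transcript_id", "start", "end") %in% names(reads)))
  lens <- transcript_lengths(ts)
  ids <- resolve_ids(ts, as.character(reads$transcript_id))
  start <- as.integer(reads$start)
  end <- as.integer(reads$end)
  L_of <- unname(lens[ids])
  bad <- which(start < 1L | end > L_of | start > end)
  if (length(bad) > 0)
    stop("read record ", bad[1], " (", ids[bad[1]], ":", start[bad[1]], "-",
         end[bad[1]], ") outside [1,", L_of[bad[1]], "]")
  out <- lapply(names(lens), function(id) {
    L <- lens[[id]]
    sel <- ids == id
    s <- tabulate(start[sel], nbins = L)
    # depth via difference array: +1 at start, -1 after end
    delta <- tabulate(start[sel], nbins = L + 1L) -
             tabulate(end[sel] + 1L, nbins = L + 1L)
    list(starts = as.integer(s), depth = as.integer(cumsum(delta))[seq_len(L)])
  })
  names(out) <- names(lens)
  structure(out, class = "CoverageSet")
}

#' @export
print.CoverageSet <- function(x, ...) {
  nread <- sum(vapply(x, function(p) sum(p$starts), numeric(1)))
  cat("CoverageSet over", length(x), "transcript(s),", nread, "reads counted\n")
  invisible(x)
}

#' Count coverage from an alignment file or read-record TSV
#'
#' Accepts SAM/BAM alignments against the transcript references, or the
#' aligner-free three-column TSV written by [write_reads_tsv()]. For
#' alignments, the read start/end are the first and last reference-consumed
#' bases of the CIGAR (soft clips excluded, deletions and splices span depth
#' only through reference-consumed blocks via the alignment end). Unmapped,
#' secondary and supplementary records are always excluded; reverse-strand
#' alignments are excluded by default because the library is stranded
#' against transcript references.
#'
#' @param path Path to a `.sam`, `.bam` or `.tsv`/`.txt` file.
#' @param ts A [transcript_set()]; alignment reference names must resolve
#'   against it (aliases of collapsed duplicates accepted).
#' @param min_mapq Minimum mapping quality (alignment input only).
#' @param primary_only Drop secondary/supplementary alignments (always
#'   `TRUE`; present for interface clarity).
#' @param include_reverse Also count reverse-strand alignments, using the
#'   alignment's reference span on the forward coordinate.
#' @return A `CoverageSet` (see [count_reads()]).
#' @export
count_from_alignments <- function(path, ts, min_mapq = 0L,
                                  primary_only = TRUE,
                                  include_reverse = FALSE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  reads <- if (ext %in% c("sam", "bam")) {
    read_alignment_records(path, min_mapq = min_mapq,
                           include_reverse = include_reverse)
  } else {
    read_records_tsv(path)
  }
  count_reads(reads, ts)
}

read_alignment_records <- function(path, min_mapq = 0L, include_reverse = FALSE) {
  ext <- tolower(tools::file_ext(path))
  bam <- if (ext == "sam") {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isMinusStrand = if (include_reverse) NA else FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   mapqFilter = as.integer(min_mapq))
  aln <- as.data.frame(GenomicAlignments::readGAlignments(bam, param = param))
  data.frame(transcript_id = as.character(aln$seqnames),
             start = as.integer(aln$start), end = as.integer(aln$end),
             stringsAsFactors = FALSE)
}

read_records_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("transcript_id", "start", "end")
  if (!all(need %in% names(df)))
    stop("read-record TSV must have header columns transcript_id, start, end")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df[need]
}

#' Serialize coverage profiles to TSV
#'
#' One row per (transcript, position) with the start and depth counts.
#'
#' @param cov A `CoverageSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(cov, path) {
  rows <- lapply(names(cov), function(id) {
    L <- length(cov[[id]]$starts)
    data.frame(transcript_id = id, position = seq_len(L),
               starts = cov[[id]]$starts, depth = cov[[id]]$depth,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
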