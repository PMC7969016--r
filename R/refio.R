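## Transcript references: reading, normalization, deduplication, structural labels.

#' Construct a TranscriptSet
#'
#' A `TranscriptSet` holds an ordered collection of transcript reference
#' sequences in the RNA alphabet (`A`, `C`, `G`, `U`, `N`), together with an
#' optional per-transcript map of structural position labels (e.g. the tRNA
#' positions `"32"`, `"47d"`, `"20"` where m3C occurs) and an alias map from
#' collapsed duplicate ids to their surviving representative.
#'
#' @param sequences Named character vector of sequences. Names are transcript
#'   ids and must be unique. `T` is converted to `U`; lower case is raised.
#' @param category Character scalar or vector recycled over transcripts; one of
#'   `"tRNA"`, `"mRNA"`, `"ncRNA"`, `"other"`.
#' @param labels Named list (by transcript id) of named character vectors;
#'   names of the inner vectors are 1-based positions, values are labels.
#' @param aliases Named character vector mapping removed duplicate ids to the
#'   id kept for their shared sequence.
#'
#' @return An object of class `TranscriptSet`.
#' @export
transcript_set <- function(sequences, category = "other", labels = list(),
                           aliases = character()) {
  if (length(sequences) > 0 && (is.null(names(sequences)) || any(!nzchar(names(sequences)))))
    stop("all sequences must be named with a transcript id")
  ids <- names(sequences)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate transcript id(s): ", paste(unique(dup), collapse = ", "))
  sequences <- vapply(seq_along(sequences), function(i)
    normalize_rna(sequences[[i]], ids[i]), character(1))
  names(sequences) <- ids
  bad_cat <- setdiff(unique(category), c("tRNA", "mRNA", "ncRNA", "other"))
  if (length(bad_cat) > 0)
    stop("unknown category: ", paste(bad_cat, collapse = ", "))
  category <- rep_len(category, length(sequences))
  names(category) <- ids
  obj <- structure(list(sequences = sequences, category = category,
                        labels = labels, aliases = aliases),
                   class = "TranscriptSet")
  validate_transcript_set(obj)
}

normalize_rna <- function(seq, id) {
  if (!nzchar(seq)) stop("transcript '", id, "' has an empty sequence")
  s <- chartr("tu", "TU", toupper(seq))
  s <- chartr("T", "U", s)
  bad <- regexpr("[^ACGUN]", s)
  if (bad > 0)
    stop("transcript '", id, "' has invalid character '",
         substr(s, bad, bad), "' at position ", bad)
  s
}

validate_transcript_set <- function(ts) {
  stopifnot(inherits(ts, "TranscriptSet"))
  ids <- names(ts$sequences)
  for (id in names(ts$labels)) {
    if (!id %in% ids) stop("labels refer to unknown transcript '", id, "'")
    pos <- as.integer(names(ts$labels[[id]]))
    L <- nchar(ts$sequences[[id]])
    if (anyNA(pos) || any(pos < 1L) || any(pos > L))
      stop("label position out of [1,", L, "] for transcript '", id, "'")
  }
  ts
}

#' @export
print.TranscriptSet <- function(x, ...) {
  cat("TranscriptSet with", length(x$sequences), "transcript(s)")
  if (length(x$aliases)) cat(",", length(x$aliases), "collapsed alias(es)")
  cat("\n")
  n <- min(6L, length(x$sequences))
  for (id in names(x$sequences)[seq_len(n)])
    cat(sprintf("  %s [%s] %d nt\n", id, x$category[[id]], nchar(x$sequences[[id]])))
  if (length(x$sequences) > n) cat("  ...\n")
  invisible(x)
}

#' @export
length.TranscriptSet <- function(x) length(x$sequences)

#' Transcript ids and lengths
#'
#' @param ts A `TranscriptSet`.
#' @return `transcript_ids()` returns the ids of surviving transcripts;
#'   `transcript_lengths()` a named integer vector of sequence lengths.
#' @export
transcript_ids <- function(ts) names(ts$sequences)

#' @rdname transcript_ids
#' @export
transcript_lengths <- function(ts) {
  vapply(ts$sequences, nchar, integer(1))
}

#' Resolve a reference name through the alias map
#'
#' Reads aligned to a transcript whose sequence was collapsed during
#' deduplication carry the removed id; this maps it to the surviving
#' representative.
#'
#' @param ts A `TranscriptSet`.
#' @param ids Character vector of reference names.
#' @return Character vector of surviving ids.
#' @export
resolve_ids <- function(ts, ids) {
  hit <- ids %in% names(ts$aliases)
  ids[hit] <- unname(ts$aliases[ids[hit]])
  unknown <- setdiff(unique(ids), names(ts$sequences))
  if (length(unknown) > 0)
    stop("unknown reference name(s): ", paste(unknown, collapse = ", "))
  ids
}

#' Read transcript references from FASTA
#'
#' Sequences are normalized to the RNA alphabet (`T` becomes `U`, case is
#' raised); the id is the FASTA header up to the first whitespace, for
#' compatibility with SAM reference names.
#'
#' @param path Path to a FASTA file (multi-line records allowed).
#' @param category Category assigned to every record (`"tRNA"`, `"mRNA"`,
#'   `"ncRNA"` or `"other"`).
#' @return A [transcript_set()].
#' @export
read_fasta <- function(path, category = "other") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  if (length(ids) > 0 && any(!nzchar(ids))) stop("empty FASTA header in ", path)
  names(seqs) <- ids
  transcript_set(seqs, category = category)
}

#' Write a TranscriptSet as FASTA
#'
#' Sequences are written in the RNA alphabet, wrapped at 60 columns.
#'
#' @param ts A `TranscriptSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ts, path) {
  set <- Biostrings::BStringSet(ts$sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Collapse transcripts with identical sequences
#'
#' Multiple tRNA gene copies often share one mature sequence; reads cannot
#' distinguish them, so identical sequences are collapsed to the first-seen
#' id before counting. The alias map records every removed id.
#'
#' @param ts A `TranscriptSet`.
#' @return A `TranscriptSet` with unique sequences, survivor order preserved.
#'   Idempotent. Labels of removed transcripts are merged into the survivor
#'   (survivor's own labels win on conflict).
#' @export
deduplicate <- function(ts) {
  keep <- !duplicated(unname(ts$sequences))
  ids <- names(ts$sequences)
  rep_id <- ids[keep][match(ts$sequences, ts$sequences[keep])]
  new_alias <- stats::setNames(rep_id[!keep], ids[!keep])
  # previously collapsed ids must chase through to the new survivor
  old <- ts$aliases
  if (length(old) > 0) {
    chased <- ifelse(old %in% names(new_alias), new_alias[old], old)
    old <- stats::setNames(unname(chased), names(old))
  }
  labels <- ts$labels
  for (rm in names(new_alias)) {
    if (!is.null(labels[[rm]])) {
      tgt <- new_alias[[rm]]
      merged <- c(labels[[tgt]], labels[[rm]])
      labels[[tgt]] <- merged[!duplicated(names(merged))]
      labels[[rm]] <- NULL
    }
  }
  structure(list(sequences = ts$sequences[keep], category = ts$category[keep],
                 labels = labels, aliases = c(old, new_alias)),
            class = "TranscriptSet")
}

#' Attach structural position labels from a TSV
#'
#' The file has three tab-separated columns `transcript_id`, `position`
#' (1-based), `label`; lines starting with `#` are skipped, and a header row
#' naming the columns is recognized and skipped.
#'
#' @param path Path to the labels TSV.
#' @param ts A `TranscriptSet` the labels must refer to.
#' @return `ts` with labels attached.
#' @export
read_labels <- function(path, ts) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) return(ts)
  first <- tolower(gsub("\\s+$", "", lines[rows[1]]))
  if (identical(strsplit(first, "\t")[[1]][1:2], c("transcript_id", "position")))
    rows <- rows[-1]
  for (r in rows) {
    f <- strsplit(lines[r], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("labels row at line ", r, " does not have 3 tab-separated fields")
    id <- f[1]
    if (!id %in% names(ts$sequences))
      stop("labels row at line ", r, ": unknown transcript '", id, "'")
    pos <- suppressWarnings(as.integer(f[2]))
    L <- nchar(ts$sequences[[id]])
    if (is.na(pos) || pos < 1L || pos > L)
      stop("labels row at line ", r, ": position '", f[2],
           "' outside [1,", L, "] for transcript '", id, "'")
    lab <- stats::setNames(f[3], as.character(pos))
    merged <- c(ts$labels[[id]], lab)
    ts$labels[[id]] <- merged[!duplicated(names(merged), fromLast = TRUE)]
  }
  validate_transcript_set(ts)
}

#' Look up the structural label of a position, if any
#'
#' @param ts A `TranscriptSet`.
#' @param id Transcript id.
#' @param position 1-based position.
#' @return The label string, or `NA_character_`.
#' @export
position_label <- function(ts, id, position) {
  lab <- ts$labels[[id]]
  if (is.null(lab)) return(rep(NA_character_, length(position)))
  unname(lab[as.character(position)])
}
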