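## Motif windows, base composition, heat-map tables and serialization.

#' Extract motif windows around called sites
#'
#' Collects the `2 * flank + 1`-nt sequence centred on each called site
#' (default 7 nt: 3 upstream, 3 downstream) and tallies a position frequency
#' matrix over offsets `-flank..+flank`. Sites too close to a transcript end
#' are skipped — a padded logo would misstate frequencies — and counted in
#' `n_skipped`.
#'
#' @param calls Output of [call_sites()]; only rows with `called == TRUE`
#'   are used.
#' @param ts The [transcript_set()].
#' @param flank Bases on each side of the site.
#' @return A `MotifMatrix`: list with `counts` (4 x (2*flank+1) integer
#'   matrix, rows `A,C,G,U`, columns the offsets), `windows` (character),
#'   `site_ids` (transcript:position of each window), `n_skipped`, `flank`.
#' @export
extract_motif_windows <- function(calls, ts, flank = 3L) {
  called <- calls[which(calls$called), , drop = FALSE]
  lens <- transcript_lengths(ts)
  windows <- character(0)
  site_ids <- character(0)
  n_skipped <- 0L
  for (k in seq_len(nrow(called))) {
    id <- called$transcript_id[k]
    i <- called$position[k]
    if (i - flank < 1L || i + flank > lens[[id]]) {
      n_skipped <- n_skipped + 1L
      next
    }
    windows <- c(windows, substr(ts$sequences[[id]], i - flank, i + flank))
    site_ids <- c(site_ids, paste0(id, ":", i))
  }
  mm <- motif_from_windows(windows, flank = flank)
  mm$site_ids <- site_ids
  mm$n_skipped <- n_skipped
  mm
}

#' Tally a position frequency matrix from window sequences
#'
#' @param windows Character vector of `2 * flank + 1`-nt RNA strings.
#' @param flank Bases on each side of the central site.
#' @return A `MotifMatrix` (see [extract_motif_windows()]).
#' @export
motif_from_windows <- function(windows, flank = 3L) {
  w <- 2L * flank + 1L
  if (length(windows) > 0 && any(nchar(windows) != w))
    stop("all windows must have length ", w)
  offs <- as.character(seq.int(-flank, flank))
  counts <- matrix(0L, 4L, w, dimnames = list(c("A", "C", "G", "U"), offs))
  for (j in seq_len(w)) {
    tab <- table(factor(substring(windows, j, j), levels = c("A", "C", "G", "U")))
    counts[, j] <- as.integer(tab)
  }
  structure(list(counts = counts, windows = windows,
                 site_ids = character(length(windows)),
                 n_skipped = 0L, flank = as.integer(flank)),
            class = "MotifMatrix")
}

#' @export
print.MotifMatrix <- function(x, ...) {
  cat("MotifMatrix over", length(x$windows), "window(s) (", x$n_skipped,
      "site(s) skipped at transcript ends)\n")
  print(x$counts)
  cat("consensus:", consensus_motif(x), "\n")
  invisible(x)
}

#' Consensus string of a motif matrix
#'
#' Most frequent base per offset; ties resolved in `A < C < G < U` order,
#' `N` where a column has no windows.
#'
#' @param mm A `MotifMatrix`.
#' @return A character scalar of length `2 * flank + 1`.
#' @export
consensus_motif <- function(mm) {
  if (length(mm$windows) == 0) return(strrep("N", ncol(mm$counts)))
  paste(rownames(mm$counts)[apply(mm$counts, 2, which.max)], collapse = "")
}

#' Base composition of called sites
#'
#' The number of called sites whose reference base is A, C, G or U — a
#' specificity diagnostic: m3C chemistry should yield calls almost
#' exclusively at C.
#'
#' @param calls Output of [call_sites()].
#' @return Named integer vector over `A`, `C`, `G`, `U`.
#' @export
base_composition <- function(calls) {
  called <- calls[which(calls$called), , drop = FALSE]
  tab <- table(factor(called$ref_base, levels = c("A", "C", "G", "U")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Heat-map table of mean cleavage ratios per arm
#'
#' One row per site, columns the replicate-mean cleavage ratio in the Ctrl,
#' HAC and DM-HAC arms. Rows are labeled `transcript:position` or
#' `transcript:position:label` when a structural label is annotated.
#'
#' @param evals Output of [call_sites()] (any row subset, e.g.
#'   [filter_calls()]).
#' @param site_subset Optional character vector of `transcript:position` ids
#'   to restrict the table to.
#' @return A `data.frame` with columns `site`, `Ctrl`, `HAC`, `DM.HAC`.
#' @export
heatmap_table <- function(evals, site_subset = NULL) {
  site <- paste0(evals$transcript_id, ":", evals$position)
  keep <- if (is.null(site_subset)) seq_len(nrow(evals)) else which(site %in% site_subset)
  evals <- evals[keep, , drop = FALSE]
  site <- site[keep]
  lab <- evals$label
  site <- ifelse(is.na(lab), site, paste0(site, ":", lab))
  data.frame(site = site, Ctrl = evals$mean_ctrl, HAC = evals$mean_hac,
             DM.HAC = evals$mean_dmhac, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write the site evaluation table as TSV
#'
#' @param calls Output of [call_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write called sites as BED6
#'
#' Coordinates convert from the 1-based inclusive site position to 0-based
#' half-open; the score is the mean HAC cleavage ratio scaled to 0-1000.
#'
#' @param calls Output of [call_sites()]; only called rows are written.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(calls, path) {
  called <- calls[which(calls$called), , drop = FALSE]
  name <- paste0(called$transcript_id, ":", called$position)
  name <- ifelse(is.na(called$label), name, paste0(name, ":", called$label))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t+", called$transcript_id,
                   called$position - 1L, called$position, name,
                   pmin(1000L, as.integer(round(called$mean_hac * 1000))))
  writeLines(lines, path)
  invisible(path)
}

#' Write motif counts as TSV
#'
#' Rows `A`, `C`, `G`, `U`; columns the window offsets `-flank..+flank`.
#'
#' @param mm A `MotifMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_tsv <- function(mm, path) {
  df <- data.frame(base = rownames(mm$counts), mm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write motif windows as FASTA
#'
#' One record per window, named by its site id; re-tallying the windows with
#' [motif_from_windows()] reproduces the matrix exactly.
#'
#' @param mm A `MotifMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_fasta <- function(mm, path) {
  ids <- mm$site_ids
  if (length(ids) != length(mm$windows) || any(!nzchar(ids)))
    ids <- paste0("window_", seq_along(mm$windows))
  set <- Biostrings::BStringSet(stats::setNames(mm$windows, ids))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write a heat-map table as TSV
#'
#' @param hm Output of [heatmap_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap_tsv <- function(hm, path) {
  utils::write.table(hm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
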