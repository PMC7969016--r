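# Shared fixtures and independent oracles, built in code at test time.

options(hacseq.verbose = FALSE)

# Brute-force start/depth counting: nested loop over reads x positions.
# Deliberately naive and independent of count_reads().
oracle_counts <- function(reads, lens) {
  out <- lapply(lens, function(L) list(starts = integer(L), depth = integer(L)))
  for (k in seq_len(nrow(reads))) {
    id <- reads$transcript_id[k]
    out[[id]]$starts[reads$start[k]] <- out[[id]]$starts[reads$start[k]] + 1L
    for (pos in seq_len(lens[[id]]))
      if (reads$start[k] <= pos && pos <= reads$end[k])
        out[[id]]$depth[pos] <- out[[id]]$depth[pos] + 1L
  }
  out
}

random_reads <- function(n, lens) {
  ids <- sample(names(lens), n, replace = TRUE)
  L <- unname(lens[ids])
  start <- vapply(L, function(l) sample.int(l, 1L), integer(1))
  end <- start + vapply(seq_len(n), function(k)
    sample.int(L[k] - start[k] + 1L, 1L), integer(1)) - 1L
  data.frame(transcript_id = ids, start = start, end = end,
             stringsAsFactors = FALSE)
}

random_transcript_set <- function(n_tx, min_len = 30L, max_len = 120L) {
  lens <- sample(min_len:max_len, n_tx, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("tx", seq_len(n_tx))
  transcript_set(seqs)
}

# Minimal single-transcript coverage nest for call_sites(): per-arm ratio
# vectors are realized through hand-built starts/depth profiles.
profiles_from_ratios <- function(L, site, ratios, depth = 400L) {
  # ratios: list(Ctrl = c(...), HAC = c(...), `DM-HAC` = c(...)) at the site
  nest <- list()
  for (g in names(ratios)) {
    nest[[g]] <- lapply(ratios[[g]], function(r) {
      starts <- integer(L)
      d <- rep.int(depth, L)
      starts[1L] <- depth            # all other reads are full length
      starts[site + 1L] <- as.integer(round(r * depth))
      starts[1L] <- depth - starts[site + 1L]
      cov <- list(tx1 = list(starts = starts, depth = d))
      structure(cov, class = "CoverageSet")
    })
  }
  nest
}

single_tx_set <- function(L = 60L, site = 30L) {
  s <- rep("A", L)
  s[site] <- "C"
  transcript_set(c(tx1 = paste(s, collapse = "")))
}
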