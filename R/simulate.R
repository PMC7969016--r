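## Generative simulator of three-arm HAC-seq libraries.
##
## Per molecule the model follows the library chemistry: stochastic
## methylation of planted sites, demethylase pre-treatment (DM-HAC arm),
## random fragmentation with end repair, hydrazine-aniline cleavage at
## surviving marks with loss of everything 5' of the cleaved base (the 5'
## fragment's damaged end cannot be adapter-ligated), a pre-library
## demethylation step that erases remaining marks (optionally leaving a
## residual RT hard-stop), and size selection.

HAC_GROUPS <- c("Ctrl", "HAC", "DM-HAC")

#' Simulation configuration
#'
#' Parameters of the synthetic three-arm library generator. Defaults mirror a
#' typical ribo-depleted total-RNA experiment: two biological replicates per
#' arm, random fragmentation tuned for a mean fragment around 200 nt on long
#' RNAs (tRNA-length references mostly stay intact), fully efficient
#' chemical cleavage, no residual reverse-transcription stops after the
#' pre-library demethylation, and a 15-300 nt retained-fragment window.
#'
#' @param replicates Replicates per group (>= 1; the caller needs >= 2).
#' @param molecules Molecules simulated per transcript per replicate.
#' @param lambda Per-internucleotide-bond break probability of the random
#'   fragmentation step, in `[0,1]`. `1/200` gives ~200 nt mean fragments.
#' @param cleavage Global probability `c` that the chemistry cleaves a
#'   still-methylated site, in `[0,1]`. Per-site overrides live in the truth
#'   table.
#' @param rt_stop Residual probability `epsilon` that a mark surviving to
#'   library preparation truncates the read at the mark instead of being
#'   erased, in `[0,1]`. Default 0: the protocol demethylates before reverse
#'   transcription.
#' @param frag_min,frag_max Retained fragment length window (size selection).
#' @param max_read_length Optional clip of the read 3' end (sequencing length);
#'   never moves the 5' start, which carries the signal.
#' @param seed Integer RNG seed; mandatory, the generator is deterministic
#'   given the seed.
#' @return An object of class `SimConfig`.
#' @export
sim_config <- function(replicates = 2L, molecules = 2000L, lambda = 1 / 200,
                       cleavage = 1.0, rt_stop = 0, frag_min = 15L,
                       frag_max = 300L, max_read_length = NULL, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(replicates >= 1, molecules >= 1,
            lambda >= 0, lambda <= 1, cleavage >= 0, cleavage <= 1,
            rt_stop >= 0, rt_stop <= 1, frag_min >= 1, frag_min <= frag_max)
  structure(list(replicates = as.integer(replicates),
                 molecules = as.integer(molecules),
                 lambda = lambda, cleavage = cleavage, rt_stop = rt_stop,
                 frag_min = as.integer(frag_min),
                 frag_max = as.integer(frag_max),
                 max_read_length = if (is.null(max_read_length)) NULL
                                   else as.integer(max_read_length),
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Planted modification truth table
#'
#' @param transcript_id Transcript carrying the site.
#' @param position 1-based modified position.
#' @param stoichiometry Fraction `s` of molecules methylated at the site.
#' @param demethylation Probability `d` that the demethylase pre-treatment of
#'   the DM-HAC arm removes the mark. `d = 0` models an AlkB-resistant site.
#' @param cleavage Optional per-site cleavage probability overriding the
#'   global value; `NA` uses the global one.
#' @return A `data.frame` with one row per site.
#' @export
modification_truth <- function(transcript_id, position, stoichiometry,
                               demethylation = 1, cleavage = NA_real_) {
  n <- length(transcript_id)
  if (length(position) != n) stop("transcript_id and position lengths differ")
  df <- data.frame(transcript_id = as.character(transcript_id),
                   position = as.integer(position),
                   stoichiometry = as.numeric(rep_len(stoichiometry, n)),
                   demethylation = as.numeric(rep_len(demethylation, n)),
                   cleavage = as.numeric(rep_len(cleavage, n)),
                   stringsAsFactors = FALSE)
  probs <- c(df$stoichiometry, df$demethylation, df$cleavage[!is.na(df$cleavage)])
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0,1]")
  if (anyDuplicated(df[c("transcript_id", "position")]))
    stop("at most one truth record per (transcript, position)")
  df
}

check_truth <- function(truth, ts, require_c = TRUE) {
  lens <- transcript_lengths(ts)
  for (k in seq_len(nrow(truth))) {
    id <- truth$transcript_id[k]
    if (!id %in% names(lens))
      stop("truth site on unknown transcript '", id, "'")
    p <- truth$position[k]
    if (p < 1L || p > lens[[id]])
      stop("truth position ", p, " outside [1,", lens[[id]],
           "] on transcript '", id, "'")
    base <- substr(ts$sequences[[id]], p, p)
    if (require_c && base != "C")
      stop("truth site ", id, ":", p, " is on base '", base,
           "' (expected C; set require_c = FALSE for negative controls)")
  }
  invisible(truth)
}

#' Simulate a three-arm HAC-seq experiment
#'
#' Generates read records for every `(group, replicate)` library over the
#' groups `Ctrl`, `HAC` and `DM-HAC`. For each molecule, in order: (1) each
#' truth site is methylated with probability `s`; (2) in the DM-HAC arm each
#' mark is removed with probability `d`; (3) every internucleotide bond
#' breaks independently with probability `lambda` and all fragmentation ends
#' are repaired; (4) in the HAC and DM-HAC arms each still-marked site on a
#' fragment cleaves with probability `c`, deleting the marked base and
#' discarding everything 5' of it, so the surviving piece begins one base 3'
#' of the 3'-most realized cleavage; (5) marks that survive to library
#' preparation are erased by the demethylation step, except that with
#' probability `rt_stop` a surviving mark truncates the read to begin one
#' base 3' of the mark; (6) fragments outside the size window are dropped.
#'
#' Output is deterministic given the config seed: the molecule loop runs in
#' fixed `(group, replicate, transcript, molecule)` order over one seeded
#' RNG stream.
#'
#' @param ts A [transcript_set()].
#' @param truth A [modification_truth()] table (zero rows allowed).
#' @param config A [sim_config()].
#' @param require_c Require planted sites to sit on a reference `C`
#'   (disable to plant negative-control sites on other bases).
#' @return A list with elements `reads` (named list `"<group>.<rep>"` of
#'   `data.frame(transcript_id, start, end)`), `truth` (the validated truth
#'   table) and `config`.
#' @export
simulate_experiment <- function(ts, truth, config, require_c = TRUE) {
  stopifnot(inherits(ts, "TranscriptSet"), inherits(config, "SimConfig"))
  check_truth(truth, ts, require_c = require_c)
  lens <- transcript_lengths(ts)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  reads <- list()
  for (group in HAC_GROUPS) {
    for (rep_i in seq_len(config$replicates)) {
      per_tx <- vector("list", length(lens))
      for (t in seq_along(lens)) {
        id <- names(lens)[t]
        sites <- truth[truth$transcript_id == id, , drop = FALSE]
        sites <- sites[order(sites$position), , drop = FALSE]
        per_tx[[t]] <- simulate_library(id, lens[[t]], sites, group, config)
      }
      reads[[paste0(group, ".", rep_i)]] <- do.call(rbind, per_tx)
    }
  }
  list(reads = reads, truth = truth, config = config)
}

## One (transcript, library): returns data.frame(transcript_id, start, end).
simulate_library <- function(id, L, sites, group, config) {
  N <- config$molecules
  K <- nrow(sites)
  p <- sites$position
  c_eff <- ifelse(is.na(sites$cleavage), config$cleavage, sites$cleavage)
  cleaving_arm <- group != "Ctrl"

  # marks carried into fragmentation
  marked <- if (K > 0) {
    m <- matrix(stats::runif(N * K) < rep(sites$stoichiometry, each = N), N, K)
    if (group == "DM-HAC")
      m <- m & !(matrix(stats::runif(N * K), N, K) <
                   matrix(rep(sites$demethylation, each = N), N, K))
    m
  } else matrix(FALSE, N, 0)

  if (config$lambda == 0 && config$rt_stop == 0) {
    # closed-form fast path: one fragment [1, L] per molecule
    start <- rep(1L, N)
    if (cleaving_arm && K > 0) {
      cleaved <- marked & (matrix(stats::runif(N * K), N, K) <
                             matrix(rep(c_eff, each = N), N, K))
      for (k in seq_len(K))           # ascending p: last cleaved wins
        start[cleaved[, k]] <- p[k] + 1L
    }
    end <- rep(as.integer(L), N)
    keep <- (end - start + 1L) >= config$frag_min &
            (end - start + 1L) <= config$frag_max
    start <- start[keep]; end <- end[keep]
  } else {
    brk <- if (L > 1) matrix(stats::runif(N * (L - 1L)) < config$lambda, N, L - 1L)
           else matrix(FALSE, N, 0)
    start <- integer(0); end <- integer(0)
    for (m in seq_len(N)) {
      bpos <- which(brk[m, ])
      fa <- c(1L, bpos + 1L)
      fb <- c(bpos, as.integer(L))
      for (f in seq_along(fa)) {
        a <- fa[f]; b <- fb[f]
        inside <- if (K > 0) which(p >= a & p <= b & marked[m, ]) else integer(0)
        if (cleaving_arm && length(inside) > 0) {
          realized <- inside[stats::runif(length(inside)) < c_eff[inside]]
          if (length(realized) > 0) {
            a <- p[max(realized)] + 1L
            inside <- inside[p[inside] > p[max(realized)]]   # marks on retained piece
          }
        }
        if (a > b) next
        if (config$rt_stop > 0 && length(inside) > 0) {
          stopped <- inside[stats::runif(length(inside)) < config$rt_stop]
          if (length(stopped) > 0) a <- max(a, p[max(stopped)] + 1L)
        }
        if (a > b) next
        len <- b - a + 1L
        if (len < config$frag_min || len > config$frag_max) next
        start <- c(start, a); end <- c(end, b)
      }
    }
  }
  if (!is.null(config$max_read_length))
    end <- pmin(end, start + config$max_read_length - 1L)
  if (length(start) == 0)
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  data.frame(transcript_id = id, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' Write simulated reads as a read-record TSV
#'
#' Three tab-separated columns `transcript_id`, `start`, `end` (1-based,
#' inclusive), with a header row. This is the aligner-free input path of
#' [count_from_alignments()].
#'
#' @param reads A `data.frame(transcript_id, start, end)`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  utils::write.table(reads[c("transcript_id", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulated reads as SAM
#'
#' Emits a minimal SAM: `@SQ` lines from the transcript set and one
#' forward-strand, fully-matched (`<len>M`) alignment per read. Sequences are
#' written in the DNA alphabet as SAM convention expects.
#'
#' @param reads A `data.frame(transcript_id, start, end)`.
#' @param ts The `TranscriptSet` the reads were simulated from.
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, ts, path) {
  lens <- transcript_lengths(ts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens), con)
  if (nrow(reads) > 0) {
    seqs <- vapply(seq_len(nrow(reads)), function(i) {
      s <- substr(ts$sequences[[reads$transcript_id[i]]],
                  reads$start[i], reads$end[i])
      chartr("U", "T", s)
    }, character(1))
    writeLines(sprintf("r%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                       seq_len(nrow(reads)), reads$transcript_id,
                       reads$start, reads$end - reads$start + 1L, seqs), con)
  }
  invisible(path)
}

#' Write the planted-site truth table as TSV
#'
#' @param truth A [modification_truth()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
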