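## End-to-end orchestration: simulate or count -> call -> report.

#' Read a sample sheet
#'
#' Tab-separated columns `file`, `group` (one of `Ctrl`, `HAC`, `DM-HAC`)
#' and `replicate` (integer), with a header row; `#` comment lines skipped.
#' Relative file paths resolve against the sheet's directory.
#'
#' @param path Path to the sheet.
#' @return A `data.frame(file, group, replicate)`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("file", "group", "replicate")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns file, group, replicate")
  bad <- setdiff(unique(df$group), HAC_GROUPS)
  if (length(bad) > 0)
    stop("unknown group(s) in sample sheet: ", paste(bad, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", df$file)
  df$file[rel] <- file.path(dirname(path), df$file[rel])
  df$replicate <- as.integer(df$replicate)
  df[need]
}

## reads: named list "<group>.<rep>" -> data.frame OR CoverageSet.
## Returns nested profiles[[group]][[rep]] for call_sites().
nest_profiles <- function(per_sample, ts) {
  groups <- sub("\\..*$", "", names(per_sample))
  reps <- as.integer(sub("^.*\\.", "", names(per_sample)))
  out <- list()
  for (g in unique(groups)) {
    sel <- which(groups == g)
    sel <- sel[order(reps[sel])]
    out[[g]] <- lapply(sel, function(k) {
      x <- per_sample[[k]]
      if (inherits(x, "CoverageSet")) x else count_reads(x, ts)
    })
  }
  out
}

#' Run the full HAC-seq analysis pipeline
#'
#' Executes every stage behind one call: obtain per-library reads (either by
#' simulating from a planted truth table or by counting alignment/read
#' files from a sample sheet), build coverage profiles, call sites with the
#' three-criterion procedure, and write the report outputs (`calls.tsv`,
#' `called.bed`, `motif_counts.tsv`, `motif_windows.fasta`, `heatmap.tsv`)
#' to `outdir`.
#'
#' @param ts A [transcript_set()] (deduplicated internally).
#' @param samples Either the result of [simulate_experiment()], a named list
#'   `"<group>.<rep>"` of read `data.frame`s, or a sample-sheet
#'   `data.frame(file, group, replicate)` from [read_sample_sheet()].
#' @param config A [calling_config()].
#' @param outdir Output directory, created if needed; `NULL` skips writing.
#' @param flank Motif window flank (bases each side of the site).
#' @param min_mapq,include_reverse Alignment filters, used only when
#'   `samples` is a sample sheet.
#' @return Invisibly, a list with `calls`, `called`, `motif`, `heatmap`,
#'   `profiles`, `transcripts`, and `files` (paths written).
#' @export
run_hacseq <- function(ts, samples, config = calling_config(), outdir = NULL,
                       flank = 3L, min_mapq = 0L, include_reverse = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  ts <- deduplicate(ts)
  stage <- function(msg) {
    if (isTRUE(getOption("hacseq.verbose", TRUE)))
      message(sprintf("[hacseq %6.1fs] %s", proc.time()[["elapsed"]] - t0, msg))
  }

  if (is.list(samples) && !is.data.frame(samples) && !is.null(samples$reads))
    samples <- samples$reads
  if (is.data.frame(samples)) {
    stage("counting alignments from sample sheet")
    per_sample <- lapply(seq_len(nrow(samples)), function(k)
      count_from_alignments(samples$file[k], ts, min_mapq = min_mapq,
                            include_reverse = include_reverse))
    names(per_sample) <- group_key(samples$group, samples$replicate)
  } else {
    stage("counting simulated/preloaded read records")
    per_sample <- samples
  }
  profiles <- nest_profiles(per_sample, ts)

  stage("calling sites")
  calls <- call_sites(profiles, config, ts)
  called <- filter_calls(calls, "called")
  stage(sprintf("%d site(s) called over %d evaluable position(s)",
                nrow(called), sum(calls$status == "ok")))

  motif <- extract_motif_windows(calls, ts, flank = flank)
  hm <- heatmap_table(called)

  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- c(calls = write_calls_tsv(calls, file.path(outdir, "calls.tsv")),
               bed = write_bed(calls, file.path(outdir, "called.bed")),
               motif = write_motif_tsv(motif, file.path(outdir, "motif_counts.tsv")),
               windows = write_windows_fasta(motif, file.path(outdir, "motif_windows.fasta")),
               heatmap = write_heatmap_tsv(hm, file.path(outdir, "heatmap.tsv")))
    stage(paste("report written to", outdir))
  }
  invisible(list(calls = calls, called = called, motif = motif, heatmap = hm,
                 profiles = profiles, transcripts = ts, files = files))
}

#' Load a pipeline configuration from YAML or JSON
#'
#' The file mirrors [calling_config()] field names under `calling:` and
#' [sim_config()] names under `simulation:`; unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A list with `calling` (a `CallingConfig`) and `simulation`
#'   (a list of [sim_config()] overrides, possibly empty).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cal <- raw$calling
  if (!is.null(cal)) {
    unknown <- setdiff(names(cal), names(formals(calling_config)))
    if (length(unknown) > 0)
      stop("unknown calling config key(s): ", paste(unknown, collapse = ", "))
  }
  sim <- raw$simulation
  if (!is.null(sim)) {
    unknown <- setdiff(names(sim), names(formals(sim_config)))
    if (length(unknown) > 0)
      stop("unknown simulation config key(s): ", paste(unknown, collapse = ", "))
  }
  list(calling = do.call(calling_config, if (is.null(cal)) list() else cal),
       simulation = if (is.null(sim)) list() else sim)
}
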