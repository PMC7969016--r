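## Cleavage-ratio computation and three-criterion m3C site calling.

#' Calling configuration
#'
#' Thresholds of the three-criterion procedure. Defaults follow common
#' practice for chemical-cleavage site calling: a site must show (i) a mean
#' cleavage ratio of at least `r_min` in the HAC arm, (ii) a significant
#' (`p < alpha`) increase of at least `fold_min`-fold over the untreated
#' control, and (iii) a significant `fold_min`-fold decrease when the RNA
#' was demethylated before cleavage. All thresholds are inclusive (`>=`).
#' `min_depth` additionally requires the position after the site to be
#' covered in every library, guarding against apparent cleavage in
#' low-coverage regions.
#'
#' @param r_min Minimum mean HAC-arm cleavage ratio (criterion i).
#' @param fold_min Minimum fold change for criteria (ii) and (iii).
#' @param alpha Significance level for both tests.
#' @param min_depth Minimum read depth at position `i + 1` required in every
#'   library for site `i` to be evaluable.
#' @param base_filter If `TRUE`, restrict calls to reference base `C`.
#'   Off by default so the base composition of calls remains a specificity
#'   diagnostic.
#' @param p_adjust `"none"` (raw p-values, the default) or `"BH"`
#'   (Benjamini-Hochberg over all evaluable sites per run).
#' @return An object of class `CallingConfig`.
#' @export
calling_config <- function(r_min = 0.5, fold_min = 2.5, alpha = 0.05,
                           min_depth = 20L, base_filter = FALSE,
                           p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(r_min >= 0, r_min <= 1, fold_min >= 1, alpha > 0, alpha < 1,
            min_depth >= 1)
  structure(list(r_min = r_min, fold_min = fold_min, alpha = alpha,
                 min_depth = as.integer(min_depth),
                 base_filter = isTRUE(base_filter), p_adjust = p_adjust),
            class = "CallingConfig")
}

#' Per-position cleavage-ratio profile
#'
#' The cleavage ratio of site `i` is the number of reads starting at the
#' following position `i + 1` divided by the read depth at `i + 1`:
#' cleavage deletes the modified base and only the 3' fragment, beginning at
#' `i + 1`, survives library preparation. Position `L` has no ratio.
#'
#' @param starts,depth Integer vectors of length `L` (see [count_reads()]),
#'   or `starts` may be a single profile element of a `CoverageSet`.
#' @return Numeric vector of length `L - 1`; `NA` where `depth[i + 1]` is 0
#'   (undefined, excluded from calling).
#' @export
cleavage_ratio_profile <- function(starts, depth = NULL) {
  if (is.list(starts) && is.null(depth)) {
    depth <- starts$depth
    starts <- starts$starts
  }
  L <- length(starts)
  stopifnot(length(depth) == L, L >= 2)
  s <- starts[-1L]
  d <- depth[-1L]
  ifelse(d > 0L, s / d, NA_real_)
}

#' Two-sided unpaired Student's t-test on replicate cleavage ratios
#'
#' Classic equal-variance (pooled) two-sample t-test, applied to the
#' per-replicate cleavage ratios of two groups. Degenerate cases are defined
#' so thresholding stays meaningful at two replicates: if the pooled
#' variance is zero the p-value is 0 when the means differ and 1 when all
#' values are identical. With fewer than two defined values in either group
#' the site is untestable and `NA` is returned (criteria fail closed).
#'
#' @param a,b Numeric vectors of ratios; `NA`s are dropped.
#' @return A p-value in `[0,1]`, or `NA_real_` if untestable.
#' @export
ttest_unpaired <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  if (na < 2L || nb < 2L) return(NA_real_)
  ma <- mean(a)
  mb <- mean(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) return(if (ma == mb) 1 else 0)
  tstat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(tstat), df = na + nb - 2)
}

#' Cleavage ratio from gel band intensities
#'
#' The fraction cleaved as quantified on a northern blot: the intensity of
#' the cleaved band over the sum of cleaved and uncleaved (full-length)
#' bands.
#'
#' @param cleaved,uncleaved Non-negative band intensities.
#' @return A fraction in `[0,1]`.
#' @export
band_cleavage_ratio <- function(cleaved, uncleaved) {
  stopifnot(all(cleaved >= 0), all(uncleaved >= 0))
  tot <- cleaved + uncleaved
  if (any(tot == 0)) stop("no signal: cleaved and uncleaved are both zero")
  cleaved / tot
}

group_key <- function(group, rep_i) paste0(group, ".", rep_i)

## Validate the nested profiles structure and return replicate count.
check_profile_groups <- function(profiles) {
  missing_g <- setdiff(HAC_GROUPS, names(profiles))
  if (length(missing_g) > 0)
    stop("missing group(s): ", paste(missing_g, collapse = ", "))
  reps <- vapply(profiles[HAC_GROUPS], length, integer(1))
  if (length(unique(reps)) != 1L)
    stop("unequal replicate counts across groups: ",
         paste(reps, collapse = ", "))
  if (reps[[1]] < 2L) stop("at least 2 replicates per group are required")
  reps[[1]]
}

#' Call m3C sites with the three-criterion procedure
#'
#' For every transcript position `i` whose following position `i + 1` is
#' covered to at least `min_depth` in every library, per-replicate cleavage
#' ratios are computed in each arm and the three criteria evaluated:
#' `c1`, mean HAC ratio `>= r_min`; `c2`, `fold_min`-fold increase of HAC
#' over Ctrl with `p < alpha`; `c3`, `fold_min`-fold decrease from HAC to
#' DM-HAC with `p < alpha`. A zero denominator passes the fold component
#' when the HAC mean is positive (a site absent from the control is the
#' ideal positive). A site is called iff all three hold; reference base `N`
#' is never callable. Every position is returned with a status (`"ok"` or
#' `"low_depth"`) so nothing is silently dropped.
#'
#' @param profiles Nested list `profiles[[group]][[replicate]]`, each a
#'   `CoverageSet` from [count_reads()]; groups must be exactly `Ctrl`,
#'   `HAC`, `DM-HAC` with equal replicate counts (>= 2).
#' @param config A [calling_config()].
#' @param ts The [transcript_set()] the profiles were counted against.
#' @return A `data.frame` with one row per (transcript, position `1..L-1`):
#'   id, position, reference base, structural label, per-replicate ratio
#'   columns (`Ctrl.1`, ...), group means, fold changes, p-values, criterion
#'   flags `c1`/`c2`/`c3`, `called`, `status`.
#' @export
call_sites <- function(profiles, config = calling_config(), ts) {
  stopifnot(inherits(config, "CallingConfig"), inherits(ts, "TranscriptSet"))
  R <- check_profile_groups(profiles)
  lens <- transcript_lengths(ts)
  sample_names <- unlist(lapply(HAC_GROUPS, function(g) group_key(g, seq_len(R))))

  per_tx <- lapply(names(lens), function(id) {
    L <- lens[[id]]
    if (L < 2L) return(NULL)
    ratio <- matrix(NA_real_, L - 1L, 3L * R,
                    dimnames = list(NULL, sample_names))
    depth_ok <- matrix(FALSE, L - 1L, 3L * R)
    col <- 0L
    for (g in HAC_GROUPS) for (r in seq_len(R)) {
      col <- col + 1L
      prof <- profiles[[g]][[r]][[id]]
      if (is.null(prof))
        stop("transcript '", id, "' missing from group ", g, " replicate ", r)
      ratio[, col] <- cleavage_ratio_profile(prof$starts, prof$depth)
      depth_ok[, col] <- prof$depth[-1L] >= config$min_depth
    }
    evaluable <- rowSums(depth_ok) == ncol(depth_ok)
    idx_c <- seq_len(R)
    idx_h <- R + seq_len(R)
    idx_d <- 2L * R + seq_len(R)
    mean_ctrl <- rowMeans(ratio[, idx_c, drop = FALSE])
    mean_hac <- rowMeans(ratio[, idx_h, drop = FALSE])
    mean_dm <- rowMeans(ratio[, idx_d, drop = FALSE])
    p_inc <- vapply(seq_len(L - 1L), function(i)
      ttest_unpaired(ratio[i, idx_h], ratio[i, idx_c]), numeric(1))
    p_dec <- vapply(seq_len(L - 1L), function(i)
      ttest_unpaired(ratio[i, idx_h], ratio[i, idx_d]), numeric(1))
    base <- substring(ts$sequences[[id]], seq_len(L - 1L), seq_len(L - 1L))
    lab <- position_label(ts, id, seq_len(L - 1L))
    cbind(data.frame(transcript_id = id, position = seq_len(L - 1L),
                     ref_base = base, label = lab, stringsAsFactors = FALSE),
          as.data.frame(ratio),
          data.frame(mean_ctrl = mean_ctrl, mean_hac = mean_hac,
                     mean_dmhac = mean_dm, p_inc = p_inc, p_dec = p_dec,
                     evaluable = evaluable, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, per_tx)
  if (is.null(out) || nrow(out) == 0)
    stop("no transcript of length >= 2 to evaluate")
  rownames(out) <- NULL

  out$fold_increase <- out$mean_hac / out$mean_ctrl
  out$fold_decrease <- out$mean_hac / out$mean_dmhac
  if (config$p_adjust == "BH") {
    out$p_inc_adj <- NA_real_
    out$p_dec_adj <- NA_real_
    out$p_inc_adj[out$evaluable] <- stats::p.adjust(out$p_inc[out$evaluable], "BH")
    out$p_dec_adj[out$evaluable] <- stats::p.adjust(out$p_dec[out$evaluable], "BH")
    p2 <- out$p_inc_adj
    p3 <- out$p_dec_adj
  } else {
    p2 <- out$p_inc
    p3 <- out$p_dec
  }

  fold_up_ok <- (out$mean_ctrl == 0 & out$mean_hac > 0) |
    (!is.na(out$fold_increase) & out$fold_increase >= config$fold_min)
  fold_dn_ok <- (out$mean_dmhac == 0 & out$mean_hac > 0) |
    (!is.na(out$fold_decrease) & out$fold_decrease >= config$fold_min)

  out$c1 <- out$mean_hac >= config$r_min
  out$c2 <- fold_up_ok & !is.na(p2) & p2 < config$alpha
  out$c3 <- fold_dn_ok & !is.na(p3) & p3 < config$alpha
  out$called <- out$c1 & out$c2 & out$c3 & out$ref_base != "N"
  if (config$base_filter) out$called <- out$called & out$ref_base == "C"

  low <- !out$evaluable
  out$c1[low] <- NA
  out$c2[low] <- NA
  out$c3[low] <- NA
  out$called[low] <- FALSE
  out$status <- ifelse(out$evaluable, "ok", "low_depth")
  out$evaluable <- NULL
  out
}

#' Restrict a call table to evaluable or called rows
#'
#' @param calls Output of [call_sites()].
#' @param what `"called"` or `"evaluable"`.
#' @return The filtered `data.frame`.
#' @export
filter_calls <- function(calls, what = c("called", "evaluable")) {
  what <- match.arg(what)
  if (what == "called") calls[which(calls$called), , drop = FALSE]
  else calls[calls$status == "ok", , drop = FALSE]
}
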