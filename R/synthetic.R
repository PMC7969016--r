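## Synthetic tRNA-like references with a planted m3C site map.
##
## Thirteen tRNA-length sequences named after the human isoacceptors known
## to carry m3C, with 17 modifiable cytidines at the structural positions
## where the mark occurs in vivo: the anticodon loop (C32), the variable
## loop (C47d, on serine/leucine tRNAs with a long variable arm) and the D
## loop (C20, initiator-adjacent methionine). Sequences are synthetic:
## random RNA of realistic length with the site's local sequence context
## set to the GGNCU motif characteristic of m3C. They are NOT the real
## GtRNAdb sequences and carry no other modification chemistry.

SYNTH_TRNA_TABLE <- data.frame(
  id = c("tRNA-SerAGA", "tRNA-SerCGA", "tRNA-SerGCT", "tRNA-SerTGA",
         "tRNA-ArgCCT", "tRNA-ArgTCT", "tRNA-ThrAGT", "tRNA-ThrCGT",
         "tRNA-ThrTGT", "tRNA-LeuCAG", "tRNA-MetCAT",
         "mt-tRNA-SerTGA", "mt-tRNA-ThrTGT"),
  length = c(85L, 85L, 85L, 85L, 76L, 76L, 76L, 76L, 76L, 87L, 76L, 72L, 72L),
  stringsAsFactors = FALSE)

SYNTH_SITE_TABLE <- data.frame(
  id = c("tRNA-SerAGA", "tRNA-SerAGA", "tRNA-SerCGA", "tRNA-SerCGA",
         "tRNA-SerGCT", "tRNA-SerGCT", "tRNA-SerTGA", "tRNA-SerTGA",
         "tRNA-ArgCCT", "tRNA-ArgTCT", "tRNA-ThrAGT", "tRNA-ThrCGT",
         "tRNA-ThrTGT", "tRNA-LeuCAG", "tRNA-MetCAT",
         "mt-tRNA-SerTGA", "mt-tRNA-ThrTGT"),
  position = c(32L, 48L, 32L, 48L, 32L, 48L, 32L, 48L,
               32L, 32L, 32L, 32L, 32L, 48L, 20L, 32L, 32L),
  label = c("32", "47d", "32", "47d", "32", "47d", "32", "47d",
            "32", "32", "32", "32", "32", "47d", "20", "32", "32"),
  stoichiometry = c(0.85, 0.80, 0.85, 0.80, 0.85, 0.80, 0.85, 0.80,
                    0.90, 0.90, 0.98, 0.98, 0.98, 0.90, 0.75, 0.80, 0.95),
  stringsAsFactors = FALSE)

with_fixed_rng <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(list = ".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' Synthetic tRNA reference set with structural labels
#'
#' Thirteen synthetic tRNA-length transcripts (11 cytoplasmic, 2
#' mitochondrial) named after m3C-carrying human isoacceptors, with
#' structural position labels (`"32"`, `"47d"`, `"20"`) attached at the 17
#' modifiable cytidines. Each site sits in a planted `GGNCU` context so
#' motif extraction has a known answer. The sequences are generated from a
#' fixed internal seed and are fully reproducible; they are synthetic
#' stand-ins, not database tRNA sequences.
#'
#' @return A [transcript_set()] of category `"tRNA"`.
#' @export
synthetic_trna_set <- function() {
  with_fixed_rng(180973L, {
    seqs <- vapply(seq_len(nrow(SYNTH_TRNA_TABLE)), function(k) {
      L <- SYNTH_TRNA_TABLE$length[k]
      s <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
      sites <- SYNTH_SITE_TABLE[SYNTH_SITE_TABLE$id == SYNTH_TRNA_TABLE$id[k], ]
      for (p in sites$position) {
        s[p - 3L] <- "G"; s[p - 2L] <- "G"           # GGNCU context
        s[p] <- "C"; s[p + 1L] <- "U"
      }
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- SYNTH_TRNA_TABLE$id
    labels <- split(stats::setNames(SYNTH_SITE_TABLE$label,
                                    SYNTH_SITE_TABLE$position),
                    SYNTH_SITE_TABLE$id)
    transcript_set(seqs, category = "tRNA", labels = labels[names(seqs)[names(seqs) %in% names(labels)]])
  })
}

#' Planted m3C truth table for the synthetic tRNA set
#'
#' Seventeen sites mirroring the field's canonical m3C map: C32 and C47d on
#' all four serine isoacceptors, single C32 sites on the arginine,
#' threonine and mitochondrial tRNAs, C47d on leucine, C20 on methionine.
#' Default stoichiometries are high (0.75-0.98), demethylation is complete
#' (`d = 1`), and cleavage uses the global efficiency.
#'
#' @param alkb_resistant_ser Model the demethylase-resistant behaviour of
#'   C32 on A36-serine isoacceptors (SerAGA, SerCGA, SerTGA) by setting
#'   their `d` to 0: such sites cleave in both HAC and DM-HAC arms and must
#'   fail criterion (iii).
#' @param low_stoich_mt Plant `mt-tRNA-SerTGA` C32 at stoichiometry 0.35,
#'   below the default cleavage-ratio cutoff, so it must fail criterion (i).
#' @return A [modification_truth()] table.
#' @export
synthetic_m3c_truth <- function(alkb_resistant_ser = FALSE,
                                low_stoich_mt = FALSE) {
  tab <- SYNTH_SITE_TABLE
  d <- rep(1, nrow(tab))
  if (alkb_resistant_ser) {
    res <- tab$id %in% c("tRNA-SerAGA", "tRNA-SerCGA", "tRNA-SerTGA") &
      tab$label == "32"
    d[res] <- 0
  }
  s <- tab$stoichiometry
  if (low_stoich_mt) s[tab$id == "mt-tRNA-SerTGA"] <- 0.35
  modification_truth(tab$id, tab$position, s, demethylation = d)
}
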