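#' In silico proteolytic digestion
#'
#' Digests a protein sequence with trypsin (cleaves C-terminal to K/R not
#' followed by P) or Glu-C (cleaves C-terminal to E, optionally also D).
#' When the modification blocks cleavage (e.g. lysine acetylation vs
#' trypsin), peptides spanning otherwise-cleavable target residues are also
#' produced, up to `max_mods` blocked sites: those longer forms only exist
#' for modification patterns that actually occupy the spanned sites, which
#' [enumerate_isomers()] and [count_identifiable()] enforce per isomer via
#' the `blockable_internal` annotation.  Missed cleavages are counted on
#' sites that cannot be blocked by a modification.
#'
#' @param sequence Uppercase protein sequence string.
#' @param enzyme `"trypsin"` or `"glu-c"`.
#' @param missed_cleavages Maximum number of missed (unblockable or
#'   unmodified) internal cleavage sites per peptide.
#' @param min_length,max_length Peptide length bounds (residues).
#' @param modification A [modification()]; eligible sites are annotated per
#'   peptide and `blocks_cleavage` governs blocked-form generation.
#' @param max_mods Maximum modifications available to block internal
#'   cleavage sites (0 disables blocked forms and yields the plain
#'   enzymatic digest).
#' @param cleave_d For Glu-C, also cleave after D.
#' @return A data.frame sorted by (start, end) with columns `start`, `end`
#'   (protein coordinates), `peptide`, `n_sites`, and list columns `sites`
#'   (eligible modification sites, peptide coordinates) and
#'   `blockable_internal` (internal cleavage sites a modification could
#'   block, peptide coordinates); `n_missed` counts internal sites that no
#'   modification can block.
#' @examples
#' digest("AKRPGKE", "trypsin", min_length = 1)
#' digest("AEGEDK", "glu-c", min_length = 1)
#' @export
digest <- function(sequence, enzyme = c("trypsin", "glu-c"),
                   missed_cleavages = 0L, min_length = 2L,
                   max_length = Inf, modification = acetylation(),
                   max_mods = 0L, cleave_d = FALSE) {
  enzyme <- match.arg(enzyme)
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence))
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)

  cleave_after <- switch(enzyme,
    trypsin = which(res %in% c("K", "R") &
                      c(res[-1] != "P", TRUE)),
    `glu-c` = which(res %in% if (cleave_d) c("E", "D") else "E")
  )
  cleave_after <- setdiff(cleave_after, n)  # C-terminus is a boundary anyway
  blockable_res <- if (modification$blocks_cleavage) {
    intersect(modification$target_residues,
              switch(enzyme, trypsin = c("K", "R"), `glu-c` = c("E", "D")))
  } else character(0)

  bounds <- c(0L, cleave_after, n)  # peptide (i, j]: bounds i < j
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  k <- length(starts)

  rows <- list()
  for (i in seq_len(k)) {
    for (j in i:k) {
      s <- starts[i]; e <- ends[j]
      internal <- cleave_after[cleave_after >= s & cleave_after < e]
      blockable <- internal[res[internal] %in% blockable_res]
      hard_missed <- length(internal) - length(blockable)
      if (hard_missed > missed_cleavages) break
      # even with every available modification blocking, remaining missed
      # blockable sites must fit the budget
      if (hard_missed + max(0L, length(blockable) - max_mods) >
          missed_cleavages) next
      len <- e - s + 1L
      if (len < min_length || len > max_length) next
      pep <- substr(sequence, s, e)
      sites <- which(strsplit(pep, "", fixed = TRUE)[[1]] %in%
                       modification$target_residues)
      rows[[length(rows) + 1L]] <- data.frame(
        start = s, end = e, peptide = pep, n_sites = length(sites),
        n_missed = hard_missed,
        sites = I(list(sites)),
        blockable_internal = I(list(blockable - s + 1L))
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      peptide = character(), n_sites = integer(),
                      n_missed = integer(), sites = I(list()),
                      blockable_internal = I(list())))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
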