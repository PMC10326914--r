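#' Enumerate combinatorial modification isomers of a peptide
#'
#' Places `m` copies of a modification on the eligible sites of a peptide in
#' every possible way, producing the complete set of `choose(k, m)`
#' positional isomers.  All isomers share the same precursor mass; only the
#' fragment-level evidence can tell them apart.
#'
#' @param peptide Sequence string or [modified_peptide()] scaffold
#'   (unmodified).
#' @param modification The [modification()] to place; default
#'   [acetylation()].
#' @param m Number of modification copies (0 <= m <= number of eligible
#'   sites).
#' @param sites Eligible site indices (peptide coordinates).  Default: every
#'   residue in the modification's target set.
#' @param parent_offset Protein position of peptide residue 1, for labels.
#' @param labels Optional character vector naming each isomer (in
#'   lexicographic site-combination order); default labels are built with
#'   [isomer_label()].
#' @return An object of class `isomer_set`: list with elements `sequence`,
#'   `modification`, `m`, `sites`, `site_combinations`, `isomers` (list of
#'   [modified_peptide()]), `labels`.
#' @examples
#' iso <- enumerate_isomers("GKGGKGLGKGGAKR", m = 2, parent_offset = 4)
#' length(iso$isomers)  # choose(4, 2) = 6
#' @export
enumerate_isomers <- function(peptide, modification = acetylation(), m,
                              sites = NULL, parent_offset = 1L,
                              labels = NULL) {
  sequence <- if (inherits(peptide, "modified_peptide")) {
    parent_offset <- peptide$parent_offset
    peptide$sequence
  } else peptide
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (is.null(sites)) {
    sites <- which(res %in% modification$target_residues)
  }
  sites <- sort(as.integer(sites))
  k <- length(sites)
  m <- as.integer(m)
  if (m < 0L || m > k) {
    stop(sprintf("m = %d but peptide has %d eligible sites", m, k),
         call. = FALSE)
  }
  # combn emits combinations in lexicographic order; guard the scalar-x
  # case where combn(x, m) would expand x to seq_len(x)
  combos <- if (m == 0L) {
    list(integer(0))
  } else if (length(sites) == 1L) {
    list(sites)
  } else {
    asplit(utils::combn(sites, m), 2L)
  }
  combos <- lapply(combos, as.integer)
  isomers <- lapply(combos, function(cc) {
    modified_peptide(sequence, cc, modification, parent_offset)
  })
  if (is.null(labels)) {
    labels <- vapply(isomers, isomer_label, character(1))
  }
  stopifnot(length(labels) == length(isomers))
  structure(
    list(sequence = sequence, modification = modification, m = m,
         sites = sites, site_combinations = combos, isomers = isomers,
         labels = labels),
    class = "isomer_set"
  )
}

#' @export
print.isomer_set <- function(x, ...) {
  cat(sprintf("<isomer_set> %s: %d x %s on sites {%s} -> %d isomers\n",
              x$sequence, x$m, x$modification$name,
              paste(x$sites, collapse = ","), length(x$isomers)))
  cat(" ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Subset an isomer set by label
#'
#' @param iso_set An [enumerate_isomers()] result.
#' @param labels Labels of the isomers to keep, in the requested order.
#' @return A smaller `isomer_set`.
#' @export
subset_isomers <- function(iso_set, labels) {
  idx <- match(labels, iso_set$labels)
  if (anyNA(idx)) {
    stop("unknown isomer label(s): ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  iso_set$site_combinations <- iso_set$site_combinations[idx]
  iso_set$isomers <- iso_set$isomers[idx]
  iso_set$labels <- iso_set$labels[idx]
  iso_set
}

#' The diacetylated histone H4 4-17 benchmark isomers
#'
#' The tryptic histone H4 peptide 4-17 (GKGGKGLGKGGAKR, lysines at protein
#' positions 5, 8, 12 and 16) carrying two acetyl groups is the classic
#' hard case for positional-isomer analysis: its six diacetylated forms are
#' conventionally numbered P1 = K5/K16, P2 = K8/K12, P3 = K5/K12,
#' P4 = K8/K16, P5 = K5/K8 and P6 = K12/K16.  In any mixture of P1-P4, P4
#' yields no isomer-unique fragment at all, yet it does yield a unique
#' fragment-fragment correlation.
#'
#' @param labels Which isomers to include (default all six).
#' @return An `isomer_set` with the conventional P labels.
#' @examples
#' h4_diacetyl_isomers(c("P1", "P2", "P3", "P4"))
#' @export
h4_diacetyl_isomers <- function(labels = paste0("P", 1:6)) {
  iso <- enumerate_isomers("GKGGKGLGKGGAKR", acetylation(), m = 2L,
                           parent_offset = 4L)
  # lexicographic combination order: {2,5} {2,9} {2,13} {5,9} {5,13} {9,13}
  # = K5/K8,  K5/K12, K5/K16, K8/K12, K8/K16, K12/K16
  iso$labels <- c("P5", "P3", "P1", "P2", "P4", "P6")
  subset_isomers(iso, labels)
}
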