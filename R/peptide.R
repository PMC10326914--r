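#' Construct a modified peptide (one combinatorial isomer)
#'
#' A `modified_peptide` is a residue sequence plus a specific assignment of
#' modifications to sites, i.e. one positional isomer.  Site indices are
#' 1-based peptide coordinates; `parent_offset` maps residue 1 to its
#' position in the parent protein so that display labels use protein
#' numbering (e.g. the histone H4 4-17 peptide has `parent_offset = 4` and
#' its lysines at peptide sites 2, 5, 9, 13 are labelled K5, K8, K12, K16).
#'
#' @param sequence Uppercase residue string.
#' @param mod_sites Integer vector of modified site indices (all carrying
#'   `modification`), or a list of [modification()] objects named by site
#'   index for mixed modifications.
#' @param modification The [modification()] applied at `mod_sites` when they
#'   are given as an integer vector.  Default: [acetylation()].
#' @param parent_offset Protein position of peptide residue 1 (display only).
#' @return An object of class `modified_peptide`.
#' @examples
#' # the K8/K16 diacetylated histone H4 4-17 isomer
#' modified_peptide("GKGGKGLGKGGAKR", c(5, 13), parent_offset = 4)
#' @export
modified_peptide <- function(sequence, mod_sites = integer(),
                             modification = acetylation(),
                             parent_offset = 1L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  .sequence_masses(sequence)  # validates residue codes
  n <- length(res)

  if (is.numeric(mod_sites)) {
    sites <- as.integer(mod_sites)
    mods <- stats::setNames(rep(list(modification), length(sites)),
                            as.character(sites))
  } else if (is.list(mod_sites)) {
    sites <- as.integer(names(mod_sites))
    mods <- stats::setNames(mod_sites, as.character(sites))
  } else {
    stop("mod_sites must be an integer vector or a named list", call. = FALSE)
  }
  if (anyDuplicated(sites)) stop("duplicate modification sites", call. = FALSE)
  if (any(sites < 1L | sites > n)) {
    stop("modification site outside [1, ", n, "]", call. = FALSE)
  }
  for (s in sites) {
    mod <- mods[[as.character(s)]]
    if (!inherits(mod, "modification")) {
      stop("mod_sites entries must be modification objects", call. = FALSE)
    }
    if (!res[s] %in% mod$target_residues) {
      stop(sprintf("residue %s at site %d is not a valid target for %s",
                   res[s], s, mod$name), call. = FALSE)
    }
  }
  ord <- order(sites)
  structure(
    list(sequence = sequence, residues = res, parent_offset = parent_offset,
         mod_sites = mods[ord]),
    class = "modified_peptide"
  )
}

#' @export
print.modified_peptide <- function(x, ...) {
  cat(sprintf("<modified_peptide> %s (n=%d) %s\n", x$sequence,
              length(x$residues),
              if (length(x$mod_sites)) isomer_label(x) else "unmodified"))
  invisible(x)
}

# integer vector of modified site indices (peptide coordinates)
mod_site_indices <- function(p) as.integer(names(p$mod_sites))

#' Protein-coordinate label of an isomer's modification pattern
#'
#' @param p A [modified_peptide()].
#' @return A string like `"K8ac/K16ac"` using protein numbering.
#' @export
isomer_label <- function(p) {
  sites <- mod_site_indices(p)
  if (length(sites) == 0L) return("unmodified")
  paste(vapply(sites, function(s) {
    mod <- p$mod_sites[[as.character(s)]]
    sprintf("%s%d%s", p$residues[s], s + p$parent_offset - 1L,
            substr(mod$name, 1L, 2L))
  }, character(1)), collapse = "/")
}

#' Monoisotopic neutral mass of a modified peptide
#'
#' Sum of residue masses, plus one water for the intact termini, plus all
#' modification mass shifts.
#'
#' @param p A [modified_peptide()] or a plain sequence string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_neutral_mass("GKGGKGLGKGGAKR")  # 1269.763
#' @export
peptide_neutral_mass <- function(p) {
  if (is.character(p)) p <- modified_peptide(p)
  sum(.sequence_masses(p$sequence)) + WATER_MASS +
    sum(vapply(p$mod_sites, `[[`, numeric(1), "delta_mass"))
}
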