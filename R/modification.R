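#' Define a covalent modification
#'
#' A modification is a named monoisotopic mass shift restricted to a set of
#' target residues.  `blocks_cleavage` records whether the modification
#' abolishes enzymatic cleavage at the modified residue, as lysine
#' acetylation does for trypsin.
#'
#' @param name Modification name (free text, used in labels).
#' @param delta_mass Monoisotopic mass shift in Da.
#' @param target_residues Character vector of single-letter residue codes the
#'   modification can occupy.
#' @param blocks_cleavage Logical; does the modification suppress enzymatic
#'   cleavage at the modified residue?
#' @return An object of class `modification`.
#' @examples
#' acetylation()
#' modification("trimethyl", 42.04695, "K", blocks_cleavage = TRUE)
#' @export
modification <- function(name, delta_mass, target_residues,
                         blocks_cleavage = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(delta_mass) || length(delta_mass) != 1L ||
      !is.finite(delta_mass)) {
    stop("delta_mass must be a single finite number (Da)", call. = FALSE)
  }
  target_residues <- unique(as.character(target_residues))
  if (length(target_residues) == 0L) {
    stop("target_residues must be non-empty", call. = FALSE)
  }
  structure(
    list(name = name, delta_mass = delta_mass,
         target_residues = target_residues,
         blocks_cleavage = isTRUE(blocks_cleavage)),
    class = "modification"
  )
}

#' @rdname modification
#' @details `acetylation()` is the built-in default: +42.010565 Da on lysine,
#'   blocking tryptic cleavage at the acetylated residue.
#' @export
acetylation <- function() {
  modification("acetyl", 42.010565, "K", blocks_cleavage = TRUE)
}

#' @export
print.modification <- function(x, ...) {
  cat(sprintf("<modification> %s: %+.6f Da on {%s}%s\n", x$name,
              x$delta_mass, paste(x$target_residues, collapse = ","),
              if (x$blocks_cleavage) ", blocks cleavage" else ""))
  invisible(x)
}

#' Load modification definitions from a YAML config file
#'
#' The file holds one mapping per modification:
#' ```
#' acetyl:
#'   delta_mass: 42.010565
#'   target_residues: K
#'   blocks_cleavage: true
#' ```
#'
#' @param path Path to a YAML file.
#' @return Named list of [modification()] objects.
#' @export
read_modification_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg))) {
    stop("modification config must be a named mapping", call. = FALSE)
  }
  lapply(stats::setNames(names(cfg), names(cfg)), function(nm) {
    entry <- cfg[[nm]]
    modification(
      name = nm,
      delta_mass = as.numeric(entry$delta_mass),
      target_residues = unlist(strsplit(as.character(entry$target_residues),
                                        "[, ]+")),
      blocks_cleavage = isTRUE(entry$blocks_cleavage)
    )
  })
}
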