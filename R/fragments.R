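#' Backbone fragment masses of a modified peptide
#'
#' Fragment kinds follow ion-trap CID nomenclature: `b` and `y` terminal
#' ions, and internal ions produced by two backbone cleavages.  An internal
#' b-type ion (`internal_b`) carries neither terminal group (no water); an
#' internal a-type ion (`internal_a`) additionally loses CO.  A fragment is
#' identified by its inclusive 1-based residue span `(start, end)` in
#' peptide coordinates: `b_i` spans `(1, i)` with `i < n`, `y_j` spans
#' `(n - j + 1, n)`, and internal spans satisfy
#' `2 <= start < end <= n - 1` (length at least 2).  Modifications falling
#' inside the span are retained and shift the fragment mass.
#'
#' @param p A [modified_peptide()] (or plain sequence string).
#' @param kind One of `"b"`, `"y"`, `"internal_b"`, `"internal_a"`.
#' @param start,end Inclusive residue span in peptide coordinates.
#' @param charge Positive integer charge state.
#' @return `fragment_neutral_mass()` returns the neutral monoisotopic mass
#'   in Da; `fragment_mz()` the mass-to-charge ratio in Th,
#'   `(neutral + charge * proton) / charge`.
#' @examples
#' p4 <- modified_peptide("GKGGKGLGKGGAKR", c(5, 13), parent_offset = 4)
#' fragment_mz(p4, "internal_b", 3, 8)  # 512.28, the GGK(ac)GLG marker
#' fragment_mz(p4, "y", 10, 14)         # 530.30, the GGAK(ac)R y5 marker
#' @export
fragment_neutral_mass <- function(p, kind, start, end) {
  if (is.character(p)) p <- modified_peptide(p)
  n <- length(p$residues)
  .check_span(kind, start, end, n)
  masses <- .sequence_masses(p$sequence)
  m <- sum(masses[start:end])
  sites <- mod_site_indices(p)
  keep <- sites >= start & sites <= end
  if (any(keep)) {
    m <- m + sum(vapply(p$mod_sites[keep], `[[`, numeric(1), "delta_mass"))
  }
  switch(kind,
    b = m,
    y = m + WATER_MASS,
    internal_b = m,
    internal_a = m - CO_MASS,
    stop("unknown fragment kind: ", kind, call. = FALSE)
  )
}

#' @rdname fragment_neutral_mass
#' @export
fragment_mz <- function(p, kind, start, end, charge = 1L) {
  if (charge < 1L) stop("charge must be >= 1", call. = FALSE)
  (fragment_neutral_mass(p, kind, start, end) + charge * PROTON_MASS) / charge
}

.check_span <- function(kind, start, end, n) {
  ok <- switch(kind,
    b = start == 1L && end >= 1L && end < n,
    y = start > 1L && end == n,
    internal_b = ,
    internal_a = start >= 2L && end > start && end <= n - 1L,
    stop("unknown fragment kind: ", kind, call. = FALSE)
  )
  if (!ok) {
    stop(sprintf("invalid %s span (%d, %d) for peptide length %d",
                 kind, start, end, n), call. = FALSE)
  }
  invisible(TRUE)
}

#' Exhaustive backbone fragment enumeration
#'
#' Generates the complete, duplicate-free set of backbone fragments of the
#' requested kinds at charges `1..max_charge`: all `b_i` and `y_j` for
#' `i, j = 1..n-1` and all internal spans `(start, end)` with
#' `2 <= start < end <= n - 1`.  Neutral losses, immonium ions and isotope
#' peaks are deliberately not enumerated.
#'
#' @inheritParams fragment_neutral_mass
#' @param kinds Character vector from `c("b", "y", "internal_b",
#'   "internal_a")`.
#' @param max_charge Fragments are emitted at every charge `1..max_charge`.
#' @return A data.frame with columns `kind`, `start`, `end`, `charge`,
#'   `n_mods` (modifications retained in the span), `neutral_mass`, `mz`,
#'   sorted by (kind, start, end, charge).
#' @examples
#' nrow(generate_fragments("GKGGKGLGKGGAKR"))                    # 26 b/y ions
#' nrow(generate_fragments("GKGGKGLGKGGAKR", "internal_b"))      # 66 internals
#' @export
generate_fragments <- function(p, kinds = c("b", "y"), max_charge = 1L) {
  if (is.character(p)) p <- modified_peptide(p)
  n <- length(p$residues)
  if (n < 2L) stop("peptide must have at least 2 residues", call. = FALSE)
  kinds <- match.arg(kinds, c("b", "y", "internal_b", "internal_a"),
                     several.ok = TRUE)
  masses <- .sequence_masses(p$sequence)
  sites <- mod_site_indices(p)
  deltas <- vapply(p$mod_sites, `[[`, numeric(1), "delta_mass")
  # cumulative residue+mod mass so any span is a difference of two prefixes
  per_res <- masses
  if (length(sites)) per_res[sites] <- per_res[sites] + deltas
  prefix <- c(0, cumsum(per_res))
  span_mass <- function(s, e) prefix[e + 1L] - prefix[s]
  n_mods_in <- function(s, e) {
    if (length(sites) == 0L) return(integer(length(s)))
    mapply(function(a, b) sum(sites >= a & sites <= b), s, e)
  }

  spans <- list()
  if ("b" %in% kinds) {
    spans$b <- data.frame(kind = "b", start = 1L, end = seq_len(n - 1L))
  }
  if ("y" %in% kinds) {
    spans$y <- data.frame(kind = "y", start = seq(2L, n), end = n)
  }
  for (ik in intersect(c("internal_a", "internal_b"), kinds)) {
    if (n >= 4L) {
      se <- expand.grid(start = 2L:(n - 2L), end = 3L:(n - 1L))
      se <- se[se$end > se$start, , drop = FALSE]
      spans[[ik]] <- data.frame(kind = ik, start = se$start, end = se$end)
    }
  }
  out <- do.call(rbind, unname(spans))
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(kind = character(), start = integer(), end = integer(),
                      charge = integer(), n_mods = integer(),
                      neutral_mass = numeric(), mz = numeric()))
  }
  out$neutral_mass <- span_mass(out$start, out$end)
  out$neutral_mass <- out$neutral_mass +
    ifelse(out$kind == "y", WATER_MASS, 0) -
    ifelse(out$kind == "internal_a", CO_MASS, 0)
  out$n_mods <- n_mods_in(out$start, out$end)
  out <- out[rep(seq_len(nrow(out)), each = max_charge), , drop = FALSE]
  out$charge <- rep(seq_len(max_charge), length.out = nrow(out))
  out$mz <- (out$neutral_mass + out$charge * PROTON_MASS) / out$charge
  out <- out[order(out$kind, out$start, out$end, out$charge), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[c("kind", "start", "end", "charge", "n_mods", "neutral_mass", "mz")]
}
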