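#' Fragment and correlation signatures of an isomer set
#'
#' `signature_1d()` lists, per isomer, every fragment m/z the isomer can
#' produce (the information available to standard 1D MS/MS).
#' `signature_2d()` lists, per isomer, every unordered pair of fragment m/z
#' values whose fragments have disjoint residue spans and can therefore be
#' produced together from a single precursor dissociation (the information
#' a partial-covariance map reads out).  Terminal/terminal pairs are b x y
#' with non-overlapping spans (including complementary pairs);
#' terminal/internal pairs combine a b or y ion with a disjoint internal
#' ion.  Internal/internal pairs are not enumerated.
#'
#' @param iso_set An [enumerate_isomers()] result.
#' @param kinds Fragment kinds for the 1D signature (default terminal b/y;
#'   add `"internal_b"` to include internal marker ions).
#' @param pair_kinds Which correlation classes to enumerate.
#' @param internal_kind Internal ion type used in terminal/internal pairs.
#' @param max_charge Fragments enumerated at charges `1..max_charge`.
#' @return `signature_1d()`: named list (by isomer label) of sorted unique
#'   m/z vectors.  `signature_2d()`: named list of data.frames with columns
#'   `mz_lo`, `mz_hi` (canonical order, `mz_lo <= mz_hi`), one row per
#'   distinct pair.
#' @examples
#' iso <- h4_diacetyl_isomers(c("P1", "P2", "P3", "P4"))
#' sig <- signature_1d(iso)
#' any(abs(sig$P4 - 530.3045) < 0.01)  # acetylated y5 present in P4
#' @export
signature_1d <- function(iso_set, kinds = c("b", "y"), max_charge = 1L) {
  sigs <- lapply(iso_set$isomers, function(p) {
    fr <- generate_fragments(p, kinds = kinds, max_charge = max_charge)
    sort(unique(round(fr$mz, 6L)))
  })
  stats::setNames(sigs, iso_set$labels)
}

#' @rdname signature_1d
#' @export
signature_2d <- function(iso_set,
                         pair_kinds = c("terminal/terminal",
                                        "terminal/internal"),
                         internal_kind = "internal_b", max_charge = 1L) {
  pair_kinds <- match.arg(pair_kinds, several.ok = TRUE)
  sigs <- lapply(iso_set$isomers, function(p) {
    .correlation_pairs(p, pair_kinds, internal_kind, max_charge)
  })
  stats::setNames(sigs, iso_set$labels)
}

# all disjoint-span fragment pairs of one isomer, canonical + deduplicated
.correlation_pairs <- function(p, pair_kinds, internal_kind, max_charge) {
  term <- generate_fragments(p, kinds = c("b", "y"),
                             max_charge = max_charge)
  a <- numeric(0); b <- numeric(0)
  if ("terminal/terminal" %in% pair_kinds) {
    bs <- term[term$kind == "b", ]
    ys <- term[term$kind == "y", ]
    if (nrow(bs) && nrow(ys)) {
      g <- expand.grid(i = seq_len(nrow(bs)), j = seq_len(nrow(ys)))
      ok <- ys$start[g$j] > bs$end[g$i]  # disjoint spans
      a <- c(a, bs$mz[g$i[ok]]); b <- c(b, ys$mz[g$j[ok]])
    }
  }
  if ("terminal/internal" %in% pair_kinds) {
    int <- generate_fragments(p, kinds = internal_kind,
                              max_charge = max_charge)
    if (nrow(int) && nrow(term)) {
      g <- expand.grid(i = seq_len(nrow(term)), j = seq_len(nrow(int)))
      ok <- int$start[g$j] > term$end[g$i] |  # terminal b left of internal
        term$start[g$i] > int$end[g$j]        # terminal y right of internal
      a <- c(a, term$mz[g$i[ok]]); b <- c(b, int$mz[g$j[ok]])
    }
  }
  lo <- round(pmin(a, b), 6L); hi <- round(pmax(a, b), 6L)
  pairs <- unique(data.frame(mz_lo = lo, mz_hi = hi))
  pairs <- pairs[order(pairs$mz_lo, pairs$mz_hi), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Find isomer-unique marker ions and marker ion correlations
#'
#' A fragment m/z (mode `"1d"`) or an unordered m/z pair (mode `"2d"`) is a
#' *marker* for an isomer when no other isomer in the set produces a signal
#' matching it within `tolerance` (both coordinates, for pairs).
#' Combinatorial isomer degeneracy is exact -- degenerate fragments share
#' identical elemental composition -- so the default tolerance is a pure
#' numerical guard, not an instrument resolution.
#'
#' @inheritParams signature_1d
#' @inheritParams signature_2d
#' @param mode `"1d"` (marker ions) or `"2d"` (marker ion correlations).
#' @param tolerance Match tolerance in Th (must be positive).
#' @return An object of class `marker_report`: list with `summary` (one row
#'   per isomer: `label`, `n_signals`, `n_unique`, `identifiable`) and
#'   `unique` (per isomer, the unique m/z vector or unique-pair
#'   data.frame), plus `mode` and `tolerance`.
#' @examples
#' iso <- h4_diacetyl_isomers(c("P1", "P2", "P3", "P4"))
#' find_unique_markers(iso, "2d")$summary
#' @export
find_unique_markers <- function(iso_set, mode = c("1d", "2d"),
                                tolerance = 1e-6,
                                kinds = c("b", "y"),
                                pair_kinds = c("terminal/terminal",
                                               "terminal/internal"),
                                internal_kind = "internal_b",
                                max_charge = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop("tolerance must be positive", call. = FALSE)
  }
  if (length(iso_set$isomers) < 2L) {
    stop("uniqueness analysis needs at least 2 isomers", call. = FALSE)
  }
  labels <- iso_set$labels
  if (mode == "1d") {
    sigs <- signature_1d(iso_set, kinds = kinds, max_charge = max_charge)
    uniq <- lapply(seq_along(sigs), function(i) {
      others <- sort(unlist(sigs[-i], use.names = FALSE))
      v <- sigs[[i]]
      v[!.has_match(v, others, tolerance)]
    })
    n_sig <- vapply(sigs, length, integer(1))
    n_unq <- vapply(uniq, length, integer(1))
  } else {
    sigs <- signature_2d(iso_set, pair_kinds = pair_kinds,
                         internal_kind = internal_kind,
                         max_charge = max_charge)
    uniq <- lapply(seq_along(sigs), function(i) {
      mine <- sigs[[i]]
      keep <- rep(TRUE, nrow(mine))
      for (j in seq_along(sigs)[-i]) {
        keep <- keep & !.has_pair_match(mine, sigs[[j]], tolerance)
      }
      mine[keep, , drop = FALSE]
    })
    n_sig <- vapply(sigs, nrow, integer(1))
    n_unq <- vapply(uniq, nrow, integer(1))
  }
  structure(
    list(summary = data.frame(label = labels, n_signals = unname(n_sig),
                              n_unique = unname(n_unq),
                              identifiable = unname(n_unq > 0L)),
         unique = stats::setNames(uniq, labels),
         signatures = sigs, mode = mode, tolerance = tolerance),
    class = "marker_report"
  )
}

#' @export
print.marker_report <- function(x, ...) {
  cat(sprintf("<marker_report> mode %s, tolerance %g Th\n", x$mode,
              x$tolerance))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# which elements of v have a neighbour in sorted vector 'ref' within tol
.has_match <- function(v, ref, tol) {
  if (length(ref) == 0L || length(v) == 0L) return(rep(FALSE, length(v)))
  idx <- findInterval(v, ref)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(ref))
  (abs(v - ref[lo]) <= tol) | (abs(v - ref[hi]) <= tol)
}

# rows of 'mine' matched by some row of 'other' within tol on both coords;
# tolerance-width hash buckets prune candidates, then exact verification
.has_pair_match <- function(mine, other, tol) {
  if (nrow(mine) == 0L) return(logical(0))
  if (nrow(other) == 0L) return(rep(FALSE, nrow(mine)))
  okey <- paste(floor(other$mz_lo / tol), floor(other$mz_hi / tol))
  klo <- floor(mine$mz_lo / tol)
  khi <- floor(mine$mz_hi / tol)
  cand <- rep(FALSE, nrow(mine))
  for (dx in -1:1) for (dy in -1:1) {
    cand <- cand | paste(klo + dx, khi + dy) %in% okey
  }
  hit <- cand
  for (r in which(cand)) {
    hit[r] <- any(abs(other$mz_lo - mine$mz_lo[r]) <= tol &
                    abs(other$mz_hi - mine$mz_hi[r]) <= tol)
  }
  hit
}

#' Survey a protein database for isomer identifiability
#'
#' For every digestion peptide of every protein and every modification
#' multiplicity in `m_range`, enumerates the combinatorial isomer set,
#' drops isomers inconsistent with the digestion pattern (an unmodified
#' blockable cleavage site counts as a missed cleavage), and counts how
#' many isomers are identifiable by a unique 1D marker ion vs by a unique
#' 2D marker ion correlation.
#'
#' @param proteins Named character vector of sequences, or the path of a
#'   FASTA file (read with [Biostrings::readAAStringSet()]).
#' @inheritParams digest
#' @param m_range Modification multiplicities to survey.
#' @param kinds_1d Fragment kinds counted as 1D evidence.
#' @param max_charge Charge states enumerated per fragment.
#' @param tolerance Uniqueness tolerance in Th.
#' @return Data.frame with one row per (protein, peptide, m): `protein_id`,
#'   `peptide`, `start`, `m`, `n_isomers`, `n_id_1d`, `n_id_2d`.  Isomer
#'   sets with fewer than two digestion-consistent isomers are skipped
#'   (there is no mixture to resolve).
#' @export
count_identifiable <- function(proteins, enzyme = "trypsin",
                               missed_cleavages = 0L, min_length = 4L,
                               max_length = 30L,
                               modification = acetylation(),
                               m_range = 1:3, kinds_1d = c("b", "y"),
                               max_charge = 1L, tolerance = 1e-6) {
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins)) {
    aa <- Biostrings::readAAStringSet(proteins)
    proteins <- stats::setNames(as.character(aa), names(aa))
  }
  empty <- data.frame(protein_id = character(), peptide = character(),
                      start = integer(), m = integer(),
                      n_isomers = integer(), n_id_1d = integer(),
                      n_id_2d = integer())
  if (length(proteins) == 0L) return(empty)
  if (is.null(names(proteins))) {
    names(proteins) <- paste0("protein", seq_along(proteins))
  }
  rows <- list()
  for (pid in names(proteins)) {
    peps <- digest(proteins[[pid]], enzyme = enzyme,
                   missed_cleavages = missed_cleavages,
                   min_length = min_length, max_length = max_length,
                   modification = modification,
                   max_mods = max(m_range))
    for (r in seq_len(nrow(peps))) {
      sites <- peps$sites[[r]]
      blockable <- peps$blockable_internal[[r]]
      for (m in m_range[m_range <= length(sites) & m_range >= 1L]) {
        iso <- enumerate_isomers(peps$peptide[r], modification, m,
                                 sites = sites,
                                 parent_offset = peps$start[r])
        consistent <- vapply(iso$site_combinations, function(cc) {
          peps$n_missed[r] + sum(!blockable %in% cc) <= missed_cleavages
        }, logical(1))
        if (sum(consistent) < 2L) next
        iso <- .keep_isomers(iso, which(consistent))
        rep1 <- find_unique_markers(iso, "1d", tolerance = tolerance,
                                    kinds = kinds_1d,
                                    max_charge = max_charge)
        rep2 <- find_unique_markers(iso, "2d", tolerance = tolerance,
                                    max_charge = max_charge)
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = pid, peptide = peps$peptide[r],
          start = peps$start[r], m = m,
          n_isomers = length(iso$isomers),
          n_id_1d = sum(rep1$summary$identifiable),
          n_id_2d = sum(rep2$summary$identifiable))
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id, out$start, out$peptide, out$m), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.keep_isomers <- function(iso_set, idx) {
  iso_set$site_combinations <- iso_set$site_combinations[idx]
  iso_set$isomers <- iso_set$isomers[idx]
  iso_set$labels <- iso_set$labels[idx]
  iso_set
}
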