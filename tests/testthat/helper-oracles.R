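# shared fixtures and independent brute-force oracles

# reference monoisotopic values, computed independently (hand sums of the
# standard residue masses; cross-checked against pyteomics during
# development) and frozen here
REF <- list(
  h4_neutral = 1269.76295,          # GKGGKGLGKGGAKR, unmodified
  water = 18.01056,
  g_peptide = 75.03203,             # single glycine + water
  int38_ac_mz = 512.28272,          # GGK(ac)GLG internal b, 1+
  y5_ac_mz = 530.30452,             # GGAK(ac)R y5, 1+
  y5_mz = 488.29396,                # GGAKR y5, 1+
  b1_g_mz = 58.02874,               # glycine b1, 1+
  acetyl = 42.010565
)

h4_p <- function(sites) {
  modified_peptide("GKGGKGLGKGGAKR", sites, parent_offset = 4)
}

# random test peptide with n_k lysines at random interior positions
random_k_peptide <- function(len, n_k) {
  pool <- c("G", "A", "S", "L", "V", "P", "F", "D", "E")
  res <- sample(pool, len, replace = TRUE)
  ksites <- sample(seq_len(len), n_k)
  res[ksites] <- "K"
  paste(res, collapse = "")
}

# brute-force uniqueness oracle: full cross product over signatures
brute_unique_1d <- function(sigs, i, tol) {
  mine <- sigs[[i]]
  others <- unlist(sigs[-i], use.names = FALSE)
  keep <- vapply(mine, function(v) all(abs(others - v) > tol), logical(1))
  mine[keep]
}

brute_unique_2d <- function(sigs, i, tol) {
  mine <- sigs[[i]]
  keep <- vapply(seq_len(nrow(mine)), function(r) {
    for (j in seq_along(sigs)[-i]) {
      o <- sigs[[j]]
      if (nrow(o) && any(abs(o$mz_lo - mine$mz_lo[r]) <= tol &
                           abs(o$mz_hi - mine$mz_hi[r]) <= tol)) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  mine[keep, , drop = FALSE]
}

# small two-component model with one coincident product pair per
# component, for estimator and scoring tests
two_component_model <- function(grid = mz_grid(400, 490, 0.2),
                                l1 = 70, l2 = 30, ...) {
  mixture_model(list(
    list(label = "A", lambda = l1, channels = list(
      fragmentation_channel(data.frame(mz = c(410, 470), yield = 0.5),
                            0.4),
      fragmentation_channel(data.frame(mz = 430, yield = 0.5), 0.3))),
    list(label = "B", lambda = l2, channels = list(
      fragmentation_channel(data.frame(mz = c(420, 480), yield = 0.5),
                            0.4),
      fragmentation_channel(data.frame(mz = 440, yield = 0.5), 0.3)))),
    grid = grid, ...)
}
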