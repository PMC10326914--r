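test_that("trypsin and Glu-C digestion follow the cleavage rules", {
  tr <- digest("AKRPGKE", "trypsin", min_length = 1)
  expect_equal(tr$peptide, c("AK", "RPGK", "E"))  # R|P blocks cleavage
  gc <- digest("AEGEDK", "glu-c", min_length = 1)
  expect_equal(gc$peptide, c("AE", "GE", "DK"))
  gd <- digest("AEGEDK", "glu-c", min_length = 1, cleave_d = TRUE)
  expect_equal(gd$peptide, c("AE", "GE", "D", "K"))
  # no cleavage sites: the whole sequence is the single peptide
  expect_equal(digest("GGAGGS", "trypsin", min_length = 1)$peptide,
               "GGAGGS")
  expect_error(digest("AKR", "pepsin"), "arg")
})

test_that("missed cleavages and acetyl-blocked forms are generated", {
  d1 <- digest("GKGAKR", "trypsin", missed_cleavages = 1, min_length = 1)
  expect_true("GKGAK" %in% d1$peptide)
  expect_true("GAKR" %in% d1$peptide)
  # blocked forms exist only when modifications are available to block
  d0 <- digest("GKGAKR", "trypsin", min_length = 1, max_mods = 0)
  expect_false("GKGAKR" %in% d0$peptide)
  d2 <- digest("GKGAKR", "trypsin", min_length = 1, max_mods = 2)
  expect_true("GKGAKR" %in% d2$peptide)
  row <- d2[d2$peptide == "GKGAKR", ]
  expect_equal(row$blockable_internal[[1]], c(2L, 5L))
  # min/max length filters
  expect_true(all(nchar(digest("GKGAKRGGKA", "trypsin",
                               min_length = 3)$peptide) >= 3))
})

test_that("isomer enumeration produces all C(k, m) site combinations", {
  iso <- enumerate_isomers("GKGGKGLGKGGAKR", m = 2, parent_offset = 4)
  expect_length(iso$isomers, 6L)  # choose(4, 2)
  expect_length(enumerate_isomers("GKGGKGLGKGGAKR", m = 0)$isomers, 1L)
  expect_length(enumerate_isomers("GKGGKGLGKGGAKR", m = 4)$isomers, 1L)
  expect_error(enumerate_isomers("GKGGKGLGKGGAKR", m = 5), "eligible")
  # all isomers share the precursor mass exactly
  masses <- vapply(iso$isomers, peptide_neutral_mass, numeric(1))
  expect_equal(max(masses) - min(masses), 0)
  # conventional P labelling maps to the right protein sites
  h4 <- h4_diacetyl_isomers()
  expect_equal(h4$labels, paste0("P", 1:6))
  combos <- setNames(h4$site_combinations, h4$labels)
  expect_equal(combos$P1, c(2L, 13L))   # K5/K16
  expect_equal(combos$P2, c(5L, 9L))    # K8/K12
  expect_equal(combos$P4, c(5L, 13L))   # K8/K16
  p4 <- subset_isomers(h4, "P4")$isomers[[1]]
  expect_equal(isomer_label(p4), "K8ac/K16ac")
  expect_error(subset_isomers(h4, "P7"), "unknown isomer")
})

test_that("1D signatures carry the known shared and distinct ions", {
  iso <- h4_diacetyl_isomers(c("P1", "P2", "P3", "P4"))
  sig <- signature_1d(iso, kinds = c("b", "y", "internal_b"))
  has <- function(v, mz) any(abs(v - mz) < 1e-3)
  expect_true(has(sig$P4, REF$y5_ac_mz))     # P4 carries acetylated y5
  expect_true(has(sig$P1, REF$y5_ac_mz))     # so does P1 (K16 acetylated)
  expect_false(has(sig$P2, REF$y5_ac_mz))    # P2's y5 is unmodified
  expect_true(has(sig$P2, REF$y5_mz))
  # b1 = G is shared by every isomer (no modifiable site in span)
  expect_true(all(vapply(sig, has, logical(1), mz = REF$b1_g_mz)))
})

test_that("2D signatures pair only fragments with disjoint spans", {
  iso <- h4_diacetyl_isomers(c("P1", "P2", "P3", "P4"))
  sig <- signature_2d(iso)
  haspair <- function(d, a, b) any(abs(d$mz_lo - a) < 1e-3 &
                                     abs(d$mz_hi - b) < 1e-3)
  expect_true(haspair(sig$P4, REF$int38_ac_mz, REF$y5_ac_mz))
  expect_false(haspair(sig$P2, REF$int38_ac_mz, REF$y5_ac_mz))
  # canonical unordered storage
  expect_true(all(vapply(sig, function(d) all(d$mz_lo <= d$mz_hi),
                         logical(1))))
  # a fragment never pairs with itself; complementary pairs are included
  small <- enumerate_isomers("GKGR", m = 1)
  s2 <- signature_2d(small)[[1]]
  expect_false(any(s2$mz_lo == s2$mz_hi))
  p <- small$isomers[[1]]
  b1 <- fragment_mz(p, "b", 1, 1)
  y3 <- fragment_mz(p, "y", 2, 4)
  expect_true(haspair(s2, min(b1, y3), max(b1, y3)))
  # the lone internal span (2, 3) pairs with b1 and y1 but nothing else
  i23 <- fragment_mz(p, "internal_b", 2, 3)
  y1 <- fragment_mz(p, "y", 4, 4)
  expect_true(haspair(s2, min(b1, i23), max(b1, i23)))
  expect_true(haspair(s2, min(y1, i23), max(y1, i23)))
})

test_that("P4 has no unique fragment but a unique correlation in P1-P4", {
  iso <- h4_diacetyl_isomers(c("P1", "P2", "P3", "P4"))
  r1 <- find_unique_markers(iso, "1d", kinds = c("b", "y", "internal_b"))
  expect_length(r1$unique$P4, 0L)
  expect_false(r1$summary$identifiable[r1$summary$label == "P4"])
  r2 <- find_unique_markers(iso, "2d")
  u4 <- r2$unique$P4
  expect_gt(nrow(u4), 0L)
  expect_true(any(abs(u4$mz_lo - REF$int38_ac_mz) < 1e-3 &
                    abs(u4$mz_hi - REF$y5_ac_mz) < 1e-3))
  expect_true(all(r2$summary$identifiable))
  # the marker pair occurs in exactly one isomer's signature
  n_owners <- sum(vapply(r2$signatures, function(d) {
    any(abs(d$mz_lo - REF$int38_ac_mz) < 1e-3 &
          abs(d$mz_hi - REF$y5_ac_mz) < 1e-3)
  }, logical(1)))
  expect_equal(n_owners, 1L)
})

test_that("marker analysis validates its inputs", {
  iso <- h4_diacetyl_isomers(c("P1", "P2"))
  expect_error(find_unique_markers(iso, "1d", tolerance = 0), "positive")
  expect_error(find_unique_markers(h4_diacetyl_isomers("P1"), "1d"),
               "at least 2")
})

test_that("single-site isomers are always 1D-identifiable", {
  # when m = 1 and sites are far apart, flanking b ions pin the site
  iso <- enumerate_isomers("GAKGGAKGGA", m = 1)
  r1 <- find_unique_markers(iso, "1d")
  expect_true(all(r1$summary$identifiable))
})

test_that("uniqueness agrees with the brute-force cross-product oracle", {
  withr::with_seed(77, {
    for (rep in 1:30) {
      seq <- random_k_peptide(8, 3)
      iso <- enumerate_isomers(seq, m = 2)
      for (mode in c("1d", "2d")) {
        rep_ <- find_unique_markers(iso, mode,
                                    kinds = c("b", "y", "internal_b"))
        sigs <- rep_$signatures
        for (i in seq_along(sigs)) {
          if (mode == "1d") {
            expect_equal(rep_$unique[[i]],
                         brute_unique_1d(sigs, i, 1e-6))
          } else {
            expect_equal(rep_$unique[[i]],
                         brute_unique_2d(sigs, i, 1e-6),
                         ignore_attr = TRUE)
          }
        }
      }
    }
  })
})

test_that("a unique fragment always implies a unique correlation", {
  withr::with_seed(88, {
    for (rep in 1:25) {
      seq <- random_k_peptide(sample(8:14, 1), 3)
      iso <- enumerate_isomers(seq, m = 2)
      r1 <- find_unique_markers(iso, "1d")
      r2 <- find_unique_markers(iso, "2d")
      expect_true(all(r2$summary$identifiable[r1$summary$identifiable]))
    }
  })
})

test_that("identifiability survey aggregates per peptide and multiplicity", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">h4_tail", "GKGGKGLGKGGAKR"), fa)
  tab <- count_identifiable(fa, enzyme = "trypsin", missed_cleavages = 2,
                            min_length = 4, m_range = 2)
  expect_true(any(tab$peptide == "GKGGKGLGKGGAKR" & tab$n_isomers == 6))
  expect_true(all(tab$n_id_2d >= tab$n_id_1d))
  # a protein without target residues yields no isomer sets
  expect_equal(nrow(count_identifiable(c(p1 = "GGAGGSAGGE"))), 0L)
  # empty input yields an empty, well-formed table
  empty <- count_identifiable(character(0))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("protein_id", "peptide", "m", "n_isomers", "n_id_1d",
                    "n_id_2d") %in% names(empty)))
})
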