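test_that("contact maps from coordinates match a brute-force atom scan", {
  # synthetic 4-residue toy with tabulated coordinates
  set.seed(11)
  atoms <- tibble::tibble(
    resno = rep(1:4, each = 3),
    element = rep(c("C", "N", "O"), 4),
    x = c(0, 1, 0.5,   4, 5, 4.5,   8, 9, 8.5,   0.5, 1.5, 1),
    y = c(0, 0, 1,     0, 0, 1,     0, 0, 1,     3, 3, 4),
    z = 0
  )
  cm <- contact_map_from_atoms(atoms, threshold = 4.5, min_separation = 2)
  # oracle: O(atoms^2) scan
  oracle <- list()
  for (a in 1:(nrow(atoms) - 1)) for (b in (a + 1):nrow(atoms)) {
    ri <- atoms$resno[a]; rj <- atoms$resno[b]
    if (abs(ri - rj) < 2) next
    d <- sqrt((atoms$x[a] - atoms$x[b])^2 + (atoms$y[a] - atoms$y[b])^2 +
                (atoms$z[a] - atoms$z[b])^2)
    if (d <= 4.5) oracle[[paste(min(ri, rj), max(ri, rj))]] <- TRUE
  }
  got <- paste(cm$pairs[, 1], cm$pairs[, 2])
  expect_setequal(got, names(oracle))
})

test_that("contact threshold is inclusive below, exclusive above", {
  mk <- function(d) tibble::tibble(
    resno = c(1, 3), element = "C",
    x = c(0, d), y = 0, z = 0
  )
  expect_equal(contact_map_from_atoms(mk(4.4))$n_contacts, 1L)
  expect_equal(contact_map_from_atoms(mk(4.6))$n_contacts, 0L)
})

test_that("hydrogens are ignored and atom order does not matter", {
  atoms <- tibble::tibble(
    resno = c(1, 1, 3), element = c("C", "H", "C"),
    x = c(0, 4, 10), y = 0, z = 0
  )
  # the H at x=4 would be within 4.5 of nothing relevant; move residue 3 close
  atoms2 <- atoms
  atoms2$x[3] <- 6  # within 2 of the H but 6 from the C
  expect_equal(contact_map_from_atoms(atoms2)$n_contacts, 0L)
  shuffled <- atoms2[c(3, 1, 2), ]
  expect_identical(contact_map_from_atoms(shuffled)$pairs,
                   contact_map_from_atoms(atoms2)$pairs)
})

test_that("unmapped residues are skipped with a warning", {
  atoms <- tibble::tibble(resno = c(1, 3, 5), element = "C",
                          x = c(0, 1, 2), y = 0, z = 0)
  mapping <- tibble::tibble(resno = c(1, 3), position = c(1, 3))
  expect_warning(
    cm <- contact_map_from_atoms(atoms, mapping = mapping),
    "no alignment mapping"
  )
  expect_true(all(cm$pairs <= 3))
})

test_that("encoding activates one feature per position and per contact", {
  parents <- parent_set(c(A = "ACD", B = "AFE"))
  cm <- contact_map(rbind(c(1, 3)))
  enc <- build_encoding(parents, cm)
  # hand-constructed table: pos1 {A}, pos2 {C,F}, pos3 {D,E},
  # contact (1,3) pairs {AD, AE}
  expect_equal(enc$n_se, 5L)
  expect_equal(enc$n_st, 2L)
  X <- encode_sequences(c("ACD", "AFE", "ACE"), enc)
  expect_equal(unname(Matrix::rowSums(X)), rep(3 + 1, 3))  # 3 pos + 1 contact
  expect_equal(attr(X, "extra_active"), rep(0L, 3))
  idx <- enc$index
  active1 <- which(X[1, ] == 1)
  expect_setequal(
    paste(idx$type, idx$pos_i, idx$aa_i, idx$aa_j)[active1],
    c("residue 1 A NA", "residue 2 C NA", "residue 3 D NA",
      "contact 1 A D")
  )
  # identical sequences -> identical vectors; distinct -> distinct
  expect_equal(as.matrix(X[1, , drop = FALSE]),
               as.matrix(encode_sequences("ACD", enc)))
  expect_false(all(X[1, ] == X[3, ]))
})

test_that("assignment-based encoding equals sequence-based encoding", {
  sys <- toy_system(length = 24, n_blocks = 3)
  for (d in sys$designs) {
    n <- 3^3
    A <- chimeraGP:::assignment_chunk(0:(n - 1), 3, 3)
    X_fast <- encode_assignments(A, d, sys$encoding)
    seqs <- build_sequences(A, sys$parents, d)
    X_slow <- encode_sequences(seqs, sys$encoding)
    expect_equal(as.matrix(X_fast), as.matrix(X_slow))
  }
})

test_that("encoding is injective up to sequence identity on a library", {
  sys <- toy_system(length = 24, n_blocks = 3)
  chim <- enumerate_chimeras(sys$parents, sys$designs, sequences = TRUE)
  X <- encode_sequences(chim$sequence, sys$encoding)
  keys <- apply(as.matrix(X), 1, paste, collapse = "")
  expect_equal(duplicated(keys), duplicated(chim$sequence))
})

test_that("unseen residues are counted as extra active features", {
  parents <- parent_set(c(A = "ACD", B = "AFE"))
  cm <- contact_map(rbind(c(1, 3)))
  enc <- build_encoding(parents, cm)
  X <- encode_sequences("AWD", enc)  # W unseen at position 2
  expect_equal(attr(X, "extra_active"), 1L)
  # with the homolog in the alphabet, no extras remain
  enc2 <- build_encoding(parents, cm, extra_sequences = "AWD")
  X2 <- encode_sequences("AWD", enc2)
  expect_equal(attr(X2, "extra_active"), 0L)
  expect_equal(unname(Matrix::rowSums(X2)), 4)
})

test_that("gaps contribute no features and void their contacts", {
  parents <- parent_set(c(A = "ACD", B = "A-E"))
  cm <- contact_map(rbind(c(1, 2), c(1, 3)))
  enc <- build_encoding(parents, cm)
  X <- encode_sequences(c("ACD", "A-E"), enc)
  # gapped sequence: 2 residues + 1 live contact (1,3); contact (1,2) void
  expect_equal(unname(Matrix::rowSums(X)), c(3 + 2, 2 + 1))
  expect_equal(attr(X, "extra_active"), c(0L, 0L))
})

test_that("similarity counts are dot products of the encoding parts", {
  sys <- toy_system(length = 24, n_blocks = 3)
  chim <- enumerate_chimeras(sys$parents, sys$designs, sequences = TRUE)
  take <- chim$sequence[c(1, 5, 9)]
  X <- encode_sequences(take, sys$encoding)
  sc <- similarity_counts(X, sys$encoding)
  # identical chimeras: full counts
  expect_equal(sc$positions[1, 1], sys$parents$length)
  expect_equal(sc$contacts[1, 1], sys$encoding$contacts$n_contacts)
  # manual comparison oracle
  for (i in 1:3) for (j in 1:3) {
    a <- strsplit(take[i], "")[[1]]; b <- strsplit(take[j], "")[[1]]
    expect_equal(sc$positions[i, j], sum(a == b))
    pr <- sys$encoding$contacts$pairs
    expect_equal(sc$contacts[i, j],
                 sum(a[pr[, 1]] == b[pr[, 1]] & a[pr[, 2]] == b[pr[, 2]]))
  }
  expect_true(all(sc$contacts >= 0 &
                    sc$contacts <= sys$encoding$contacts$n_contacts))
  # parents differing everywhere share nothing
  p2 <- parent_set(c(A = "AAA", B = "CCC"))
  e2 <- build_encoding(p2, contact_map(rbind(c(1, 3))))
  X2 <- encode_sequences(c("AAA", "CCC"), e2)
  s2 <- similarity_counts(X2, e2)
  expect_equal(s2$positions[1, 2], 0)
  expect_equal(s2$contacts[1, 2], 0)
})

test_that("covarying columns collapse to groups and expand back exactly", {
  M <- cbind(a = c(1, 0, 1), b = c(1, 0, 1), c = c(0, 1, 0),
             z = c(0, 0, 0), o = c(1, 1, 1))
  cc <- collapse_covarying(M)
  expect_equal(max(cc$groups$group), 4)
  expect_equal(cc$groups$group[1], cc$groups$group[2])
  expect_equal(cc$groups$constant[4], "zero")
  expect_equal(cc$groups$constant[5], "one")
  expect_equal(unname(expand_collapsed(cc$reduced, cc$groups)), unname(M))
  # randomized toy vs brute-force pairwise comparison
  set.seed(5)
  for (rep in 1:5) {
    M <- matrix(rbinom(12 * 20, 1, 0.4), 12, 20)
    M[, 7] <- M[, 3]; M[, 15] <- M[, 3]
    cc <- collapse_covarying(M)
    same_group <- outer(cc$groups$group, cc$groups$group, "==")
    brute <- matrix(TRUE, 20, 20)
    for (i in 1:20) for (j in 1:20) brute[i, j] <- all(M[, i] == M[, j])
    expect_equal(same_group, brute)
    expect_equal(unname(expand_collapsed(cc$reduced, cc$groups)), unname(M))
  }
  # all-distinct columns stay singletons
  M <- diag(5)
  expect_equal(max(collapse_covarying(M)$groups$group), 5)
})

test_that("hydrophobicity sums the Kyte-Doolittle scale over TM positions", {
  expect_equal(hydrophobicity_score("II", 1:2), 9.0)
  expect_equal(hydrophobicity_score("MKTA", integer(0)), 0.0)
  expect_equal(hydrophobicity_score("RIR", 1:3), -4.5 + 4.5 - 4.5)
  expect_error(hydrophobicity_score("AXA", 1:3), class = "chimeraGP_error")
})

test_that("baseline summaries group by signal peptide and match arithmetic", {
  meas <- tibble::tibble(
    chimera_name = c("a", "b", "c", "d"),
    GFP_mean = c(1, 3, 10, 20),
    mKate_mean = c(2, 2, 4, 4)
  )
  g1 <- baseline_group_summary(meas, rep("P1", 4), properties = "GFP_mean")
  expect_equal(g1$mean, mean(meas$GFP_mean))
  g2 <- baseline_group_summary(meas, c("P1", "P1", "P2", "P2"),
                               properties = c("GFP_mean", "mKate_mean"))
  expect_equal(g2$mean[g2$group == "P1" & g2$property == "GFP_mean"], 2)
  expect_equal(g2$mean[g2$group == "P2" & g2$property == "GFP_mean"], 15)
  expect_warning(
    baseline_group_summary(meas, factor(rep("P1", 4), levels = c("P1", "P2")),
                           properties = "GFP_mean"),
    "Empty group"
  )
  # signal peptide parent is the block-1 contributor
  sys <- toy_system(length = 24, n_blocks = 3)
  expect_equal(signal_peptide_parent(c(2, 1, 1), sys$parents), "P2")
})
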