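# Descriptor formulas against hand computations and independent
# brute-force oracles; matrix assembly and pretreatment.

test_that("HNar matches hand evaluations and errors on one heavy atom", {
  ethane <- molecule(c("C", "C"), bonds = rbind(c(1, 2)))
  expect_equal(hnar(ethane), 1)
  expect_equal(hnar(mol_benzene()), 2)
  expect_equal(hnar(mol_isobutane_heavy()), 4 / (1 + 1 / 3 + 1 + 1))
  expect_error(hnar(mol_methane()), "at least 2 heavy atoms")
})

test_that("IDM matches hand entropy computations and its bound", {
  two <- molecule(c("C", "O"), bonds = rbind(c(1, 2)))
  expect_equal(idm(two), 0)
  expect_equal(idm(mol_ethanol_heavy()), 1.5)  # distances 1,1,2; W = 4
  for (mol in oracle_molecules()) {
    if (sum(mol$atoms$element != "H") < 2) next
    A <- sum(mol$atoms$element != "H")
    expect_lte(idm(mol), log2(A * (A - 1) / 2) + 1e-12)
  }
})

test_that("Mp averages carbon-scaled polarizabilities over all atoms", {
  expect_equal(mp(mol_methane()),
               (1 + 4 * 0.667 / 1.76) / 5)
  # order invariance: permuting atoms leaves Mp unchanged
  set.seed(1)
  m <- random_molecule(7)
  perm <- sample(nrow(m$atoms))
  remap <- order(perm)
  m2 <- molecule(m$atoms$element[perm],
                 bonds = cbind(remap[m$bonds$from], remap[m$bonds$to],
                               m$bonds$order),
                 coords = as.matrix(m$atoms[perm, c("x", "y", "z")]))
  expect_equal(mp(m2), mp(m))
})

test_that("GATS matches the hand case, degenerate sentinels and sign", {
  w123 <- molecule(c("C", "N", "O"), bonds = rbind(c(1, 2), c(2, 3)))
  # path with weights (1, 2, 3), lag 1 -> exactly 1 by the hand formula
  fake <- weight_scheme("u")
  fake$values[c("C", "N", "O")] <- c(1, 2, 3)
  expect_equal(gats(w123, 1, fake), 1)
  # all-carbon molecule has zero weight variance under any scheme
  expect_warning(val <- gats(mol_benzene(), 1, "v"), "zero weight variance")
  expect_identical(val, 0)
  # no pair at a lag beyond the diameter
  expect_warning(val2 <- gats(mol_ethanol_heavy(), 5, "e"), "no heavy-atom pair")
  expect_identical(val2, 0)
})

test_that("GATS is invariant to adding a constant to the weights", {
  mol <- mol_ethanol_heavy()
  base <- weight_scheme("u")
  base$values[c("C", "O")] <- c(1.3, 2.1)
  shifted <- base
  shifted$values <- base$values + 0.7
  expect_equal(gats(mol, 1, base), gats(mol, 1, shifted))
  expect_gte(suppressWarnings(gats(mol, 2, base)), 0)
})

test_that("DISP matches the hand case and is translation invariant", {
  two <- molecule(c("C", "O"), bonds = rbind(c(1, 2)),
                  coords = rbind(c(0, 0, 0), c(1, 0, 0)))
  fake <- weight_scheme("u")
  fake$values[c("C", "O")] <- c(1, 3)
  expect_equal(disp(two, fake), 0.25)
  # uniform weights put both centres at the centroid
  expect_equal(disp(random_molecule(11), "u"), 0)
})

test_that("MoRSE signal 1 counts atom pairs under unit weights", {
  for (mol in list(mol_water(), mol_methane(), random_molecule(21))) {
    n <- nrow(mol$atoms)
    expect_equal(morse(mol, 1, "u"), n * (n - 1) / 2)
  }
  expect_error(morse(mol_water(), 0, "u"), "1..32")
  expect_error(morse(mol_water(), 33, "u"), "1..32")
})

test_that("every descriptor equals its independent brute-force oracle", {
  for (mol in oracle_molecules()) {
    nh <- sum(mol$atoms$element != "H")
    if (nh >= 2) {
      expect_equal(hnar(mol), oracle_hnar(mol), tolerance = 1e-10,
                   info = mol$name)
      expect_equal(idm(mol), oracle_idm(mol), tolerance = 1e-10,
                   info = mol$name)
      for (lag in 1:3) for (code in c("v", "e"))
        expect_equal(suppressWarnings(gats(mol, lag, code)),
                     oracle_gats(mol, lag, code), tolerance = 1e-10,
                     info = paste(mol$name, lag, code))
    }
    expect_equal(mp(mol), oracle_mp(mol), tolerance = 1e-10, info = mol$name)
    for (code in c("m", "e")) {
      expect_equal(disp(mol, code), oracle_disp(mol, code),
                   tolerance = 1e-10, info = paste(mol$name, code))
      for (sig in c(2, 22, 32))
        expect_equal(morse(mol, sig, code), oracle_morse(mol, sig, code),
                     tolerance = 1e-10, info = paste(mol$name, sig, code))
    }
  }
})

test_that("MoRSE and DISP are invariant under rigid motions", {
  for (seed in 1:5) {
    mol <- random_molecule(seed + 40)
    moved <- rigid_motion(mol, seed)
    for (code in c("u", "e", "m")) {
      expect_equal(disp(moved, code), disp(mol, code), tolerance = 1e-9)
      expect_equal(morse(moved, 22, code), morse(mol, 22, code),
                   tolerance = 1e-9)
      expect_equal(morse(moved, 2, code), morse(mol, 2, code),
                   tolerance = 1e-9)
    }
  }
})

test_that("compute_matrix assembles the requested columns with guards", {
  mols <- list(mol_water(), mol_methane(), mol_benzene())
  m <- compute_matrix(mols, c("Mp", "DISPe", "Mor2u"))
  expect_identical(dim(m), c(3L, 3L))
  expect_identical(colnames(m), c("Mp", "DISPe", "Mor2u"))
  expect_true(all(is.finite(m)))
  expect_error(compute_matrix(list()), "empty")
  expect_warning(m2 <- compute_matrix(mols, c("Mp", "Mp")), "duplicate")
  expect_identical(colnames(m2), "Mp")
  # single-cell failure names compound and descriptor
  expect_error(compute_matrix(list(mol_water(), mol_methane()), "HNar"),
               "HNar.*water")
  expect_error(compute_matrix(mols, "Nope3x"), "unknown descriptor")
})

test_that("pretreatment removes zero, near-constant and tiny-variance columns", {
  set.seed(9)
  n <- 39
  x <- cbind(zero = rep(0, n),
             const = c(rep(1.234, 20), rnorm(19)),
             tiny = rnorm(n, sd = sqrt(0.00049 / (n - 1) * n * 0.9)),
             keep = rnorm(n))
  # force exact variances around the boundary
  x[, "tiny"] <- scale(x[, "tiny"]) * sqrt(0.00049)
  kept <- pretreat(x)
  expect_identical(colnames(kept), "keep")
  pt <- attr(kept, "pretreatment")
  expect_setequal(pt$descriptor, c("zero", "const", "tiny"))
  expect_identical(pt$reason[pt$descriptor == "zero"], "zero")
  expect_identical(pt$reason[pt$descriptor == "const"], "constant")
  expect_identical(pt$reason[pt$descriptor == "tiny"], "low_variance")
  # boundary: variance just above the threshold is kept
  x2 <- cbind(a = drop(scale(rnorm(n))) * sqrt(0.00051), b = rnorm(n))
  expect_identical(colnames(pretreat(x2)), c("a", "b"))
  expect_error(pretreat(cbind(z = rep(0, 5))), "every descriptor")
})
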