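# Hand-built molecules (approximate but fixed geometries) and fully
# independent brute-force descriptor oracles. The oracles share no code
# with the package: plain loops over atoms, bonds and distances.

mol_methane <- function() {
  molecule(c("C", "H", "H", "H", "H"), bonds = cbind(1, 2:5),
           coords = rbind(c(0, 0, 0), c(0.629, 0.629, 0.629),
                          c(-0.629, -0.629, 0.629),
                          c(-0.629, 0.629, -0.629),
                          c(0.629, -0.629, -0.629)), name = "methane")
}

mol_water <- function() {
  molecule(c("O", "H", "H"), bonds = rbind(c(1, 2), c(1, 3)),
           coords = rbind(c(0, 0, 0), c(0.9572, 0, 0),
                          c(-0.2399, 0.9266, 0)), name = "water")
}

mol_ethanol_heavy <- function() {
  molecule(c("C", "C", "O"), bonds = rbind(c(1, 2), c(2, 3)),
           coords = rbind(c(0, 0, 0), c(1.52, 0, 0), c(2.02, 1.33, 0)),
           name = "ethanol-heavy")
}

mol_benzene <- function() {
  ang <- (0:5) * pi / 3
  molecule(rep("C", 6), bonds = cbind(1:6, c(2:6, 1), rep(c(2, 1), 3)),
           coords = cbind(1.39 * cos(ang), 1.39 * sin(ang), 0),
           name = "benzene")
}

mol_isobutane_heavy <- function() {
  molecule(rep("C", 4), bonds = rbind(c(1, 2), c(2, 3), c(2, 4)),
           coords = rbind(c(1.5, 0, 0), c(0, 0, 0), c(-0.75, 1.3, 0),
                          c(-0.75, -1.3, 0)), name = "isobutane-heavy")
}

# Random but valid molecule: random heavy-atom tree (optionally one extra
# ring-closing edge), hydrogens filling standard valences, normal random
# coordinates. Deterministic given the seed.
random_molecule <- function(seed) {
  set.seed(seed)
  valence <- c(C = 4, N = 3, O = 2, S = 2)
  nh <- sample(3:7, 1)
  elements <- sample(names(valence), nh, replace = TRUE,
                     prob = c(0.6, 0.15, 0.2, 0.05))
  bonds <- if (nh > 1) cbind(2:nh, vapply(2:nh, function(i)
    sample.int(i - 1, 1), integer(1)), 1) else NULL
  deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = nh)
  # maybe close a ring between two degree-deficient vertices
  if (nh >= 4 && runif(1) < 0.5) {
    free <- which(deg < valence[elements] - 1)
    free <- free[!free %in% c(1, 2)]
    if (length(free) >= 2) {
      pick <- sample(free, 2)
      already <- any(bonds[, 1] %in% pick & bonds[, 2] %in% pick)
      if (!already) {
        bonds <- rbind(bonds, c(pick, 1))
        deg[pick] <- deg[pick] + 1
      }
    }
  }
  elements_all <- elements
  for (i in seq_len(nh)) {
    n_h <- valence[elements[i]] - deg[i]
    if (n_h > 0) {
      idx <- length(elements_all) + seq_len(n_h)
      elements_all <- c(elements_all, rep("H", n_h))
      bonds <- rbind(bonds, cbind(i, idx, 1))
    }
  }
  molecule(elements_all, bonds = bonds,
           coords = matrix(rnorm(3 * length(elements_all), sd = 1.5),
                           ncol = 3),
           name = paste0("random-", seed))
}

oracle_molecules <- function() {
  c(list(mol_methane(), mol_water(), mol_ethanol_heavy(), mol_benzene(),
         mol_isobutane_heavy()),
    lapply(101:105, random_molecule))
}

## ---- independent oracles -------------------------------------------------

oracle_heavy_indices <- function(mol) which(mol$atoms$element != "H")

oracle_distances <- function(mol) {
  heavy <- oracle_heavy_indices(mol)
  b <- mol$bonds
  keep <- b$from %in% heavy & b$to %in% heavy
  el <- cbind(match(b$from[keep], heavy), match(b$to[keep], heavy))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(heavy) - igraph::vcount(g)))
  unname(igraph::distances(g))
}

oracle_degrees <- function(mol) {
  heavy <- oracle_heavy_indices(mol)
  b <- mol$bonds
  keep <- b$from %in% heavy & b$to %in% heavy
  tabulate(match(c(b$from[keep], b$to[keep]), heavy),
           nbins = length(heavy))
}

oracle_hnar <- function(mol) {
  deg <- oracle_degrees(mol)
  length(deg) / sum(1 / deg)
}

oracle_idm <- function(mol) {
  d <- oracle_distances(mol)
  total <- 0; w <- 0
  n <- nrow(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) w <- w + d[i, j]
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- d[i, j] / w
    total <- total - p * log2(p)
  }
  total
}

oracle_weights <- function(mol, code, include_h) {
  tab <- atomic_properties()
  col <- c(m = "mass", v = "vdw_volume", e = "sanderson_en",
           p = "polarizability")[code]
  els <- mol$atoms$element
  if (!include_h) els <- els[els != "H"]
  if (code == "u") return(rep(1, length(els)))
  ref <- tab[[col]][tab$element == "C"]
  vapply(els, function(e) tab[[col]][tab$element == e] / ref, numeric(1),
         USE.NAMES = FALSE)
}

oracle_mp <- function(mol) mean(oracle_weights(mol, "p", TRUE))

oracle_gats <- function(mol, lag, code) {
  d <- oracle_distances(mol)
  w <- oracle_weights(mol, code, include_h = FALSE)
  A <- length(w)
  num <- 0; npairs <- 0
  for (i in seq_len(A)) for (j in seq_len(A)) {
    if (i != j && d[i, j] == lag) {
      num <- num + (w[i] - w[j])^2
      npairs <- npairs + 1
    }
  }
  npairs <- npairs / 2
  ss <- sum((w - mean(w))^2)
  if (npairs == 0 || ss == 0) return(0)
  (num / (2 * npairs)) / (ss / (A - 1))
}

oracle_disp <- function(mol, code) {
  w <- oracle_weights(mol, code, include_h = TRUE)
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  wc <- c(sum(w * xyz[, 1]), sum(w * xyz[, 2]), sum(w * xyz[, 3])) / sum(w)
  gc <- colMeans(xyz)
  sqrt(sum((wc - gc)^2))
}

oracle_morse <- function(mol, signal, code) {
  w <- oracle_weights(mol, code, include_h = TRUE)
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  s <- signal - 1
  total <- 0
  n <- nrow(xyz)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    term <- if (s * r == 0) 1 else sin(s * r) / (s * r)
    total <- total + w[i] * w[j] * term
  }
  total
}

# random rigid motion (proper rotation + translation) of a molecule
rigid_motion <- function(mol, seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- rnorm(3, sd = 5)
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")]) %*% q
  xyz <- sweep(xyz, 2, shift, "+")
  molecule(mol$atoms$element, bonds = as.matrix(mol$bonds), coords = xyz,
           name = mol$name)
}
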