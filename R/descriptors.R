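# Molecular descriptors: Narumi harmonic index, distance-magnitude
# information content, mean carbon-scaled polarizability, Geary
# autocorrelation, geometric/property centre displacement, 3D-MoRSE.

#' Narumi harmonic topological index (HNar)
#'
#' Harmonic mean of the heavy-atom vertex degrees: the number of
#' non-hydrogen atoms divided by the sum of reciprocal vertex degrees.
#' Larger values indicate more branching.
#'
#' @param mol A [molecule()].
#' @return A single number.
#' @export
#' @examples
#' benzene <- molecule(rep("C", 6),
#'                     bonds = cbind(1:6, c(2:6, 1), rep(c(2, 1), 3)))
#' hnar(benzene)  # 2: 2-regular graph
hnar <- function(mol) {
  g <- heavy_atom_graph(mol)
  g$n_heavy / sum(1 / g$degrees)
}

#' Mean information content on the distance magnitude (IDM)
#'
#' Shannon entropy (bits) of the topological distance magnitudes: with
#' Wiener sum W = sum of upper-triangle distances d_ij, IDM =
#' -sum (d_ij / W) log2(d_ij / W). Grows with molecular size.
#'
#' @param mol A [molecule()].
#' @return A single number (bits).
#' @export
idm <- function(mol) {
  g <- heavy_atom_graph(mol)
  d <- g$distances[upper.tri(g$distances)]
  w <- sum(d)
  p <- d / w
  -sum(p * log2(p))
}

#' Mean atomic polarizability, carbon-scaled (Mp)
#'
#' Average of carbon-scaled atomic polarizabilities over all atoms,
#' hydrogens included: Mp = (sum alpha_i / alpha_C) / n. A constitutional
#' descriptor: it depends only on the molecular formula.
#'
#' @param mol A [molecule()] with explicit hydrogens.
#' @return A single number.
#' @export
#' @examples
#' ch4 <- molecule(c("C", rep("H", 4)), bonds = cbind(1, 2:5))
#' mp(ch4)  # (1 + 4 * 0.379) / 5
mp <- function(mol) {
  mean(weight_vector(mol, "p", include_h = TRUE))
}

#' Geary autocorrelation at a topological lag (GATS)
#'
#' Spatial autocorrelation of a carbon-scaled atomic property over the
#' hydrogen-depleted graph: the mean squared property difference across
#' vertex pairs at topological distance `lag`, relative to the overall
#' property variance. Values near 1 indicate no autocorrelation.
#'
#' If no vertex pair sits at the requested lag, or the property has zero
#' variance over the heavy atoms, the descriptor is degenerate and a
#' sentinel 0 is returned with a warning (rather than NaN), keeping
#' descriptor matrices finite for downstream selection.
#'
#' @param mol A [molecule()].
#' @param lag Positive integer topological distance.
#' @param scheme A [weight_scheme()] or code (`"GATS2v"` uses `"v"`).
#' @return A single non-negative number.
#' @export
gats <- function(mol, lag, scheme) {
  stopifnot(length(lag) == 1, lag >= 1, lag == round(lag))
  g <- heavy_atom_graph(mol)
  w <- weight_vector(mol, scheme, include_h = FALSE)
  at_lag <- g$distances == lag
  n_pairs <- sum(at_lag) / 2      # unordered pairs at this lag
  denom_ss <- sum((w - mean(w))^2)
  if (n_pairs == 0) {
    warning("no heavy-atom pair at lag ", lag, "; returning sentinel 0")
    return(0)
  }
  if (denom_ss == 0) {
    warning("zero weight variance; returning sentinel 0")
    return(0)
  }
  diff2 <- outer(w, w, "-")^2
  num <- sum(diff2[at_lag]) / (2 * n_pairs)      # ordered sum / 2*Delta
  den <- denom_ss / (g$n_heavy - 1)
  num / den
}

#' Displacement between geometric and property centres (DISP)
#'
#' Euclidean distance (Angstrom) between the property-weighted centroid
#' and the plain geometric centroid of a molecule, all atoms including
#' hydrogens. DISPe (electronegativity weighting) and DISPm (mass
#' weighting) appear in the retention models; the value is invariant to
#' rigid motion of the molecule.
#'
#' @param mol A [molecule()] with 3D coordinates.
#' @param scheme A [weight_scheme()] or code.
#' @return A single non-negative number (Angstrom).
#' @export
disp <- function(mol, scheme) {
  require_3d(mol)
  w <- weight_vector(mol, scheme, include_h = TRUE)
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  wc <- colSums(xyz * w) / sum(w)
  gc <- colMeans(xyz)
  sqrt(sum((wc - gc)^2))
}

#' 3D-MoRSE signal (Mor)
#'
#' Electron-diffraction style molecular transform: for signal number k the
#' scattering parameter is s = k - 1 (1/Angstrom) and
#' Mor_k = sum over atom pairs i < j of w_i w_j sin(s r_ij) / (s r_ij),
#' with the s = 0 term read as 1 (sinc limit). All atoms including
#' hydrogens; weights carbon-scaled.
#'
#' @param mol A [molecule()] with 3D coordinates.
#' @param signal Integer signal number in 1..32.
#' @param scheme A [weight_scheme()] or code.
#' @return A single number.
#' @export
morse <- function(mol, signal, scheme) {
  if (length(signal) != 1 || signal < 1 || signal > 32 || signal != round(signal))
    stop("signal must be an integer in 1..32")
  require_3d(mol)
  w <- weight_vector(mol, scheme, include_h = TRUE)
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  s <- signal - 1
  n <- nrow(xyz)
  total <- 0
  for (i in seq_len(n - 1)) {
    dxyz <- xyz[(i + 1):n, , drop = FALSE] -
      matrix(xyz[i, ], n - i, 3, byrow = TRUE)
    r <- sqrt(rowSums(dxyz^2))
    sr <- s * r
    sinc <- ifelse(sr == 0, 1, sin(sr) / sr)
    total <- total + sum(w[i] * w[(i + 1):n] * sinc)
  }
  total
}
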