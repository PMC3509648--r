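# Hydrogen-depleted molecular graph: vertex degrees and topological
# distance matrix (unit bond lengths; bond order ignored).

#' Heavy-atom graph of a molecule
#'
#' Builds the hydrogen-suppressed molecular graph and returns all-pairs
#' shortest-path (topological) distances together with the vertex degrees.
#' Edges have unit length regardless of bond order, the standard
#' convention for topological indices.
#'
#' @param mol A [molecule()].
#' @return An object of class `heavy_atom_graph`: list with `distances`
#'   (A x A integer matrix), `degrees` (integer vector), `n_heavy`,
#'   `adjacency` (logical matrix).
#' @export
#' @examples
#' etoh <- molecule(c("C", "C", "O"), bonds = rbind(c(1, 2), c(2, 3)))
#' heavy_atom_graph(etoh)$degrees  # 1 2 1
heavy_atom_graph <- function(mol) {
  stopifnot(inherits(mol, "qsrr_molecule"))
  heavy <- which(!mol$atoms$is_hydrogen)
  A <- length(heavy)
  if (A < 2) stop("heavy-atom graph needs at least 2 heavy atoms")
  remap <- match(seq_len(n_atoms(mol)), heavy)
  adj <- matrix(FALSE, A, A)
  b <- mol$bonds
  keep <- !is.na(remap[b$from]) & !is.na(remap[b$to])
  for (k in which(keep)) {
    i <- remap[b$from[k]]; j <- remap[b$to[k]]
    adj[i, j] <- TRUE; adj[j, i] <- TRUE
  }
  # breadth-first search from every vertex
  d <- matrix(NA_integer_, A, A)
  nbrs <- apply(adj, 1, which, simplify = FALSE)
  for (s in seq_len(A)) {
    dist <- rep(NA_integer_, A)
    dist[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- unique(unlist(nbrs[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (length(nxt)) dist[nxt] <- dist[frontier[1]] + 1L
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  if (anyNA(d))
    stop("heavy-atom graph is disconnected; topological descriptors undefined")
  structure(list(distances = d, degrees = as.integer(rowSums(adj)),
                 n_heavy = A, adjacency = adj),
            class = "heavy_atom_graph")
}

#' @export
print.heavy_atom_graph <- function(x, ...) {
  cat("<heavy-atom graph> ", x$n_heavy, " vertices, ",
      sum(x$adjacency) / 2, " edges, diameter ", max(x$distances), "\n",
      sep = "")
  invisible(x)
}
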