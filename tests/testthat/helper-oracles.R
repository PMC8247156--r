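# Independent oracles used across the suite. Both are deliberately naive:
# the LP oracle enumerates basic solutions instead of pivoting, and the graph
# oracle works from the adjacency matrix with hand-rolled BFS, so neither
# shares code with the implementation it checks.

# Brute-force LP oracle: max c'x s.t. A x = b, lb <= x <= ub (finite bounds).
# Enumerates every choice of m basic columns and every lb/ub assignment of
# the nonbasic columns; returns the best feasible objective or NA.
lp_bruteforce <- function(obj, A, b, lb, ub, tol = 1e-7) {
  A <- as.matrix(A)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  A_full <- A; b_full <- b
  qrt <- qr(t(A))                       # drop linearly dependent rows so a
  keep <- qrt$pivot[seq_len(qrt$rank)]  # nonsingular basis exists at vertices
  A <- A[keep, , drop = FALSE]; b <- b[keep]
  m <- nrow(A); n <- ncol(A)
  best <- NA_real_
  for (basis in utils::combn(n, m, simplify = FALSE)) {
    B <- A[, basis, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    nonb <- setdiff(seq_len(n), basis)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(nonb)))
    for (g in seq_len(max(1L, nrow(grid)))) {
      x <- numeric(n)
      if (length(nonb)) {
        hi <- as.logical(grid[g, ])
        x[nonb] <- ifelse(hi, ub[nonb], lb[nonb])
      }
      rhs <- b - if (length(nonb)) A[, nonb, drop = FALSE] %*% x[nonb] else 0
      xb <- drop(solve(B, rhs))
      x[basis] <- xb
      if (all(xb >= lb[basis] - tol) && all(xb <= ub[basis] + tol) &&
          max(abs(A_full %*% x - b_full)) <= tol) {
        val <- sum(obj * x)
        if (is.na(best) || val > best) best <- val
      }
    }
  }
  best
}

# BFS all-pairs distances on an adjacency matrix (0 = unreachable marker Inf)
bfs_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ] > 0)) {
        if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; queue <- c(queue, w) }
      }
    }
    D[s, ] <- dist
  }
  D
}

# Hand computation of every connectivity index from an adjacency matrix,
# mirroring the definitions: average local clustering (deg<=1 -> 0), density
# mean(k)/(n-1), heterogeneity sd_pop(k)/mean(k), centralization max(k)/n,
# path metrics on the largest connected component.
graph_metrics_oracle <- function(adj) {
  n <- nrow(adj)
  k <- rowSums(adj)
  clus <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    e <- sum(adj[nb, nb]) / 2
    2 * e / (length(nb) * (length(nb) - 1))
  }, 0)
  D <- bfs_distances(adj)
  comp <- rep(0L, n); cid <- 0L
  for (i in seq_len(n)) if (comp[i] == 0L) {
    cid <- cid + 1L
    comp[is.finite(D[i, ])] <- cid
  }
  big <- which(comp == which.max(tabulate(comp)))
  Db <- D[big, big, drop = FALSE]
  ecc <- apply(Db, 1, max)
  pairs <- Db[upper.tri(Db)]
  list(n_nodes = n, n_edges = sum(adj) / 2, avg_neighbors = mean(k),
       diameter = if (length(big) > 1) max(ecc) else 0,
       radius = if (length(big) > 1) min(ecc) else 0,
       char_path_length = if (length(pairs)) mean(pairs) else 0,
       clustering = mean(clus),
       density = if (n > 1) mean(k) / (n - 1) else 0,
       heterogeneity = if (mean(k) > 0) sqrt(mean((k - mean(k))^2)) / mean(k) else 0,
       centralization = max(k) / n)
}

# igraph graph from an adjacency matrix with chemical-kind node names
graph_from_adj <- function(adj) {
  rownames(adj) <- colnames(adj) <- paste0("m", seq_len(nrow(adj)))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$kind <- "chemical"
  igraph::V(g)$compartment <- "c"
  g
}

# Minimal two-step fixture: EX_S -(uptake)-> S -> M -> biomass, one enzyme on
# the middle step. Used by several suites.
linear_fixture <- function(kcat = 100, abundance = 0.01, uptake = 10) {
  mets <- data.frame(id = c("S[e]", "M[c]"), name = c("S", "M"),
                     compartment = c("e", "c"), kind = "chemical",
                     stringsAsFactors = FALSE)
  rx <- list(
    reaction("EX_S", c("S[e]" = -1), lb = -uptake, ub = 0, kind = "exchange"),
    reaction("r1", c("S[e]" = -1, "M[c]" = 1), gpr = parse_gpr("g1")),
    reaction("r_bio", c("M[c]" = -1)))
  model <- metabolic_model(mets, rx, genes = "g1", objective = "r_bio",
                           protein_map = c(g1 = "P1"))
  kt <- as_kcat_table(data.frame(protein = "P1", reaction = "r1",
                                 kcat_per_h = kcat, sa = NA_real_,
                                 mw_da = 5e4, source = "s"))
  ab <- as_abundance_table(data.frame(protein = "P1", abundance = abundance,
                                      unit = "mmol_gDW", taxon = "t",
                                      rank = "species"))
  list(model = model, kinetics = kt, abundances = ab,
       vmax = kcat * abundance, uptake = uptake)
}
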