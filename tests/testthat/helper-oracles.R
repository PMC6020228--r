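# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementation: quaternion
# eigenvalue superposition vs SVD Kabsch, Floyd-Warshall path counting vs
# Brandes betweenness, direct O(N^2) scans vs the package's contact pass.

# Minimal RMSD via the quaternion-eigenvalue method (Horn): the optimal
# superposition RMSD follows from the largest eigenvalue of the 4x4 key
# matrix built from the correlation of the centered point sets.
quaternion_rmsd <- function(mobile, reference) {
  m <- nrow(mobile)
  x <- sweep(mobile, 2, colMeans(mobile))
  y <- sweep(reference, 2, colMeans(reference))
  s <- crossprod(x, y)
  key <- matrix(0, 4, 4)
  key[1, 1] <- s[1, 1] + s[2, 2] + s[3, 3]
  key[1, 2] <- key[2, 1] <- s[2, 3] - s[3, 2]
  key[1, 3] <- key[3, 1] <- s[3, 1] - s[1, 3]
  key[1, 4] <- key[4, 1] <- s[1, 2] - s[2, 1]
  key[2, 2] <- s[1, 1] - s[2, 2] - s[3, 3]
  key[2, 3] <- key[3, 2] <- s[1, 2] + s[2, 1]
  key[2, 4] <- key[4, 2] <- s[1, 3] + s[3, 1]
  key[3, 3] <- -s[1, 1] + s[2, 2] - s[3, 3]
  key[3, 4] <- key[4, 3] <- s[2, 3] + s[3, 2]
  key[4, 4] <- -s[1, 1] - s[2, 2] + s[3, 3]
  lambda <- max(eigen(key, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(x^2) + sum(y^2) - 2 * lambda) / m
  sqrt(max(msd, 0))
}

# All-pairs shortest-path lengths by Floyd-Warshall on an adjacency matrix.
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

# Shortest-path counts: np[s, t] via DP over increasing distance.
fw_path_counts <- function(adj, d) {
  n <- nrow(adj)
  np <- matrix(0, n, n)
  diag(np) <- 1
  for (len in seq_len(n)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (is.finite(d[s, t]) && d[s, t] == len) {
        pred <- which(adj[, t] > 0 & d[s, ] == len - 1)
        np[s, t] <- sum(np[s, pred])
      }
    }
  }
  np
}

# Exhaustive normalized betweenness (fractional counting, norm (n-1)(n-2)/2).
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  np <- fw_path_counts(adj, d)
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s < t && s != v && t != v && is.finite(d[s, t]) && np[s, t] > 0 &&
          is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        b[v] <- b[v] + np[s, v] * np[v, t] / np[s, t]
      }
    }
  }
  if (n > 2) b / ((n - 1) * (n - 2) / 2) else b
}

bf_efficiency <- function(adj) {
  d <- fw_distances(adj)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

bf_removal_impact <- function(adj) {
  n <- nrow(adj)
  e0 <- bf_efficiency(adj)
  vapply(seq_len(n), function(v) {
    (e0 - bf_efficiency(adj[-v, -v, drop = FALSE])) / e0
  }, numeric(1))
}

# Brute-force residue contact scan: direct double loop over residue pairs.
bf_contacts <- function(structure, dmin = 2.5, dmax = 5.0,
                        include_ligand = FALSE) {
  atoms <- structure[structure$element != "H", ]
  if (!include_ligand) atoms <- atoms[!atoms$is_hetero, ]
  key <- paste(atoms$chain, atoms$resid, sep = ":")
  res <- unique(key)
  edges <- list()
  for (i in seq_along(res)) {
    ai <- atoms[key == res[i], ]
    for (j in seq_along(res)) {
      if (j <= i) next
      aj <- atoms[key == res[j], ]
      dm <- Inf
      for (p in seq_len(nrow(ai))) for (q in seq_len(nrow(aj))) {
        dd <- sqrt((ai$x[p] - aj$x[q])^2 + (ai$y[p] - aj$y[q])^2 +
                     (ai$z[p] - aj$z[q])^2)
        dm <- min(dm, dd)
      }
      if (dm >= dmin && dm <= dmax) {
        edges[[length(edges) + 1L]] <- c(res[i], res[j])
      }
    }
  }
  edges
}

# Wrap an adjacency matrix as a contact_network for the centrality code.
adj_to_network <- function(adj, node_names = NULL) {
  n <- nrow(adj)
  if (is.null(node_names)) node_names <- sprintf("A:%d:ALA", seq_len(n))
  pairs <- which(adj > 0 & upper.tri(adj), arr.ind = TRUE)
  out <- list(
    nodes = tibble::tibble(node = node_names, chain = "A",
                           resid = seq_len(n), resname = "ALA",
                           is_ligand = FALSE),
    edges = tibble::tibble(a = node_names[pairs[, 1]],
                           b = node_names[pairs[, 2]],
                           distance = 4.0),
    params = list(dmin = 2.5, dmax = 5.0, ligand_included = FALSE))
  class(out) <- "contact_network"
  out
}

random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  on <- up[stats::runif(length(up)) < p]
  adj[on] <- 1L
  adj + t(adj)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# Small helical/loop peptide with backbone + one side-chain atom per
# residue; used for selection, gate-distance and PDB round-trip tests.
toy_peptide <- function(resids = 55:60, chain = "A") {
  rows <- list()
  serial <- 0L
  for (k in seq_along(resids)) {
    # gentle zig-zag keeps the CA trace non-collinear
    base <- c(3.8 * k, 1.4 * (k %% 2), 0.4 * k)
    for (at in list(c("N", "N", 0, 0.5, 0), c("CA", "C", 0, 0, 0),
                    c("C", "C", 0.7, -0.5, 0), c("O", "O", 0.7, -1.5, 0),
                    c("CB", "C", 0, 0, 1.5))) {
      serial <- serial + 1L
      rows[[serial]] <- tibble::tibble(
        serial = serial, name = at[1], element = at[2], resname = "LEU",
        chain = chain, resid = resids[k],
        x = base[1] + as.numeric(at[3]), y = base[2] + as.numeric(at[4]),
        z = base[3] + as.numeric(at[5]), is_hetero = FALSE)
    }
  }
  as_structure(dplyr::bind_rows(rows))
}
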