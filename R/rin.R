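# Contact-based residue interaction networks (RINs) and centrality analysis.
#
# Contacts: an edge joins two residues when the minimum over their
# heavy-atom pairs lies inside the distance window [dmin, dmax] (defaults
# 2.5-5.0 A, endpoints inclusive). Edges are unweighted for path
# computations; the stored minimum distance is metadata. Two centralities
# are computed: normalized shortest-path betweenness, and removal-impact
# ("residue centrality"): the relative drop in global network efficiency
# when a node is deleted. Z-scores use the population SD, and residues with
# Z >= 2 form the central set by default.

water_resnames <- c("HOH", "WAT", "H2O", "DOD", "SOL", "TIP", "TIP3")

#' Build a residue interaction network from a structure
#'
#' @param structure A `pdb_structure` atom tibble.
#' @param dmin,dmax Contact window in Angstrom, endpoints inclusive.
#' @param include_ligand If `TRUE`, non-water hetero residues become nodes
#'   (one node per hetero residue, e.g. a bound palmitate); water is never
#'   included.
#' @param exclude_sequence_neighbors If `TRUE`, drop edges between residues
#'   adjacent in sequence (same chain, |delta resid| = 1).
#' @return A `contact_network`: list with `nodes` (tibble `node`, `chain`,
#'   `resid`, `resname`, `is_ligand`), `edges` (tibble `a`, `b`, `distance`),
#'   and `params`.
#' @examples
#' net <- detect_contacts(build_toy_barrel())
#' nrow(net$edges)
#' @export
detect_contacts <- function(structure, dmin = 2.5, dmax = 5.0,
                            include_ligand = FALSE,
                            exclude_sequence_neighbors = FALSE) {
  if (dmin >= dmax) abort("dmin must be smaller than dmax")
  atoms <- structure[structure$element != "H", , drop = FALSE]
  atoms <- atoms[!(atoms$resname %in% water_resnames), , drop = FALSE]
  if (!include_ligand) atoms <- atoms[!atoms$is_hetero, , drop = FALSE]
  res_key <- paste(atoms$chain, atoms$resid, sep = ":")
  res_tab <- atoms |>
    dplyr::distinct(.data$chain, .data$resid, .data$resname,
                    is_ligand = .data$is_hetero) |>
    dplyr::mutate(node = paste(.data$chain, .data$resid, .data$resname,
                               sep = ":"))
  if (nrow(res_tab) < 2) abort("structure must contain at least 2 residues")
  res_index <- match(res_key, paste(res_tab$chain, res_tab$resid, sep = ":"))

  xyz <- coords_matrix(atoms)
  # all-pairs residue minimum distances via a single atom-pair distance pass
  n_res <- nrow(res_tab)
  dmin_mat <- matrix(Inf, n_res, n_res)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  d2[d2 < 0] <- 0
  for (i in seq_len(nrow(atoms))) {
    ri <- res_index[i]
    row_min <- tapply(d2[i, ], res_index, min)
    upd <- sqrt(row_min) < dmin_mat[ri, as.integer(names(row_min))]
    dmin_mat[ri, as.integer(names(row_min))[upd]] <- sqrt(row_min)[upd]
  }
  dmin_mat <- pmin(dmin_mat, t(dmin_mat))
  pairs <- which(upper.tri(dmin_mat) &
                   dmin_mat >= dmin & dmin_mat <= dmax, arr.ind = TRUE)
  edges <- tibble(a = res_tab$node[pairs[, 1]],
                  b = res_tab$node[pairs[, 2]],
                  distance = dmin_mat[pairs])
  if (exclude_sequence_neighbors && nrow(edges) > 0) {
    ia <- match(edges$a, res_tab$node); ib <- match(edges$b, res_tab$node)
    seq_adj <- res_tab$chain[ia] == res_tab$chain[ib] &
      abs(res_tab$resid[ia] - res_tab$resid[ib]) == 1 &
      !res_tab$is_ligand[ia] & !res_tab$is_ligand[ib]
    edges <- edges[!seq_adj, , drop = FALSE]
  }
  out <- list(nodes = res_tab[, c("node", "chain", "resid", "resname",
                                  "is_ligand")],
              edges = edges,
              params = list(dmin = dmin, dmax = dmax,
                            ligand_included = include_ligand,
                            exclude_sequence_neighbors =
                              exclude_sequence_neighbors))
  class(out) <- "contact_network"
  out
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("<contact_network> %d nodes, %d edges (window %.1f-%.1f A%s)\n",
              nrow(x$nodes), nrow(x$edges), x$params$dmin, x$params$dmax,
              if (x$params$ligand_included) ", ligand included" else ""))
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges[, c("a", "b")],
                                directed = FALSE,
                                vertices = network$nodes$node)
}

#' Normalized shortest-path betweenness per node
#'
#' Betweenness with fractional counting over equal-length shortest paths,
#' normalized by `(n-1)(n-2)/2` (undirected, unweighted edges).
#'
#' @param network A [detect_contacts()] result.
#' @return Tibble `node`, `betweenness`.
#' @export
betweenness_centrality <- function(network) {
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  if (n == 0) abort("empty network")
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  tibble(node = names(b), betweenness = as.numeric(b) / norm)
}

graph_efficiency <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  d <- igraph::distances(g, weights = NA)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0  # disconnected pairs contribute zero
  mean(inv)
}

#' Removal-impact (residue) centrality
#'
#' For each node, the relative drop in global network efficiency when the
#' node is deleted: `(E(G) - E(G \ i)) / E(G)`, where efficiency `E` is the
#' mean over node pairs of the inverse shortest-path length (disconnected
#' pairs contribute zero).
#'
#' @param network A [detect_contacts()] result with at least 3 nodes.
#' @return Tibble `node`, `impact`.
#' @export
removal_impact <- function(network) {
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  if (n < 3) abort("degenerate network: need at least 3 nodes")
  e0 <- graph_efficiency(g)
  if (e0 == 0) abort("network has no connected pairs")
  impacts <- vapply(igraph::V(g)$name, function(v) {
    (e0 - graph_efficiency(igraph::delete_vertices(g, v))) / e0
  }, numeric(1))
  tibble(node = names(impacts), impact = as.numeric(impacts))
}

#' Z-scores and central set for a centrality vector
#'
#' `Z_i = (c_i - mean) / SD_population`; when the SD is zero all Z are zero.
#' Nodes with `Z >= z_threshold` form the central set (default threshold 2).
#'
#' @param values Tibble with `node` and one numeric centrality column.
#' @param z_threshold Central-set cutoff on Z.
#' @return The input with added columns `z` and `central`.
#' @export
centrality_zscores <- function(values, z_threshold = 2) {
  if (nrow(values) < 2) abort("degenerate input: need at least 2 nodes")
  num_col <- setdiff(names(values), "node")[1]
  v <- values[[num_col]]
  sd_pop <- sqrt(mean((v - mean(v))^2))
  z <- if (sd_pop > 0) (v - mean(v)) / sd_pop else rep(0, length(v))
  dplyr::mutate(values, z = z, central = z >= z_threshold)
}

#' Full centrality report for a network
#'
#' Computes betweenness and removal-impact centralities with Z-scores, and
#' the central residue set on the chosen metric. When the ligand node is
#' present and ranks first by betweenness, the report flags it: the ligand
#' tends to dominate the network when included.
#'
#' @param network A [detect_contacts()] result.
#' @param metric Which Z-score defines the central set:
#'   `"removal_impact"` (default) or `"betweenness"`.
#' @param z_threshold Central-set cutoff (default 2).
#' @return A `centrality_report`: tibble with per-node `betweenness`,
#'   `impact`, `z_betweenness`, `z_impact`, `z`, `central`; attributes
#'   `metric`, `z_threshold`, `ligand_dominates`.
#' @export
centrality_report <- function(network,
                              metric = c("removal_impact", "betweenness"),
                              z_threshold = 2) {
  metric <- match.arg(metric)
  bt <- centrality_zscores(betweenness_centrality(network), z_threshold)
  im <- centrality_zscores(removal_impact(network), z_threshold)
  out <- dplyr::inner_join(
    dplyr::rename(bt, z_betweenness = "z", central_betweenness = "central"),
    dplyr::rename(im, z_impact = "z", central_impact = "central"),
    by = "node")
  out$z <- if (metric == "removal_impact") out$z_impact else out$z_betweenness
  out$central <- out$z >= z_threshold
  lig_nodes <- network$nodes$node[network$nodes$is_ligand]
  ligand_dominates <- length(lig_nodes) > 0 &&
    out$node[which.max(out$betweenness)] %in% lig_nodes
  if (ligand_dominates) {
    warn("ligand node has the top betweenness: the ligand dominates this network")
  }
  attr(out, "metric") <- metric
  attr(out, "z_threshold") <- z_threshold
  attr(out, "ligand_dominates") <- ligand_dominates
  class(out) <- c("centrality_report", class(out))
  out
}

central_set <- function(report) report$node[report$central]

#' Differential centrality between a reference and variant structures
#'
#' Compares the central residue set of a reference structure with those of
#' one or more variant structures (e.g. the independent mutant monomers from
#' several crystal forms). A node is "gained" when central in at least one
#' variant but not in the reference, "lost" when central in the reference
#' but in no variant. Nodes absent from a report are treated as non-central
#' there.
#'
#' @param reference A [centrality_report()] for the reference structure.
#' @param variants List of [centrality_report()]s for variant structures.
#' @return A `differential_centrality` list: `reference_central`,
#'   `variant_central` (per variant), `gained`, `lost`.
#' @export
compare_centrality <- function(reference, variants) {
  if (inherits(variants, "centrality_report")) variants <- list(variants)
  ref_nodes <- reference$node
  var_sets <- lapply(variants, central_set)
  overlap <- any(vapply(variants, function(v) any(v$node %in% ref_nodes),
                        logical(1)))
  if (!overlap) abort("no overlap between reference and variant node sets")
  ref_central <- central_set(reference)
  any_variant <- unique(unlist(var_sets))
  structure(list(reference_central = ref_central,
                 variant_central = var_sets,
                 gained = setdiff(any_variant, ref_central),
                 lost = setdiff(ref_central, any_variant)),
            class = "differential_centrality")
}

#' @export
print.differential_centrality <- function(x, ...) {
  cat(sprintf("<differential_centrality> %d reference-central, %d gained, %d lost\n",
              length(x$reference_central), length(x$gained), length(x$lost)))
  invisible(x)
}

#' Write a network in simple interaction format
#'
#' One edge per line: `nodeA nodeB distance`.
#'
#' @param network A [detect_contacts()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path) {
  writeLines(sprintf("%s %s %.3f", network$edges$a, network$edges$b,
                     network$edges$distance), path)
  invisible(path)
}
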