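two_residue_structure <- function(gap) {
  # two single-atom residues whose closest heavy atoms are `gap` apart
  as_structure(tibble::tibble(
    serial = 1:2, name = "CA", element = "C", resname = "ALA", chain = "A",
    resid = c(1L, 5L), x = c(0, gap), y = 0, z = 0, is_hetero = FALSE))
}

test_that("contact edges require the minimum heavy-atom distance inside the window", {
  expect_equal(nrow(detect_contacts(two_residue_structure(3.0))$edges), 1)
  expect_equal(nrow(detect_contacts(two_residue_structure(2.0))$edges), 0)
  expect_equal(nrow(detect_contacts(two_residue_structure(6.0))$edges), 0)
  # endpoints inclusive
  expect_equal(nrow(detect_contacts(two_residue_structure(2.5))$edges), 1)
  expect_equal(nrow(detect_contacts(two_residue_structure(5.0))$edges), 1)
  expect_error(detect_contacts(two_residue_structure(3), dmin = 5, dmax = 2.5),
               "dmin")
})

test_that("contact detection equals the brute-force all-pairs scan on toy barrels", {
  for (params in list(list(lig = FALSE, r = 7.5), list(lig = TRUE, r = 7.5),
                      list(lig = TRUE, r = 9))) {
    barrel <- build_toy_barrel(radius = params$r, with_ligand = params$lig)
    net <- detect_contacts(barrel, include_ligand = params$lig)
    oracle <- bf_contacts(barrel, include_ligand = params$lig)
    got <- sort(paste(pmin(net$edges$a, net$edges$b),
                      pmax(net$edges$a, net$edges$b)))
    node_of <- setNames(net$nodes$node,
                        paste(net$nodes$chain, net$nodes$resid, sep = ":"))
    want <- sort(vapply(oracle, function(e) {
      paste(pmin(node_of[e[1]], node_of[e[2]]),
            pmax(node_of[e[1]], node_of[e[2]]))
    }, character(1)))
    expect_equal(got, want)
    expect_true(nrow(net$edges) > 0)
    expect_true(all(net$edges$distance >= 2.5 & net$edges$distance <= 5))
  }
})

test_that("contact network is invariant to atom order and excludes water and hydrogens", {
  set.seed(53)
  barrel <- build_toy_barrel(with_ligand = TRUE)
  net1 <- detect_contacts(barrel, include_ligand = TRUE)
  perm <- sample(nrow(barrel))
  net2 <- detect_contacts(portalwatch:::new_structure(barrel[perm, ]),
                          include_ligand = TRUE)
  key <- function(net) sort(paste(pmin(net$edges$a, net$edges$b),
                                  pmax(net$edges$a, net$edges$b)))
  expect_equal(key(net1), key(net2))
  # water never becomes a node even with ligand inclusion
  wat <- barrel
  wat$resname[wat$is_hetero] <- "HOH"
  net3 <- detect_contacts(wat, include_ligand = TRUE)
  expect_false(any(grepl("HOH", net3$nodes$node)))
  # hydrogens are ignored: add an H bridging two distant residues
  far <- two_residue_structure(6.0)
  h <- far[1, ]; h$serial <- 3L; h$name <- "H1"; h$element <- "H"; h$x <- 3
  with_h <- portalwatch:::new_structure(rbind(far, h))
  expect_equal(nrow(detect_contacts(with_h)$edges), 0)
})

test_that("sequence-neighbour exclusion drops only |delta resid| = 1 edges", {
  pep <- toy_peptide(resids = 10:15)
  net_all <- detect_contacts(pep)
  net_ex <- detect_contacts(pep, exclude_sequence_neighbors = TRUE)
  ia <- match(net_all$edges$a, net_all$nodes$node)
  ib <- match(net_all$edges$b, net_all$nodes$node)
  adj <- abs(net_all$nodes$resid[ia] - net_all$nodes$resid[ib]) == 1
  expect_equal(nrow(net_ex$edges), sum(!adj))
})

test_that("betweenness matches hand values on path and complete graphs", {
  path3 <- adj_to_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  b <- betweenness_centrality(path3)
  expect_equal(b$betweenness, c(0, 1, 0))
  k4 <- adj_to_network(matrix(1, 4, 4) - diag(4))
  expect_true(all(betweenness_centrality(k4)$betweenness == 0))
})

test_that("betweenness and removal impact match exhaustive oracles on all small graphs", {
  set.seed(54)
  n_checked <- 0
  while (n_checked < 40) {
    n <- sample(4:8, 1)
    adj <- random_adjacency(n, runif(1, 0.25, 0.7))
    net <- adj_to_network(adj)
    expect_equal(betweenness_centrality(net)$betweenness, bf_betweenness(adj),
                 tolerance = 1e-12)
    if (sum(adj) > 0 && bf_efficiency(adj) > 0) {
      expect_equal(removal_impact(net)$impact, bf_removal_impact(adj),
                   tolerance = 1e-12)
    }
    n_checked <- n_checked + 1
  }
})

test_that("removal impact ranks cut vertices above leaves and is symmetric on K4", {
  path3 <- adj_to_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  imp <- removal_impact(path3)
  expect_gt(imp$impact[2], imp$impact[1])
  k4 <- adj_to_network(matrix(1, 4, 4) - diag(4))
  expect_equal(length(unique(round(removal_impact(k4)$impact, 12))), 1)
  two <- adj_to_network(rbind(c(0, 1), c(1, 0)))
  expect_error(removal_impact(two), "at least 3")
})

test_that("Z-scores use population SD, are affine invariant, and gate the central set", {
  v <- tibble::tibble(node = letters[1:5], impact = c(0, 0, 0, 0, 10))
  z <- centrality_zscores(v)
  expect_equal(z$z[5], 2)  # (10 - 2) / 4 by direct arithmetic
  expect_equal(z$z[1], -0.5)
  expect_equal(z$node[z$central], "e")
  expect_equal(mean(z$z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z$z^2)), 1, tolerance = 1e-12)
  # all equal -> all zero, empty central set
  flat <- centrality_zscores(tibble::tibble(node = letters[1:4],
                                            impact = rep(3, 4)))
  expect_true(all(flat$z == 0))
  expect_false(any(flat$central))
  # affine rescaling leaves Z unchanged
  v2 <- v; v2$impact <- 7 * v$impact - 3
  expect_equal(centrality_zscores(v2)$z, z$z)
  expect_error(centrality_zscores(v[1, ]), "at least 2")
})

test_that("differential centrality reports gained and lost nodes per the union rule", {
  mk_report <- function(nodes, central_nodes) {
    out <- tibble::tibble(node = nodes, z = ifelse(nodes %in% central_nodes,
                                                   3, 0),
                          central = nodes %in% central_nodes,
                          betweenness = 0)
    class(out) <- c("centrality_report", class(out))
    out
  }
  nodes <- sprintf("A:%d:ALA", 1:6)
  ref <- mk_report(nodes, nodes[1])
  same <- compare_centrality(ref, list(ref, ref))
  expect_length(same$gained, 0)
  expect_length(same$lost, 0)
  # node central in 1 of 6 variants only -> gained
  variants <- c(lapply(1:5, function(i) mk_report(nodes, nodes[1])),
                list(mk_report(nodes, c(nodes[1], nodes[4]))))
  diffc <- compare_centrality(ref, variants)
  expect_equal(diffc$gained, nodes[4])
  expect_length(diffc$lost, 0)
  # lost: central in reference, central in no variant
  diffc2 <- compare_centrality(mk_report(nodes, nodes[1:2]),
                               list(mk_report(nodes, nodes[1])))
  expect_equal(diffc2$lost, nodes[2])
  expect_error(compare_centrality(ref, list(mk_report(letters[1:3], "a"))),
               "overlap")
})

test_that("an engineered hub gain in a perturbed network is detected", {
  set.seed(55)
  adj <- random_adjacency(10, 0.25)
  adj[1, ] <- 0; adj[, 1] <- 0
  adj[1, 2] <- adj[2, 1] <- 1  # node 1 is a leaf in the reference
  hub <- adj
  hub[1, ] <- 1; hub[, 1] <- 1; diag(hub) <- 0  # node 1 becomes a hub
  ref_rep <- centrality_report(adj_to_network(adj))
  hub_rep <- centrality_report(adj_to_network(hub))
  diffc <- compare_centrality(ref_rep, list(hub_rep))
  expect_true("A:1:ALA" %in% diffc$gained)
})

test_that("the ligand dominates the network when included", {
  barrel <- build_toy_barrel(with_ligand = TRUE)
  net <- detect_contacts(barrel, include_ligand = TRUE)
  lig <- net$nodes$node[net$nodes$is_ligand]
  expect_length(lig, 1)
  g_deg <- table(c(net$edges$a, net$edges$b))
  lig_deg <- as.integer(g_deg[lig])
  # axial ligand contacts every strand: its degree beats any single removal
  expect_gte(lig_deg, max(g_deg[names(g_deg) != lig]) - 1)
  expect_warning(rep_l <- centrality_report(net), "ligand dominates")
  expect_true(attr(rep_l, "ligand_dominates"))
  no_lig <- detect_contacts(barrel, include_ligand = FALSE)
  expect_warning(centrality_report(no_lig), NA)
})
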