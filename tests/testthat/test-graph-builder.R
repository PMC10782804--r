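test_that("node selection honours the interface cutoff", {
  far <- parse_pdb(two_ca_pdb(sep = 20), c("A", "B"))
  expect_error(select_interface_nodes(far), "empty interface")
  near <- parse_pdb(two_ca_pdb(sep = 5), c("A", "B"))
  nodes <- select_interface_nodes(near)
  expect_equal(nrow(nodes), 2L)
  expect_equal(nodes$chain, c("A", "B"))
})

test_that("node and edge sets match brute-force quadratic scans", {
  for (seed in 1:20) {
    gen <- generate_complex(12, 100 + seed)
    cx <- parse_pdb(gen$pdb, c("A", "B"))
    res <- lapply(seq_len(nrow(cx$residues)), get_residue, complex = cx)
    n <- length(res)
    D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      D[i, j] <- min_heavy_atom_distance(res[[i]], res[[j]])
    }
    ch <- cx$residues$chain
    is_node <- vapply(seq_len(n), function(i) {
      min(D[i, ch != ch[i]]) <= 8.5
    }, TRUE)
    nodes <- select_interface_nodes(cx)
    expect_equal(sort(nodes$ridx), which(is_node))

    edges <- build_edges(cx, nodes)
    idx <- nodes$ridx
    want_int <- want_ifc <- NULL
    for (i in seq_along(idx)) for (j in seq_along(idx)) {
      if (i >= j) next
      d <- D[idx[i], idx[j]]
      if (ch[idx[i]] == ch[idx[j]] && d <= 3.0) {
        want_int <- rbind(want_int, c(i, j))
      }
      if (ch[idx[i]] != ch[idx[j]] && d <= 8.5) {
        want_ifc <- rbind(want_ifc, c(i, j))
      }
    }
    norm <- function(m) if (is.null(m)) matrix(integer(0), 0, 2) else m
    expect_equal(edges$internal$index, norm(want_int),
                 ignore_attr = TRUE)
    expect_equal(edges$interface$index, norm(want_ifc),
                 ignore_attr = TRUE)
  }
})

test_that("hand-enumerated toy geometry yields the expected edges", {
  # 3 chain-A residues mutually within 2 A; 1 chain-B residue 6 A away
  lines <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
             pdb_line(2, "CA", "GLY", "A", 2, 1.5, 0, 0, "C"),
             pdb_line(3, "CA", "SER", "A", 3, 0.75, 1.3, 0, "C"),
             pdb_line(4, "CA", "LYS", "B", 1, 0.75, 0.4, 6, "C"),
             "END")
  cx <- parse_pdb(lines, c("A", "B"))
  nodes <- select_interface_nodes(cx)
  expect_equal(nrow(nodes), 4L)
  edges <- build_edges(cx, nodes)
  expect_equal(nrow(edges$internal$index), 3L)
  expect_equal(nrow(edges$interface$index), 3L)
  # 2-node version: single cross-chain pair at 5 A
  cx2 <- parse_pdb(two_ca_pdb(sep = 5), c("A", "B"))
  e2 <- build_edges(cx2, select_interface_nodes(cx2))
  expect_equal(nrow(e2$internal$index), 0L)
  expect_equal(nrow(e2$interface$index), 1L)
  expect_equal(unname(e2$interface$dist[1, "raw"]), 5)
  expect_equal(unname(e2$interface$dist[1, "normalized"]), 5 / 8.5)
})

test_that("edge distance normalization is linear and range-guarded", {
  expect_equal(normalize_edge_distance(0, 8.5), 0)
  expect_equal(normalize_edge_distance(8.5, 8.5), 1)
  expect_equal(normalize_edge_distance(4.25, 8.5), 0.5)
  expect_error(normalize_edge_distance(9, 8.5), "distance out of range")
  expect_error(normalize_edge_distance(-1, 8.5), "distance out of range")
})

test_that("edge types respect chain membership and node sets are monotone", {
  for (seed in c(31, 32, 33)) {
    gen <- generate_complex(14, seed)
    cx <- parse_pdb(gen$pdb, c("A", "B"))
    nodes <- select_interface_nodes(cx)
    edges <- build_edges(cx, nodes)
    ii <- edges$internal$index
    if (nrow(ii)) {
      expect_true(all(nodes$chain[ii[, 1]] == nodes$chain[ii[, 2]]))
    }
    fi <- edges$interface$index
    expect_true(all(nodes$chain[fi[, 1]] != nodes$chain[fi[, 2]]))
    # monotone in the cutoff
    n6 <- tryCatch(select_interface_nodes(cx, 6.0)$key,
                   error = function(e) character(0))
    expect_true(all(n6 %in% nodes$key))
    # normalized distances within [0, 1]
    expect_true(all(edges$interface$dist[, "normalized"] >= 0 &
                      edges$interface$dist[, "normalized"] <= 1))
  }
})

test_that("graph construction is invariant under rigid motion and chain swap", {
  gen <- generate_complex(12, 41)
  cx <- parse_pdb(gen$pdb, c("A", "B"))
  nodes <- select_interface_nodes(cx)
  edges <- build_edges(cx, nodes)

  R <- dockgraph:::random_rotation(2)
  cx_m <- dockgraph:::transform_complex(cx, R, c(5, -9, 3))
  nodes_m <- select_interface_nodes(cx_m)
  expect_identical(nodes_m$key, nodes$key)
  edges_m <- build_edges(cx_m, nodes_m)
  expect_identical(edges_m$internal$index, edges$internal$index)
  expect_identical(edges_m$interface$index, edges$interface$index)
  expect_equal(edges_m$interface$dist, edges$interface$dist,
               tolerance = 1e-9)

  # swapped chain order: same node set, deterministically reordered
  cx_s <- parse_pdb(gen$pdb, c("B", "A"))
  nodes_s <- select_interface_nodes(cx_s)
  expect_setequal(nodes_s$key, nodes$key)
  edges_s <- build_edges(cx_s, nodes_s)
  expect_equal(nrow(edges_s$internal$index), nrow(edges$internal$index))
  expect_equal(nrow(edges_s$interface$index), nrow(edges$interface$index))
})

test_that("HDF5 container round-trips graphs exactly", {
  g1 <- toy_graph(1, d = 6L, target = 0.25)
  g2 <- toy_graph(2, d = 6L, target = 0.75)
  path <- tempfile(fileext = ".h5")
  write_graphs(list(g1, g2), path)
  back <- read_graphs(path)
  expect_setequal(names(back), c(g1$graph_id, g2$graph_id))
  expect_same_graph(back[[g1$graph_id]], g1)
  expect_same_graph(back[[g2$graph_id]], g2)
  expect_equal(back[[g1$graph_id]]$feature_config$dim, 6L)
})

test_that("a ten-graph container reports ten graph ids", {
  graphs <- lapply(1:10, function(s) toy_graph(s, d = 5L, target = s / 10))
  path <- tempfile(fileext = ".h5")
  write_graphs(graphs, path)
  expect_length(read_graphs(path), 10L)
})

test_that("schema mismatches and corrupt containers are refused", {
  g1 <- toy_graph(1, d = 6L)
  g2 <- toy_graph(2, d = 9L)
  expect_error(write_graphs(list(g1, g2), tempfile(fileext = ".h5")),
               "inconsistent feature schema")
  path <- tempfile(fileext = ".h5")
  write_graphs(list(g1), path)
  expect_error(append_graphs(list(g2), path),
               "inconsistent feature schema")
  expect_error(read_graphs(tempfile(fileext = ".h5")), "corrupt container")
  # missing dataset
  rhdf5::h5delete(path, paste0(g1$graph_id, "/node_feats"))
  expect_error(read_graphs(path), "corrupt container")
})
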