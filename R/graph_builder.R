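# Interface residue graphs: node selection at the chain-chain interface,
# internal (same-chain) and interface (cross-chain) edges with raw and
# normalized distances, and an HDF5 container for graph sets.

#' Select interface residue nodes
#'
#' A residue becomes a graph node iff its minimum heavy-atom distance to any
#' residue of the other chain is at most \code{interface_cutoff}. Nodes are
#' ordered by chain, then residue number, then insertion code.
#'
#' @param complex A \code{ppi_complex} with two chains.
#' @param interface_cutoff Interface distance cutoff, Angstrom.
#' @param dist_matrix Optional precomputed residue minimum-distance matrix
#'   (internal reuse).
#' @return Data frame of nodes: chain, resno, icode, resname, key, ridx.
#' @export
select_interface_nodes <- function(complex, interface_cutoff = 8.5,
                                   dist_matrix = NULL) {
  res <- complex$residues
  if (length(unique(res$chain)) != 2L) stop("two chains required")
  M <- if (is.null(dist_matrix)) residue_min_dist_matrix(complex) else
    dist_matrix
  a <- which(res$chain == complex$chains[1])
  b <- which(res$chain == complex$chains[2])
  cross <- M[a, b, drop = FALSE]
  keep_a <- a[apply(cross, 1, min) <= interface_cutoff]
  keep_b <- b[apply(cross, 2, min) <= interface_cutoff]
  ridx <- c(keep_a, keep_b)   # residues table is already in node order
  if (length(ridx) == 0L) {
    stop("empty interface: no residue within ", interface_cutoff,
         " Angstrom of the partner chain")
  }
  out <- res[ridx, , drop = FALSE]
  out$ridx <- ridx
  rownames(out) <- NULL
  out
}

#' Build internal and interface edges over selected nodes
#'
#' Interface edges join cross-chain node pairs with minimum heavy-atom
#' distance at most \code{interface_cutoff}; internal edges join same-chain
#' node pairs within \code{internal_cutoff}. Each undirected pair is stored
#' once (i < j) with its raw distance and the distance normalized by the
#' edge type's own cutoff.
#'
#' @inheritParams select_interface_nodes
#' @param nodes Node data frame from [select_interface_nodes()].
#' @param internal_cutoff Same-chain edge cutoff, Angstrom.
#' @return List with \code{internal} and \code{interface}, each a list of
#'   \code{index} (m x 2 node indices, i < j), \code{dist} (m x 2: raw,
#'   normalized).
#' @export
build_edges <- function(complex, nodes, internal_cutoff = 3.0,
                        interface_cutoff = 8.5, dist_matrix = NULL) {
  M <- if (is.null(dist_matrix)) residue_min_dist_matrix(complex) else
    dist_matrix
  n <- nrow(nodes)
  D <- M[nodes$ridx, nodes$ridx, drop = FALSE]
  same <- outer(nodes$chain, nodes$chain, "==")
  upper <- upper.tri(D)
  mk <- function(mask, cutoff) {
    sel <- which(upper & mask & D <= cutoff, arr.ind = TRUE)
    sel <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
    d <- D[sel]
    list(index = matrix(as.integer(sel), ncol = 2),
         dist = cbind(raw = d,
                      normalized = vapply(d, normalize_edge_distance, 0,
                                          cutoff = cutoff)))
  }
  list(internal = mk(same, internal_cutoff),
       interface = mk(!same, interface_cutoff))
}

#' Normalize an edge distance by its cutoff
#'
#' @param d Raw distance, Angstrom, in \code{[0, cutoff]}.
#' @param cutoff Cutoff of the edge type, Angstrom.
#' @return \code{d / cutoff}, in \code{[0, 1]}.
#' @export
normalize_edge_distance <- function(d, cutoff) {
  if (d < 0 || d > cutoff) {
    stop("distance out of range: ", d, " for cutoff ", cutoff)
  }
  d / cutoff
}

#' Build the interface graph of a two-chain complex
#'
#' Runs node selection, edge construction and feature assembly, returning
#' the persistable graph object.
#'
#' @inheritParams build_edges
#' @param config A \code{feature_config}.
#' @param graph_id Identifier of the graph (defaults to the complex id).
#' @param complex_id Identifier of the parent complex (for dataset indexing).
#' @param target Optional scalar label: fnat in \code{[0,1]} or a class in
#'   \code{{0,1}}.
#' @param bsa,pssm,embeddings Feature sources forwarded to
#'   [assemble_node_features()]; \code{bsa} is computed on the fly when
#'   required and missing.
#' @return An \code{interface_graph}: list with \code{graph_id},
#'   \code{complex_id}, \code{nodes}, \code{node_feats},
#'   \code{internal_index}, \code{internal_dist}, \code{interface_index},
#'   \code{interface_dist}, \code{target}, \code{feature_config}.
#' @export
build_graph <- function(complex, config,
                        graph_id = complex$id, complex_id = complex$id,
                        target = NA_real_, internal_cutoff = 3.0,
                        interface_cutoff = 8.5, bsa = NULL, pssm = NULL,
                        embeddings = NULL) {
  M <- residue_min_dist_matrix(complex)
  nodes <- select_interface_nodes(complex, interface_cutoff, dist_matrix = M)
  edges <- build_edges(complex, nodes, internal_cutoff, interface_cutoff,
                       dist_matrix = M)
  if (config$use_bsa && is.null(bsa)) bsa <- compute_bsa_all(complex)
  feats <- assemble_node_features(complex, nodes, config, bsa = bsa,
                                  pssm = pssm, embeddings = embeddings)
  structure(list(graph_id = graph_id, complex_id = complex_id,
                 nodes = nodes[, c("chain", "resno", "icode", "resname",
                                   "key")],
                 node_feats = feats,
                 internal_index = edges$internal$index,
                 internal_dist = edges$internal$dist,
                 interface_index = edges$interface$index,
                 interface_dist = edges$interface$dist,
                 target = as.numeric(target),
                 feature_config = config),
            class = "interface_graph")
}

#' @export
print.interface_graph <- function(x, ...) {
  cat("interface_graph '", x$graph_id, "': ", nrow(x$nodes), " nodes, ",
      nrow(x$internal_index), " internal + ", nrow(x$interface_index),
      " interface edges, d = ", ncol(x$node_feats),
      if (!is.na(x$target)) sprintf(", target %.3f", x$target) else "",
      "\n", sep = "")
  invisible(x)
}

serialize_config <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
}

deserialize_config <- function(json) {
  l <- jsonlite::fromJSON(json)
  feature_config(l$use_type, l$use_polarity, l$use_bsa, l$use_charge,
                 l$use_pssm_block, l$use_embedding, l$embedding_dim)
}

#' Write a collection of interface graphs to an HDF5 container
#'
#' Layout: one group per \code{graph_id} with datasets \code{nodes} (string
#' table), \code{node_feats}, \code{edge_internal_index},
#' \code{edge_internal_dist}, \code{edge_interface_index},
#' \code{edge_interface_dist}, group attributes \code{target} and
#' \code{complex_id}, and a file-level attribute \code{feature_config}
#' (serialized JSON). All graphs in one container must share one feature
#' schema.
#'
#' @param graphs List of \code{interface_graph} objects.
#' @param path Output file path (overwritten).
#' @return \code{path}, invisibly.
#' @export
write_graphs <- function(graphs, path) {
  if (length(graphs) == 0L) stop("no graphs to write")
  dims <- vapply(graphs, function(g) ncol(g$node_feats), 0L)
  if (length(unique(dims)) != 1L) {
    stop("inconsistent feature schema: node feature dimensions ",
         paste(unique(dims), collapse = " vs "))
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(as.character(serialize_config(
    graphs[[1]]$feature_config)), fid, "feature_config")
  rhdf5::H5Fclose(fid)
  for (g in graphs) {
    grp <- g$graph_id
    rhdf5::h5createGroup(path, grp)
    nodes_tab <- with(g$nodes, rbind(chain, as.character(resno),
                                     icode, resname))
    rhdf5::h5write(nodes_tab, path, paste0(grp, "/nodes"))
    rhdf5::h5write(g$node_feats, path, paste0(grp, "/node_feats"))
    rhdf5::h5write(g$internal_index, path,
                   paste0(grp, "/edge_internal_index"))
    rhdf5::h5write(unname(g$internal_dist), path,
                   paste0(grp, "/edge_internal_dist"))
    rhdf5::h5write(g$interface_index, path,
                   paste0(grp, "/edge_interface_index"))
    rhdf5::h5write(unname(g$interface_dist), path,
                   paste0(grp, "/edge_interface_dist"))
    gid <- rhdf5::H5Gopen(rhdf5::H5Fopen(path), grp)
    rhdf5::h5writeAttribute(as.numeric(g$target), gid, "target")
    rhdf5::h5writeAttribute(as.character(g$complex_id), gid, "complex_id")
    rhdf5::H5Gclose(gid)
    rhdf5::h5closeAll()
  }
  invisible(path)
}

#' Append graphs to an existing container
#'
#' Refuses graphs whose feature dimension differs from the container's
#' schema ("inconsistent feature schema").
#'
#' @inheritParams write_graphs
#' @export
append_graphs <- function(graphs, path) {
  existing <- read_graphs(path)
  cfg <- existing[[1]]$feature_config
  for (g in graphs) {
    if (ncol(g$node_feats) != cfg$dim) {
      stop("inconsistent feature schema: container stores d = ", cfg$dim,
           ", graph '", g$graph_id, "' has d = ", ncol(g$node_feats))
    }
  }
  write_graphs(c(existing, graphs), path)
}

#' Read an interface-graph container
#'
#' @param path HDF5 container written by [write_graphs()].
#' @return Named list of \code{interface_graph} objects (names are
#'   graph_ids).
#' @export
read_graphs <- function(path) {
  if (!file.exists(path)) stop("corrupt container: file not found")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  attrs <- rhdf5::h5readAttributes(path, "/")
  if (is.null(attrs$feature_config)) {
    stop("corrupt container: missing feature_config attribute")
  }
  config <- deserialize_config(attrs$feature_config)
  contents <- rhdf5::h5ls(path)
  ids <- contents$name[contents$group == "/" & contents$otype == "H5I_GROUP"]
  need <- c("nodes", "node_feats", "edge_internal_index",
            "edge_internal_dist", "edge_interface_index",
            "edge_interface_dist")
  out <- list()
  for (grp in ids) {
    have <- contents$name[contents$group == paste0("/", grp)]
    if (!all(need %in% have)) {
      stop("corrupt container: group '", grp, "' is missing datasets ",
           paste(setdiff(need, have), collapse = ", "))
    }
    rd <- function(nm) rhdf5::h5read(path, paste0(grp, "/", nm))
    nt <- rd("nodes")
    nodes <- data.frame(chain = nt[1, ], resno = as.integer(nt[2, ]),
                        icode = nt[3, ], resname = nt[4, ],
                        stringsAsFactors = FALSE)
    nodes$key <- paste0(nodes$chain, ":", nodes$resno, ":",
                        trimws(nodes$icode))
    ga <- rhdf5::h5readAttributes(path, grp)
    fix_idx <- function(m) matrix(as.integer(m), ncol = 2)
    fix_dst <- function(m) {
      m <- matrix(as.numeric(m), ncol = 2)
      colnames(m) <- c("raw", "normalized")
      m
    }
    out[[grp]] <- structure(list(
      graph_id = grp,
      complex_id = as.character(ga$complex_id),
      nodes = nodes,
      node_feats = matrix(as.numeric(rd("node_feats")),
                          nrow = nrow(nodes)),
      internal_index = fix_idx(rd("edge_internal_index")),
      internal_dist = fix_dst(rd("edge_internal_dist")),
      interface_index = fix_idx(rd("edge_interface_index")),
      interface_dist = fix_dst(rd("edge_interface_dist")),
      target = as.numeric(ga$target),
      feature_config = config), class = "interface_graph")
  }
  out
}
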