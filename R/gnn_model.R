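# The scoring network: two attention graph-convolution branches (one over
# internal edges, one over interface edges), Louvain community pooling with
# element-wise max aggregation between the two convolution layers, a
# max read-out per branch, and a dense head. Forward and backward passes
# are written out explicitly; gradients are validated against finite
# differences in the test suite.

#' Network architecture specification
#'
#' Defaults reproduce the published trainable-parameter counts exactly:
#' total parameters = \code{32*input_dim + 9673} with the default widths
#' (52169 at d = 1328, 51465 at d = 1306).
#'
#' @param input_dim Node feature dimension d (from the feature config).
#' @param conv1_out,conv2_out Widths of the two convolution layers.
#' @param head_hidden Hidden width of the dense head.
#' @param task \code{"regression"} (fnat) or \code{"classification"}
#'   (biological-vs-crystal interface).
#' @param leaky_slope Negative slope of the attention LeakyReLU.
#' @return A \code{network_spec} list.
#' @export
network_spec <- function(input_dim, conv1_out = 16L, conv2_out = 32L,
                         head_hidden = 128L,
                         task = c("regression", "classification"),
                         leaky_slope = 0.2) {
  structure(list(input_dim = as.integer(input_dim),
                 conv1_out = as.integer(conv1_out),
                 conv2_out = as.integer(conv2_out),
                 head_hidden = as.integer(head_hidden),
                 head_out = 1L, edge_feature_dim = 1L,
                 task = match.arg(task), leaky_slope = leaky_slope),
            class = "network_spec")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_conv <- function(nin, nout) {
  list(W = glorot(nin, nout),                     # node transform, no bias
       V = glorot(1, 1)[1],                       # scalar edge transform
       a = as.numeric(glorot(2 * nout + 1, 1)))   # attention vector
}

#' Initialize network weights
#'
#' Glorot-uniform ranges; biases (dense head only) start at zero.
#'
#' @param spec A \code{network_spec}.
#' @param seed Integer seed.
#' @return Named list of weight tensors: branches \code{int} and \code{ifc}
#'   each with \code{conv1}/\code{conv2} (\code{W}, \code{V}, \code{a}),
#'   and \code{head} (\code{Wh}, \code{bh}, \code{Wo}, \code{bo}).
#' @export
init_network <- function(spec, seed = 0L) {
  local_seed_eval(seed, {
    list(int = list(conv1 = init_conv(spec$input_dim, spec$conv1_out),
                    conv2 = init_conv(spec$conv1_out, spec$conv2_out)),
         ifc = list(conv1 = init_conv(spec$input_dim, spec$conv1_out),
                    conv2 = init_conv(spec$conv1_out, spec$conv2_out)),
         head = list(Wh = glorot(2L * spec$conv2_out, spec$head_hidden),
                     bh = numeric(spec$head_hidden),
                     Wo = glorot(spec$head_hidden, spec$head_out),
                     bo = numeric(spec$head_out)))
  })
}

#' Count trainable parameters by enumerating every weight tensor
#'
#' @param spec A \code{network_spec}.
#' @param seed Seed for the throwaway instantiation (does not affect the
#'   count).
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(spec, seed = 0L) {
  w <- init_network(spec, seed)
  sum(vapply(rapply(w, length, how = "unlist"), as.integer, 0L))
}

# ---- attention graph convolution -------------------------------------------

# Directed edge structure: dst/src integer vectors (both orientations of
# every undirected edge), ed = edge feature (normalized distance).
directed_edges <- function(index, norm_dist) {
  if (is.null(index) || nrow(index) == 0L) {
    return(list(dst = integer(0), src = integer(0), ed = numeric(0)))
  }
  list(dst = c(index[, 1], index[, 2]),
       src = c(index[, 2], index[, 1]),
       ed = c(norm_dist, norm_dist))
}

# Forward pass of one attention convolution layer.
# z_i = W x_i; e'_k = V d_k; s_k = a . [z_dst | z_src | e'_k];
# alpha = softmax_{k in edges into i}(LeakyReLU(s_k));
# h_i = ReLU(sum_k alpha_k z_src_k); isolated nodes yield zero vectors.
conv_layer_forward <- function(X, edges, w, nout, slope = 0.2) {
  n <- nrow(X)
  Z <- X %*% w$W
  m <- length(edges$dst)
  if (m == 0L) {
    return(list(H = matrix(0, n, nout), Z = Z, m = 0L))
  }
  a_i <- w$a[seq_len(nout)]
  a_j <- w$a[nout + seq_len(nout)]
  a_e <- w$a[2L * nout + 1L]
  e <- w$V * edges$ed
  s <- as.numeric(Z[edges$dst, , drop = FALSE] %*% a_i +
                  Z[edges$src, , drop = FALSE] %*% a_j) + a_e * e
  r <- ifelse(s > 0, s, slope * s)
  # per-destination softmax (tied scores handled exactly by exp/sum)
  udst <- sort(unique(edges$dst))
  pos <- match(edges$dst, udst)
  gmax <- vapply(split(r, pos), max, 0)
  ex <- exp(r - gmax[pos])
  gsum <- as.numeric(rowsum(ex, pos))
  alpha <- ex / gsum[pos]
  U <- rowsum(alpha * Z[edges$src, , drop = FALSE], pos)
  Hpre <- matrix(0, n, nout)
  Hpre[udst, ] <- U
  H <- pmax(Hpre, 0)
  list(H = H, Z = Z, s = s, r = r, alpha = alpha, e = e,
       udst = udst, pos = pos, Hpre = Hpre, m = m)
}

# Backward pass; returns gradients for W, V, a and the input X.
conv_layer_backward <- function(dH, X, edges, w, nout, cache, slope = 0.2) {
  n <- nrow(X)
  gW <- matrix(0, nrow(w$W), ncol(w$W)); gV <- 0
  ga <- numeric(length(w$a))
  if (cache$m == 0L) {
    return(list(W = gW, V = gV, a = ga, X = matrix(0, n, ncol(X))))
  }
  Z <- cache$Z
  a_i <- w$a[seq_len(nout)]; a_j <- w$a[nout + seq_len(nout)]
  a_e <- w$a[2L * nout + 1L]
  dHpre <- dH * (cache$Hpre > 0)
  # through h_i = sum_k alpha_k z_src
  dAlpha <- rowSums(dHpre[edges$dst, , drop = FALSE] *
                      Z[edges$src, , drop = FALSE])
  dZ <- matrix(0, n, nout)
  agg <- rowsum(cache$alpha * dHpre[edges$dst, , drop = FALSE], edges$src)
  dZ[as.integer(rownames(agg)), ] <- agg
  # softmax backward per destination group
  gdot <- as.numeric(rowsum(cache$alpha * dAlpha, cache$pos))
  dR <- cache$alpha * (dAlpha - gdot[cache$pos])
  dS <- dR * ifelse(cache$s > 0, 1, slope)
  # attention vector and edge transform
  ga[seq_len(nout)] <- colSums(dS * Z[edges$dst, , drop = FALSE])
  ga[nout + seq_len(nout)] <- colSums(dS * Z[edges$src, , drop = FALSE])
  ga[2L * nout + 1L] <- sum(dS * cache$e)
  gV <- sum(dS * a_e * edges$ed)
  # score terms back into Z
  addZ <- function(dZ, idx, contrib) {
    agg <- rowsum(contrib, idx)
    tgt <- as.integer(rownames(agg))
    dZ[tgt, ] <- dZ[tgt, , drop = FALSE] + agg
    dZ
  }
  dZ <- addZ(dZ, edges$dst, dS %o% a_i)
  dZ <- addZ(dZ, edges$src, dS %o% a_j)
  list(W = crossprod(X, dZ), V = gV, a = ga, X = dZ %*% t(w$W))
}

# ---- community pooling -----------------------------------------------------

# Louvain communities of the internal-edge graph (deterministic: local
# fixed RNG seed). Internal edges never cross chains, so communities are
# chain-confined by construction. Cluster ids are relabelled 1..c in node
# order.
louvain_clusters <- function(n, internal_index) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(internal_index) && nrow(internal_index) > 0L) {
    g <- igraph::add_edges(g, as.integer(t(internal_index)))
  }
  memb <- local_seed_eval(1860310L,
    igraph::membership(igraph::cluster_louvain(g)))
  as.integer(match(memb, unique(memb)))
}

# Pooled edge structure: distinct-cluster pairs joined by at least one
# original edge, carrying the minimum raw member distance, normalized by
# the branch cutoff.
pool_edges <- function(clusters, index, dist, cutoff) {
  if (is.null(index) || nrow(index) == 0L) {
    return(list(index = matrix(integer(0), 0, 2),
                dist = cbind(raw = numeric(0), normalized = numeric(0))))
  }
  ci <- clusters[index[, 1]]; cj <- clusters[index[, 2]]
  lo <- pmin(ci, cj); hi <- pmax(ci, cj)
  keep <- lo != hi
  if (!any(keep)) {
    return(list(index = matrix(integer(0), 0, 2),
                dist = cbind(raw = numeric(0), normalized = numeric(0))))
  }
  key <- paste(lo[keep], hi[keep])
  raw <- as.numeric(tapply(dist[keep, 1], key, min))
  ord <- names(tapply(dist[keep, 1], key, min))
  pairs <- do.call(rbind, lapply(strsplit(ord, " "), as.integer))
  o <- order(pairs[, 1], pairs[, 2])
  list(index = pairs[o, , drop = FALSE],
       dist = cbind(raw = raw[o], normalized = raw[o] / cutoff))
}

# Element-wise max over cluster members; argmax rows retained for backprop.
max_pool_forward <- function(H, clusters) {
  ncl <- max(clusters)
  P <- matrix(0, ncl, ncol(H))
  AM <- matrix(0L, ncl, ncol(H))
  for (c in seq_len(ncl)) {
    ix <- which(clusters == c)
    sub <- H[ix, , drop = FALSE]
    am <- ix[max.col(t(sub), ties.method = "first")]
    P[c, ] <- H[cbind(am, seq_len(ncol(H)))]
    AM[c, ] <- am
  }
  list(P = P, argmax = AM)
}

max_pool_backward <- function(dP, argmax, n) {
  dH <- matrix(0, n, ncol(dP))
  for (c in seq_len(nrow(dP))) {
    idx <- cbind(argmax[c, ], seq_len(ncol(dP)))
    dH[idx] <- dH[idx] + dP[c, ]
  }
  dH
}

#' Community pooling of node features over the internal-edge graph
#'
#' Clusters are Louvain communities of the internal-edge graph (chain-
#' confined by construction; singletons form their own cluster). Pooled
#' node features are element-wise maxima over cluster members; pooled edges
#' join distinct clusters linked by at least one input edge and inherit the
#' minimum raw member distance. Pooling has no trainable parameters.
#'
#' @param node_feats Numeric matrix n x f.
#' @param internal_index m x 2 matrix of undirected internal edges (i < j).
#' @param internal_dist m x 2 matrix (raw, normalized), matching
#'   \code{internal_index}.
#' @param cutoff Cutoff used to re-normalize pooled distances.
#' @return List: \code{pooled_feats}, \code{pooled_edges} (index + dist),
#'   \code{clusters} (integer assignment per node).
#' @export
community_pool <- function(node_feats, internal_index,
                           internal_dist = NULL, cutoff = 3.0) {
  if (nrow(node_feats) == 0L) stop("at least one node required")
  cl <- louvain_clusters(nrow(node_feats), internal_index)
  mp <- max_pool_forward(node_feats, cl)
  pe <- if (is.null(internal_dist)) NULL else
    pool_edges(cl, internal_index, internal_dist, cutoff)
  list(pooled_feats = mp$P, pooled_edges = pe, clusters = cl)
}

# ---- whole-network forward / backward --------------------------------------

# Precompute everything about a graph that the optimizer re-uses every
# epoch: directed edge structures for both branches at both levels, and the
# cluster assignment.
prepare_graph <- function(graph, internal_cutoff = 3.0,
                          interface_cutoff = 8.5) {
  n <- nrow(graph$node_feats)
  cl <- louvain_clusters(n, graph$internal_index)
  p_int <- pool_edges(cl, graph$internal_index, graph$internal_dist,
                      internal_cutoff)
  p_ifc <- pool_edges(cl, graph$interface_index, graph$interface_dist,
                      interface_cutoff)
  list(X = graph$node_feats,
       n = n, clusters = cl,
       target = graph$target,
       graph_id = graph$graph_id, complex_id = graph$complex_id,
       e1_int = directed_edges(graph$internal_index,
                               graph$internal_dist[, 2]),
       e1_ifc = directed_edges(graph$interface_index,
                               graph$interface_dist[, 2]),
       e2_int = directed_edges(p_int$index, p_int$dist[, 2]),
       e2_ifc = directed_edges(p_ifc$index, p_ifc$dist[, 2]))
}

branch_forward <- function(pg, bw, e1, e2, spec) {
  c1 <- conv_layer_forward(pg$X, e1, bw$conv1, spec$conv1_out,
                           spec$leaky_slope)
  mp <- max_pool_forward(c1$H, pg$clusters)
  c2 <- conv_layer_forward(mp$P, e2, bw$conv2, spec$conv2_out,
                           spec$leaky_slope)
  ro_am <- max.col(t(c2$H), ties.method = "first")
  ro <- c2$H[cbind(ro_am, seq_len(ncol(c2$H)))]
  list(c1 = c1, mp = mp, c2 = c2, ro = ro, ro_am = ro_am)
}

branch_backward <- function(dro, pg, bw, e1, e2, spec, cache) {
  dH2 <- matrix(0, nrow(cache$c2$H), ncol(cache$c2$H))
  dH2[cbind(cache$ro_am, seq_along(dro))] <- dro
  g2 <- conv_layer_backward(dH2, cache$mp$P, e2, bw$conv2, spec$conv2_out,
                            cache$c2, spec$leaky_slope)
  dH1 <- max_pool_backward(g2$X, cache$mp$argmax, pg$n)
  g1 <- conv_layer_backward(dH1, pg$X, e1, bw$conv1, spec$conv1_out,
                            cache$c1, spec$leaky_slope)
  list(conv1 = g1[c("W", "V", "a")], conv2 = g2[c("W", "V", "a")])
}

net_forward_prepared <- function(pg, weights, spec) {
  bi <- branch_forward(pg, weights$int, pg$e1_int, pg$e2_int, spec)
  bf <- branch_forward(pg, weights$ifc, pg$e1_ifc, pg$e2_ifc, spec)
  x <- c(bi$ro, bf$ro)
  hpre <- as.numeric(crossprod(weights$head$Wh, x)) + weights$head$bh
  h <- pmax(hpre, 0)
  out <- sum(weights$head$Wo * h) + weights$head$bo
  list(raw = as.numeric(out), x = x, hpre = hpre, h = h, bi = bi, bf = bf)
}

net_backward_prepared <- function(dout, pg, weights, spec, cache) {
  gWo <- matrix(cache$h * dout, ncol = 1)
  gbo <- dout
  dh <- as.numeric(weights$head$Wo) * dout
  dhpre <- dh * (cache$hpre > 0)
  gWh <- cache$x %o% dhpre
  gbh <- dhpre
  dx <- as.numeric(weights$head$Wh %*% dhpre)
  k <- spec$conv2_out
  gi <- branch_backward(dx[seq_len(k)], pg, weights$int, pg$e1_int,
                        pg$e2_int, spec, cache$bi)
  gf <- branch_backward(dx[k + seq_len(k)], pg, weights$ifc, pg$e1_ifc,
                        pg$e2_ifc, spec, cache$bf)
  list(int = gi, ifc = gf,
       head = list(Wh = gWh, bh = gbh, Wo = gWo, bo = gbo))
}

#' Score one interface graph with the network
#'
#' Runs both branches (conv1 -> community pool -> conv2 -> max read-out),
#' concatenates the two 32-wide read-outs, and applies the dense head. At
#' inference the regression output is clamped to \code{[0, 1]} and the
#' classification output is passed through the logistic function; with
#' \code{raw = TRUE} the untransformed head output is returned (as used in
#' training).
#'
#' @param graph An \code{interface_graph}.
#' @param spec A \code{network_spec} with \code{input_dim} equal to the
#'   graph's feature dimension.
#' @param weights Weights from [init_network()] or [train_model()].
#' @param raw Return the untransformed head output.
#' @return Scalar score.
#' @export
network_forward <- function(graph, spec, weights, raw = FALSE) {
  if (ncol(graph$node_feats) != spec$input_dim) {
    stop("shape error: graph has d = ", ncol(graph$node_feats),
         ", spec expects ", spec$input_dim)
  }
  pg <- prepare_graph(graph)
  out <- net_forward_prepared(pg, weights, spec)$raw
  if (raw) return(out)
  if (spec$task == "regression") min(max(out, 0), 1) else stats::plogis(out)
}

# flatten/unflatten weight trees for the optimizer
flatten_weights <- function(w) rapply(w, identity, how = "unlist")

weight_template <- function(w) rapply(w, function(x) x, how = "list")

apply_update <- function(w, g, f) {
  if (is.list(w)) {
    for (nm in names(w)) w[[nm]] <- apply_update(w[[nm]], g[[nm]], f)
    w
  } else {
    f(w, g)
  }
}

map2_weights <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- map2_weights(a[[nm]], b[[nm]], f)
    out
  } else {
    f(a, b)
  }
}

zero_like <- function(w) rapply(w, function(x) x * 0, how = "replace")

#' One attention graph-convolution layer (standalone)
#'
#' Directed edges, both orientations of every undirected pair: row k
#' \code{(i, j)} makes node j a neighbour of destination node i. Attention
#' coefficients are softmax-normalized per destination node; isolated nodes
#' yield zero vectors.
#'
#' @param node_feats Numeric matrix n x in.
#' @param edges m x 2 integer matrix of directed edges (destination,
#'   source).
#' @param edge_feats Numeric length-m edge feature (normalized distance).
#' @param weights List with \code{W} (in x out), \code{V} (scalar) and
#'   \code{a} (length 2*out + 1), e.g. one \code{conv1}/\code{conv2} entry
#'   of [init_network()].
#' @param leaky_slope Negative slope of the attention LeakyReLU.
#' @return Numeric matrix n x out.
#' @export
conv_forward <- function(node_feats, edges, edge_feats, weights,
                         leaky_slope = 0.2) {
  nout <- ncol(weights$W)
  if (ncol(node_feats) != nrow(weights$W)) {
    stop("shape error: features have ", ncol(node_feats),
         " columns, W expects ", nrow(weights$W))
  }
  if (length(weights$a) != 2L * nout + 1L) {
    stop("shape error: attention vector length ", length(weights$a),
         ", expected ", 2L * nout + 1L)
  }
  edges <- if (is.null(edges) || nrow(edges) == 0L) {
    list(dst = integer(0), src = integer(0), ed = numeric(0))
  } else {
    if (length(edge_feats) != nrow(edges)) {
      stop("shape error: ", nrow(edges), " edges but ",
           length(edge_feats), " edge features")
    }
    list(dst = as.integer(edges[, 1]), src = as.integer(edges[, 2]),
         ed = as.numeric(edge_feats))
  }
  conv_layer_forward(node_feats, edges, weights, nout, leaky_slope)$H
}
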