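# Desk-scale synthetic fixtures: two-chain complexes with pseudo-backbone
# geometry, rigid-body decoy ladders with computable fnat/DockQ, and full
# benchmark sets (graphs + index + truth table) with deterministic
# synthetic embeddings.

unit <- function(v) v / sqrt(sum(v^2))

perp_unit <- function(u) {
  w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(w - sum(w * u) * u)
}

# Self-avoiding persistent random walk of CA positions, step 3.8 Angstrom.
ca_walk <- function(n, min_sep = 4.0, max_tries = 200L) {
  ca <- matrix(0, n, 3)
  dir <- unit(stats::rnorm(3))
  for (i in 2:n) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      cand_dir <- unit(dir + 0.9 * stats::rnorm(3))
      cand <- ca[i - 1, ] + 3.8 * cand_dir
      prev <- ca[seq_len(max(i - 2, 1)), , drop = FALSE]
      if (i == 2 || min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_sep) {
        ca[i, ] <- cand; dir <- cand_dir; placed <- TRUE
        break
      }
    }
    if (!placed) stop("generation failed: self-avoiding walk stuck")
  }
  ca
}

# Idealized residue atoms around each CA: N, CA, C, O plus one pseudo
# side-chain atom (CB), with plausible ~1.2-2.4 Angstrom offsets.
backbone_atoms <- function(ca) {
  n <- nrow(ca)
  atoms <- vector("list", n)
  for (i in seq_len(n)) {
    u <- if (i < n) unit(ca[i + 1, ] - ca[i, ]) else unit(ca[i, ] - ca[i - 1, ])
    v <- perp_unit(u)
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    pos <- rbind(N  = ca[i, ] - 1.46 * u + 0.40 * v,
                 CA = ca[i, ],
                 C  = ca[i, ] + 1.52 * u + 0.30 * v,
                 O  = ca[i, ] + 1.52 * u + 0.30 * v + 1.23 * w,
                 CB = ca[i, ] + 1.53 * v)
    atoms[[i]] <- pos
  }
  atoms
}

format_chain <- function(atoms, seqs, chain, serial0) {
  elements <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
  three <- names(AA1)[match(strsplit(seqs, "")[[1]], AA1)]
  lines <- character(0)
  serial <- serial0
  for (i in seq_along(atoms)) {
    for (nm in rownames(atoms[[i]])) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm, three[i], chain, i,
        atoms[[i]][nm, 1], atoms[[i]][nm, 2], atoms[[i]][nm, 3],
        1, 0, elements[nm]))
    }
  }
  list(lines = lines, serial = serial)
}

#' Generate a synthetic two-chain complex
#'
#' Two self-avoiding pseudo-backbone chains (N, CA, C, O and one pseudo
#' side-chain atom per residue; residue identities uniform over the 20
#' standard amino acids), docked so that at least \code{min_contacts}
#' cross-chain residue pairs lie within 5 Angstrom and no cross-chain atom
#' pair clashes below 2.2 Angstrom. Byte-identical output for a given
#' seed.
#'
#' @param n_res_per_chain Residues per chain (>= 3).
#' @param seed Integer seed.
#' @param min_contacts Minimum number of 5-Angstrom cross-chain residue
#'   contacts.
#' @return List: \code{pdb} (character vector of PDB lines),
#'   \code{sequences} (named: A, B), \code{seed}.
#' @export
generate_complex <- function(n_res_per_chain, seed, min_contacts = 3L) {
  stopifnot(n_res_per_chain >= 3L)
  res <- local_seed_eval(seed, {
    out <- NULL
    for (attempt in 1:25) {
      out <- tryCatch(
        generate_complex_once(n_res_per_chain, min_contacts),
        error = function(e) NULL)
      if (!is.null(out)) break
    }
    out
  })
  if (is.null(res)) {
    stop("generation failed: no contact-forming placement found; re-seed")
  }
  res$seed <- seed
  res
}

generate_complex_once <- function(n, min_contacts) {
  seq_a <- paste(sample(AA_ORDER, n, replace = TRUE), collapse = "")
  seq_b <- paste(sample(AA_ORDER, n, replace = TRUE), collapse = "")
  at_a <- backbone_atoms(ca_walk(n))
  at_b <- backbone_atoms(ca_walk(n))
  A <- do.call(rbind, at_a)
  B0 <- do.call(rbind, at_b)
  # slide chain B toward A along a random direction until enough contacts
  # form, rejecting clashes
  dirv <- unit(stats::rnorm(3))
  start <- colMeans(A) + dirv * (max(sqrt(rowSums(sweep(A, 2, colMeans(A))^2)))
                                 + max(sqrt(rowSums(sweep(B0, 2,
                                                          colMeans(B0))^2)))
                                 + 12)
  rid_b <- rep(seq_len(n), each = 5L)
  # jump ahead: sliding by s shrinks the minimum cross distance by at most s
  off0 <- start - colMeans(B0)
  Bs <- sweep(B0, 2, off0, "+")
  d2s <- outer(rowSums(A^2), rowSums(Bs^2), "+") - 2 * tcrossprod(A, Bs)
  s_start <- max(0, floor(sqrt(max(min(d2s), 0)) - 8))
  for (s in seq(s_start, 150, by = 0.25)) {
    off <- start - dirv * s - colMeans(B0)
    B <- sweep(B0, 2, off, "+")
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    if (min(d2) < 2.2^2) stop("clash before contact formation")
    contact <- which(d2 <= 25, arr.ind = TRUE)
    if (nrow(contact) > 0L) {
      pairs <- unique(paste(rep(seq_len(n), each = 5L)[contact[, 1]],
                            rid_b[contact[, 2]]))
      if (length(pairs) >= min_contacts) {
        fa <- format_chain(at_a, seq_a, "A", 0L)
        at_b_shift <- lapply(at_b, function(m) sweep(m, 2, off, "+"))
        fb <- format_chain(at_b_shift, seq_b, "B", fa$serial)
        return(list(pdb = c(fa$lines, fb$lines, "END"),
                    sequences = c(A = seq_a, B = seq_b)))
      }
    }
  }
  stop("no contact within slide range")
}

#' Generate a rigid-body decoy ladder from a reference complex
#'
#' Decoy i (i = 0..n-1) rotates chain B about its centroid and translates
#' it, both by magnitude \code{i/(n-1)} of the configured maxima along
#' per-decoy random axes; decoy 0 is the reference itself. True fnat and
#' DockQ are computed for every decoy against the reference.
#'
#' @param reference Result of [generate_complex()], or a
#'   \code{ppi_complex}.
#' @param n_decoys Number of decoys (including decoy 0).
#' @param max_translation Maximum translation, Angstrom.
#' @param max_rotation Maximum rotation, degrees.
#' @param seed Integer seed.
#' @param complex_id Identifier used in graph/decoy ids.
#' @return List: \code{decoys} (named list of \code{ppi_complex}),
#'   \code{truth} (data frame: graph_id, complex_id, perturbation, fnat,
#'   dockq).
#' @export
generate_decoys <- function(reference, n_decoys = 10L,
                            max_translation = 5, max_rotation = 120,
                            seed = 0L, complex_id = "cpx") {
  ref <- if (inherits(reference, "ppi_complex")) reference else
    parse_pdb(reference$pdb, c("A", "B"), id = complex_id)
  sel_b <- ref$atoms$chain == "B"
  away <- unit(colMeans(as.matrix(ref$atoms[sel_b, c("x", "y", "z")])) -
                 colMeans(as.matrix(ref$atoms[!sel_b, c("x", "y", "z")])))
  # one perturbation direction per ladder: decoy quality then decays
  # monotonically with the magnitude i/(n-1)
  prm <- local_seed_eval((seed * 7919L) %% 2147483647, {
    list(axis = unit(stats::rnorm(3)),
         shift = unit(away + 0.6 * stats::rnorm(3)))
  })
  decoys <- vector("list", n_decoys)
  rows <- vector("list", n_decoys)
  for (i in seq_len(n_decoys) - 1L) {
    gid <- sprintf("%s_d%03d", complex_id, i)
    if (i == 0L) {
      dec <- ref
    } else {
      frac <- i / (n_decoys - 1L)
      theta <- frac * max_rotation * pi / 180
      K <- matrix(c(0, prm$axis[3], -prm$axis[2],
                    -prm$axis[3], 0, prm$axis[1],
                    prm$axis[2], -prm$axis[1], 0), 3, 3)
      R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
      # pivot between chain B's closest approach to chain A and B's
      # centroid: rotations disrupt contacts across the whole interface
      # without fully separating the chains
      XA <- as.matrix(ref$atoms[!sel_b, c("x", "y", "z")])
      XB <- as.matrix(ref$atoms[sel_b, c("x", "y", "z")])
      d2 <- outer(rowSums(XB^2), rowSums(XA^2), "+") - 2 * tcrossprod(XB, XA)
      ctr <- 0.7 * XB[which.min(apply(d2, 1, min)), ] + 0.3 * colMeans(XB)
      dec <- transform_complex(ref, R,
                               as.numeric(ctr - ctr %*% R) +
                                 frac * max_translation * prm$shift,
                               chain = "B")
    }
    dec$id <- gid
    decoys[[i + 1L]] <- dec
    q <- dockq(dec, ref)
    rows[[i + 1L]] <- data.frame(graph_id = gid, complex_id = complex_id,
                                 perturbation = if (i == 0L) 0 else
                                   i / (n_decoys - 1L),
                                 fnat = q$fnat, dockq = q$dockq,
                                 stringsAsFactors = FALSE)
  }
  names(decoys) <- vapply(decoys, function(d) d$id, "")
  list(decoys = decoys, truth = do.call(rbind, rows))
}

# Planted-signal target: a documented smooth function of node-feature
# means — a logistic read-out of the graph's mean buried surface area
# (spatially coherent, directly observed by the network, and varying both
# along decoy ladders and across complexes); used for recovery tests.
planted_target <- function(node_feats, config) {
  bo <- feature_block_offset(config, "bsa")
  if (is.na(bo)) stop("planted signal requires the bsa feature block")
  stats::plogis((mean(node_feats[, bo]) - 10) / 6)
}

#' Generate a full synthetic benchmark
#'
#' Runs the whole pipeline: complexes, decoy ladders, interface graphs
#' with synthetic embeddings, and targets (true fnat, or the planted
#' smooth function of node-feature means for learning-sanity tests).
#'
#' @param n_complexes,n_decoys Benchmark size.
#' @param n_res_per_chain Residues per chain.
#' @param embedding_dim Width of the synthetic embedding block.
#' @param seed Master seed.
#' @param planted_signal Replace fnat targets by the planted function.
#' @param config Feature configuration (default: embedding preset at
#'   \code{embedding_dim}).
#' @param out_dir Optional directory; when given, decoy PDB files, the
#'   graph container (\code{graphs.h5}), the truth table
#'   (\code{labels.tsv}) and the index (\code{index.json}) are written
#'   there.
#' @return List: \code{graphs} (named list of \code{interface_graph}),
#'   \code{index} (complex_id -> graph_ids), \code{truth} (data frame),
#'   \code{config}.
#' @export
make_benchmark <- function(n_complexes, n_decoys, n_res_per_chain = 25L,
                           embedding_dim = 16L, seed = 0L,
                           planted_signal = FALSE,
                           config = feature_preset("esm", embedding_dim),
                           out_dir = NULL) {
  stopifnot(n_complexes >= 1L, n_decoys >= 1L)
  graphs <- list()
  truth <- list()
  embedder <- synthetic_embedder(seed, config$embedding_dim)
  for (c in seq_len(n_complexes)) {
    cid <- sprintf("cpx%03d", c)
    # interface sizes vary across complexes, as in real benchmarks
    ref <- generate_complex(n_res_per_chain, seed * 1000L + c,
                            min_contacts = 4L + 2L * ((c - 1L) %% 5L))
    lad <- generate_decoys(ref, n_decoys, seed = seed * 1000L + c,
                           complex_id = cid)
    emb <- if (config$use_embedding) {
      list(A = embed_chain(embedder, ref$sequences[["A"]]),
           B = embed_chain(embedder, ref$sequences[["B"]]))
    } else NULL
    kept <- logical(length(lad$decoys))
    for (j in seq_along(lad$decoys)) {
      dec <- lad$decoys[[j]]
      g <- tryCatch(
        build_graph(dec, config, graph_id = dec$id, complex_id = cid,
                    target = lad$truth$fnat[j], embeddings = emb),
        error = function(e) {
          if (grepl("empty interface", conditionMessage(e))) {
            warning("skipping decoy ", dec$id, ": ",
                    conditionMessage(e), call. = FALSE)
            NULL
          } else stop(e)
        })
      if (is.null(g)) next
      kept[j] <- TRUE
      if (planted_signal) g$target <- planted_target(g$node_feats, config)
      graphs[[g$graph_id]] <- g
      if (!is.null(out_dir)) {
        writeLines(write_pdb(dec),
                   file.path(out_dir, paste0(dec$id, ".pdb")))
      }
    }
    truth[[c]] <- lad$truth[kept, , drop = FALSE]
  }
  truth <- do.call(rbind, truth)
  if (planted_signal) {
    truth$target <- vapply(graphs[truth$graph_id],
                           function(g) g$target, 0)
  }
  index <- dataset_index(graphs)
  if (!is.null(out_dir)) {
    write_graphs(graphs, file.path(out_dir, "graphs.h5"))
    utils::write.table(truth, file.path(out_dir, "labels.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(jsonlite::toJSON(index), file.path(out_dir, "index.json"))
  }
  list(graphs = graphs, index = index, truth = truth, config = config)
}
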