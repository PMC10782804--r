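# Shared fixtures, all built in code.

# Minimal PDB line for one atom.
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     element = substr(name, 1, 1), occ = 1, altloc = " ",
                     icode = " ", record = "ATOM  ") {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else
    sprintf("%-4s", name)
  sprintf("%s%5d %s%s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altloc, resname, chain, resno, icode,
          x, y, z, occ, 0, element)
}

# Two single-CA chains at a configurable separation.
two_ca_pdb <- function(sep = 5) {
  c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
    pdb_line(2, "CA", "ALA", "B", 1, sep, 0, 0, "C"),
    "END")
}

# A small labelled toy graph with controllable feature dimension.
toy_graph <- function(seed = 1, d = 6L, n = 5L, target = 0.5) {
  cpx <- generate_complex(max(n, 5L), seed)
  cx <- parse_pdb(cpx$pdb, c("A", "B"), id = sprintf("toy%d", seed))
  cfg <- feature_config(use_type = FALSE, use_polarity = FALSE,
                        use_bsa = FALSE, use_charge = TRUE,
                        use_embedding = TRUE, embedding_dim = d - 1L)
  emb <- synthetic_embedder(seed, d - 1L)
  build_graph(cx, cfg, target = target,
              embeddings = list(A = embed_chain(emb, cpx$sequences[["A"]]),
                                B = embed_chain(emb, cpx$sequences[["B"]])))
}

# Small benchmark shared between training tests (cached per session).
.bench_cache <- new.env()
small_bench <- function(n_complexes = 4L, n_decoys = 5L, seed = 3L,
                        embedding_dim = 8L, planted = FALSE) {
  key <- paste(n_complexes, n_decoys, seed, embedding_dim, planted)
  if (is.null(.bench_cache[[key]])) {
    .bench_cache[[key]] <- suppressWarnings(
      make_benchmark(n_complexes, n_decoys, n_res_per_chain = 15L,
                     embedding_dim = embedding_dim, seed = seed,
                     planted_signal = planted))
  }
  .bench_cache[[key]]
}

expect_same_graph <- function(a, b) {
  expect_identical(a$nodes$key, b$nodes$key)
  expect_equal(a$node_feats, b$node_feats, tolerance = 1e-6)
  expect_identical(a$internal_index, b$internal_index)
  expect_identical(a$interface_index, b$interface_index)
  expect_equal(unname(a$internal_dist), unname(b$internal_dist),
               tolerance = 1e-6)
  expect_equal(unname(a$interface_dist), unname(b$interface_dist),
               tolerance = 1e-6)
  expect_equal(a$target, b$target, tolerance = 1e-9)
}
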