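test_that("type one-hot uses the fixed alphabetical one-letter ordering", {
  expect_equal(which(one_hot_type("ALA") == 1), 1L)
  expect_equal(which(one_hot_type("TYR") == 1), 20L)
  for (aa in names(dockgraph:::AA1)) {
    v <- one_hot_type(aa)
    expect_equal(sum(v), 1)
    expect_equal(length(v), 20L)
  }
  expect_error(one_hot_type("XYZ"), "unencodable residue")
})

test_that("every standard residue maps to exactly one polarity class", {
  classes <- dockgraph:::POLARITY_CLASSES
  expect_setequal(unname(unlist(classes)), dockgraph:::AA_ORDER)
  expect_equal(polarity_feature("GLU"),
               as.numeric(names(classes) == "negative"))
  expect_equal(polarity_feature("LEU"),
               as.numeric(names(classes) == "apolar"))
  for (aa in names(dockgraph:::AA1)) {
    expect_equal(sum(polarity_feature(aa)), 1)
  }
})

test_that("charge table: ARG/LYS +1, ASP/GLU -1, HIS +0.1, rest 0", {
  expect_equal(residue_charge("ARG"), 1)
  expect_equal(residue_charge("LYS"), 1)
  expect_equal(residue_charge("ASP"), -1)
  expect_equal(residue_charge("HIS"), 0.1)
  expect_equal(residue_charge("ALA"), 0)
  expect_equal(sum(vapply(rep("GLY", 10), residue_charge, 0)), 0)
})

test_that("feature dimension identity holds for all 16 flag combinations", {
  flags <- expand.grid(ty = c(TRUE, FALSE), po = c(TRUE, FALSE),
                       ps = c(TRUE, FALSE), em = c(TRUE, FALSE))
  for (i in seq_len(nrow(flags))) {
    f <- flags[i, ]
    cfg <- feature_config(f$ty, f$po, TRUE, TRUE, f$ps, f$em, 1280L)
    expect_equal(cfg$dim,
                 20 * f$ty + 4 * f$po + 1 + 1 + 22 * f$ps + 1280 * f$em)
    expect_equal(feature_dim(cfg), cfg$dim)
  }
  expect_equal(feature_preset("esm-pssm")$dim, 1328L)
  expect_equal(feature_preset("esm")$dim, 1306L)
  expect_equal(feature_preset("pssm-only")$dim, 48L)
  expect_equal(feature_preset("minimal")$dim, 26L)
})

test_that("PSSM parsing aligns rows, extracts Cons, and guards misalignment", {
  rows <- c("1 K 1 2 3 4 5 6 7 8 5 9 0 1 2 3 4 5 6 7 8 9 0.8",
            "2 A 9 0 1 2 3 4 5 6 7 8 9 0 1 2 3 4 5 6 7 8 1.2",
            "3 Y 0 1 2 3 4 5 6 7 8 9 0 1 2 3 4 5 6 7 8 4 0.3")
  p <- parse_pssm(rows)
  expect_equal(dim(p$scores), c(3L, 20L))
  expect_equal(p$ic, c(0.8, 1.2, 0.3))
  # Cons = each row's score of its own wild-type residue
  expect_equal(p$cons[1], unname(p$scores[1, "K"]))
  expect_equal(unname(p$cons), c(5, 9, 4))
  expect_error(parse_pssm(rows, chain_length = 4), "profile misaligned")
  expect_error(parse_pssm(c(rows, "4 G 1 2 3")), "malformed profile")
  expect_error(parse_pssm(sub("0.8", "zz", rows)), "malformed profile")
})

test_that("synthetic embedding provider is pure, seed- and dim-sensitive", {
  e0 <- synthetic_embedder(0, 1280L)
  m1 <- embed_chain(e0, "GAK")
  expect_equal(dim(m1), c(3L, 1280L))
  expect_identical(m1, embed_chain(e0, "GAK"))
  expect_false(identical(m1, embed_chain(synthetic_embedder(1, 1280L),
                                         "GAK")))
  expect_equal(dim(embed_chain(synthetic_embedder(0, 8L), "GAK")),
               c(3L, 8L))
  expect_error(embed_chain(e0, ""), "embedding provider error")
})

test_that("precomputed embedding provider reads matrices and validates", {
  m <- matrix(stats::rnorm(12), 3, 4)
  f <- tempfile()
  write.table(m, f, row.names = FALSE, col.names = FALSE)
  prov <- precomputed_embedder(c(GAK = f))
  expect_equal(embed_chain(prov, "GAK"), m, tolerance = 1e-6)
  expect_error(embed_chain(prov, "AAA"), "embedding provider error")
})

test_that("assembled feature matrices have the configured layout and no NaN", {
  gen <- generate_complex(8, 21)
  cx <- parse_pdb(gen$pdb, c("A", "B"))
  nodes <- select_interface_nodes(cx)
  cfg <- feature_preset("esm-pssm", embedding_dim = 8L)
  prov <- synthetic_embedder(0, 8L)
  mk_pssm <- function(seq, seed) {
    n <- nchar(seq)
    set.seed(seed)
    rows <- vapply(seq_len(n), function(i) {
      paste(i, substr(seq, i, i),
            paste(sample(-5:9, 20, replace = TRUE), collapse = " "),
            round(stats::runif(1, 0, 2), 2))
    }, "")
    parse_pssm(rows, chain_length = n)
  }
  feats <- assemble_node_features(
    cx, nodes, cfg,
    bsa = compute_bsa_all(cx),
    pssm = list(A = mk_pssm(gen$sequences[["A"]], 1),
                B = mk_pssm(gen$sequences[["B"]], 2)),
    embeddings = list(A = embed_chain(prov, gen$sequences[["A"]]),
                      B = embed_chain(prov, gen$sequences[["B"]])))
  expect_equal(dim(feats), c(nrow(nodes), 20 + 4 + 1 + 1 + 22 + 8))
  expect_true(all(is.finite(feats)))
  # spot-check the layout: type block one-hot, charge column position
  expect_true(all(rowSums(feats[, 1:20, drop = FALSE]) == 1))
  ch_col <- dockgraph:::feature_block_offset(cfg, "charge")
  expect_equal(feats[, ch_col],
               vapply(nodes$resname, residue_charge, 0, USE.NAMES = FALSE))
  # missing sources fail loudly
  expect_error(assemble_node_features(cx, nodes, cfg, bsa = NULL),
               "missing feature for node")
})

test_that("BSA vanishes for residues far from the partner chain", {
  lines <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
             pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0, "C"),
             pdb_line(3, "CA", "ALA", "B", 1, 60, 0, 0, "C"),
             "END")
  cx <- parse_pdb(lines, c("A", "B"))
  expect_lt(abs(compute_bsa(cx, "A:1:")), 1e-6)
})

test_that("a residue enclosed by the partner chain buries its whole SASA", {
  # single CA of chain A caged by chain B atoms on a dense sphere
  pts <- dockgraph:::fibonacci_sphere(40) * 4.5
  lines <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
             vapply(seq_len(nrow(pts)), function(i) {
               pdb_line(i + 1, "CA", "GLY", "B", i,
                        pts[i, 1], pts[i, 2], pts[i, 3], "C")
             }, ""),
             "END")
  cx <- parse_pdb(lines, c("A", "B"))
  iso <- 4 * pi * (1.7 + 1.4)^2     # lone atom, fully accessible
  bsa <- compute_bsa(cx, "A:1:")
  expect_equal(bsa, iso, tolerance = 0.02)
})

test_that("BSA at 100 sphere points agrees with 1000 points within 5%", {
  # 5% measured against the residue's accessible area (the feature scale;
  # small buried patches carry intrinsic quadrature noise of a few
  # sphere-point areas), plus 5% on the complex-total BSA
  for (seed in c(13, 14)) {
    gen <- generate_complex(8, seed)
    cx <- parse_pdb(gen$pdb, c("A", "B"))
    b100 <- compute_bsa_all(cx, n_points = 100L)
    b1000 <- compute_bsa_all(cx, n_points = 1000L)
    frame <- dockgraph:::canonical_frame(
      as.matrix(cx$atoms[, c("x", "y", "z")]))
    iso <- numeric(length(b1000))
    for (ch in cx$chains) {
      s <- dockgraph:::residue_sasa(cx, cx$atoms$chain == ch,
                                    n_points = 1000L, frame = frame)
      iso[as.integer(rownames(s))] <- s
    }
    expect_true(all(abs(b100 - b1000) <= pmax(0.05 * b1000, 0.05 * iso)))
    expect_lt(abs(sum(b100) - sum(b1000)), 0.05 * sum(b1000))
  }
})

test_that("BSA is invariant under rigid motion of the whole complex", {
  gen <- generate_complex(8, 17)
  cx <- parse_pdb(gen$pdb, c("A", "B"))
  b1 <- compute_bsa_all(cx)
  R <- dockgraph:::random_rotation(9)
  cx2 <- dockgraph:::transform_complex(cx, R, c(-20, 7, 13))
  b2 <- compute_bsa_all(cx2)
  expect_lt(max(abs(b1 - b2)), 1e-3)
})
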