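test_that("native contacts follow the cutoff and match brute force", {
  expect_length(native_contacts(parse_pdb(two_ca_pdb(20), c("A", "B"))), 0L)
  one <- native_contacts(parse_pdb(two_ca_pdb(3), c("A", "B")))
  expect_equal(one, "A:1:|B:1:")

  gen <- generate_complex(10, 51)
  cx <- parse_pdb(gen$pdb, c("A", "B"))
  res <- lapply(seq_len(nrow(cx$residues)), get_residue, complex = cx)
  ch <- cx$residues$chain
  want <- character(0)
  for (i in which(ch == "A")) for (j in which(ch == "B")) {
    if (min_heavy_atom_distance(res[[i]], res[[j]]) <= 5.0) {
      want <- c(want, paste0(cx$residues$key[i], "|", cx$residues$key[j]))
    }
  }
  expect_setequal(native_contacts(cx), want)
})

test_that("fnat is 1 against itself, 0 when separated, and set-consistent", {
  gen <- generate_complex(12, 53)
  ref <- parse_pdb(gen$pdb, c("A", "B"))
  expect_equal(fnat(ref, ref), 1.0)
  apart <- dockgraph:::transform_complex(ref, diag(3), c(50, 0, 0),
                                         chain = "B")
  expect_equal(fnat(apart, ref), 0.0)

  lad <- generate_decoys(gen, n_decoys = 6L, seed = 53, complex_id = "c")
  ref_set <- native_contacts(ref)
  for (d in lad$decoys) {
    expect_equal(fnat(d, ref),
                 length(intersect(native_contacts(d), ref_set)) /
                   length(ref_set))
  }
})

test_that("fnat is invariant under joint rigid motion of the model", {
  gen <- generate_complex(10, 57)
  ref <- parse_pdb(gen$pdb, c("A", "B"))
  lad <- generate_decoys(gen, n_decoys = 4L, seed = 57, complex_id = "c")
  mod <- lad$decoys[[3]]
  moved <- dockgraph:::transform_complex(mod, dockgraph:::random_rotation(3),
                                         c(7, 7, -7))
  expect_equal(fnat(moved, ref), fnat(mod, ref), tolerance = 1e-12)
})

test_that("Kabsch superposition recovers sampled rotations", {
  set.seed(8)
  A <- matrix(stats::rnorm(30, sd = 5), 10, 3)
  fit0 <- kabsch_superpose(A, A)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  for (seed in 1:5) {
    R <- dockgraph:::random_rotation(seed)
    t <- stats::rnorm(3, sd = 10)
    B <- A %*% R + matrix(t, 10, 3, byrow = TRUE)
    fit <- kabsch_superpose(A, B)
    expect_equal(fit$rmsd, 0, tolerance = 1e-6)
    expect_equal(fit$rotation, t(R), tolerance = 1e-6)
    # returned transform really maps B onto A
    Bfit <- B %*% fit$rotation +
      matrix(fit$translation, 10, 3, byrow = TRUE)
    expect_equal(sqrt(mean(rowSums((Bfit - A)^2))), fit$rmsd,
                 tolerance = 1e-9)
  }
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "insufficient points")
})

test_that("DockQ is 1 for the reference and assembles from its components", {
  gen <- generate_complex(12, 61)
  ref <- parse_pdb(gen$pdb, c("A", "B"))
  self <- dockq(ref, ref)
  expect_equal(self$dockq, 1.0, tolerance = 1e-9)
  expect_equal(self$fnat, 1.0)
  expect_lt(self$irmsd, 1e-6)
  expect_lt(self$lrmsd, 1e-6)

  lad <- generate_decoys(gen, n_decoys = 5L, seed = 61, complex_id = "c")
  for (d in lad$decoys[-1]) {
    q <- dockq(d, ref)
    expect_equal(q$dockq,
                 (q$fnat + 1 / (1 + (q$irmsd / 1.5)^2) +
                    1 / (1 + (q$lrmsd / 8.5)^2)) / 3,
                 tolerance = 1e-12)
  }
  # dissociated limit: fnat 0 and large RMSDs drive DockQ towards 0
  apart <- dockgraph:::transform_complex(ref, diag(3), c(500, 0, 0),
                                         chain = "B")
  expect_lt(dockq(apart, ref)$dockq, 0.01)
})

test_that("interpolated AUC matches the exact rank-sum AUC", {
  # perfect separation
  expect_equal(roc_curve_interpolated(c(0.9, 0.8, 0.2, 0.1),
                                      c(1, 1, 0, 0))$auc, 1.0,
               tolerance = 1e-9)
  rank_auc <- function(s, l) {
    r <- rank(s)
    np <- sum(l == 1); nn <- sum(l == 0)
    (sum(r[l == 1]) - np * (np + 1) / 2) / (np * nn)
  }
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(20:500, 1)
    s <- stats::rnorm(n)
    if (rep %% 2 == 0) s <- round(s, 1)   # force ties
    l <- stats::rbinom(n, 1, 0.4)
    if (length(unique(l)) < 2) next
    expect_equal(roc_curve_interpolated(s, l)$auc, rank_auc(s, l),
                 tolerance = 1e-3)
  }
  expect_error(roc_curve_interpolated(1:4, c(1, 1, 1, 1)),
               "degenerate labels")
})

test_that("random scores give chance-level AUC", {
  set.seed(23)
  aucs <- replicate(40, {
    s <- stats::rnorm(120)
    l <- rep(c(0, 1), 60)
    roc_curve_interpolated(s, l)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("classification metrics reproduce a hand-computed table", {
  # confusion table TP=3 FP=1 FN=2 TN=4 at threshold 0.5
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.15, 0.1, 0.05)
  labels <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  m <- classification_metrics(scores, labels)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
  mcc_direct <- (3 * 4 - 1 * 2) /
    sqrt((3 + 1) * (3 + 2) * (4 + 1) * (4 + 2))
  expect_equal(m$mcc, mcc_direct)
  expect_equal(m$accuracy, 0.7)

  perfect <- classification_metrics(labels, labels)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$mcc, 1)

  cont <- classification_metrics(scores, labels, targets = scores)
  expect_equal(cont$r_squared, 1)
  expect_equal(cont$pearson, 1)
  expect_warning(classification_metrics(c(0.9, 0.8), c(1, 1),
                                        threshold = 0.1),
                 "MCC")
  expect_error(classification_metrics(1:3, 1:2), "shape error")
})

test_that("success rate counts planted top-1 hits and is monotone in k", {
  rec <- do.call(rbind, lapply(1:13, function(i) {
    data.frame(complex_id = sprintf("c%02d", i),
               graph_id = sprintf("c%02d_d%d", i, 1:5),
               predicted_score = c(0.9, 0.7, 0.5, 0.3, 0.1),
               is_near_native = FALSE)
  }))
  # plant hits in the top-1 slot of exactly 2 complexes,
  # and a rank-3 hit in a third
  rec$is_near_native[rec$graph_id %in% c("c01_d1", "c02_d1")] <- TRUE
  rec$is_near_native[rec$graph_id == "c03_d3"] <- TRUE
  expect_equal(success_rate(rec, 1), 100 * 2 / 13)
  expect_equal(success_rate(rec, 5), 100 * 3 / 13)
  ks <- c(1, 5, 20, 50)
  sr <- vapply(ks, function(k) success_rate(rec, k), 0)
  expect_true(all(diff(sr) >= 0))
  none <- rec; none$is_near_native <- FALSE
  expect_equal(success_rate(none, 50), 0)
  all_top <- rec
  all_top$is_near_native <- all_top$graph_id %in%
    sprintf("c%02d_d1", 1:13)
  expect_equal(success_rate(all_top, 1), 100)
  expect_error(success_rate(rec[0, ], 1), "no cases")
})

test_that("quality records rank decoys by score with lexicographic ties", {
  truth <- data.frame(graph_id = c("a_1", "a_2", "a_3"),
                      complex_id = "a",
                      fnat = c(1, 0.5, 0), dockq = c(1, 0.4, 0.1))
  scores <- c(a_1 = 0.5, a_2 = 0.5, a_3 = 0.9)
  rec <- quality_records(truth, scores)
  expect_equal(rec$rank, c(2L, 3L, 1L))
  expect_equal(rec$is_near_native, c(TRUE, TRUE, FALSE))
})
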