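# Structural quality labels (fnat, interface/ligand RMSD, DockQ) and
# scoring-performance metrics (interpolated ROC/AUC, thresholded
# classification metrics, per-complex success rates).

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Cross-chain native contacts of a complex
#'
#' @param complex A \code{ppi_complex} with two chains.
#' @param contact_cutoff Heavy-atom contact cutoff, Angstrom (CAPRI
#'   convention: 5).
#' @return Character vector of contact keys
#'   \code{"chainA:res|chainB:res"}, one per residue pair within cutoff.
#' @export
native_contacts <- function(complex, contact_cutoff = 5.0) {
  M <- residue_min_dist_matrix(complex)
  res <- complex$residues
  a <- which(res$chain == complex$chains[1])
  b <- which(res$chain == complex$chains[2])
  hits <- which(M[a, b, drop = FALSE] <= contact_cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(character(0))
  sort(paste0(res$key[a[hits[, 1]]], "|", res$key[b[hits[, 2]]]))
}

#' Fraction of native contacts (fnat)
#'
#' @param model,reference \code{ppi_complex} objects sharing residue keys
#'   (contacts involving residues absent from the other structure are
#'   ignored, with a warning).
#' @param contact_cutoff Contact cutoff, Angstrom.
#' @return \code{|contacts(model) intersect contacts(reference)| /
#'   |contacts(reference)|}, in \code{[0, 1]}.
#' @export
fnat <- function(model, reference, contact_cutoff = 5.0) {
  ref_c <- native_contacts(reference, contact_cutoff)
  if (length(ref_c) == 0L) stop("no native contacts in reference")
  shared <- intersect(model$residues$key, reference$residues$key)
  if (length(shared) < nrow(reference$residues)) {
    warning("ignoring ", nrow(reference$residues) - length(shared),
            " reference residue(s) unmatched in the model")
    keep <- vapply(strsplit(ref_c, "|", fixed = TRUE),
                   function(p) all(p %in% shared), TRUE)
    ref_c <- ref_c[keep]
    if (length(ref_c) == 0L) stop("no native contacts in reference")
  }
  mod_c <- native_contacts(model, contact_cutoff)
  length(intersect(mod_c, ref_c)) / length(ref_c)
}

#' Kabsch superposition
#'
#' Least-squares optimal proper rotation (determinant +1, reflections
#' corrected) and translation mapping \code{coords_b} onto
#' \code{coords_a}.
#'
#' @param coords_a,coords_b n x 3 matrices of matched points, n >= 3.
#' @return List: \code{rotation} (3 x 3), \code{translation} (length 3)
#'   such that \code{coords_b \%*\% rotation + translation} best fits
#'   \code{coords_a}, and \code{rmsd} of the fit.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) < 3L || nrow(coords_a) != nrow(coords_b)) {
    stop("insufficient points: need >= 3 matched coordinate pairs")
  }
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  s <- svd(crossprod(B, A))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fit <- B %*% R
  rmsd <- sqrt(mean(rowSums((fit - A)^2)))
  list(rotation = R, translation = ca - as.numeric(cb %*% R), rmsd = rmsd)
}

# matched backbone coordinate pair for a residue-key subset
matched_backbone <- function(model, reference, keys, chains = NULL) {
  mk <- function(cx) {
    a <- cx$atoms
    rkey <- cx$residues$key[a$ridx]
    sel <- rkey %in% keys & a$atom %in% BACKBONE_ATOMS
    if (!is.null(chains)) sel <- sel & a$chain %in% chains
    data.frame(id = paste(rkey[sel], a$atom[sel]), i = which(sel))
  }
  am <- mk(model); ar <- mk(reference)
  common <- intersect(am$id, ar$id)
  if (length(common) < 3L) {
    stop("incomplete backbone: only ", length(common),
         " matched backbone atoms")
  }
  list(model = as.matrix(model$atoms[am$i[match(common, am$id)],
                                     c("x", "y", "z")]),
       reference = as.matrix(reference$atoms[ar$i[match(common, ar$id)],
                                             c("x", "y", "z")]))
}

#' DockQ quality score of a docking model
#'
#' \code{DockQ = (fnat + 1/(1 + (irmsd/1.5)^2) + 1/(1 + (lrmsd/8.5)^2)) /
#' 3}. The ligand RMSD is the backbone RMSD of the shorter chain after
#' superposing the longer (receptor) chain; the interface RMSD is the
#' backbone RMSD over reference interface residues (any cross-chain heavy
#' atom within 10 Angstrom) after superposing on those residues.
#'
#' @inheritParams fnat
#' @param interface_cutoff Interface-residue definition for the iRMSD
#'   term, Angstrom.
#' @return List: \code{dockq}, \code{fnat}, \code{irmsd}, \code{lrmsd}.
#' @export
dockq <- function(model, reference, contact_cutoff = 5.0,
                  interface_cutoff = 10.0) {
  fn <- fnat(model, reference, contact_cutoff)
  res <- reference$residues
  nres <- table(factor(res$chain, levels = reference$chains))
  receptor <- reference$chains[which.max(nres)]
  ligand <- setdiff(reference$chains, receptor)
  if (length(ligand) == 0L) ligand <- receptor

  # ligand RMSD: superpose receptor backbones, measure ligand backbone
  rec <- matched_backbone(model, reference, res$key, chains = receptor)
  fit <- kabsch_superpose(rec$reference, rec$model)
  lig <- matched_backbone(model, reference, res$key, chains = ligand)
  lig_fit <- lig$model %*% fit$rotation +
    matrix(fit$translation, nrow(lig$model), 3, byrow = TRUE)
  lrmsd <- sqrt(mean(rowSums((lig_fit - lig$reference)^2)))

  # interface RMSD: superpose on reference interface residue backbones
  M <- residue_min_dist_matrix(reference)
  a <- which(res$chain == reference$chains[1])
  b <- which(res$chain == reference$chains[2])
  cross <- M[a, b, drop = FALSE]
  ikeys <- c(res$key[a[apply(cross, 1, min) <= interface_cutoff]],
             res$key[b[apply(cross, 2, min) <= interface_cutoff]])
  ib <- matched_backbone(model, reference, ikeys)
  irmsd <- kabsch_superpose(ib$reference, ib$model)$rmsd

  q <- (fn + 1 / (1 + (irmsd / 1.5)^2) + 1 / (1 + (lrmsd / 8.5)^2)) / 3
  list(dockq = q, fnat = fn, irmsd = irmsd, lrmsd = lrmsd)
}

#' Interpolated ROC curve and AUC
#'
#' Builds the empirical ROC by sweeping scores in descending order,
#' processing tied score groups atomically, then linearly interpolates the
#' TPR at fixed FPR grid points; the AUC is the trapezoidal area on the
#' grid.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @param fpr_grid FPR evaluation grid.
#' @return List: \code{fpr} (the grid), \code{tpr} (interpolated),
#'   \code{auc}.
#' @export
roc_curve_interpolated <- function(scores, labels,
                                   fpr_grid = seq(0, 1, by = 0.001)) {
  if (length(scores) != length(labels)) stop("shape error: lengths differ")
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("degenerate labels: one class only")
  o <- order(-scores)
  s <- scores[o]; l <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1L - l)
  last <- !duplicated(grp, fromLast = TRUE)   # end of each tied group
  fpr <- c(0, fp[last] / nn); tpr <- c(0, tp[last] / np)
  # vertical ROC segments (duplicated FPR) are kept by an epsilon offset
  # (negative, so grid points on a vertical take its upper end) and
  # interpolation follows the exact polygon
  fpr_sep <- fpr + (seq_along(fpr) - length(fpr)) * 1e-12
  tpr_at <- stats::approx(fpr_sep, tpr, xout = fpr_grid, ties = "ordered",
                          rule = 2)$y
  auc <- sum(diff(fpr_grid) * (utils::head(tpr_at, -1) +
                                 utils::tail(tpr_at, -1)) / 2)
  list(fpr = fpr_grid, tpr = tpr_at, auc = auc)
}

#' Thresholded classification metrics plus continuous agreement
#'
#' Textbook precision, recall, F1, MCC and accuracy at a score threshold;
#' when continuous \code{targets} are supplied, also \code{r_squared}
#' (\code{1 - SS_res/SS_tot}) and the Pearson correlation between scores
#' and targets.
#'
#' @param scores Numeric predictions.
#' @param labels Binary truth labels.
#' @param threshold Scores >= threshold predict the positive class.
#' @param targets Optional continuous ground-truth values.
#' @return Named list of metrics.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5,
                                   targets = NULL) {
  if (length(scores) != length(labels)) stop("shape error: lengths differ")
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L); tn <- sum(pred == 0L & labels == 0L)
  precision <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) {
    warning("empty confusion-table marginal; MCC set to 0")
    0
  } else {
    (tp * tn - fp * fn) / sqrt(denom)
  }
  out <- list(precision = precision, recall = recall, f1 = f1, mcc = mcc,
              accuracy = (tp + tn) / length(labels))
  if (!is.null(targets)) {
    ss_res <- sum((targets - scores)^2)
    ss_tot <- sum((targets - mean(targets))^2)
    out$r_squared <- 1 - ss_res / ss_tot
    out$pearson <- if (stats::sd(scores) == 0 || stats::sd(targets) == 0) {
      NA_real_
    } else stats::cor(scores, targets)
  }
  out
}

#' Per-complex top-k success rate
#'
#' A case succeeds if at least one near-native model appears among its
#' top-k ranked decoys; ranks are assigned by descending predicted score,
#' ties broken lexicographically by graph_id.
#'
#' @param records Data frame with columns \code{complex_id},
#'   \code{graph_id}, \code{predicted_score} and \code{is_near_native}
#'   (logical or 0/1). See [quality_records()].
#' @param k Rank depth.
#' @return Percentage of complexes with a hit in the top k.
#' @export
success_rate <- function(records, k = 1L) {
  if (is.null(records) || nrow(records) == 0L) stop("no cases")
  hit <- vapply(split(records, records$complex_id), function(rc) {
    o <- order(-rc$predicted_score, rc$graph_id)
    any(as.logical(rc$is_near_native[o][seq_len(min(k, nrow(rc)))]))
  }, TRUE)
  100 * mean(hit)
}

#' Assemble per-decoy quality records
#'
#' Combines truth labels and predicted scores into the record table used
#' by [success_rate()], adding the near-native flag (DockQ > 0.23) and the
#' within-complex rank.
#'
#' @param truth Data frame with \code{graph_id}, \code{complex_id},
#'   \code{fnat}, \code{dockq}.
#' @param scores Named numeric vector of predicted scores keyed by
#'   graph_id (or a data frame with \code{graph_id} and \code{score}).
#' @param near_native_threshold DockQ threshold defining the positive
#'   class.
#' @return Data frame of quality records.
#' @export
quality_records <- function(truth, scores,
                            near_native_threshold = 0.23) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$score, scores$graph_id)
  }
  rec <- data.frame(graph_id = truth$graph_id,
                    complex_id = truth$complex_id,
                    fnat = truth$fnat, dockq = truth$dockq,
                    predicted_score = unname(scores[truth$graph_id]),
                    stringsAsFactors = FALSE)
  rec$is_near_native <- rec$dockq > near_native_threshold
  rec$rank <- NA_integer_
  for (cx in unique(rec$complex_id)) {
    sel <- rec$complex_id == cx
    o <- order(-rec$predicted_score[sel], rec$graph_id[sel])
    rec$rank[sel][o] <- seq_len(sum(sel))
  }
  rec
}
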