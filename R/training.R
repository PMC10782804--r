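# Dataset splitting by complex, the Adam optimization loop for the fnat
# regression and interface-classification tasks, and k-fold
# cross-validation.

#' Training configuration
#'
#' Defaults follow the published protocol: mean-squared-error loss, Adam,
#' batch size 128, learning rate 0.001, 20 epochs, 80/20 split by complex.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size (the last batch may be smaller).
#' @param epochs Number of passes over the training set.
#' @param loss \code{"mse"} (regression) or \code{"bce"} (classification,
#'   on \{0,1\} targets).
#' @param seed Seed controlling initialization and per-epoch shuffling.
#' @param split_fractions Train/evaluation fractions, summing to 1.
#' @return A \code{train_config} list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 128L,
                         epochs = 20L, loss = c("mse", "bce"),
                         seed = 0L, split_fractions = c(0.8, 0.2)) {
  stopifnot(epochs >= 1L, abs(sum(split_fractions) - 1) < 1e-9)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss = match.arg(loss),
                 seed = as.integer(seed),
                 split_fractions = split_fractions),
            class = "train_config")
}

#' Build a dataset index from a graph collection
#'
#' @param graphs Named list of \code{interface_graph}s.
#' @return Named list mapping complex_id to the character vector of its
#'   graph_ids.
#' @export
dataset_index <- function(graphs) {
  ids <- vapply(graphs, function(g) g$graph_id, "")
  if (anyDuplicated(ids)) stop("graph_ids must be unique")
  split(unname(ids), vapply(graphs, function(g) g$complex_id, ""))
}

#' Split a dataset index into train and evaluation parts, by complex
#'
#' The partition is at complex granularity: no complex contributes graphs
#' to both sides. Sizes follow the fractions rounded to the nearest
#' complex (always leaving at least one complex on each side).
#'
#' @param index Dataset index ([dataset_index()]).
#' @param fractions Two fractions summing to 1.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with \code{train} and \code{eval} sub-indices.
#' @export
split_by_complex <- function(index, fractions = c(0.8, 0.2), seed = 0L) {
  n <- length(index)
  if (n < 2L) stop("cannot split: need at least 2 complexes")
  ord <- local_seed_eval(seed, sample.int(n))
  n_train <- min(max(round(fractions[1] * n), 1L), n - 1L)
  cx <- names(index)[ord]
  list(train = index[sort(cx[seq_len(n_train)])],
       eval = index[sort(cx[(n_train + 1L):n])])
}

adam_state <- function(weights) {
  list(m = zero_like(weights), v = zero_like(weights), t = 0L)
}

adam_step <- function(weights, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_weights(state$m, grads,
                          function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_weights(state$v, grads,
                          function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- rapply(state$m, function(m) m / bc1, how = "replace")
  vhat <- rapply(state$v, function(v) v / bc2, how = "replace")
  step <- map2_weights(mhat, vhat, function(m, v) lr * m / (sqrt(v) + eps))
  list(weights = map2_weights(weights, step, `-`), state = state)
}

batch_pass <- function(prepared, batch, weights, spec, loss) {
  B <- length(batch)
  total <- 0
  grads <- NULL
  for (gi in batch) {
    pg <- prepared[[gi]]
    fw <- net_forward_prepared(pg, weights, spec)
    y <- pg$target
    if (loss == "mse") {
      total <- total + (fw$raw - y)^2
      dout <- 2 * (fw$raw - y) / B
    } else {
      p <- stats::plogis(fw$raw)
      eps <- 1e-12
      total <- total - (y * log(p + eps) + (1 - y) * log(1 - p + eps))
      dout <- (p - y) / B
    }
    g <- net_backward_prepared(dout, pg, weights, spec, fw)
    grads <- if (is.null(grads)) g else map2_weights(grads, g, `+`)
  }
  list(loss = total / B, grads = grads)
}

#' Train the scoring network
#'
#' Runs \code{cfg$epochs} passes of mini-batch Adam over the training
#' graphs, reshuffling each epoch under a seed derived from
#' \code{cfg$seed}. Regression uses the mean-squared-error loss on the raw
#' head output; classification uses binary cross-entropy on the logistic
#' output.
#'
#' @param graphs Named list of labelled \code{interface_graph}s (or
#'   pre-prepared graphs from the internal cache).
#' @param spec A \code{network_spec}; its \code{task} should match
#'   \code{cfg$loss}.
#' @param cfg A \code{train_config}.
#' @param index Optional dataset index restricting training to the listed
#'   graph_ids (e.g. the \code{train} part of [split_by_complex()]).
#' @param weights Optional warm-start weights.
#' @param verbose Print one line per epoch.
#' @return List with \code{weights}, \code{loss_trace} (one mean training
#'   loss per epoch), \code{spec} and \code{cfg}.
#' @export
train_model <- function(graphs, spec, cfg = train_config(), index = NULL,
                        weights = NULL, verbose = FALSE) {
  ids <- if (is.null(index)) {
    vapply(graphs, function(g) g$graph_id, "")
  } else {
    unlist(index, use.names = FALSE)
  }
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("no training data")
  missing_ids <- setdiff(ids, names(graphs))
  if (length(missing_ids)) {
    stop("no training data: graphs missing for ",
         paste(missing_ids, collapse = ", "))
  }
  prepared <- lapply(graphs[ids], function(g) {
    if (!is.null(g$e1_int)) return(g)   # already prepared
    if (is.na(g$target)) stop("unlabeled graph: ", g$graph_id)
    prepare_graph(g)
  })
  for (pg in prepared) if (is.na(pg$target)) {
    stop("unlabeled graph: ", pg$graph_id)
  }
  if (is.null(weights)) weights <- init_network(spec, cfg$seed)
  state <- adam_state(weights)
  trace <- numeric(cfg$epochs)
  nb <- length(prepared)
  for (ep in seq_len(cfg$epochs)) {
    ord <- local_seed_eval((cfg$seed * 1009L + ep) %% 2147483647,
                           sample.int(nb))
    bounds <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (b in bounds) {
      bp <- batch_pass(prepared, names(prepared)[b], weights, spec,
                       cfg$loss)
      ep_loss <- ep_loss + bp$loss * length(b)
      if (cfg$learning_rate > 0) {
        upd <- adam_step(weights, bp$grads, state, cfg$learning_rate)
        weights <- upd$weights
        state <- upd$state
      }
    }
    trace[ep] <- ep_loss / nb
    if (verbose) {
      message(sprintf("epoch %3d  loss %.6f", ep, trace[ep]))
    }
  }
  list(weights = weights, loss_trace = trace, spec = spec, cfg = cfg)
}

#' Score a set of graphs with trained weights
#'
#' @param graphs Named list of \code{interface_graph}s.
#' @param spec,weights Network specification and trained weights.
#' @return Data frame: graph_id, complex_id, target, score (inference
#'   scale: clamped to \code{[0,1]} for regression, logistic for
#'   classification).
#' @export
predict_graphs <- function(graphs, spec, weights) {
  data.frame(
    graph_id = vapply(graphs, function(g) g$graph_id, ""),
    complex_id = vapply(graphs, function(g) g$complex_id, ""),
    target = vapply(graphs, function(g) as.numeric(g$target), 0),
    score = vapply(graphs, network_forward, 0, spec = spec,
                   weights = weights),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' k-fold cross-validation by complex
#'
#' Complexes are partitioned into k folds; each fold serves once as the
#' validation set for a model trained on the remaining folds. Validation
#' predictions are scored with the full metric suite
#' ([classification_metrics()]) plus the interpolated AUC, using
#' \code{label_threshold} on the targets to define the positive class.
#'
#' @param graphs Named list of labelled \code{interface_graph}s.
#' @param index Dataset index ([dataset_index()]).
#' @param k Number of folds.
#' @param spec,cfg Network and training configuration.
#' @param label_threshold Targets strictly above this value are the
#'   positive class (default the near-native DockQ convention, 0.23).
#' @param score_threshold Score cut for the thresholded metrics.
#' @return List with \code{folds} (per-fold data frames of predictions),
#'   \code{metrics} (per-fold metric rows) and \code{summary} (mean and sd
#'   per metric across folds).
#' @export
cross_validate <- function(graphs, index, k = 10L, spec,
                           cfg = train_config(), label_threshold = 0.23,
                           score_threshold = 0.5) {
  n <- length(index)
  if (k > n) stop("too many folds: k = ", k, " for ", n, " complexes")
  ord <- local_seed_eval(cfg$seed, sample.int(n))
  fold_of <- rep_len(seq_len(k), n)[order(ord)]
  folds <- list(); metr <- list()
  for (f in seq_len(k)) {
    val_cx <- names(index)[fold_of == f]
    tr_idx <- index[setdiff(names(index), val_cx)]
    fit <- train_model(graphs, spec, cfg, index = tr_idx)
    val_ids <- unlist(index[val_cx], use.names = FALSE)
    pred <- predict_graphs(graphs[val_ids], spec, fit$weights)
    pred$fold <- f
    labels <- as.integer(pred$target > label_threshold)
    m <- classification_metrics(pred$score, labels,
                                threshold = score_threshold,
                                targets = pred$target)
    m$auc <- if (length(unique(labels)) == 2L) {
      roc_curve_interpolated(pred$score, labels)$auc
    } else NA_real_
    folds[[f]] <- pred
    metr[[f]] <- as.data.frame(m)
  }
  metrics <- do.call(rbind, metr)
  metrics$fold <- seq_len(k)
  num <- metrics[, setdiff(names(metrics), "fold"), drop = FALSE]
  list(folds = folds, metrics = metrics,
       summary = data.frame(metric = names(num),
                            mean = vapply(num, mean, 0, na.rm = TRUE),
                            sd = vapply(num, stats::sd, 0, na.rm = TRUE),
                            row.names = NULL))
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the weight tensors with the network spec and the
#' feature configuration; the loader refuses checkpoints whose feature
#' configuration does not match a supplied graph container's.
#'
#' @param fit Result of [train_model()].
#' @param feature_config The \code{feature_config} the training graphs
#'   were built with.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
save_checkpoint <- function(fit, feature_config, path) {
  obj <- list(weights = fit$weights, spec = unclass(fit$spec),
              feature_config = unclass(feature_config),
              loss_trace = fit$loss_trace)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expected_config Optional \code{feature_config} to validate
#'   against (e.g. from [read_graphs()]).
#' @export
load_checkpoint <- function(path, expected_config = NULL) {
  obj <- readRDS(path)
  if (!is.null(expected_config) &&
      !identical(unclass(obj$feature_config)[
        c("use_type", "use_polarity", "use_bsa", "use_charge",
          "use_pssm_block", "use_embedding", "embedding_dim")],
        unclass(expected_config)[
          c("use_type", "use_polarity", "use_bsa", "use_charge",
            "use_pssm_block", "use_embedding", "embedding_dim")])) {
    stop("inconsistent feature schema: checkpoint was trained under a ",
         "different feature configuration")
  }
  obj$spec <- do.call(network_spec, obj$spec[
    c("input_dim", "conv1_out", "conv2_out", "head_hidden", "task",
      "leaky_slope")])
  obj$feature_config <- do.call(feature_config, obj$feature_config[
    c("use_type", "use_polarity", "use_bsa", "use_charge",
      "use_pssm_block", "use_embedding", "embedding_dim")])
  obj
}
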