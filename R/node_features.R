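# Node feature blocks: amino-acid type one-hot, polarity class, buried
# surface area, formal charge, PSSM-derived conservation, and per-residue
# language-model embeddings, assembled under a FeatureConfig.

# polarity classes, by one-letter code
POLARITY_CLASSES <- list(
  apolar   = c("A","C","F","G","I","L","M","P","V","W"),
  polar    = c("N","Q","S","T","Y","H"),
  positive = c("K","R"),
  negative = c("D","E"))

CHARGE_TABLE <- c(ARG = 1, LYS = 1, ASP = -1, GLU = -1, HIS = 0.1)

#' Feature configuration for node feature assembly
#'
#' Controls which feature blocks enter the per-node feature vector. The
#' implied node dimension is
#' \code{20*use_type + 4*use_polarity + use_bsa + use_charge +
#' 22*use_pssm_block + embedding_dim*use_embedding}.
#'
#' @param use_type Amino-acid type one-hot (20 columns).
#' @param use_polarity Polarity class one-hot (4 columns).
#' @param use_bsa Buried surface area (1 column, Angstrom^2).
#' @param use_charge Formal charge (1 column).
#' @param use_pssm_block Conservation + information content + 20 PSSM
#'   scores (22 columns).
#' @param use_embedding Per-residue language-model embedding block.
#' @param embedding_dim Width of the embedding block (default 1280, the
#'   ESM-2 650M per-residue representation width).
#' @return A \code{feature_config} list with the flags plus \code{dim}.
#' @export
feature_config <- function(use_type = TRUE, use_polarity = TRUE,
                           use_bsa = TRUE, use_charge = TRUE,
                           use_pssm_block = FALSE, use_embedding = TRUE,
                           embedding_dim = 1280L) {
  cfg <- list(use_type = isTRUE(use_type), use_polarity = isTRUE(use_polarity),
              use_bsa = isTRUE(use_bsa), use_charge = isTRUE(use_charge),
              use_pssm_block = isTRUE(use_pssm_block),
              use_embedding = isTRUE(use_embedding),
              embedding_dim = as.integer(embedding_dim))
  cfg$dim <- feature_dim(cfg)
  class(cfg) <- "feature_config"
  cfg
}

#' @rdname feature_config
#' @param config A \code{feature_config}.
#' @export
feature_dim <- function(config) {
  with(config, 20L * use_type + 4L * use_polarity + use_bsa + use_charge +
         22L * use_pssm_block + embedding_dim * use_embedding)
}

#' Named feature presets
#'
#' \code{"esm-pssm"} (1328 dims: all blocks), \code{"esm"} (1306: embedding
#' but no PSSM block), \code{"pssm-only"} (48: PSSM block, no embedding) and
#' \code{"minimal"} (26: neither).
#'
#' @param name Preset name.
#' @param embedding_dim Embedding width override (presets that disable the
#'   embedding ignore it).
#' @return A \code{feature_config}.
#' @export
feature_preset <- function(name = c("esm-pssm", "esm", "pssm-only", "minimal"),
                           embedding_dim = 1280L) {
  switch(match.arg(name),
    "esm-pssm"  = feature_config(use_pssm_block = TRUE,
                                 embedding_dim = embedding_dim),
    "esm"       = feature_config(embedding_dim = embedding_dim),
    "pssm-only" = feature_config(use_pssm_block = TRUE,
                                 use_embedding = FALSE),
    "minimal"   = feature_config(use_embedding = FALSE))
}

#' @export
print.feature_config <- function(x, ...) {
  on <- names(Filter(isTRUE, x[startsWith(names(x), "use_")]))
  cat("feature_config:", paste(sub("^use_", "", on), collapse = "+"),
      "-> d =", x$dim, "\n")
  invisible(x)
}

norm_res <- function(residue_name) {
  code <- if (nchar(residue_name) == 3L) AA1[toupper(residue_name)] else
    toupper(residue_name)
  if (is.na(code) || !code %in% AA_ORDER) {
    stop("unencodable residue: ", residue_name)
  }
  code
}

#' One-hot amino-acid type (20 columns, alphabetical one-letter order)
#'
#' @param residue_name Three-letter (or one-letter) standard amino-acid code.
#' @return Numeric 20-vector with a single 1.
#' @export
one_hot_type <- function(residue_name) {
  v <- numeric(20)
  v[match(norm_res(residue_name), AA_ORDER)] <- 1
  v
}

#' One-hot polarity class (apolar, polar, positive, negative)
#'
#' @inheritParams one_hot_type
#' @return Numeric 4-vector with a single 1.
#' @export
polarity_feature <- function(residue_name) {
  code <- norm_res(residue_name)
  v <- numeric(4)
  v[which(vapply(POLARITY_CLASSES, function(s) code %in% s, TRUE))] <- 1
  v
}

#' Formal side-chain charge at neutral pH
#'
#' ARG/LYS +1, ASP/GLU -1, HIS +0.1, all others 0.
#'
#' @inheritParams one_hot_type
#' @return Scalar charge.
#' @export
residue_charge <- function(residue_name) {
  code <- norm_res(residue_name)
  three <- names(AA1)[match(code, AA1)]
  v <- CHARGE_TABLE[three]
  if (is.na(v)) 0 else unname(v)
}

#' Parse a tabular PSSM profile
#'
#' Expected whitespace-delimited columns, one row per residue of one chain:
#' \code{pos wt s_A s_C ... s_Y ic} — position, wild-type one-letter code,
#' 20 log-odds substitution scores in alphabetical one-letter order, and the
#' information content.
#'
#' @param text Character vector of lines (or one string with newlines).
#' @param chain_length Optional; when given, a row-count mismatch raises
#'   "profile misaligned".
#' @return A \code{pssm_profile}: list with \code{wt} (character),
#'   \code{scores} (L x 20 matrix, columns \code{AA_ORDER}), \code{ic}
#'   (numeric) and \code{cons} (each row's score of its own wild-type
#'   residue, the conservation feature).
#' @export
parse_pssm <- function(text, chain_length = NULL) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) != 23L)
  if (length(bad)) stop("malformed profile: row ", bad[1],
                        " does not have 23 fields")
  tab <- do.call(rbind, parts)
  scores <- suppressWarnings(matrix(as.numeric(tab[, 3:22]), ncol = 20))
  ic <- suppressWarnings(as.numeric(tab[, 23]))
  if (anyNA(scores) || anyNA(ic)) stop("malformed profile: non-numeric field")
  wt <- toupper(tab[, 2])
  if (!all(wt %in% AA_ORDER)) stop("malformed profile: unknown wild-type code")
  if (!is.null(chain_length) && nrow(scores) != chain_length) {
    stop("profile misaligned: ", nrow(scores), " rows for a ",
         chain_length, "-residue chain")
  }
  colnames(scores) <- AA_ORDER
  structure(list(wt = wt, scores = scores, ic = ic,
                 cons = scores[cbind(seq_along(wt), match(wt, AA_ORDER))]),
            class = "pssm_profile")
}

#' Deterministic synthetic embedding provider
#'
#' Stands in for a protein language model: emits per-residue vectors with
#' standard-normal-like values, fully determined by (sequence, seed). The
#' provider contract is a pure function \code{f(sequence) -> L x dim matrix}.
#'
#' @param seed Integer seed of the provider.
#' @param embedding_dim Vector width per residue.
#' @return A provider function usable with [embed_chain()].
#' @export
synthetic_embedder <- function(seed = 0L, embedding_dim = 1280L) {
  embedding_dim <- as.integer(embedding_dim)
  force(seed)
  f <- function(sequence) {
    if (!nzchar(sequence)) stop("embedding provider error: empty sequence")
    codes <- utf8ToInt(sequence)
    h <- (sum(codes * (seq_along(codes) %% 97 + 1)) * 131 + 7919 * seed) %%
      2147483629
    L <- nchar(sequence)
    local_seed_eval(h, matrix(stats::rnorm(L * embedding_dim),
                              nrow = L, ncol = embedding_dim))
  }
  attr(f, "embedding_dim") <- embedding_dim
  f
}

#' Embedding provider backed by precomputed matrices
#'
#' For workflows where per-residue embeddings were computed elsewhere (e.g.
#' by a real ESM-2 run) and saved as whitespace-delimited numeric tables,
#' one file per chain keyed by sequence.
#'
#' @param files Named character vector: names are chain sequences, values
#'   are file paths to L x dim numeric tables.
#' @return A provider function usable with [embed_chain()].
#' @export
precomputed_embedder <- function(files) {
  force(files)
  function(sequence) {
    path <- files[[sequence]]
    if (is.null(path)) {
      stop("embedding provider error: no precomputed matrix for sequence")
    }
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
    if (nrow(m) != nchar(sequence)) {
      stop("embedding provider error: row count does not match sequence")
    }
    m
  }
}

#' Per-residue embedding matrix for one chain
#'
#' @param provider A provider function (e.g. from [synthetic_embedder()]).
#' @param sequence One-letter amino-acid string.
#' @return Numeric matrix, \code{nchar(sequence)} rows.
#' @export
embed_chain <- function(provider, sequence) {
  m <- tryCatch(provider(sequence), error = function(e) {
    if (grepl("embedding provider error", conditionMessage(e))) stop(e)
    stop("embedding provider error: ", conditionMessage(e))
  })
  if (!is.matrix(m) || nrow(m) != nchar(sequence) || !all(is.finite(m))) {
    stop("embedding provider error: invalid matrix returned")
  }
  m
}

#' Assemble the node feature matrix for a set of graph nodes
#'
#' Column layout, with inactive blocks omitted:
#' \code{[type(20) | polarity(4) | bsa(1) | charge(1) | cons(1) |
#' pssm_ic(1) | pssm(20) | embedding(E)]}.
#'
#' @param complex The \code{ppi_complex} the nodes belong to.
#' @param nodes Data frame of selected nodes (from
#'   [select_interface_nodes()]).
#' @param config A \code{feature_config}.
#' @param bsa Named numeric vector of buried surface areas keyed by residue
#'   key; required when \code{config$use_bsa}. Use [compute_bsa_all()].
#' @param pssm Named list of \code{pssm_profile}s, one per chain; required
#'   when \code{config$use_pssm_block}.
#' @param embeddings Named list of per-chain embedding matrices (rows follow
#'   the chain's retained residues); required when
#'   \code{config$use_embedding}.
#' @return Numeric matrix \code{nrow(nodes) x config$dim}.
#' @export
assemble_node_features <- function(complex, nodes, config,
                                   bsa = NULL, pssm = NULL,
                                   embeddings = NULL) {
  n <- nrow(nodes)
  blocks <- list()
  if (config$use_type) {
    blocks$type <- t(vapply(nodes$resname, one_hot_type, numeric(20)))
  }
  if (config$use_polarity) {
    blocks$polarity <- t(vapply(nodes$resname, polarity_feature, numeric(4)))
  }
  if (config$use_bsa) {
    if (is.null(bsa) || !all(nodes$key %in% names(bsa))) {
      stop("missing feature for node: bsa")
    }
    blocks$bsa <- matrix(unname(bsa[nodes$key]), ncol = 1)
  }
  if (config$use_charge) {
    blocks$charge <- matrix(vapply(nodes$resname, residue_charge, 0),
                            ncol = 1)
  }
  # position of each node within its chain's retained residues, used to
  # index per-chain profile/embedding rows
  chpos <- function(i) {
    sum(complex$residues$chain == nodes$chain[i] &
          seq_len(nrow(complex$residues)) <= nodes$ridx[i])
  }
  pos <- vapply(seq_len(n), chpos, 0L)
  if (config$use_pssm_block) {
    rows <- lapply(seq_len(n), function(i) {
      p <- pssm[[nodes$chain[i]]]
      if (is.null(p) || pos[i] > length(p$ic)) {
        stop("missing feature for node: pssm (", nodes$key[i], ")")
      }
      c(p$cons[pos[i]], p$ic[pos[i]], p$scores[pos[i], ])
    })
    blocks$pssm <- do.call(rbind, rows)
  }
  if (config$use_embedding) {
    rows <- lapply(seq_len(n), function(i) {
      e <- embeddings[[nodes$chain[i]]]
      if (is.null(e) || pos[i] > nrow(e)) {
        stop("missing feature for node: embedding (", nodes$key[i], ")")
      }
      e[pos[i], ]
    })
    blocks$embedding <- do.call(rbind, rows)
  }
  out <- do.call(cbind, blocks)
  dimnames(out) <- NULL
  if (ncol(out) != config$dim) {
    stop("shape error: assembled ", ncol(out), " columns, expected ",
         config$dim)
  }
  if (!all(is.finite(out))) stop("missing feature for node: non-finite value")
  out
}

# Column index of a named block's first column under a config (used by the
# planted-signal benchmark and documented for users poking at matrices).
feature_block_offset <- function(config, block) {
  widths <- c(type = 20L * config$use_type,
              polarity = 4L * config$use_polarity,
              bsa = 1L * config$use_bsa,
              charge = 1L * config$use_charge,
              cons = 1L * config$use_pssm_block,
              pssm_ic = 1L * config$use_pssm_block,
              pssm = 20L * config$use_pssm_block,
              embedding = config$embedding_dim * config$use_embedding)
  if (widths[[block]] == 0L) return(NA_integer_)
  before <- which(names(widths) == block) - 1L
  as.integer(sum(widths[seq_len(before)]) + 1L)
}
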