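# Parsing and geometry for two-chain protein complexes.
#
# A complex is stored column-wise for speed: one atom table plus one residue
# table, with `ridx` linking atoms to residues. Heavy atoms only; residue
# identity is (chain, author number, insertion code), never renumbered.

AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
         "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")
names(AA1) <- AA3

# one-letter codes in the fixed alphabetical order used for one-hot features
AA_ORDER <- sort(AA1)

#' Parse a PDB-format text stream into a two-chain complex
#'
#' Reads ATOM records (plus HETATM records for selenomethionine), keeps the
#' two requested chains, strips hydrogens, waters and other heteroatoms,
#' resolves alternate locations to the highest-occupancy conformer (ties
#' broken by file order), maps MSE to MET, and drops residues whose name is
#' not one of the 20 standard amino acids (with a warning) or which retain
#' no heavy atoms.
#'
#' @param text PDB content: a single string or a character vector of lines.
#' @param chain_pair Two chain identifiers to extract, e.g. \code{c("A","B")}.
#' @param id Free-text model identifier attached to the result.
#' @return An object of class \code{ppi_complex}: a list with elements
#'   \code{id}, \code{chains} (the two chain ids, in the requested order),
#'   \code{atoms} (data frame: chain, resno, icode, resname, atom, element,
#'   x, y, z, ridx) and \code{residues} (data frame: chain, resno, icode,
#'   resname, key).
#' @seealso [chain_sequence()], [write_pdb()], [min_heavy_atom_distance()]
#' @export
parse_pdb <- function(text, chain_pair = c("A", "B"), id = "model") {
  stopifnot(length(chain_pair) == 2L)
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  rec <- substr(lines, 1, 6)
  keep <- which(rec == "ATOM  " | rec == "HETATM")
  if (length(keep) == 0L) stop("chain not found: no ATOM records present")
  ln <- lines[keep]
  lineno <- keep

  too_short <- nchar(ln) < 54
  if (any(too_short)) {
    stop("malformed record at line ", lineno[which(too_short)[1]],
         ": ATOM record shorter than coordinate fields")
  }
  fx <- function(a, b) substr(ln, a, b)
  resname <- trimws(fx(18, 20))
  chain   <- fx(22, 22)
  is_het  <- substr(ln, 1, 6) == "HETATM"
  sel <- chain %in% chain_pair & (!is_het | resname == "MSE")
  if (!any(sel)) stop("chain not found: ", paste(chain_pair, collapse = ","))
  ln <- ln[sel]; lineno <- lineno[sel]
  resname <- resname[sel]; chain <- chain[sel]

  num <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(substr(ln, a, b)))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("malformed record at line ", lineno[bad[1]],
           ": non-numeric ", what, " field")
    }
    v
  }
  x <- num(31, 38, "x"); y <- num(39, 46, "y"); z <- num(47, 54, "z")
  occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ[!is.finite(occ)] <- 1
  atom   <- trimws(substr(ln, 13, 16))
  altloc <- substr(ln, 17, 17)
  resno  <- suppressWarnings(as.integer(substr(ln, 23, 26)))
  bad <- which(is.na(resno))
  if (length(bad)) {
    stop("malformed record at line ", lineno[bad[1]],
         ": non-numeric residue number")
  }
  icode  <- substr(ln, 27, 27)
  elem   <- toupper(trimws(substr(ln, 77, 78)))
  # fall back on the atom name when the element column is absent
  noel <- elem == ""
  if (any(noel)) elem[noel] <- substr(gsub("[0-9']", "", atom[noel]), 1, 1)

  a <- data.frame(chain = chain, resno = resno, icode = icode,
                  resname = resname, atom = atom, element = elem,
                  x = x, y = y, z = z, occ = occ, altloc = altloc,
                  ord = seq_along(ln), stringsAsFactors = FALSE)

  a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  a$resname[a$resname == "MSE"] <- "MET"

  nonstd <- !(a$resname %in% AA3)
  if (any(nonstd)) {
    dropped <- unique(paste0(a$chain[nonstd], ":", a$resno[nonstd], ":",
                             a$resname[nonstd]))
    warning("dropping ", length(dropped),
            " non-standard residue(s): ", paste(dropped, collapse = " "))
    a <- a[!nonstd, , drop = FALSE]
  }

  # altloc: keep the highest-occupancy conformer per atom, ties -> first
  akey <- paste(a$chain, a$resno, a$icode, a$atom, sep = "\r")
  if (anyDuplicated(akey)) {
    o <- order(akey, -a$occ, a$ord)
    a <- a[o, , drop = FALSE]
    a <- a[!duplicated(akey[o]), , drop = FALSE]
  }

  for (ch in chain_pair) {
    if (!any(a$chain == ch)) stop("chain not found: ", ch)
  }

  a$chain <- factor(a$chain, levels = chain_pair)
  a <- a[order(a$chain, a$resno, a$icode, a$ord), , drop = FALSE]
  a$chain <- as.character(a$chain)

  rkey <- paste(a$chain, a$resno, a$icode, sep = "\r")
  a$ridx <- match(rkey, unique(rkey))
  first <- !duplicated(a$ridx)
  residues <- data.frame(chain = a$chain[first], resno = a$resno[first],
                         icode = a$icode[first], resname = a$resname[first],
                         key = paste0(a$chain[first], ":", a$resno[first],
                                      ":", trimws(a$icode[first])),
                         stringsAsFactors = FALSE)
  a$occ <- a$altloc <- a$ord <- NULL
  rownames(a) <- NULL; rownames(residues) <- NULL

  structure(list(id = id, chains = chain_pair, atoms = a,
                 residues = residues),
            class = "ppi_complex")
}

#' Read a two-chain complex from a PDB file
#'
#' @inheritParams parse_pdb
#' @param path Path to a PDB file.
#' @return A \code{ppi_complex}; see [parse_pdb()].
#' @export
read_complex <- function(path, chain_pair = c("A", "B"),
                         id = sub("\\.pdb$", "", basename(path))) {
  parse_pdb(readLines(path, warn = FALSE), chain_pair, id = id)
}

#' @export
print.ppi_complex <- function(x, ...) {
  nres <- table(factor(x$residues$chain, levels = x$chains))
  cat("ppi_complex '", x$id, "': chains ",
      paste(sprintf("%s (%d res)", x$chains, as.integer(nres)),
            collapse = ", "),
      "; ", nrow(x$atoms), " heavy atoms\n", sep = "")
  invisible(x)
}

#' Serialize a complex back to PDB text
#'
#' Writes one ATOM record per retained heavy atom, wwPDB v3.3 columns,
#' occupancy 1.00 and B-factor 0.00. Parsing the output reproduces the
#' complex (round-trip idempotence on retained content).
#'
#' @param complex A \code{ppi_complex}.
#' @return A character vector of PDB lines (including a final END record).
#' @export
write_pdb <- function(complex) {
  a <- complex$atoms
  nm <- ifelse(nchar(a$atom) < 4L, sprintf(" %-3s", a$atom),
               sprintf("%-4s", a$atom))
  lines <- sprintf(
    "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), nm, a$resname, a$chain, a$resno, a$icode,
    a$x, a$y, a$z, 1, 0, a$element)
  c(lines, "END")
}

#' One-letter amino-acid sequence of one chain
#'
#' @param complex A \code{ppi_complex}.
#' @param chain_id Chain identifier.
#' @return Single string; one letter per retained residue, ordered by
#'   residue number then insertion code (selenomethionine was already mapped
#'   to M at parse time).
#' @export
chain_sequence <- function(complex, chain_id) {
  if (!chain_id %in% complex$chains) stop("chain not found: ", chain_id)
  res <- complex$residues[complex$residues$chain == chain_id, , drop = FALSE]
  if (nrow(res) == 0L) stop("empty chain: ", chain_id)
  paste(AA1[res$resname], collapse = "")
}

#' Extract one residue as a standalone object
#'
#' @param complex A \code{ppi_complex}.
#' @param i Row index into \code{complex$residues}, or a residue key
#'   \code{"chain:number:icode"}.
#' @return List with \code{chain_id}, \code{number}, \code{insertion_code},
#'   \code{name}, \code{atoms} (names), \code{elements} and \code{coords}
#'   (matrix n x 3).
#' @export
get_residue <- function(complex, i) {
  if (is.character(i)) {
    i <- match(i, complex$residues$key)
    if (is.na(i)) stop("residue key not found")
  }
  r <- complex$residues[i, ]
  sel <- complex$atoms$ridx == i
  list(chain_id = r$chain, number = r$resno,
       insertion_code = trimws(r$icode), name = r$resname,
       atoms = complex$atoms$atom[sel],
       elements = complex$atoms$element[sel],
       coords = as.matrix(complex$atoms[sel, c("x", "y", "z")]))
}

#' Minimum heavy-atom distance between two residues
#'
#' @param res_a,res_b Residue objects from [get_residue()].
#' @return Minimum Euclidean distance (Angstrom) over all heavy-atom pairs;
#'   symmetric in its arguments.
#' @export
min_heavy_atom_distance <- function(res_a, res_b) {
  A <- res_a$coords; B <- res_b$coords
  if (is.null(A) || nrow(A) == 0L || is.null(B) || nrow(B) == 0L) {
    stop("empty residue")
  }
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(min(d2), 0))
}

# All-pairs residue minimum heavy-atom distance matrix (nres x nres).
# Quadratic in atoms; complexes here are small so this is the workhorse
# behind node selection, edges and native contacts.
residue_min_dist_matrix <- function(complex) {
  xyz <- as.matrix(complex$atoms[, c("x", "y", "z")])
  g <- complex$atoms$ridx
  n <- nrow(complex$residues)
  sq <- rowSums(xyz^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(xyz)
  D2[D2 < 0] <- 0
  idx <- split(seq_along(g), factor(g, levels = seq_len(n)))
  # min-pool atom rows, then atom columns, into residue blocks
  rowmin <- matrix(0, n, length(g))
  for (i in seq_len(n)) {
    block <- D2[idx[[i]], , drop = FALSE]
    rowmin[i, ] <- if (nrow(block) == 1L) block else apply(block, 2, min)
  }
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    block <- rowmin[, idx[[j]], drop = FALSE]
    M[, j] <- if (ncol(block) == 1L) block else apply(block, 1, min)
  }
  sqrt(M)
}

# Apply a rigid-body transform x -> x R + t to all atoms (or to one chain).
transform_complex <- function(complex, rotation = diag(3),
                              translation = c(0, 0, 0), chain = NULL) {
  sel <- if (is.null(chain)) rep(TRUE, nrow(complex$atoms)) else
    complex$atoms$chain == chain
  xyz <- as.matrix(complex$atoms[sel, c("x", "y", "z")])
  xyz <- xyz %*% rotation +
    matrix(translation, nrow(xyz), 3, byrow = TRUE)
  complex$atoms[sel, c("x", "y", "z")] <- xyz
  complex
}

# Deterministic random proper rotation (det +1) from a seed.
random_rotation <- function(seed) {
  r <- local_seed_eval(seed, matrix(stats::rnorm(9), 3, 3))
  qr_d <- qr(r)
  Q <- qr.Q(qr_d)
  Q <- Q %*% diag(sign(diag(qr.R(qr_d))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
local_seed_eval <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
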