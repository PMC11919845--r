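#' @importFrom stats rnorm runif setNames dist rbinom
#' @importFrom utils head read.delim write.table
NULL

# Fixed 48-element vocabulary for the atomic-symbol one-hot (slot 49 = "other").
# The 48 elements cover organic chemistry plus metals and halogens commonly
# seen in drug molecules.
ATOM_VOCAB <- c(
  "C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B",
  "Si", "Se", "As", "H", "Li", "Na", "K", "Mg", "Ca", "Fe",
  "Zn", "Cu", "Mn", "Co", "Ni", "Cr", "Mo", "V", "Al", "Sn",
  "Pb", "Hg", "Cd", "Ag", "Au", "Pt", "Pd", "Ti", "W", "Sb",
  "Bi", "Ba", "Sr", "Tl", "Ge", "Ga", "Te", "Ru"
)

CHARGE_SLOTS <- c(-2L, -1L, 0L, 1L, 2L)  # slot 6 = other
DEGREE_SLOTS <- 0L:5L                    # slot 7 = ">= 6"
ATOM_FEATURE_DIM <- 49L + 6L + 7L + 1L + 1L

#' Featurize a single atom
#'
#' Builds the 64-dimensional indicator feature vector of an atom: a 49-slot
#' one-hot over the element symbol (48-element vocabulary plus an "other"
#' slot), a 6-slot one-hot over the formal charge (-2, -1, 0, +1, +2, other),
#' a 7-slot one-hot over the heavy-atom degree (0..5, ">= 6"), and two binary
#' flags for aromaticity and ring membership. Out-of-vocabulary symbols and
#' charges route to their "other" slot; degrees above 5 clamp to the last slot.
#'
#' @param symbol element symbol, e.g. `"C"`
#' @param formal_charge integer formal charge
#' @param degree non-negative integer heavy-atom degree
#' @param is_aromatic logical aromaticity flag
#' @param is_in_ring logical ring-membership flag
#' @return numeric 0/1 indicator vector of length 64
#' @examples
#' sum(featurize_atom("C", 0, 4, FALSE, FALSE))  # 3
#' @export
featurize_atom <- function(symbol, formal_charge, degree, is_aromatic, is_in_ring) {
  stopifnot(degree >= 0)
  v <- numeric(ATOM_FEATURE_DIM)
  si <- match(symbol, ATOM_VOCAB)
  v[if (is.na(si)) 49L else si] <- 1
  ci <- match(as.integer(formal_charge), CHARGE_SLOTS)
  v[49L + (if (is.na(ci)) 6L else ci)] <- 1
  di <- min(as.integer(degree), 6L)
  v[55L + di + 1L] <- 1
  v[63L] <- as.numeric(isTRUE(as.logical(is_aromatic)))
  v[64L] <- as.numeric(isTRUE(as.logical(is_in_ring)))
  v
}

#' Convert a SMILES string into a molecular graph
#'
#' Parses the SMILES with OpenBabel (via ChemmineR/ChemmineOB) into a
#' heavy-atom graph: one node per non-hydrogen atom, two directed edges per
#' bond, and 64-dimensional node features from [featurize_atom()]. Aromaticity
#' and ring membership come from ChemmineR ring perception; an atom is flagged
#' aromatic when it belongs to an aromatic ring.
#'
#' @param smiles a single SMILES string
#' @param drug_id identifier stored on the graph (default: the SMILES itself)
#' @return an object of class `molecular_graph`: a list with `drug_id`,
#'   `smiles`, `node_features` (num_atoms x 64 matrix), `edges` (m x 2 integer
#'   matrix of directed atom-index pairs, empty for single-atom molecules) and
#'   `num_atoms`
#' @export
smiles_to_graph <- function(smiles, drug_id = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0L) {
    stop("SMILES string could not be parsed: '", smiles, "'")
  }
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (is.null(ab) || nrow(ab) == 0L) {
    stop("SMILES string yields an empty molecule: '", smiles, "'")
  }
  bb <- ChemmineR::bondblock(mol)
  symbols <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)

  # keep heavy atoms only (OpenBabel may materialize explicit hydrogens for
  # charged species such as [NH4+])
  heavy <- which(symbols != "H")
  if (length(heavy) == 0L) stop("SMILES string has no heavy atoms: '", smiles, "'")
  remap <- integer(n)
  remap[heavy] <- seq_along(heavy)

  edges <- matrix(integer(0), 0L, 2L)
  if (!is.null(bb) && nrow(bb) > 0L) {
    b1 <- as.integer(bb[, 1L]); b2 <- as.integer(bb[, 2L])
    keep <- symbols[b1] != "H" & symbols[b2] != "H"
    b1 <- remap[b1[keep]]; b2 <- remap[b2[keep]]
    if (length(b1) > 0L) {
      edges <- cbind(c(b1, b2), c(b2, b1))
    }
  }
  colnames(edges) <- c("from", "to")

  # degree over heavy-atom bonds
  degree <- integer(length(heavy))
  if (nrow(edges) > 0L) {
    tb <- table(factor(edges[, 1L], levels = seq_along(heavy)))
    degree <- as.integer(tb)
  }

  # ring perception; aromatic atoms = members of an aromatic ring
  in_ring <- rep(FALSE, length(heavy))
  aromatic <- rep(FALSE, length(heavy))
  rg <- tryCatch(
    suppressWarnings(ChemmineR::rings(mol, type = "all", arom = TRUE, inner = FALSE)),
    error = function(e) NULL
  )
  if (!is.null(rg) && length(rg$RINGS) > 0L) {
    for (ri in seq_along(rg$RINGS)) {
      atoms <- as.integer(sub("^.*_", "", rg$RINGS[[ri]]))
      atoms <- remap[atoms[symbols[atoms] != "H"]]
      in_ring[atoms] <- TRUE
      if (isTRUE(rg$AROMATIC[[ri]])) aromatic[atoms] <- TRUE
    }
  }

  charges <- decode_sdf_charge(ab)
  charges <- charges[heavy]
  feat <- t(vapply(
    seq_along(heavy),
    function(i) featurize_atom(symbols[heavy[i]], charges[i], degree[i],
                               aromatic[i], in_ring[i]),
    numeric(ATOM_FEATURE_DIM)
  ))

  structure(
    list(
      drug_id = drug_id,
      smiles = smiles,
      node_features = feat,
      edges = edges,
      num_atoms = length(heavy)
    ),
    class = "molecular_graph"
  )
}

# SDF atom-block charge column uses the legacy code 0=0, 1=+3, 2=+2, 3=+1,
# 5=-1, 6=-2, 7=-3 (4 = doublet radical, treated as neutral).
decode_sdf_charge <- function(ab) {
  code <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else integer(nrow(ab))
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0L
  as.integer(out)
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", x$drug_id, ": ", x$num_atoms, " atoms, ",
      nrow(x$edges) %/% 2L, " bonds\n", sep = "")
  invisible(x)
}

#' Parse a table of SMILES strings into molecular graphs
#'
#' @param smiles named character vector (names = drug ids) or data frame with
#'   columns `drug_id` and `smiles`
#' @return named list of `molecular_graph` objects
#' @export
smiles_table_to_graphs <- function(smiles) {
  if (is.data.frame(smiles)) {
    ids <- as.character(smiles$drug_id)
    sm <- as.character(smiles$smiles)
  } else {
    ids <- names(smiles) %||% as.character(smiles)
    sm <- as.character(smiles)
  }
  setNames(lapply(seq_along(sm), function(i) smiles_to_graph(sm[i], ids[i])), ids)
}
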