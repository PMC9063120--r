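#' Parse a SMILES string into a molecule object
#'
#' Parsing is delegated to OpenBabel through \pkg{ChemmineR}/\pkg{ChemmineOB}.
#' The returned object is a light heavy-atom representation: explicit
#' hydrogens are folded into per-atom implicit hydrogen counts, aromatic
#' rings are re-perceived so that kekulized and aromatic SMILES of the same
#' molecule yield identical graphs, and per-atom formal charge, stereo
#' parity, hybridization and degree are derived from the connection table.
#'
#' Unparseable SMILES are rejected by returning `NULL` (the "drop" signal);
#' callers that process lists of molecules drop such records and report the
#' offending indices.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `gp_mol`, or `NULL` when the string cannot be
#'   parsed as a valid molecule.
#' @examples
#' mol <- parse_smiles("CCO")
#' mol$n_atoms  # 3 heavy atoms
#' is.null(parse_smiles("not_a_smiles"))
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(sdf)) return(NULL)
  mol_from_sdf(sdf[[1]], smiles)
}

#' Parse a vector of SMILES strings
#'
#' Batch counterpart of [parse_smiles()]. Invalid entries are dropped and
#' their positions recorded, mirroring the record-drop rule used for
#' unloadable molecules in large SMILES collections.
#'
#' @param smiles Character vector of SMILES.
#' @param quiet Suppress the message listing dropped indices.
#' @return A list with elements `mols` (list of `gp_mol`), `kept` (indices of
#'   parsed entries) and `dropped` (indices of rejected entries).
#' @export
parse_smiles_batch <- function(smiles, quiet = FALSE) {
  stopifnot(is.character(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (!is.null(sdf) && length(sdf) == length(smiles)) {
    mols <- lapply(seq_along(smiles), function(i) {
      tryCatch(mol_from_sdf(sdf[[i]], smiles[i]), error = function(e) NULL)
    })
  } else {
    # Batch conversion failed somewhere: fall back to per-record parsing so
    # one bad SMILES does not take down the whole batch.
    mols <- lapply(smiles, parse_smiles)
  }
  dropped <- which(vapply(mols, is.null, logical(1L)))
  kept <- setdiff(seq_along(smiles), dropped)
  if (length(dropped) && !quiet) {
    message("Dropped ", length(dropped), " unparseable SMILES at indices: ",
            paste(dropped, collapse = ", "))
  }
  list(mols = mols[kept], kept = kept, dropped = dropped)
}

# Default valences used to derive implicit hydrogen counts.
DEFAULT_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

ATOMIC_NUMBER <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Br = 35, I = 53
)

# Build a gp_mol from a single ChemmineR SDF record.
mol_from_sdf <- function(sdf, smiles) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = length(bb) > 0, byrow = TRUE)

  element <- sub("_.*$", "", rownames(ab))
  n_all <- nrow(ab)
  # V2000 charge codes: 1..3 -> +3..+1, 5..7 -> -1..-3 (4 is a radical flag).
  ccode <- if (ncol(ab) >= 5) as.integer(ab[, 5L]) else integer(n_all)
  charge <- ifelse(ccode %in% c(1:3, 5:7), 4L - ccode, 0L)
  parity <- if (ncol(ab) >= 6) as.integer(ab[, 6L]) else integer(n_all)

  # Bond-less molecules come back as a degenerate all-zero block.
  if (ncol(bb) < 3L) bb <- matrix(numeric(0), ncol = 3L)
  bb <- bb[bb[, 1L] > 0 & bb[, 2L] > 0, , drop = FALSE]
  bonds <- if (nrow(bb)) {
    cbind(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
          order = as.integer(bb[, 3L]))
  } else {
    matrix(integer(0), ncol = 3, dimnames = list(NULL, c("i", "j", "order")))
  }

  # Fold explicit hydrogens (e.g. from [nH]) into implicit H counts.
  is_h <- element == "H"
  extra_h <- integer(n_all)
  if (any(is_h)) {
    keep <- which(!is_h)
    remap <- integer(n_all)
    remap[keep] <- seq_along(keep)
    keep_bond <- !(is_h[bonds[, "i"]] | is_h[bonds[, "j"]])
    for (r in which(!keep_bond)) {
      heavy <- if (is_h[bonds[r, "i"]]) bonds[r, "j"] else bonds[r, "i"]
      if (!is_h[heavy]) extra_h[heavy] <- extra_h[heavy] + 1L
    }
    bonds <- bonds[keep_bond, , drop = FALSE]
    bonds[, "i"] <- remap[bonds[, "i"]]
    bonds[, "j"] <- remap[bonds[, "j"]]
    element <- element[keep]
    charge <- charge[keep]
    parity <- parity[keep]
    extra_h <- extra_h[keep]
    rn_heavy <- rownames(ab)[keep]
  } else {
    rn_heavy <- rownames(ab)
  }
  n <- length(element)
  if (n == 0L) return(NULL)

  # Aromatic perception: OpenBabel writes kekulized bond orders, so the same
  # aromatic ring can come back with different single/double alternations
  # depending on the input SMILES. Re-perceive aromatic rings and flag their
  # atoms and bonds so downstream encodings are kekulization-invariant.
  aromatic_atom <- logical(n)
  bond_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  arom_bonds <- character(0)
  ringinfo <- tryCatch(
    ChemmineR::rings(sdf, upper = 10, type = "all", arom = TRUE),
    error = function(e) NULL
  )
  if (!is.null(ringinfo) && length(ringinfo$RINGS)) {
    idx_of <- stats::setNames(seq_len(n), rn_heavy)
    for (ri in seq_along(ringinfo$RINGS)) {
      if (!isTRUE(ringinfo$AROMATIC[[ri]])) next
      members <- idx_of[ringinfo$RINGS[[ri]]]
      if (anyNA(members)) next
      aromatic_atom[members] <- TRUE
      m <- length(members)
      arom_bonds <- c(arom_bonds,
                      bond_key(members, members[c(2:m, 1L)]))
    }
  }
  bond_aromatic <- if (nrow(bonds)) {
    bond_key(bonds[, "i"], bonds[, "j"]) %in% arom_bonds
  } else {
    logical(0)
  }

  degree <- tabulate(c(bonds[, "i"], bonds[, "j"]), nbins = n)
  order_sum <- numeric(n)
  n_double <- integer(n)
  n_triple <- integer(n)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      ij <- bonds[r, c("i", "j")]
      order_sum[ij] <- order_sum[ij] + bonds[r, "order"]
      if (bonds[r, "order"] == 2L) n_double[ij] <- n_double[ij] + 1L
      if (bonds[r, "order"] == 3L) n_triple[ij] <- n_triple[ij] + 1L
    }
  }

  # Implicit hydrogens from default valences (charge-adjusted); kekulized
  # orders are used on purpose, since they are what fixes H counts.
  val <- unname(DEFAULT_VALENCE[element])
  val[is.na(val)] <- 0
  adj <- ifelse(element %in% c("N", "P", "O", "S"), charge, -abs(charge))
  implicit_h <- pmax(0L, as.integer(val + adj - order_sum)) + extra_h

  hybridization <- ifelse(
    n_triple > 0L | n_double >= 2L, 1L,                 # sp
    ifelse(n_double > 0L | aromatic_atom, 2L, 3L)       # sp2 / sp3
  )

  structure(
    list(
      smiles = smiles,
      n_atoms = n,
      element = element,
      charge = as.integer(charge),
      stereo = as.integer(parity),
      aromatic = aromatic_atom,
      degree = as.integer(degree),
      implicit_h = as.integer(implicit_h),
      hybridization = as.integer(hybridization),
      bonds = cbind(bonds, aromatic = as.integer(bond_aromatic))
    ),
    class = "gp_mol"
  )
}

#' @export
print.gp_mol <- function(x, ...) {
  cat("<gp_mol> ", x$smiles, ": ", x$n_atoms, " heavy atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

# Fixed node-feature encoding ------------------------------------------------

GRAPH_ELEMENTS <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B")
GRAPH_MAX_DEGREE <- 5L
GRAPH_CHARGES <- -2:2
GRAPH_HYBRID <- 1:3          # sp, sp2, sp3
GRAPH_STEREO <- 0:2          # none, parity 1, parity 2

one_hot_bucket <- function(value, levels) {
  v <- numeric(length(levels) + 1L)
  k <- match(value, levels)
  v[if (is.na(k)) length(levels) + 1L else k] <- 1
  v
}

node_feature_length <- function() {
  length(GRAPH_ELEMENTS) + 1L +          # atom type + other
    (GRAPH_MAX_DEGREE + 1L) + 1L +       # degree 0..5 + overflow
    length(GRAPH_CHARGES) + 1L +         # formal charge + other
    length(GRAPH_HYBRID) + 1L +          # hybridization + other
    1L +                                 # aromatic flag
    length(GRAPH_STEREO) + 1L            # chirality tag + other
}

#' Build a featurized molecular graph
#'
#' Converts a parsed molecule into the graph representation consumed by the
#' GIN: heavy atoms as nodes with a fixed-length feature vector (one-hot atom
#' type, degree, formal charge and hybridization with overflow buckets, an
#' aromaticity flag, and a chirality/stereo-parity tag) and one undirected
#' edge per chemical bond. Node indices in `edges` are 0-based.
#'
#' @param mol A `gp_mol` from [parse_smiles()].
#' @return An object of class `gp_graph` with fields `n_nodes`,
#'   `node_features` (matrix, one row per atom) and `edges` (matrix with
#'   0-based columns `i`, `j`, one row per bond, `i < j`).
#' @examples
#' g <- build_graph(parse_smiles("c1ccccc1"))
#' g$n_nodes          # 6
#' nrow(g$edges)      # 6
#' @export
build_graph <- function(mol) {
  stopifnot(inherits(mol, "gp_mol"))
  n <- mol$n_atoms
  feats <- t(vapply(seq_len(n), function(a) {
    c(
      one_hot_bucket(mol$element[a], GRAPH_ELEMENTS),
      one_hot_bucket(min(mol$degree[a], GRAPH_MAX_DEGREE + 1L),
                     0:GRAPH_MAX_DEGREE),
      one_hot_bucket(mol$charge[a], GRAPH_CHARGES),
      one_hot_bucket(mol$hybridization[a], GRAPH_HYBRID),
      as.numeric(mol$aromatic[a]),
      one_hot_bucket(min(mol$stereo[a], 3L), GRAPH_STEREO)
    )
  }, numeric(node_feature_length())))

  edges <- if (nrow(mol$bonds)) {
    cbind(i = pmin(mol$bonds[, "i"], mol$bonds[, "j"]) - 1L,
          j = pmax(mol$bonds[, "i"], mol$bonds[, "j"]) - 1L)
  } else {
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  }

  structure(
    list(n_nodes = n, node_features = feats, edges = edges),
    class = "gp_graph"
  )
}

#' @export
print.gp_graph <- function(x, ...) {
  cat("<gp_graph> ", x$n_nodes, " nodes, ", nrow(x$edges), " edges, ",
      ncol(x$node_features), " features/node\n", sep = "")
  invisible(x)
}

# Degrees recomputed from the edge list (used by invariants/tests).
graph_degrees <- function(graph) {
  tabulate(c(graph$edges[, "i"], graph$edges[, "j"]) + 1L,
           nbins = graph$n_nodes)
}
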