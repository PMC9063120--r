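#' Extended-connectivity fingerprint (ECFP)
#'
#' Computes a folded binary circular fingerprint by iterative neighborhood
#' hashing. Each atom starts from an invariant built from its atomic number,
#' heavy degree, implicit hydrogen count, formal charge and aromaticity
#' (optionally its stereo parity); at every iteration up to `radius` the
#' identifier is re-hashed together with the sorted (bond order, neighbor
#' identifier) pairs of its neighborhood. Aromatic bonds carry a single
#' uniform order code so the fingerprint does not depend on which kekulized
#' form a SMILES was written in. All identifiers from all iterations are
#' folded into `n_bits` bits; bit collisions are accepted, as usual for
#' fingerprints of this length.
#'
#' @param mol A `gp_mol` from [parse_smiles()].
#' @param radius Number of neighborhood-growing iterations (default 4).
#' @param n_bits Folded vector length (default 2048).
#' @param use_chirality Include the stereo-parity tag in the initial atom
#'   invariant (default `FALSE`).
#' @return Integer 0/1 vector of length `n_bits` with attributes `radius`
#'   and `n_bits`, class `gp_ecfp`.
#' @examples
#' fp <- compute_ecfp(parse_smiles("CCO"))
#' length(fp)  # 2048
#' sum(fp)     # a handful of set bits
#' @export
compute_ecfp <- function(mol, radius = 4L, n_bits = 2048L,
                         use_chirality = FALSE) {
  stopifnot(inherits(mol, "gp_mol"), radius >= 0L, n_bits >= 1L)
  n <- mol$n_atoms

  z <- unname(ATOMIC_NUMBER[mol$element])
  z[is.na(z)] <- 0

  ids <- vapply(seq_len(n), function(a) {
    inv <- c(z[a], mol$degree[a], mol$implicit_h[a], mol$charge[a],
             as.integer(mol$aromatic[a]))
    if (use_chirality) inv <- c(inv, mol$stereo[a])
    hash_int_vec(inv)
  }, numeric(1L))

  # Adjacency with bond order codes (aromatic -> 4, kekulization-invariant).
  nbr <- vector("list", n)
  if (nrow(mol$bonds)) {
    code <- ifelse(mol$bonds[, "aromatic"] == 1L, 4L, mol$bonds[, "order"])
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[r, "i"]; j <- mol$bonds[r, "j"]
      nbr[[i]] <- rbind(nbr[[i]], c(code[r], j))
      nbr[[j]] <- rbind(nbr[[j]], c(code[r], i))
    }
  }

  all_ids <- ids
  for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(n), function(a) {
      nb <- nbr[[a]]
      if (is.null(nb)) {
        hash_int_vec(c(r, ids[a]))
      } else {
        pairs <- cbind(nb[, 1L], ids[nb[, 2L]])
        ord <- order(pairs[, 1L], pairs[, 2L])
        hash_int_vec(c(r, ids[a], t(pairs[ord, , drop = FALSE])))
      }
    }, numeric(1L))
    ids <- new_ids
    all_ids <- c(all_ids, new_ids)
  }

  bits <- integer(n_bits)
  bits[unique(all_ids %% n_bits) + 1L] <- 1L
  structure(bits, radius = radius, n_bits = n_bits, class = "gp_ecfp")
}

#' ECFP matrix for a set of SMILES
#'
#' Parses each SMILES and stacks fingerprints into a matrix, dropping (and
#' reporting) unparseable records.
#'
#' @param smiles Character vector of SMILES.
#' @inheritParams compute_ecfp
#' @param quiet Suppress the dropped-record message.
#' @return Matrix with one row per loadable molecule (rownames = SMILES) and
#'   attribute `dropped` holding the indices of rejected inputs.
#' @export
ecfp_matrix <- function(smiles, radius = 4L, n_bits = 2048L,
                        use_chirality = FALSE, quiet = FALSE) {
  parsed <- parse_smiles_batch(smiles, quiet = quiet)
  m <- t(vapply(
    parsed$mols,
    function(mol) as.integer(compute_ecfp(mol, radius, n_bits, use_chirality)),
    integer(n_bits)
  ))
  if (length(parsed$mols) == 0L) m <- matrix(integer(0), ncol = n_bits)
  rownames(m) <- smiles[parsed$kept]
  attr(m, "dropped") <- parsed$dropped
  m
}
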