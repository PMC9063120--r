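# Label algebra for multi-target binary activity panels.
#
# A full label over n binary targets is indexed as one of 2^n combination
# classes; a partial label (with missing entries) is consistent with the
# 2^m classes obtained by completing its m missing positions. MISSING is
# represented as NA throughout.

MAX_ONEHOT_TARGETS <- 16L

check_n_targets <- function(n) {
  if (n > MAX_ONEHOT_TARGETS) {
    stop("one-hot combination mode supports at most ", MAX_ONEHOT_TARGETS,
         " targets (2^n class explosion); got ", n)
  }
  invisible(n)
}

#' Encode a full binary label vector as a combination-class index
#'
#' The n binary target labels are read left to right as a binary number with
#' the first target in the most significant position, giving a class index
#' in `[0, 2^n)`. For the five-target CYP450-style panel, `[0,0,0,0,0]` is
#' class 0 (the all-negative class) and `[0,1,1,0,1]` is class 13.
#'
#' @param binary Vector of 0/1 values with no missing entries.
#' @return Integer class index in `[0, 2^length(binary))`.
#' @examples
#' encode_full_label(c(0, 1, 1, 0, 1))  # 13
#' @export
encode_full_label <- function(binary) {
  n <- length(binary)
  check_n_targets(n)
  if (anyNA(binary)) {
    stop("label vector has missing entries; use enumerate_candidates()")
  }
  if (!all(binary %in% c(0, 1))) stop("label entries must be 0 or 1")
  as.integer(sum(binary * 2^((n - 1L):0)))
}

#' Decode a combination-class index back to a binary label vector
#'
#' Exact inverse of [encode_full_label()].
#'
#' @param class_index Integer in `[0, 2^n_targets)`.
#' @param n_targets Number of binary targets.
#' @return Integer 0/1 vector of length `n_targets`.
#' @examples
#' decode_class(13, 5)  # c(0, 1, 1, 0, 1)
#' @export
decode_class <- function(class_index, n_targets) {
  check_n_targets(n_targets)
  if (class_index < 0 || class_index >= 2^n_targets) {
    stop("class_index ", class_index, " out of range [0, ", 2^n_targets, ")")
  }
  as.integer(floor(class_index / 2^((n_targets - 1L):0)) %% 2)
}

#' Enumerate the candidate classes of a partial label
#'
#' A partial label with m missing entries (NA) is consistent with the 2^m
#' combination classes obtained by filling the missing positions with every
#' 0/1 combination. For the worked panel example `[0,1,NA,0,0]` the
#' candidates are classes 8 and 12.
#'
#' @param partial Vector over {0, 1, NA}.
#' @return Sorted integer vector of candidate class indices.
#' @examples
#' enumerate_candidates(c(0, 1, NA, 0, 0))  # c(8, 12)
#' @export
enumerate_candidates <- function(partial) {
  n <- length(partial)
  check_n_targets(n)
  miss <- which(is.na(partial))
  if (!all(partial[!is.na(partial)] %in% c(0, 1))) {
    stop("observed label entries must be 0 or 1")
  }
  if (length(miss) == 0L) return(encode_full_label(partial))
  fills <- as.matrix(expand.grid(rep(list(c(0L, 1L)), length(miss))))
  cand <- apply(fills, 1L, function(f) {
    v <- partial
    v[miss] <- f
    encode_full_label(v)
  })
  sort(as.integer(cand))
}

#' Complete a partial label with teacher probabilities
#'
#' Restricts a teacher model's soft class distribution to the candidate
#' classes of the partial label and renormalizes so the result sums to 1;
#' all non-candidate classes get probability 0. When every candidate has
#' zero teacher mass, the completion falls back to a uniform distribution
#' over the candidates (and says so).
#'
#' @param partial Vector over {0, 1, NA} of length n.
#' @param teacher_probs Nonnegative vector of length `2^n` (a soft class
#'   distribution; it need not be normalized).
#' @return Numeric probability vector of length `2^n` summing to 1, with
#'   support inside the candidate set.
#' @examples
#' p <- rep(0, 32); p[9] <- 0.3; p[13] <- 0.1  # classes 8 and 12 (0-based)
#' complete_partial_label(c(0, 1, NA, 0, 0), p)[c(9, 13)]  # 0.75, 0.25
#' @export
complete_partial_label <- function(partial, teacher_probs) {
  n <- length(partial)
  check_n_targets(n)
  if (length(teacher_probs) != 2^n) {
    stop("teacher_probs must have length 2^n = ", 2^n)
  }
  if (any(teacher_probs < 0)) stop("teacher_probs must be nonnegative")
  cand <- enumerate_candidates(partial)
  out <- numeric(2^n)
  mass <- teacher_probs[cand + 1L]
  total <- sum(mass)
  if (total > 0) {
    out[cand + 1L] <- mass / total
  } else {
    message("all candidate probabilities are zero; ",
            "falling back to uniform over ", length(cand), " candidates")
    out[cand + 1L] <- 1 / length(cand)
  }
  out
}

#' Complete a partial label per target (multi-label mode)
#'
#' Alternative completion for the independent-sigmoid (Tox21-style)
#' formulation: observed entries are kept, missing entries are filled with
#' the teacher's per-target activity probability.
#'
#' @param partial Vector over {0, 1, NA}.
#' @param teacher_target_probs Per-target probabilities, same length.
#' @return Numeric vector over \[0, 1\], no missing entries.
#' @export
complete_partial_multilabel <- function(partial, teacher_target_probs) {
  if (length(partial) != length(teacher_target_probs)) {
    stop("partial and teacher_target_probs must have the same length")
  }
  if (any(teacher_target_probs < 0 | teacher_target_probs > 1)) {
    stop("teacher_target_probs must lie in [0, 1]")
  }
  out <- as.numeric(partial)
  miss <- is.na(out)
  out[miss] <- teacher_target_probs[miss]
  out
}

#' Mixup configuration
#'
#' @param alpha Shape parameter of the Beta(alpha, alpha) distribution the
#'   mixing coefficient is drawn from; default 0.4.
#' @param enabled Whether mixup noise is applied during student training.
#' @return A `gp_mixup_config` list.
#' @export
mixup_config <- function(alpha = 0.4, enabled = TRUE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("mixup alpha must be a single value > 0")
  }
  structure(list(alpha = alpha, enabled = isTRUE(enabled)),
            class = "gp_mixup_config")
}

#' Sample a mixup coefficient
#'
#' Draws the mixing coefficient lambda from Beta(alpha, alpha). Uses R's
#' global RNG stream, so results are reproducible under `set.seed()`.
#'
#' @param config A [mixup_config()].
#' @param n Number of draws.
#' @return Numeric vector of draws in \[0, 1\].
#' @export
sample_lambda <- function(config, n = 1L) {
  stopifnot(inherits(config, "gp_mixup_config"))
  stats::rbeta(n, config$alpha, config$alpha)
}

#' Mix a pair of inputs and labels
#'
#' Forms the convex combinations `lambda * x_i + (1 - lambda) * x_j` and
#' `lambda * y_i + (1 - lambda) * y_j` with the same coefficient for inputs
#' and labels.
#'
#' @param x_i,x_j Feature vectors of equal length.
#' @param y_i,y_j Label vectors of equal length.
#' @param lambda Mixing coefficient in \[0, 1\].
#' @return List with elements `x` and `y`.
#' @export
mixup_pair <- function(x_i, y_i, x_j, y_j, lambda) {
  if (length(x_i) != length(x_j)) stop("input vectors differ in length")
  if (length(y_i) != length(y_j)) stop("label vectors differ in length")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  list(x = lambda * x_i + (1 - lambda) * x_j,
       y = lambda * y_i + (1 - lambda) * y_j)
}

# One-hot matrix (rows = samples) from a vector of class indices.
class_onehot <- function(class_index, n_classes) {
  m <- matrix(0, nrow = length(class_index), ncol = n_classes)
  m[cbind(seq_along(class_index), class_index + 1L)] <- 1
  m
}

# Encode a binary label matrix (rows = samples) to class indices.
encode_label_matrix <- function(labels) {
  apply(labels, 1L, encode_full_label)
}

# Decode a vector of class indices to a binary label matrix.
decode_class_matrix <- function(class_index, n_targets) {
  t(vapply(class_index, decode_class, integer(n_targets),
           n_targets = n_targets))
}
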