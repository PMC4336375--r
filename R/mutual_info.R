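# Water-water mutual information by permuted fill modes, and the assembly
# of the water-water entropy S_ww from per-pair terms.
#
# The permuted series keeps the site-1 poses in frame order and reassigns
# the site-2 poses by a random permutation of frames: the single-site
# marginals are preserved exactly while the joint (frame-synchronized)
# structure is destroyed. The mutual information is the entropy excess of
# the decorrelated series over the original,
#
#   I_ww = (R/n) sum_i ln[ d_perm,i^12 / d_pair,i^12 ]  >= 0 in expectation,
#
# where both sets of nearest-neighbour distances use the same n, k and 12D
# metric, so the additive bias terms of the two KNN entropy estimates cancel
# by construction.

#' Decorrelate a pair series by permuting one site's frame assignment
#'
#' Site-1 poses keep their frame order; site-2 poses are reassigned by a
#' uniform random permutation of frame indices (a derangement is not
#' required). The multiset of site-2 poses -- and hence both single-site
#' marginal distributions -- is exactly preserved.
#'
#' @param pairs a \code{pair_series}.
#' @param seed integer seed making the permutation reproducible; ignored
#'   when \code{perm} is given.
#' @param perm optional explicit permutation of \code{1:n} (test hook; the
#'   identity permutation returns the input series).
#' @return a \code{pair_series} with permuted site-2 poses.
#' @export
permuted_pair_series <- function(pairs, seed = NULL, perm = NULL) {
  stopifnot(inherits(pairs, "pair_series"))
  n <- n_poses(pairs)
  if (n < 2) stop("insufficient samples: need n >= 2")
  if (is.null(perm)) {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    perm <- sample.int(n)
  }
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  b <- pose_series(pairs$b$position[perm, , drop = FALSE],
                   pairs$b$quaternion[perm, , drop = FALSE],
                   pairs$b$frame)
  pair_series(pairs$site_ids, pairs$a, b)
}

#' Mutual information estimate container
#' @keywords internal
mutual_information_estimate <- function(value, per_permutation, seed, k) {
  structure(list(value = value, per_permutation = per_permutation,
                 n_permutations = length(per_permutation),
                 seed = seed, k = as.integer(k)),
            class = "mutual_information_estimate")
}

#' @export
print.mutual_information_estimate <- function(x, ...) {
  cat(sprintf("I_ww = %.4f cal/mol/K  (mean of %d permutation(s), seed %s)\n",
              x$value, x$n_permutations, format(x$seed)))
  invisible(x)
}

#' @export
as.double.mutual_information_estimate <- function(x, ...) x$value

#' Water-water mutual information by permuted fill modes
#'
#' Estimates the additional correlation between two cavity waters beyond
#' what the separate solute-frame distributions capture. Nearest-neighbour
#' distances in the 12D pair metric are computed for the original series
#' (\code{d_pair}) and for series with the site-2 frame assignment permuted
#' (\code{d_perm}); the estimate is averaged over \code{n_permutations}
#' independent permutations to reduce permutation noise. The estimator is
#' free of the additive KNN bias because the bias terms of the two
#' 12-dimensional entropy estimates cancel.
#'
#' @param pairs a \code{pair_series} (both sites occupied in every frame).
#' @param n_permutations number of fill permutations to average over.
#' @param seed integer seed controlling the permutations.
#' @param k neighbour order.
#' @param jitter see [solute_water_entropy()].
#' @return a \code{mutual_information_estimate}; the value is in cal/mol/K.
#' @export
pair_mutual_information <- function(pairs, n_permutations = 8, seed = 1,
                                    k = 1, jitter = FALSE) {
  stopifnot(inherits(pairs, "pair_series"), n_permutations >= 1)
  n <- n_poses(pairs)
  if (n < 2) stop("insufficient samples: need n >= 2")
  d_pair <- .pair_knn(pairs$a$position, pairs$a$quaternion,
                      pairs$b$position, pairs$b$quaternion, k, jitter)
  mean_log_pair <- mean(log(d_pair))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vals <- vapply(seq_len(n_permutations), function(m) {
    perm <- sample.int(n)
    d_perm <- .pair_knn(pairs$a$position, pairs$a$quaternion,
                        pairs$b$position[perm, , drop = FALSE],
                        pairs$b$quaternion[perm, , drop = FALSE], k, jitter)
    GAS_CONSTANT_CAL * 12 * (mean(log(d_perm)) - mean_log_pair)
  }, numeric(1))
  mutual_information_estimate(mean(vals), vals, seed, k)
}

#' Water-water entropy from per-pair mutual informations
#'
#' \deqn{S_{ww} = -\sum_{pairs} (I_{ww} + S_{vol})}
#' summed over pairs of hydration sites whose centers lie within the pair
#' gate (4.0 Angstrom by default, applied when the pairs are built). The
#' excluded-volume term \code{s_vol} defaults to 0, the appropriate
#' assumption for buried sites; the bulk-water value is shipped as
#' [SVOL_BULK] for sensitivity analyses. A singly occupied cavity has no
#' pairs and \eqn{S_{ww} = 0}.
#'
#' @param mi_values numeric vector of per-pair I_ww values, cal/mol/K
#'   (\code{mutual_information_estimate} objects are accepted).
#' @param s_vol per-pair volume entropy, cal/mol/K (recycled).
#' @return S_ww in cal/mol/K.
#' @examples
#' water_water_entropy(numeric(0))          # singly occupied: 0
#' water_water_entropy(0.117)               # one pair: -0.117
#' @export
water_water_entropy <- function(mi_values, s_vol = 0) {
  if (is.list(mi_values))
    mi_values <- vapply(mi_values, as.numeric, numeric(1))
  if (length(mi_values) == 0) return(0)
  -sum(mi_values + s_vol)
}

#' Entropy-decomposition diagnostic for a pair of sites
#'
#' Computes the three KNN entropies of the decomposition
#' \eqn{I_{ww} = S^*_{sw} + S^*_{sw'} - S_{sww'}}: the 12D joint pair
#' entropy and the two 6D marginal entropies evaluated on the same pair
#' data (the uniform-reference terms cancel in the combination, leaving the
#' mutual information). This is a diagnostic only -- the production
#' estimator is [pair_mutual_information()], because combining KNN terms of
#' different dimensionality mixes bias terms that do not cancel.
#'
#' @inheritParams pair_entropy
#' @return a list with components \code{S_pair} (12D joint), \code{S_a} and
#'   \code{S_b} (6D marginals; \code{entropy_estimate} objects) and
#'   \code{mi} (their combination, cal/mol/K).
#' @export
mi_decomposition_check <- function(pairs, rho = 0.03324, k = 1,
                                   jitter = FALSE) {
  stopifnot(inherits(pairs, "pair_series"))
  S12 <- pair_entropy(pairs, rho = rho, k = k, jitter = jitter)
  S1 <- solute_water_entropy(pairs$a, rho = rho, k = k, jitter = jitter)
  S2 <- solute_water_entropy(pairs$b, rho = rho, k = k, jitter = jitter)
  list(S_pair = S12, S_a = S1, S_b = S2,
       mi = S1$value + S2$value - S12$value)
}
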