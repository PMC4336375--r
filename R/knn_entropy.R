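# Nonparametric entropy estimation from first (or kth) nearest-neighbour
# distances in the rigid-body configuration space. The absolute-entropy
# estimator is the classical unbiased KNN form
#
#   H_abs = (1/n) sum_i ln[ n d_{i,k}^p pi^{p/2} / Gamma(p/2 + 1) ]
#           - L_{k-1} + gamma
#
# with L_j the jth harmonic number and gamma Euler's constant. Relative
# (thermodynamic) entropies subtract the entropy of the uniform reference:
# number density rho over positions and the 8 pi^2 rotation-group volume
# over orientations.

#' Harmonic numbers L_j
#'
#' \eqn{L_j = \sum_{i=1}^{j} 1/i}, with \eqn{L_0 = 0}. L_{k-1} is the
#' neighbour-order bias correction of the KNN entropy estimator.
#'
#' @param j non-negative integer (vectorized).
#' @return numeric vector of harmonic numbers.
#' @examples
#' harmonic_number(0:3)  # 0, 1, 1.5, 1.8333...
#' @export
harmonic_number <- function(j) {
  j <- as.integer(j)
  if (any(j < 0)) stop("j must be >= 0")
  vapply(j, function(m) if (m == 0) 0 else sum(1 / seq_len(m)), numeric(1))
}

#' Entropy estimate container
#'
#' @param value entropy in cal/mol/K (thermodynamic estimators) or nats
#'   (raw absolute entropy).
#' @param nats the raw absolute entropy in nats, when applicable.
#' @param n_samples number of samples.
#' @param k neighbour order used.
#' @param dimension dimensionality p of the configuration space.
#' @param units \code{"cal/mol/K"} or \code{"nats"}.
#' @return An object of class \code{entropy_estimate}; \code{as.numeric()}
#'   extracts the value.
#' @keywords internal
entropy_estimate <- function(value, nats = NA_real_, n_samples, k, dimension,
                             units = "cal/mol/K") {
  stopifnot(n_samples >= 2, k >= 1)
  structure(list(value = value, nats = nats, n_samples = as.integer(n_samples),
                 k = as.integer(k), dimension = as.integer(dimension),
                 units = units),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("KNN entropy estimate: %.4f %s  (n = %d, k = %d, p = %d)\n",
              x$value, x$units, x$n_samples, x$k, x$dimension))
  invisible(x)
}

#' @export
as.double.entropy_estimate <- function(x, ...) x$value

#' Absolute KNN entropy from kth nearest-neighbour distances
#'
#' The unbiased nearest-neighbour estimate of the differential entropy of a
#' p-dimensional distribution, in nats, from the distance of each sample to
#' its kth nearest neighbour among the other samples.
#'
#' @param distances per-sample kth nearest-neighbour distances (self-match
#'   excluded); all must be strictly positive.
#' @param p dimensionality of the sample space.
#' @param n number of samples (defaults to \code{length(distances)}).
#' @param k neighbour order.
#' @return absolute entropy in nats.
#' @examples
#' # n = 2, k = 1, both distances chosen so the log argument is 1:
#' d <- (6 / (2 * pi^3))^(1/6)
#' knn_abs_entropy(c(d, d), p = 6)  # equals Euler's constant
#' @export
knn_abs_entropy <- function(distances, p, n = length(distances), k = 1) {
  stopifnot(n >= 2, k >= 1, p >= 1)
  if (any(distances <= 0))
    stop("duplicate samples: zero nearest-neighbour distance (deduplicate or use jitter)")
  unit_ball <- pi^(p / 2) / gamma(p / 2 + 1)
  mean(log(n * distances^p * unit_ball)) - harmonic_number(k - 1) + EULER_GAMMA
}

# kth-NN distances in the 6D rigid-body metric, with optional jitter for
# duplicate samples (1e-10 Angstrom, opt in: silent +-Inf is worse than an
# explicit contract)
.rigid_knn <- function(position, quaternion, k, jitter = FALSE) {
  d <- knn_rigid_cpp(position, quaternion, as.integer(k))
  if (any(d[, 1] == 0)) {
    if (!jitter)
      stop("duplicate samples: zero nearest-neighbour distance (deduplicate or use jitter = TRUE)")
    position <- position + matrix(runif(length(position), -1e-10, 1e-10),
                                  nrow(position), 3)
    d <- knn_rigid_cpp(position, quaternion, as.integer(k))
  }
  d[, k]
}

.pair_knn <- function(pa, qa, pb, qb, k, jitter = FALSE) {
  d <- knn_rigid_pair_cpp(pa, qa, pb, qb, as.integer(k))
  if (any(d[, 1] == 0)) {
    if (!jitter)
      stop("duplicate samples: zero nearest-neighbour distance (deduplicate or use jitter = TRUE)")
    pa <- pa + matrix(runif(length(pa), -1e-10, 1e-10), nrow(pa), 3)
    pb <- pb + matrix(runif(length(pb), -1e-10, 1e-10), nrow(pb), 3)
    d <- knn_rigid_pair_cpp(pa, qa, pb, qb, as.integer(k))
  }
  d[, k]
}

#' Solute-water entropy of a hydration site
#'
#' The relative entropy of the site water's position/orientation
#' distribution versus the uniform bulk reference (density \code{rho} over
#' positions, uniform over the rotation group), estimated from kth
#' nearest-neighbour distances in the 6D mixed metric:
#' \deqn{S_{sw} = R \{ H_{abs} - \ln(8\pi^2/\rho) \}}
#' which for k = 1 reduces to
#' \eqn{R\{ (1/n)\sum \ln[n d_{total}^6 \pi \rho / 48] + \gamma \}}.
#' Negative for localized sites; zero when the distribution equals the
#' reference.
#'
#' @param site a \code{site_series} or \code{pose_series} with at least 2
#'   poses.
#' @param rho bulk number density, molecules/Angstrom^3.
#' @param k neighbour order (production calculations use k = 1).
#' @param jitter if TRUE, duplicate samples are perturbed by 1e-10 Angstrom
#'   instead of raising an error.
#' @return An \code{entropy_estimate} in cal/mol/K.
#' @export
solute_water_entropy <- function(site, rho = 0.03324, k = 1, jitter = FALSE) {
  ps <- if (inherits(site, "site_series")) site$poses else site
  n <- nrow(ps$position)
  if (n < 2) stop("insufficient samples: at least 2 occupied frames required")
  d <- .rigid_knn(ps$position, ps$quaternion, k, jitter)
  H <- knn_abs_entropy(d, p = 6, n = n, k = k)
  S <- GAS_CONSTANT_CAL * (H - log(8 * pi^2 / rho))
  entropy_estimate(S, nats = H, n_samples = n, k = k, dimension = 6)
}

#' Joint pair entropy of two hydration sites
#'
#' The 12-dimensional entropy of the synchronized pose pair relative to the
#' uniform two-water reference, from kth nearest-neighbour distances in the
#' pair metric:
#' \deqn{S_{sww'} = R \{ H_{abs} - \ln(64\pi^4/\rho^2) \}}
#' which for k = 1 reduces to
#' \eqn{R\{ (1/n)\sum \ln[n d_{pair}^{12} \pi^2 \rho^2 / 46080] + \gamma \}}.
#' Both sites must be occupied in every frame of the series.
#'
#' @param pairs a \code{pair_series}.
#' @inheritParams solute_water_entropy
#' @return An \code{entropy_estimate} in cal/mol/K.
#' @export
pair_entropy <- function(pairs, rho = 0.03324, k = 1, jitter = FALSE) {
  stopifnot(inherits(pairs, "pair_series"))
  n <- n_poses(pairs)
  if (n < 2) stop("insufficient samples: at least 2 co-occupied frames required")
  d <- .pair_knn(pairs$a$position, pairs$a$quaternion,
                 pairs$b$position, pairs$b$quaternion, k, jitter)
  H <- knn_abs_entropy(d, p = 12, n = n, k = k)
  S <- GAS_CONSTANT_CAL * (H - log(64 * pi^4 / rho^2))
  entropy_estimate(S, nats = H, n_samples = n, k = k, dimension = 12)
}
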