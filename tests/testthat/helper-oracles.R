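# Shared fixtures and independent oracles. Everything here is coded
# independently of the package internals it checks.

# reference water in the body-frame orientation (bisector = +z, H1 at +x)
ref_water_atoms <- function(origin = c(0, 0, 0), r_oh = 0.9572,
                            theta = 104.52) {
  half <- theta / 2 * pi / 180
  water_atoms(origin,
              origin + c(r_oh * sin(half), 0, r_oh * cos(half)),
              origin + c(-r_oh * sin(half), 0, r_oh * cos(half)))
}

# rotation matrix about an axis
rot_axis_angle <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_rotation <- function() {
  ang <- runif(1, 0, pi)
  ax <- rnorm(3)
  rot_axis_angle(ax, ang)
}

# Hamilton product, (w, x, y, z) convention
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

# apply a rotation to the atoms of a water
rotate_water <- function(atoms, M) {
  water_atoms(as.numeric(M %*% atoms$oxygen),
              as.numeric(M %*% atoms$hydrogen1),
              as.numeric(M %*% atoms$hydrogen2))
}

# independent site-by-site double-loop nonbonded energy (Lorentz-Berthelot,
# bare Coulomb, optional CHARMM switch on LJ, optional minimum image)
brute_pair_energy <- function(a, b, switched = FALSE, box = NULL,
                              r_on = 9, r_off = 11) {
  e <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- c(a$x[i] - b$x[j], a$y[i] - b$y[j], a$z[i] - b$z[j])
    if (!is.null(box)) d <- d - box * round(d / box)
    r <- sqrt(sum(d^2))
    eps <- sqrt(a$epsilon[i] * b$epsilon[j])
    sig <- (a$sigma[i] + b$sigma[j]) / 2
    lj <- 4 * eps * ((sig / r)^12 - (sig / r)^6)
    if (switched) {
      s <- if (r <= r_on) 1 else if (r >= r_off) 0 else
        (r_off^2 - r^2)^2 * (r_off^2 + 2 * r^2 - 3 * r_on^2) /
          (r_off^2 - r_on^2)^3
      lj <- lj * s
    }
    e <- e + lj + 332.0636 * a$charge[i] * b$charge[j] / r
  }
  e
}

random_molecule <- function(n_sites, center) {
  nonbonded_sites(name = paste0("X", seq_len(n_sites)),
                  position = sweep(matrix(runif(3 * n_sites, -0.8, 0.8),
                                          n_sites, 3), 2, center, "+"),
                  charge = round(runif(n_sites, -0.8, 0.8), 3),
                  sigma = runif(n_sites, 1, 4),
                  epsilon = runif(n_sites, 0, 0.3))
}

# exhaustive optimal water-site matching (minimum total distance over all
# assignments respecting the site radii)
brute_optimal_assignment <- function(positions, sites) {
  m <- nrow(positions)
  ids <- vapply(sites, function(s) s$site_id, character(1))
  dist <- sapply(sites, function(s)
    sqrt(colSums((t(positions) - s$center)^2)))
  dist <- matrix(dist, nrow = m)
  best <- NULL; best_cost <- Inf; best_n <- -1
  options <- lapply(seq_along(sites), function(si)
    c(NA, which(dist[, si] <= sites[[si]]$radius)))
  grids <- do.call(expand.grid, options)
  for (g in seq_len(nrow(grids))) {
    as <- as.integer(grids[g, ])
    used <- as[!is.na(as)]
    if (anyDuplicated(used)) next
    n_as <- length(used)
    cost <- sum(dist[cbind(used, which(!is.na(as)))])
    if (n_as > best_n || (n_as == best_n && cost < best_cost)) {
      best <- as; best_cost <- cost; best_n <- n_as
    }
  }
  stats::setNames(best, ids)
}

# plain R nearest-neighbour distances in the mixed rigid-body metric
brute_rigid_nn <- function(pos, quat, k = 1) {
  n <- nrow(pos)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- sapply(seq_len(n), function(j) {
      if (j == i) return(Inf)
      dt2 <- sum((pos[i, ] - pos[j, ])^2)
      ang <- 2 * acos(min(1, abs(sum(quat[i, ] * quat[j, ]))))
      sqrt(dt2 + ang^2)
    })
    out[i] <- sort(d)[k]
  }
  out
}

# closed-form entropies (cal/mol/K), independent of the package constants
gauss_S_sw <- function(sigma, rho = 0.03324)
  1.9872 * (1.5 * log(2 * pi * exp(1) * sigma^2) + log(rho))
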