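# Nonbonded interaction energies: Lennard-Jones + Coulomb over site pairs
# with Lorentz-Berthelot combination rules, an optional CHARMM-style
# switching of the LJ term between 9 and 11 Angstrom, and optional
# minimum-image wrapping in an orthorhombic box. Analysis energies are
# plain pairwise sums (no Ewald): the per-site energy decomposition is
# defined on direct interaction energies.

#' TIP4P-2005 water model parameters
#'
#' The four-site rigid water model used for all built-in water energetics:
#' LJ on the oxygen only, charges on the hydrogens and on a massless M site
#' displaced from the oxygen along the H-O-H bisector. The M site is
#' reconstructed geometrically from the O/H/H coordinates (or from a pose)
#' each time it is needed.
#'
#' @return An object of class \code{water_model} with fields
#'   \code{q_H}, \code{q_M} (e), \code{sigma_O}, \code{eps_O} (Angstrom,
#'   kcal/mol), \code{r_OH}, \code{theta_HOH} (Angstrom, degrees) and
#'   \code{r_OM} (Angstrom). The net charge is zero by construction.
#' @export
tip4p2005 <- function() {
  m <- structure(list(name = "TIP4P-2005",
                      q_H = 0.5564, q_M = -1.1128,
                      sigma_O = 3.1589, eps_O = 0.1852,
                      r_OH = 0.9572, theta_HOH = 104.52,
                      r_OM = 0.1546),
                 class = "water_model")
  stopifnot(abs(2 * m$q_H + m$q_M) < 1e-12)
  m
}

#' Table of nonbonded interaction sites
#'
#' @param name character atom labels.
#' @param position n x 3 coordinate matrix, Angstrom.
#' @param charge partial charges, e.
#' @param sigma Lennard-Jones sigma, Angstrom (>= 0).
#' @param epsilon Lennard-Jones epsilon, kcal/mol (>= 0).
#' @return A data frame with class \code{nonbonded_sites} and columns
#'   name, x, y, z, charge, sigma, epsilon.
#' @export
nonbonded_sites <- function(name, position, charge, sigma, epsilon) {
  position <- as.matrix(position)
  stopifnot(ncol(position) == 3, all(sigma >= 0), all(epsilon >= 0))
  out <- data.frame(name = name, x = position[, 1], y = position[, 2],
                    z = position[, 3], charge = charge, sigma = sigma,
                    epsilon = epsilon, stringsAsFactors = FALSE)
  class(out) <- c("nonbonded_sites", "data.frame")
  out
}

#' Atomic coordinates of a rigid water from its pose
#'
#' Rebuilds the O/H1/H2 positions implied by a pose under the rigid model
#' geometry: in the body frame the oxygen sits at the origin and the
#' hydrogens lie in the xz plane, symmetric about the z axis.
#'
#' @param position oxygen position, 3-vector.
#' @param orientation unit quaternion.
#' @param model a \code{water_model}.
#' @return a \code{water_atoms} object.
#' @export
pose_to_atoms <- function(position, orientation, model = tip4p2005()) {
  half <- model$theta_HOH / 2 * pi / 180
  hx <- model$r_OH * sin(half)
  hz <- model$r_OH * cos(half)
  Rm <- quat_to_matrix(orientation)
  water_atoms(position,
              position + as.numeric(Rm %*% c(hx, 0, hz)),
              position + as.numeric(Rm %*% c(-hx, 0, hz)))
}

#' Nonbonded sites of one water molecule
#'
#' Builds the four TIP4P-2005 interaction sites (LJ oxygen, two charged
#' hydrogens, charged M site on the bisector) from either a
#' \code{water_atoms} object or a pose.
#'
#' @param x a \code{water_atoms} object, or a 3-vector oxygen position (in
#'   which case \code{orientation} must be given).
#' @param orientation unit quaternion, used when \code{x} is a position.
#' @param model a \code{water_model}.
#' @return a \code{nonbonded_sites} table with four rows.
#' @export
water_nonbonded_sites <- function(x, orientation = NULL, model = tip4p2005()) {
  if (!inherits(x, "water_atoms")) {
    stopifnot(!is.null(orientation))
    x <- pose_to_atoms(x, orientation, model)
  }
  b1 <- x$hydrogen1 - x$oxygen
  b2 <- x$hydrogen2 - x$oxygen
  bis <- b1 / .vnorm(b1) + b2 / .vnorm(b2)
  m_site <- x$oxygen + model$r_OM * bis / .vnorm(bis)
  nonbonded_sites(name = c("O", "H1", "H2", "M"),
                  position = rbind(x$oxygen, x$hydrogen1, x$hydrogen2, m_site),
                  charge = c(0, model$q_H, model$q_H, model$q_M),
                  sigma = c(model$sigma_O, 0, 0, 0),
                  epsilon = c(model$eps_O, 0, 0, 0))
}

# CHARMM switching function applied to the LJ term: 1 below r_on, 0 above
# r_off, C1-continuous in between
.lj_switch <- function(r, r_on, r_off) {
  s <- ifelse(r <= r_on, 1,
       ifelse(r >= r_off, 0,
              (r_off^2 - r^2)^2 * (r_off^2 + 2 * r^2 - 3 * r_on^2) /
                (r_off^2 - r_on^2)^3))
  s
}

#' Nonbonded interaction energy of two molecules
#'
#' Sum over all site pairs of the Lennard-Jones and Coulomb terms
#' \deqn{4\epsilon_{ij}[(\sigma_{ij}/r)^{12} - (\sigma_{ij}/r)^6]
#'   + 332.0636\, q_i q_j / r}
#' with Lorentz--Berthelot combination rules
#' (\eqn{\sigma_{ij} = (\sigma_i+\sigma_j)/2},
#' \eqn{\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}}). With
#' \code{scheme = "switched"} the LJ term is switched off smoothly between
#' \code{r_on} and \code{r_off} (9.0 and 11.0 Angstrom by default); the
#' Coulomb term is never truncated. When \code{box} is supplied, site-site
#' separations use the minimum-image convention in an orthorhombic box.
#'
#' @param a,b \code{nonbonded_sites} tables of two disjoint molecules.
#' @param scheme \code{"none"} (plain sums) or \code{"switched"}.
#' @param box optional length-3 vector of orthorhombic box edges, Angstrom.
#' @param r_on,r_off switching bounds, Angstrom.
#' @return interaction energy in kcal/mol.
#' @export
pair_energy <- function(a, b, scheme = c("none", "switched"), box = NULL,
                        r_on = 9.0, r_off = 11.0) {
  scheme <- match.arg(scheme)
  na <- nrow(a); nb <- nrow(b)
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  if (!is.null(box)) {
    stopifnot(length(box) == 3, all(box > 0))
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  r <- sqrt(dx^2 + dy^2 + dz^2)
  qq <- outer(a$charge, b$charge)
  eps <- sqrt(outer(a$epsilon, b$epsilon))
  sig <- outer(a$sigma, b$sigma, "+") / 2
  interacting <- qq != 0 | eps != 0
  if (any(r == 0 & interacting))
    stop("singularity: zero separation between interacting sites")
  r[r == 0] <- Inf  # inert coincident sites contribute nothing
  sr6 <- (sig / r)^6
  lj <- 4 * eps * (sr6^2 - sr6)
  if (scheme == "switched") lj <- lj * .lj_switch(r, r_on, r_off)
  coul <- COULOMB_CONSTANT * qq / r
  sum(lj + coul)
}

#' Mean solute-water interaction energy of a hydration site
#'
#' The mean over occupied frames of the interaction energy between the site
#' water (rebuilt from its pose under the water model geometry) and the
#' fixed solute sites.
#'
#' @param site a \code{site_series} or \code{pose_series}.
#' @param solute a \code{nonbonded_sites} table, fixed across frames.
#' @param model water model supplying geometry and parameters.
#' @param ... passed to [pair_energy()] (scheme, box, switching bounds).
#' @return E_sw in kcal/mol.
#' @export
solute_water_energy <- function(site, solute, model = tip4p2005(), ...) {
  ps <- if (inherits(site, "site_series")) site$poses else site
  n <- nrow(ps$position)
  if (n < 1) stop("insufficient samples: empty site series")
  e <- vapply(seq_len(n), function(i) {
    w <- water_nonbonded_sites(ps$position[i, ], ps$quaternion[i, ], model)
    pair_energy(w, solute, ...)
  }, numeric(1))
  mean(e)
}

#' Mean water-water interaction energy of a hydration site
#'
#' Half the mean interaction energy of the site water with all other waters
#' present in the same frame (the half-share convention: summing this
#' quantity over all waters recovers the total unique-pair energy). Frames
#' of \code{site} with no synchronized partner water contribute zero.
#'
#' @param site a \code{site_series} or \code{pose_series}.
#' @param others a \code{pose_series} or list of them holding the other
#'   waters, matched to \code{site} by frame index.
#' @inheritParams solute_water_energy
#' @return E_ww in kcal/mol.
#' @export
water_water_energy <- function(site, others, model = tip4p2005(), ...) {
  ps <- if (inherits(site, "site_series")) site$poses else site
  if (inherits(others, "pose_series") || inherits(others, "site_series"))
    others <- list(others)
  others <- lapply(others, function(o)
    if (inherits(o, "site_series")) o$poses else o)
  n <- nrow(ps$position)
  if (n < 1) return(0)
  e <- vapply(seq_len(n), function(i) {
    w <- water_nonbonded_sites(ps$position[i, ], ps$quaternion[i, ], model)
    tot <- 0
    for (o in others) {
      j <- match(ps$frame[i], o$frame)
      if (is.na(j)) next
      v <- water_nonbonded_sites(o$position[j, ], o$quaternion[j, ], model)
      tot <- tot + pair_energy(w, v, ...)
    }
    tot / 2
  }, numeric(1))
  mean(e)
}

#' Hydration energy difference
#'
#' \deqn{\Delta E_{IFST} = E_{sw} + E_{ww} - n E_{bulk}}
#' the energetic cost of moving n water molecules from bulk into the
#' solute's field.
#'
#' @param E_sw mean solute-water interaction energy, kcal/mol.
#' @param E_ww mean (half-share) water-water interaction energy, kcal/mol.
#' @param n_waters number of water molecules in the subvolume.
#' @param E_bulk bulk reference energy per water, kcal/mol.
#' @return Delta E_IFST in kcal/mol.
#' @examples
#' delta_E_ifst(-30.27, 0, 1)  # a strongly bound buried water
#' @export
delta_E_ifst <- function(E_sw, E_ww = 0, n_waters = 1, E_bulk = -11.5748) {
  E_sw + E_ww - n_waters * E_bulk
}
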