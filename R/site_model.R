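# Hydration sites and the bookkeeping that turns a trajectory of water
# poses into per-site time series: greedy frame-by-frame assignment of
# waters to sites, co-occupancy pair series, and disjoint random block
# partitions for error estimation.

#' Define a hydration site
#'
#' A hydration site is a localized region where solvent density clusters,
#' here a sphere around a reference position (typically a crystallographic
#' water oxygen).
#'
#' @param site_id character identifier; lexicographic order breaks
#'   assignment ties.
#' @param center 3-vector, Angstrom.
#' @param radius capture radius, Angstrom (> 0). The default 1.2 Angstrom
#'   is roughly half a hydrogen-bond length; buried cavity waters stay well
#'   inside it.
#' @param source_label free-text provenance (e.g. a PDB water residue id).
#' @return An object of class \code{hydration_site}.
#' @export
hydration_site <- function(site_id, center, radius = 1.2,
                           source_label = site_id) {
  stopifnot(radius > 0, length(center) == 3)
  structure(list(site_id = as.character(site_id),
                 center = as.numeric(center), radius = radius,
                 source_label = as.character(source_label)),
            class = "hydration_site")
}

#' @export
print.hydration_site <- function(x, ...) {
  cat(sprintf("hydration_site %s: center (%.2f, %.2f, %.2f), radius %.2f A\n",
              x$site_id, x$center[1], x$center[2], x$center[3], x$radius))
  invisible(x)
}

#' Time series of poses occupying one hydration site
#'
#' @param site a \code{hydration_site}.
#' @param poses a \code{pose_series} of the occupying waters (one per
#'   occupied frame).
#' @param n_frames_total total number of trajectory frames, used for the
#'   occupancy fraction.
#' @return An object of class \code{site_series} with fields \code{site},
#'   \code{poses}, \code{occupancy} and \code{n_frames_total}.
#' @export
site_series <- function(site, poses, n_frames_total) {
  stopifnot(inherits(site, "hydration_site"), inherits(poses, "pose_series"),
            nrow(poses$position) <= n_frames_total)
  occ <- nrow(poses$position) / n_frames_total
  if (occ < 0.99)
    warning(sprintf("site %s occupancy %.3f < 0.99: buried cavity sites are normally fully occupied",
                    site$site_id, occ))
  structure(list(site = site, poses = poses, occupancy = occ,
                 n_frames_total = as.integer(n_frames_total)),
            class = "site_series")
}

#' @export
print.site_series <- function(x, ...) {
  cat(sprintf("site_series %s: %d poses / %d frames (occupancy %.3f)\n",
              x$site$site_id, nrow(x$poses$position), x$n_frames_total,
              x$occupancy))
  invisible(x)
}

#' Synchronized pose pairs of two co-occupied sites
#'
#' @param site_ids character vector of the two site identifiers, in fixed
#'   order.
#' @param a,b \code{pose_series} for the two sites, with identical frame
#'   vectors (both sites occupied in every frame of the series).
#' @return An object of class \code{pair_series}.
#' @export
pair_series <- function(site_ids, a, b) {
  stopifnot(length(site_ids) == 2, inherits(a, "pose_series"),
            inherits(b, "pose_series"))
  if (!identical(a$frame, b$frame))
    stop("occupancy error: pair series requires both poses in every frame")
  structure(list(site_ids = as.character(site_ids), a = a, b = b),
            class = "pair_series")
}

#' @export
print.pair_series <- function(x, ...) {
  cat(sprintf("pair_series (%s, %s): %d co-occupied frames\n",
              x$site_ids[1], x$site_ids[2], n_poses(x)))
  invisible(x)
}

#' Assign waters to hydration sites in one frame
#'
#' Greedy nearest assignment: site-water candidate pairs with the oxygen
#' inside the site radius are taken in order of increasing distance, each
#' site capturing at most one water and each water joining at most one
#' site. Exact distance ties are broken by lexicographic site id. Unoccupied
#' sites are allowed.
#'
#' @param positions m x 3 matrix of water oxygen positions in one frame.
#' @param sites list of \code{hydration_site} objects.
#' @return named integer vector (one entry per site id) of row indices into
#'   \code{positions}, NA for unoccupied sites.
#' @export
assign_waters <- function(positions, sites) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  ids <- vapply(sites, function(s) s$site_id, character(1))
  out <- stats::setNames(rep(NA_integer_, length(sites)), ids)
  m <- nrow(positions)
  if (m == 0 || length(sites) == 0) return(out)
  cand <- do.call(rbind, lapply(seq_along(sites), function(si) {
    d <- sqrt(colSums((t(positions) - sites[[si]]$center)^2))
    ok <- which(d <= sites[[si]]$radius)
    if (!length(ok)) return(NULL)
    data.frame(site = si, water = ok, d = d[ok])
  }))
  if (is.null(cand)) return(out)
  cand <- cand[order(cand$d, ids[cand$site]), , drop = FALSE]
  taken_w <- logical(m)
  for (r in seq_len(nrow(cand))) {
    si <- cand$site[r]; wi <- cand$water[r]
    if (!is.na(out[si]) || taken_w[wi]) next
    out[si] <- wi
    taken_w[wi] <- TRUE
  }
  out
}

#' Build per-site pose series for a whole trajectory
#'
#' Runs [assign_waters()] on every frame and collects, for each site, the
#' poses of its occupying waters. Frames where a site is empty are simply
#' dropped from that site's series (the sample count of the entropy
#' estimators is the number of occupied frames).
#'
#' @param traj a \code{water_trajectory} (see [read_snapshots()]).
#' @param sites list of \code{hydration_site} objects.
#' @return named list of \code{site_series}, one per site.
#' @export
assign_trajectory <- function(traj, sites) {
  stopifnot(inherits(traj, "water_trajectory"))
  ids <- vapply(sites, function(s) s$site_id, character(1))
  acc <- lapply(ids, function(id) list(pos = NULL, quat = NULL, frame = NULL))
  names(acc) <- ids
  for (fr in traj$frames) {
    hit <- assign_waters(fr$position, sites)
    for (id in ids[!is.na(hit)]) {
      w <- hit[[id]]
      acc[[id]]$pos <- rbind(acc[[id]]$pos, fr$position[w, ])
      acc[[id]]$quat <- rbind(acc[[id]]$quat, fr$quaternion[w, ])
      acc[[id]]$frame <- c(acc[[id]]$frame, fr$frame_index)
    }
  }
  out <- lapply(seq_along(sites), function(si) {
    a <- acc[[ids[si]]]
    if (is.null(a$pos))
      stop(sprintf("site %s is never occupied", ids[si]))
    site_series(sites[[si]], pose_series(a$pos, a$quat, a$frame),
                traj$n_frames)
  })
  stats::setNames(out, ids)
}

#' Build the synchronized pair series of two sites
#'
#' Restricts both site series to the frames where both sites are occupied.
#' The pair is rejected (returns NULL) when the site centers are farther
#' apart than \code{max_center_sep}: only close pairs develop water-water
#' correlations worth the 12D estimate. Zero co-occupied frames is an
#' error.
#'
#' @param a,b \code{site_series}.
#' @param max_center_sep pair gate on the site-center separation, Angstrom.
#' @return a \code{pair_series}, or NULL when the pair is gated out.
#' @export
build_pair_series <- function(a, b, max_center_sep = 4.0) {
  stopifnot(inherits(a, "site_series"), inherits(b, "site_series"))
  sep <- .vnorm(a$site$center - b$site$center)
  if (sep > max_center_sep) return(NULL)
  common <- intersect(a$poses$frame, b$poses$frame)
  if (length(common) == 0)
    stop("occupancy error: zero co-occupied frames")
  ia <- match(common, a$poses$frame)
  ib <- match(common, b$poses$frame)
  pair_series(c(a$site$site_id, b$site$site_id),
              pose_series(a$poses$position[ia, , drop = FALSE],
                          a$poses$quaternion[ia, , drop = FALSE], common),
              pose_series(b$poses$position[ib, , drop = FALSE],
                          b$poses$quaternion[ib, , drop = FALSE], common))
}

#' Partition frames into disjoint random blocks
#'
#' Every analysis quantity is recomputed on each block to give a mean and a
#' between-block standard deviation. Blocks are disjoint random draws
#' (without replacement) so the SD is a clean between-block estimate; a
#' bootstrap mode (blocks drawn with replacement, possibly overlapping) is
#' available behind a flag.
#'
#' @param n_frames total number of frames.
#' @param n_blocks number of blocks.
#' @param block_size frames per block; \code{n_blocks * block_size} must
#'   not exceed \code{n_frames} (disjoint mode).
#' @param seed integer seed for reproducibility.
#' @param bootstrap draw each block independently with replacement.
#' @return list of integer vectors of 1-based frame positions.
#' @examples
#' blocks <- block_partition(10, 2, 5, seed = 1)
#' sort(unlist(blocks))  # every frame exactly once
#' @export
block_partition <- function(n_frames, n_blocks, block_size, seed = NULL,
                            bootstrap = FALSE) {
  stopifnot(n_blocks >= 1, block_size >= 1)
  if (!bootstrap && n_blocks * block_size > n_frames)
    stop(sprintf("sizing error: %d blocks x %d frames exceed the %d available",
                 n_blocks, block_size, n_frames))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (bootstrap) {
    lapply(seq_len(n_blocks), function(i)
      sample.int(n_frames, block_size, replace = TRUE))
  } else {
    idx <- sample.int(n_frames, n_blocks * block_size)
    split(idx, rep(seq_len(n_blocks), each = block_size))
  }
}

#' Restrict a series to a set of frame indices
#'
#' @param x a \code{pose_series}, \code{site_series} or \code{pair_series}.
#' @param frames frame indices (the 0-based \code{frame} labels) to keep.
#' @return the subset, of the same class.
#' @export
series_subset <- function(x, frames) {
  if (inherits(x, "site_series")) {
    keep <- x$poses$frame %in% frames
    ps <- pose_series(x$poses$position[keep, , drop = FALSE],
                      x$poses$quaternion[keep, , drop = FALSE],
                      x$poses$frame[keep])
    return(suppressWarnings(site_series(x$site, ps, length(frames))))
  }
  if (inherits(x, "pair_series")) {
    keep <- x$a$frame %in% frames
    return(pair_series(x$site_ids,
                       pose_series(x$a$position[keep, , drop = FALSE],
                                   x$a$quaternion[keep, , drop = FALSE],
                                   x$a$frame[keep]),
                       pose_series(x$b$position[keep, , drop = FALSE],
                                   x$b$quaternion[keep, , drop = FALSE],
                                   x$b$frame[keep])))
  }
  keep <- x$frame %in% frames
  pose_series(x$position[keep, , drop = FALSE],
              x$quaternion[keep, , drop = FALSE], x$frame[keep])
}
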