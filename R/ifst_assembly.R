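# Assembly of the per-site thermodynamic ledger
#
#   dG_IFST = dE_IFST - T dS_IFST
#   dS_IFST = S_sw + S_ww - n S_bulk
#
# plus the nonlocal entropy correction, summary and comparison statistics,
# and the end-to-end per-site report that runs the whole pipeline with
# block error estimation.

#' Hydration entropy difference
#'
#' \deqn{\Delta S_{IFST} = S_{sw} + S_{ww} - n S_{bulk}}
#'
#' @param S_sw solute-water entropy, cal/mol/K (an
#'   \code{entropy_estimate} or a number).
#' @param S_ww water-water entropy, cal/mol/K.
#' @param n_waters number of waters in the subvolume.
#' @param bulk a [bulk_reference()].
#' @return Delta S_IFST in cal/mol/K.
#' @export
delta_S_ifst <- function(S_sw, S_ww = 0, n_waters = 1,
                         bulk = bulk_reference()) {
  as.numeric(S_sw) + as.numeric(S_ww) - n_waters * bulk$S_bulk
}

#' Hydration free energy from its components
#'
#' \deqn{\Delta G_{IFST} = \Delta E_{IFST} - T\Delta S_{IFST}}
#' supplied directly as the energy term plus the (already
#' temperature-multiplied) entropy term.
#'
#' @param dE Delta E_IFST, kcal/mol.
#' @param minus_T_dS -T Delta S_IFST, kcal/mol.
#' @return Delta G_IFST in kcal/mol.
#' @examples
#' delta_G_ifst(-18.70, 2.67)  # -16.03
#' @export
delta_G_ifst <- function(dE, minus_T_dS) dE + minus_T_dS

# cal/mol/K entropy -> -T S in kcal/mol
.minus_T <- function(S_cal, temperature) -temperature * S_cal / 1000

#' Nonlocal correction to the hydration entropy
#'
#' The total hydration entropy adds a nonlocal term to the local
#' (per-subvolume) IFST sum:
#' \deqn{\Delta S_{hydration} = \Delta S_{IFST} + R(\alpha T - 1)
#'   \approx \Delta S_{IFST} - R}
#' where alpha is the solvent thermal expansion coefficient. When
#' \code{bulk$alpha} is absent the \eqn{-R} approximation is used. Reported
#' separately from the per-site ledger because it is a property of the
#' whole solute, not of any one site.
#'
#' @param dS_ifst local entropy sum, cal/mol/K.
#' @param bulk a [bulk_reference()]; \code{alpha} optional.
#' @return corrected entropy in cal/mol/K.
#' @export
nonlocal_correction <- function(dS_ifst, bulk = bulk_reference()) {
  if (is.null(bulk$alpha))
    dS_ifst - GAS_CONSTANT_CAL
  else
    dS_ifst + GAS_CONSTANT_CAL * (bulk$alpha * bulk$temperature - 1)
}

#' Agreement statistics between two sets of binding free energies
#'
#' R-squared is the squared Pearson correlation of the two lists (the
#' coefficient of determination of the least-squares linear fit of
#' predicted on reference). The mean unsigned difference (MUD) and the mean
#' signed difference are computed as reference minus predicted.
#'
#' @param reference per-site reference free energies (e.g. from alchemical
#'   perturbation), kcal/mol.
#' @param predicted per-site predicted free energies, kcal/mol.
#' @return list with \code{r_squared}, \code{mud}, \code{mean_signed}.
#' @examples
#' comparison_stats(c(-1, 0, 2), c(-2, 1, 2))
#' @export
comparison_stats <- function(reference, predicted) {
  if (length(reference) != length(predicted))
    stop("length mismatch between reference and predicted")
  if (length(reference) < 2) stop("need at least 2 sites")
  diff <- reference - predicted
  list(r_squared = stats::cor(reference, predicted)^2,
       mud = mean(abs(diff)),
       mean_signed = mean(diff))
}

#' Column-wise summary of a per-site table
#'
#' Minimum, maximum and mean of every numeric column, at two-decimal
#' reporting precision (kcal/mol).
#'
#' @param table data frame of per-site values.
#' @param digits rounding for the report.
#' @return data frame with rows minimum, maximum, mean.
#' @export
summarize_sites <- function(table, digits = 2) {
  num <- table[vapply(table, is.numeric, logical(1))]
  if (nrow(num) == 0) stop("empty table")
  out <- rbind(minimum = vapply(num, min, numeric(1)),
               maximum = vapply(num, max, numeric(1)),
               mean = vapply(num, mean, numeric(1)))
  as.data.frame(round(out, digits))
}

#' Assemble the thermodynamic ledger of one site
#'
#' Combines the measured energy and entropy components into the full
#' per-site ledger. All downstream identities hold exactly by construction:
#' \code{dG_ifst = dE_ifst + minus_T_dS_ifst} and
#' \code{minus_T_dS_ifst = -T(S_sw + S_ww - n S_bulk)/1000}.
#'
#' @param E_sw,E_ww energies, kcal/mol.
#' @param S_sw,S_ww entropies, cal/mol/K.
#' @param n_waters waters in the subvolume (1 for a single site).
#' @param bulk a [bulk_reference()].
#' @return one-row data frame with columns E_sw, E_ww, dE_ifst,
#'   minus_T_S_sw, minus_T_S_ww, minus_T_dS_ifst, dG_ifst.
#' @export
thermo_components <- function(E_sw, E_ww = 0, S_sw, S_ww = 0, n_waters = 1,
                              bulk = bulk_reference()) {
  S_sw <- as.numeric(S_sw); S_ww <- as.numeric(S_ww)
  dE <- delta_E_ifst(E_sw, E_ww, n_waters, bulk$E_bulk)
  dS <- delta_S_ifst(S_sw, S_ww, n_waters, bulk)
  mTdS <- .minus_T(dS, bulk$temperature)
  data.frame(E_sw = E_sw, E_ww = E_ww, dE_ifst = dE,
             minus_T_S_sw = .minus_T(S_sw, bulk$temperature),
             minus_T_S_ww = .minus_T(S_ww, bulk$temperature),
             minus_T_dS_ifst = mTdS,
             dG_ifst = delta_G_ifst(dE, mTdS))
}

# analysis of one block: returns per-site component rows
.analyze_block <- function(site_list, pair_list, solute, bulk, model,
                           n_permutations, seed, k, jitter, ...) {
  ids <- names(site_list)
  mi <- list()
  for (pr in pair_list) {
    est <- pair_mutual_information(pr, n_permutations = n_permutations,
                                   seed = seed, k = k, jitter = jitter)
    mi[[paste(pr$site_ids, collapse = "|")]] <- est$value
  }
  rows <- lapply(ids, function(id) {
    ss <- site_list[[id]]
    S_sw <- solute_water_entropy(ss, rho = bulk$rho, k = k, jitter = jitter)
    E_sw <- if (is.null(solute)) 0 else
      solute_water_energy(ss, solute, model = model, ...)
    partners <- Filter(function(pr) id %in% pr$site_ids, pair_list)
    E_ww <- if (length(partners)) {
      others <- lapply(partners, function(pr) {
        other <- setdiff(pr$site_ids, id)
        site_list[[other]]$poses
      })
      water_water_energy(ss, others, model = model, ...)
    } else 0
    # half of each pair's -(I_ww + S_vol) so cavity totals are conserved
    S_ww <- if (length(partners)) {
      keys <- vapply(partners, function(pr)
        paste(pr$site_ids, collapse = "|"), character(1))
      water_water_entropy(unlist(mi[keys]), s_vol = 0) / 2
    } else 0
    cbind(site_id = id, thermo_components(E_sw, E_ww, S_sw$value, S_ww,
                                          n_waters = 1, bulk = bulk),
          I_ww = if (length(partners))
            sum(unlist(mi[vapply(partners, function(pr)
              paste(pr$site_ids, collapse = "|"), character(1))]))
          else 0,
          stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-site IFST report for a trajectory
#'
#' The end-to-end pipeline: assigns waters to hydration sites, builds
#' co-occupancy pair series for site pairs within the pair gate, estimates
#' S_sw per site and I_ww per pair, computes the interaction energies, and
#' assembles the per-site ledger. When a block scheme is given, every
#' quantity is recomputed on disjoint random frame blocks and reported as
#' mean and between-block SD.
#'
#' @param traj a \code{water_trajectory}.
#' @param sites list of \code{hydration_site} objects.
#' @param solute optional \code{nonbonded_sites} table of the fixed solute
#'   (E_sw is reported as 0 when absent).
#' @param bulk a [bulk_reference()].
#' @param n_blocks,block_size optional block scheme for mean +- SD.
#' @param pair_gate maximum site-center separation for water-water pairs,
#'   Angstrom.
#' @param model water model for energetics.
#' @param n_permutations fill permutations per mutual-information estimate.
#' @param seed seed controlling blocks and permutations.
#' @param k neighbour order of the entropy estimators.
#' @param jitter see [solute_water_entropy()].
#' @param ... passed to the energy routines (scheme, box, ...).
#' @return list with \code{per_site} (data frame; mean and sd columns when
#'   blocked), \code{pairs} (pair metadata), and the \code{bulk} constants
#'   used.
#' @export
ifst_site_report <- function(traj, sites, solute = NULL,
                             bulk = bulk_reference(),
                             n_blocks = NULL, block_size = NULL,
                             pair_gate = 4.0, model = tip4p2005(),
                             n_permutations = 8, seed = 1, k = 1,
                             jitter = FALSE, ...) {
  site_list <- assign_trajectory(traj, sites)
  ids <- names(site_list)
  pair_list <- list()
  if (length(ids) > 1) {
    cmb <- utils::combn(ids, 2)
    for (j in seq_len(ncol(cmb))) {
      pr <- build_pair_series(site_list[[cmb[1, j]]], site_list[[cmb[2, j]]],
                              max_center_sep = pair_gate)
      if (!is.null(pr)) pair_list[[length(pair_list) + 1]] <- pr
    }
  }
  if (is.null(n_blocks)) {
    per_site <- .analyze_block(site_list, pair_list, solute, bulk, model,
                               n_permutations, seed, k, jitter, ...)
  } else {
    stopifnot(!is.null(block_size))
    frames <- sort(unique(unlist(lapply(traj$frames,
                                        function(f) f$frame_index))))
    blocks <- block_partition(length(frames), n_blocks, block_size,
                              seed = seed)
    rows <- lapply(seq_along(blocks), function(bi) {
      fsub <- frames[blocks[[bi]]]
      sl <- lapply(site_list, series_subset, frames = fsub)
      pl <- lapply(pair_list, series_subset, frames = fsub)
      cbind(block = bi,
            .analyze_block(sl, pl, solute, bulk, model, n_permutations,
                           seed + bi, k, jitter, ...))
    })
    all <- do.call(rbind, rows)
    num <- setdiff(names(all), c("block", "site_id"))
    agg_m <- stats::aggregate(all[num], by = list(site_id = all$site_id), mean)
    agg_s <- stats::aggregate(all[num], by = list(site_id = all$site_id),
                              stats::sd)
    names(agg_m)[-1] <- paste0(num, "_mean")
    names(agg_s)[-1] <- paste0(num, "_sd")
    per_site <- merge(agg_m, agg_s, by = "site_id")
  }
  pairs_df <- if (length(pair_list)) {
    data.frame(site_a = vapply(pair_list, function(p) p$site_ids[1],
                               character(1)),
               site_b = vapply(pair_list, function(p) p$site_ids[2],
                               character(1)),
               n_frames = vapply(pair_list, n_poses, integer(1)))
  } else data.frame(site_a = character(0), site_b = character(0),
                    n_frames = integer(0))
  list(per_site = per_site, pairs = pairs_df, bulk = bulk)
}
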