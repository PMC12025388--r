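#' Baseline-relative conformer energies
#'
#' Energy of every member minus the energy of the ensemble baseline (the
#' geometry used as conformer-search input), in kJ/mol. Negative values
#' mean the conformer search plus re-optimization found structures more
#' stable than its input.
#'
#' @param ensemble a `conformer_ensemble` whose baseline carries an
#'   energy.
#' @return numeric vector of delta-E values in kJ/mol, one per member.
#' @export
relative_energies <- function(ensemble) {
  if (is.null(ensemble$baseline) || is.null(ensemble$baseline[["energy"]])) {
    stop("ensemble baseline energy is missing", call. = FALSE)
  }
  e <- ensemble_energies(ensemble, "kJ/mol")
  e - structure_energy(ensemble$baseline, "kJ/mol")
}

#' Energy-window ensemble filter
#'
#' Retains members within `window` of the lowest-energy member, the
#' selection conformer-search tools apply to their raw ensembles. The
#' minimum is recomputed over the input members.
#'
#' @param ensemble a `conformer_ensemble` with member energies.
#' @param window window width, default 6 kcal/mol.
#' @param unit unit of `window` (default `"kcal/mol"`).
#' @return the filtered `conformer_ensemble`.
#' @export
energy_window_filter <- function(ensemble, window = 6, unit = "kcal/mol") {
  stopifnot(is.numeric(window), length(window) == 1L, window >= 0)
  e <- ensemble_energies(ensemble, "kJ/mol")
  keep <- (e - min(e)) <= convert_energy(window, unit, "kJ/mol") + 1e-12
  replace_members(ensemble, ensemble$members[keep])
}

#' Deduplicate conformers that converged to the same minimum
#'
#' Re-optimization of sampled conformers frequently collapses several of
#' them onto one minimum; this merges such duplicates. Members are
#' visited in ascending energy order (ties by index) and joined to the
#' first existing representative within both tolerances: heavy-atom
#' minimal RMSD at most `rmsd_tol` and energy difference at most
#' `energy_tol`. Representatives are their cluster's energy minima, and
#' the output is sorted by energy. Greedy ascending-energy clustering is
#' deterministic and costs O(n representatives) RMSD evaluations per
#' member.
#'
#' @param ensemble an energy-annotated `conformer_ensemble`.
#' @param rmsd_tol RMSD tolerance in angstrom (default 0.25, heavy atoms).
#' @param energy_tol energy tolerance in kJ/mol (default 1.0).
#' @param exclude_hydrogens drop H atoms in the RMSD (default `TRUE`).
#' @return the distinct-member `conformer_ensemble`, sorted by energy,
#'   with attribute `cluster` giving each input member's cluster id (in
#'   input order).
#' @export
deduplicate <- function(ensemble, rmsd_tol = 0.25, energy_tol = 1.0,
                        exclude_hydrogens = TRUE) {
  if (!is.numeric(rmsd_tol) || rmsd_tol <= 0 ||
      !is.numeric(energy_tol) || energy_tol <= 0) {
    stop("tolerances must be positive", call. = FALSE)
  }
  e <- ensemble_energies(ensemble, "kJ/mol")
  ord <- order(e, seq_along(e))
  reps <- integer(0)            # member indices of representatives
  cluster <- integer(length(e)) # cluster id per input member
  for (i in ord) {
    joined <- FALSE
    for (k in seq_along(reps)) {
      r <- reps[k]
      if (abs(e[i] - e[r]) > energy_tol) next
      d <- minimal_rmsd(ensemble$members[[r]], ensemble$members[[i]],
                        exclude_hydrogens = exclude_hydrogens)$rmsd
      if (d <= rmsd_tol) {
        cluster[i] <- k
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, i)        # ascending-energy visit: rep is cluster minimum
      cluster[i] <- length(reps)
    }
  }
  out <- replace_members(ensemble, ensemble$members[reps])
  attr(out, "cluster") <- cluster
  attr(out, "representatives") <- reps
  out
}

#' Apply chirality and coordination-mode retention filters
#'
#' Removes members whose ligand axial chirality flipped during sampling
#' (see [check_chirality()]) and, for substrate-bound complexes, members
#' whose substrate rotated into a different coordination mode than the
#' template's (see [classify_coordination()]). Members for which the
#' coordination classifier is ambiguous are flagged, not silently
#' removed.
#'
#' @param ensemble a `conformer_ensemble`.
#' @param template a `complex_template` carrying `chiral_reference`.
#' @param spec a `fragment_spec`.
#' @param anchor_indices coordination anchors (see
#'   [classify_coordination()]); required for substrate-bound complexes.
#' @param expected_sign expected sign of the chiral-reference dihedral.
#' @param major_y_positive convention flag passed to the classifier.
#' @return list with `ensemble` (retained members), `log` (data.frame
#'   with columns `member`, `reason` for every removal) and `flagged`
#'   (member indices with ambiguous classification, retained).
#' @export
apply_retention_filters <- function(ensemble, template, spec,
                                    anchor_indices = NULL,
                                    expected_sign = 1,
                                    major_y_positive = TRUE) {
  if (!length(template$chiral_reference)) {
    stop("template carries no chiral_reference", call. = FALSE)
  }
  check_mode <- template$substrate_kind == "S"
  if (check_mode && is.null(anchor_indices)) {
    stop("anchor_indices required for substrate-bound complexes",
         call. = FALSE)
  }
  removed <- data.frame(member = integer(0), reason = character(0))
  flagged <- integer(0)
  keep <- logical(length(ensemble))
  for (i in seq_along(ensemble$members)) {
    m <- ensemble$members[[i]]
    if (!check_chirality(m, template$chiral_reference, expected_sign)) {
      removed <- rbind(removed,
                       data.frame(member = i, reason = "chirality"))
      next
    }
    if (check_mode) {
      mode <- tryCatch(
        classify_coordination(m, spec, anchor_indices,
                              major_y_positive = major_y_positive),
        error = function(e) NA_character_)
      if (is.na(mode)) {
        flagged <- c(flagged, i)
      } else if (mode != template$coordination_mode) {
        removed <- rbind(removed,
                         data.frame(member = i, reason = "coordination"))
        next
      }
    }
    keep[i] <- TRUE
  }
  list(ensemble = replace_members(ensemble, ensemble$members[keep]),
       log = removed, flagged = flagged)
}

#' Summarize an ensemble's counts, energies and flexibility
#'
#' @param crest_ensemble the raw conformer-search ensemble.
#' @param dft_ensemble the re-optimized (and typically deduplicated)
#'   ensemble; defaults to `crest_ensemble`.
#' @param spec optional `fragment_spec`; when given, heavy-atom RMSD
#'   ranges per fragment are included (from [rmsd_profile()]).
#' @param n_removed_chirality,n_removed_coordination removal counts from
#'   [apply_retention_filters()].
#' @return a one-row `data.frame`: identifiers, `n_crest`,
#'   `n_distinct_dft`, `delta_E_min`/`delta_E_max` (kJ/mol, baseline
#'   relative; `NA` without a baseline energy), RMSD ranges, removal
#'   counts.
#' @export
ensemble_summary <- function(crest_ensemble, dft_ensemble = crest_ensemble,
                             spec = NULL, n_removed_chirality = 0L,
                             n_removed_coordination = 0L) {
  n_crest <- length(crest_ensemble)
  n_dft <- length(dft_ensemble)
  if (n_dft > n_crest) {
    stop("distinct re-optimized conformers cannot exceed the search count",
         call. = FALSE)
  }
  de <- tryCatch(relative_energies(dft_ensemble), error = function(e) NULL)
  out <- data.frame(
    ligand_id = dft_ensemble$ligand_id,
    substrate_kind = dft_ensemble$substrate_kind,
    coordination_mode = dft_ensemble$coordination_mode,
    n_crest = n_crest,
    n_distinct_dft = n_dft,
    delta_E_min = if (is.null(de)) NA_real_ else min(de),
    delta_E_max = if (is.null(de)) NA_real_ else max(de),
    rmsd_whole_max = NA_real_,
    rmsd_ligand_max = NA_real_,
    rmsd_substrate_max = NA_real_,
    n_removed_chirality = as.integer(n_removed_chirality),
    n_removed_coordination = as.integer(n_removed_coordination)
  )
  if (!is.null(spec)) {
    prof <- rmsd_profile(dft_ensemble, spec)
    out$rmsd_whole_max <- max(prof$rmsd_whole)
    out$rmsd_ligand_max <- max(prof$rmsd_ligand)
    out$rmsd_substrate_max <- max(prof$rmsd_substrate)
  }
  out
}
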