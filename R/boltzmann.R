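#' Boltzmann weights of conformers
#'
#' Raw weight of conformer i is `w_i = exp(-(E_i - E_min) / (k_b T))`,
#' with `E_min` the lowest energy within the conformer's group, so the
#' minimum-energy member has raw weight 1. Normalized weights sum to 1
#' within each group. Energies are converted to kJ/mol and the molar gas
#' constant plays the role of the Boltzmann constant, which is exactly
#' the per-molecule form expressed per mole.
#'
#' @param energies numeric vector of conformer energies.
#' @param unit unit of `energies` (default `"hartree"`).
#' @param temperature temperature in kelvin. The default, 289 K, is the
#'   value used for this descriptor workflow; override with
#'   `temperature = 298.15` for standard conditions.
#' @param groups optional factor/vector assigning members to groups;
#'   `E_min` and normalization are taken within each group. Default: one
#'   group.
#' @return `data.frame` with columns `group`, `w` (raw weight) and
#'   `w_hat` (normalized weight; sums to 1 per group).
#' @export
boltzmann_weights <- function(energies, unit = "hartree",
                              temperature = 289, groups = NULL) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            temperature > 0)
  if (!length(energies)) stop("empty group: no energies", call. = FALSE)
  e_kj <- convert_energy(energies, unit, "kJ/mol")
  if (is.null(groups)) groups <- rep("all", length(e_kj))
  if (length(groups) != length(e_kj)) {
    stop("groups and energies lengths differ", call. = FALSE)
  }
  kbt <- R_KJ_PER_MOL_K * temperature
  w <- numeric(length(e_kj))
  w_hat <- numeric(length(e_kj))
  for (g in unique(groups)) {
    sel <- which(groups == g)
    wg <- exp(-(e_kj[sel] - min(e_kj[sel])) / kbt)
    w[sel] <- wg
    w_hat[sel] <- wg / sum(wg)
  }
  data.frame(group = as.character(groups), w = w, w_hat = w_hat)
}

#' Weighted mean and standard deviation
#'
#' Population-form weighted statistics: `mean = sum(w v)`,
#' `sd = sqrt(sum(w (v - mean)^2))`, with `w` normalized weights.
#'
#' @param values numeric vector of per-member descriptor values.
#' @param w_hat normalized weights, same length, summing to 1 within
#'   1e-10.
#' @return list with `mean`, `sd` and `ess` (Kish effective sample size,
#'   `1 / sum(w^2)`).
#' @export
weighted_stats <- function(values, w_hat) {
  if (length(values) != length(w_hat)) {
    stop("values and weights lengths differ", call. = FALSE)
  }
  if (abs(sum(w_hat) - 1) > 1e-10) {
    stop("weights must sum to 1", call. = FALSE)
  }
  m <- sum(w_hat * values)
  v <- sum(w_hat * (values - m)^2)
  list(mean = m, sd = sqrt(max(v, 0)), ess = 1 / sum(w_hat^2))
}

#' Group-wise Boltzmann summary of a descriptor table
#'
#' Pools the two substrate-bound "major" conformer sets into one major
#' group and the two "minor" sets into one minor group (precatalyst
#' ensembles form their own group), computes Boltzmann weights within
#' each group, and reports the weighted mean, weighted standard
#' deviation and effective sample size of every descriptor column.
#'
#' @param descriptors `data.frame` from [descriptor_table()] (or any
#'   table with a `member` column plus numeric descriptor columns).
#' @param energies per-member energies aligned with `descriptors`.
#' @param groups per-member group labels (e.g. `"S-major"`, `"S-minor"`,
#'   `"NBD"`); every member must have one.
#' @param unit energy unit.
#' @param temperature kelvin (default 289).
#' @return `data.frame` with one row per group x descriptor: `group`,
#'   `descriptor`, `mean`, `sd`, `n`, `ess`.
#' @export
group_summary <- function(descriptors, energies, groups,
                          unit = "hartree", temperature = 289) {
  stopifnot(nrow(descriptors) == length(energies))
  if (length(groups) != length(energies) || anyNA(groups)) {
    stop("every member needs a group label", call. = FALSE)
  }
  wtab <- boltzmann_weights(energies, unit = unit,
                            temperature = temperature, groups = groups)
  cols <- setdiff(names(descriptors), "member")
  cols <- cols[vapply(descriptors[cols], is.numeric, logical(1))]
  rows <- list()
  for (g in unique(as.character(groups))) {
    sel <- which(groups == g)
    for (col in cols) {
      st <- weighted_stats(descriptors[[col]][sel], wtab$w_hat[sel])
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, descriptor = col, mean = st$mean, sd = st$sd,
        n = length(sel), ess = st$ess)
    }
  }
  do.call(rbind, rows)
}

#' Pool coordination modes into Boltzmann groups
#'
#' Maps per-member coordination modes to the three-group layout used for
#' descriptor averaging: `major1`/`major2` to `"S-major"`,
#' `minor1`/`minor2` to `"S-minor"`, `nbd` to `"NBD"`.
#' @param modes character vector of coordination modes.
#' @return character vector of group labels.
#' @export
pool_modes <- function(modes) {
  out <- rep(NA_character_, length(modes))
  out[modes %in% c("major1", "major2")] <- "S-major"
  out[modes %in% c("minor1", "minor2")] <- "S-minor"
  out[modes == "nbd"] <- "NBD"
  if (anyNA(out)) {
    stop("unknown coordination mode(s): ",
         paste(unique(modes[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}
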