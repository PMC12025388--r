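#' Read a multi-frame XYZ conformer ensemble
#'
#' Parses concatenated XYZ frames (the format written by conformer-search
#' tools such as CREST for `crest_conformers.xyz`). In the `"crest"`
#' dialect the first whitespace-separated token of each frame's comment
#' line is interpreted as the frame energy in hartree; the `"plain"`
#' dialect leaves energies unset.
#'
#' @param path path to a concatenated-XYZ file.
#' @param dialect `"crest"` (comment line carries hartree energy) or
#'   `"plain"`.
#' @param ligand_id,substrate_kind,coordination_mode,stage ensemble
#'   provenance, stored on the returned object.
#' @param baseline optional baseline `structure3d` (the conformer-search
#'   input geometry).
#' @return a [conformer_ensemble()] with frames in file order; atom-order
#'   consistency across frames is validated.
#' @export
read_ensemble_xyz <- function(path, dialect = c("crest", "plain"),
                              ligand_id = "L?", substrate_kind = "S",
                              coordination_mode = "major1",
                              stage = "dft", baseline = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  members <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) {
      stop(sprintf("malformed atom count line at frame %d of %s: %s",
                   frame, path, dQuote(lines[i])), call. = FALSE)
    }
    if (i + 1L + nat > length(lines)) {
      stop(sprintf("truncated frame %d in %s", frame, path), call. = FALSE)
    }
    comment <- lines[i + 1L]
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(atom_lines), "\\s+")
    nf <- lengths(toks)
    if (any(nf < 4L)) {
      stop(sprintf("malformed atom line in frame %d of %s", frame, path),
           call. = FALSE)
    }
    elements <- vapply(toks, `[[`, character(1), 1L)
    coords <- matrix(NA_real_, nat, 3L)
    for (k in 1:3) {
      coords[, k] <- suppressWarnings(
        as.numeric(vapply(toks, `[[`, character(1), k + 1L)))
    }
    if (anyNA(coords)) {
      stop(sprintf("non-numeric coordinate in frame %d of %s", frame, path),
           call. = FALSE)
    }
    energy <- NULL
    if (dialect == "crest") {
      tok1 <- strsplit(trimws(comment), "\\s+")[[1L]][1L]
      energy <- suppressWarnings(as.numeric(tok1))
      if (is.na(energy)) {
        stop(sprintf(
          "crest dialect: comment line of frame %d in %s does not start with an energy: %s",
          frame, path, dQuote(comment)), call. = FALSE)
      }
    }
    members[[frame]] <- structure3d(elements, coords, energy = energy,
                                    energy_unit = "hartree",
                                    label = trimws(comment))
    i <- i + 2L + nat
  }
  if (!length(members)) stop("no frames found in ", path, call. = FALSE)
  conformer_ensemble(members, ligand_id = ligand_id,
                     substrate_kind = substrate_kind,
                     coordination_mode = coordination_mode,
                     baseline = baseline, stage = stage)
}

#' Read a single-structure XYZ file
#'
#' @inheritParams read_ensemble_xyz
#' @return a `structure3d` (the first frame of the file).
#' @export
read_xyz <- function(path, dialect = c("plain", "crest")) {
  dialect <- match.arg(dialect)
  ens <- read_ensemble_xyz(path, dialect = dialect)
  ens$members[[1L]]
}

#' Write structures as (multi-frame) XYZ
#'
#' Coordinates are written with 10 decimal places so a read/write round
#' trip preserves them well below 1e-6 angstrom. For structures carrying
#' an energy, the comment line is the energy in hartree (CREST
#' convention); otherwise the structure label.
#'
#' @param x a `structure3d`, a list of them, or a `conformer_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  if (inherits(x, "conformer_ensemble")) x <- x$members
  if (inherits(x, "structure3d")) x <- list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in x) {
    comment <- if (!is.null(s$energy)) {
      sprintf("%.10f", structure_energy(s, "hartree"))
    } else s$label
    writeLines(c(as.character(n_atoms(s)), comment), con)
    writeLines(sprintf("%-3s %16.10f %16.10f %16.10f",
                       s$elements, s$coords[, 1], s$coords[, 2],
                       s$coords[, 3]), con)
  }
  invisible(path)
}

#' Count XYZ frames by an independent line scan
#'
#' Walks the file using only atom-count header arithmetic; used to verify
#' that the full parser returns one member per frame.
#' @param path path to a concatenated-XYZ file.
#' @return integer frame count.
#' @export
count_xyz_frames <- function(path) {
  lines <- readLines(path)
  i <- 1L
  n <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("not an atom count at line ", i, call. = FALSE)
    n <- n + 1L
    i <- i + 2L + nat
  }
  n
}

# Required property-table columns. Per-atom charge columns are named
# q_<index> (1-based atom index) and are required at least for the metal
# and donor atoms referenced by a fragment spec.
PROPERTY_COLUMNS <- c("member", "energy_hartree", "homo_hartree",
                      "lumo_hartree")

#' Ingest a per-conformer property table
#'
#' Reads a delimited text table (header row, whitespace- or
#' tab-separated) with one row per ensemble member, index-aligned with
#' the ensemble. Required columns: `member` (1-based member index),
#' `energy_hartree`, `homo_hartree`, `lumo_hartree`; per-atom natural
#' population charges in columns `q_<atom index>` (au). This fixed schema
#' decouples the pipeline from quantum-chemistry log dialects, which are
#' parsed upstream.
#'
#' @param path path to the table, or a `data.frame` already in memory.
#' @param ensemble the `conformer_ensemble` the table describes.
#' @return a `data.frame` of class `property_table`, row order matching
#'   member order.
#' @export
ingest_property_table <- function(path, ensemble) {
  tab <- if (is.data.frame(path)) {
    path
  } else {
    utils::read.table(path, header = TRUE, check.names = FALSE)
  }
  missing_cols <- setdiff(PROPERTY_COLUMNS, names(tab))
  if (length(missing_cols)) {
    stop("property table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) != length(ensemble)) {
    stop(sprintf(
      "property table alignment error: %d rows for %d ensemble members",
      nrow(tab), length(ensemble)), call. = FALSE)
  }
  tab <- tab[order(tab$member), , drop = FALSE]
  if (!identical(as.integer(tab$member), seq_len(length(ensemble)))) {
    stop("property table alignment error: member column must enumerate 1..n",
         call. = FALSE)
  }
  if (any(tab$lumo_hartree <= tab$homo_hartree)) {
    stop("property table invariant violated: LUMO energy must exceed HOMO ",
         "energy in every row", call. = FALSE)
  }
  rownames(tab) <- NULL
  class(tab) <- c("property_table", "data.frame")
  tab
}

#' Write a property table as delimited text
#' @param tab a `property_table` (or compatible data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_property_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
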