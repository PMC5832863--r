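## Interchange formats: headered TSV for tabular data, standard PDB
## (via bio3d) for coordinates.  Readers validate column inventories and
## report malformed or duplicated rows with line numbers; writers emit
## exactly what the readers accept, so synthetic fixtures and real data
## are interchangeable.

readTsvChecked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  df
}

#' Read a per-residue relaxation intensity table
#'
#' TSV with header columns \code{residue_id}, \code{residue_name},
#' \code{delay_s}, \code{intensity}, \code{noise_sd}; one row per
#' (residue, delay).  Duplicate (residue, delay) pairs are rejected with
#' the offending line numbers.
#'
#' @param path TSV file path.
#' @return Named list of \linkS4class{RelaxationSeries}, one per residue,
#'   names are residue ids.
#' @export
readIntensityTable <- function(path) {
  req <- c("residue_id", "residue_name", "delay_s", "intensity",
           "noise_sd")
  df <- readTsvChecked(path, req)
  key <- paste(df$residue_id, df$delay_s)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicated (residue, delay) rows in ", path,
         " at data lines ", paste(d + 1, collapse = ", "))
  }
  if (any(!is.finite(df$intensity)) || any(!is.finite(df$delay_s)))
    stop("non-numeric intensity/delay values in ", path, " at data lines ",
         paste(which(!is.finite(df$intensity) |
                     !is.finite(df$delay_s)) + 1, collapse = ", "))
  out <- lapply(split(df, df$residue_id), function(g) {
    RelaxationSeries(g$residue_id[1], g$delay_s, g$intensity,
                     noiseSd = g$noise_sd[1],
                     residueName = g$residue_name[1])
  })
  out[order(as.integer(names(out)))]
}

#' Write a relaxation intensity table
#'
#' @param series list of \linkS4class{RelaxationSeries}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeIntensityTable <- function(series, path) {
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(residue_id = s@residueId, residue_name = s@residueName,
               delay_s = s@delays, intensity = s@intensities,
               noise_sd = s@noiseSd)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a saturated/reference intensity table for heteronuclear NOE
#'
#' TSV with columns \code{residue_id}, \code{residue_name}, \code{i_sat},
#' \code{i_ref}, \code{noise_sd}.
#'
#' @param path TSV file path.
#' @return data.frame with those columns.
#' @export
readNoeTable <- function(path) {
  readTsvChecked(path, c("residue_id", "residue_name", "i_sat", "i_ref",
                         "noise_sd"))
}

#' Read an RDC table
#'
#' TSV with columns \code{residue_id}, \code{atom1}, \code{atom2},
#' \code{d_obs_hz}, \code{d_err_hz}.
#'
#' @param path TSV file path.
#' @return data.frame with those columns.
#' @export
readRdcTable <- function(path) {
  df <- readTsvChecked(path, c("residue_id", "atom1", "atom2",
                               "d_obs_hz", "d_err_hz"))
  if (any(df$d_err_hz < 0)) stop("d_err_hz must be non-negative")
  df
}

#' Write an RDC table
#'
#' @param rdc data.frame in the format of \code{\link{readRdcTable}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeRdcTable <- function(rdc, path) {
  utils::write.table(rdc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an ITC heats table
#'
#' TSV with columns \code{injection_index}, \code{heat_ucal}.
#'
#' @param path TSV file path.
#' @return Numeric vector of heats (ucal), ordered by injection index.
#' @export
readHeatsTable <- function(path) {
  df <- readTsvChecked(path, c("injection_index", "heat_ucal"))
  df$heat_ucal[order(df$injection_index)]
}

#' Write an ITC heats table
#'
#' @param heats numeric vector of per-injection heats (ucal).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeHeatsTable <- function(heats, path) {
  utils::write.table(
    data.frame(injection_index = seq_along(heats), heat_ucal = heats),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a (multi-model) PDB file as a StructureEnsemble
#'
#' Parses MODEL/ENDMDL records via bio3d; all models must share one atom
#' inventory.
#'
#' @param path PDB file path.
#' @return A \linkS4class{StructureEnsemble}.
#' @export
readPdbEnsemble <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("PDB parse error in ", path, ": ",
                         conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("PDB parse error in ", path, ": no ATOM records found")
  atoms <- data.frame(residueId = at$resno, residueName = at$resid,
                      atomName = at$elety, stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nAtoms <- nrow(atoms)
  if (ncol(xyz) != 3 * nAtoms)
    stop("atom-inventory mismatch between models in ", path,
         ": coordinate count is not a multiple of the atom count")
  nm <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nAtoms, 3, nm))
  for (m in seq_len(nm))
    coords[, , m] <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
  if (anyNA(coords))
    stop("missing coordinates (atom-inventory mismatch between models) ",
         "in ", path)
  StructureEnsemble(atoms, coords)
}

#' Write a StructureEnsemble as a multi-model PDB file
#'
#' @param ens a \linkS4class{StructureEnsemble}.
#' @param path output PDB path.
#' @return \code{path}, invisibly.
#' @export
writePdbEnsemble <- function(ens, path) {
  stopifnot(is(ens, "StructureEnsemble"))
  validObject(ens)
  nAtoms <- nrow(ens@atoms)
  xyz <- t(vapply(seq_len(nModels(ens)), function(m)
    as.vector(t(ens@coords[, , m])), numeric(3 * nAtoms)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = ens@atoms$residueId,
                   resid = ens@atoms$residueName,
                   elety = ens@atoms$atomName,
                   eleno = seq_len(nAtoms))
  invisible(path)
}
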