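## Ensemble superposition and precision: Kabsch least-squares fitting,
## iterative mean-structure precision, per-residue RMSD profiles and
## restraint accounting.

#' Least-squares (Kabsch) superposition of two coordinate sets
#'
#' Finds the proper rotation (det = +1; reflections excluded) and
#' translation minimizing the RMSD of the mobile coordinates onto the
#' reference over a selection, via SVD of the cross-covariance matrix.
#'
#' @param reference n x 3 coordinate matrix (Angstrom), or a
#'   \linkS4class{StructureEnsemble} (its first model is used).
#' @param mobile coordinates to superpose, same conventions.
#' @param sel optional \linkS4class{Selection} restricting the atoms used
#'   to compute the fit (requires ensemble inputs, or \code{atoms}).
#' @param atoms optional atom table (as in
#'   \linkS4class{StructureEnsemble}) describing the coordinate rows when
#'   matrices are supplied together with \code{sel}.
#' @return List with \code{rotation} (3 x 3), \code{translation}
#'   (length 3), \code{rmsd} (Angstrom, over the fitted atoms) and
#'   \code{transform}, a function mapping n x 3 coordinates through the
#'   fitted motion.
#' @examples
#' ref <- matrix(rnorm(30), ncol = 3)
#' kabschSuperpose(ref, ref)$rmsd  # 0
#' @export
kabschSuperpose <- function(reference, mobile, sel = NULL, atoms = NULL) {
  if (is(reference, "StructureEnsemble")) {
    atoms <- reference@atoms
    reference <- modelCoords(reference, 1)
  }
  if (is(mobile, "StructureEnsemble")) mobile <- modelCoords(mobile, 1)
  stopifnot(ncol(reference) == 3, all(dim(reference) == dim(mobile)))
  idx <- if (!is.null(sel)) {
    if (is.null(atoms))
      stop("a Selection requires an atom table or ensemble input")
    which(selectionIndex(atoms, sel))
  } else seq_len(nrow(reference))
  P <- mobile[idx, , drop = FALSE]
  Q <- reference[idx, , drop = FALSE]
  if (nrow(P) < 3) stop("need at least 3 atoms to superpose")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d, 1e-300))
    stop("degenerate (collinear) atom selection")
  dsign <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  transform <- function(x) sweep(sweep(x, 2, cp) %*% t(R), 2, cq, "+")
  list(rotation = R, translation = cq - drop(R %*% cp), rmsd = rmsd,
       transform = transform)
}

#' Coordinate precision of a structure ensemble
#'
#' Iteratively superposes all models onto their mean coordinates over the
#' selection (re-deriving the mean after each pass until it shifts by
#' less than \code{tol} Angstrom), then reports the mean and standard
#' deviation of the per-model RMSD to the converged mean structure.
#'
#' An alternative convention, the mean of all pairwise inter-model RMSDs,
#' is available with \code{method = "pairwise"}.
#'
#' @param ens a \linkS4class{StructureEnsemble} with >= 2 models.
#' @param sel a \linkS4class{Selection}; default all atoms.
#' @param method "mean" (RMSD to mean structure, default) or "pairwise".
#' @param tol convergence threshold on the mean-coordinate shift
#'   (Angstrom).
#' @param maxIter iteration cap.
#' @return List with \code{meanRmsd}, \code{sdRmsd} (Angstrom),
#'   \code{perModel} (per-model RMSD), and \code{meanCoords} (the
#'   converged mean over all atoms, superposed frame).
#' @examples
#' ens <- simulateEnsemble(10, 20, scatterProfile = 0.3, seed = 3)
#' ensemblePrecision(ens, Selection("1-20:N,CA,C"))
#' @export
ensemblePrecision <- function(ens, sel = NULL, method = c("mean",
                              "pairwise"), tol = 1e-6, maxIter = 50) {
  method <- match.arg(method)
  stopifnot(is(ens, "StructureEnsemble"))
  validObject(ens)
  nm <- nModels(ens)
  if (nm < 2) stop("need at least 2 models")
  idx <- if (!is.null(sel)) which(selectionIndex(ens@atoms, sel))
         else seq_len(nrow(ens@atoms))
  if (length(idx) < 3) stop("selection keeps fewer than 3 atoms")

  coords <- lapply(seq_len(nm), function(m) ens@coords[, , m])
  if (method == "pairwise") {
    pr <- utils::combn(nm, 2, function(ij) {
      kabschSuperpose(coords[[ij[1]]][idx, ], coords[[ij[2]]][idx, ])$rmsd
    })
    return(list(meanRmsd = mean(pr), sdRmsd = stats::sd(pr),
                perModel = pr, meanCoords = NULL))
  }

  meanC <- coords[[1]]
  for (it in seq_len(maxIter)) {
    aligned <- lapply(coords, function(x) {
      f <- kabschSuperpose(meanC[idx, , drop = FALSE],
                           x[idx, , drop = FALSE])
      f$transform(x)
    })
    newMean <- Reduce(`+`, aligned) / nm
    shift <- sqrt(max(rowSums((newMean[idx, , drop = FALSE] -
                               meanC[idx, , drop = FALSE])^2)))
    meanC <- newMean
    coords <- aligned
    if (shift < tol) break
  }
  perModel <- vapply(coords, function(x)
    sqrt(mean(rowSums((x[idx, , drop = FALSE] -
                       meanC[idx, , drop = FALSE])^2))), numeric(1))
  list(meanRmsd = mean(perModel), sdRmsd = stats::sd(perModel),
       perModel = perModel, meanCoords = meanC, aligned = coords)
}

#' Per-residue RMSD profile of an ensemble
#'
#' After a global superposition onto the iteratively-refined mean
#' structure (over \code{fitSel}, by default backbone atoms everywhere),
#' computes for each residue the root-mean-square deviation of its
#' selected atoms from the mean structure, pooled over models.
#'
#' @param ens a \linkS4class{StructureEnsemble}.
#' @param atomNames atoms contributing to the per-residue profile;
#'   default backbone N, CA, C.
#' @param fitSel \linkS4class{Selection} used for the global fit; default
#'   the same atom names over all residues.
#' @return data.frame with columns \code{residue_id}, \code{rmsd}
#'   (Angstrom).
#' @examples
#' ens <- simulateEnsemble(10, 20,
#'   scatterProfile = c(rep(0.3, 10), rep(1.3, 10)), seed = 3)
#' prof <- perResidueRmsd(ens)
#' which.max(prof$rmsd)
#' @export
perResidueRmsd <- function(ens, atomNames = c("N", "CA", "C"),
                           fitSel = NULL) {
  stopifnot(is(ens, "StructureEnsemble"))
  ids <- sort(unique(ens@atoms$residueId))
  if (is.null(fitSel))
    fitSel <- Selection(cbind(min(ids), max(ids)), atomNames)
  prec <- ensemblePrecision(ens, fitSel)
  meanC <- prec$meanCoords
  aligned <- prec$aligned
  prof <- vapply(ids, function(id) {
    i <- which(ens@atoms$residueId == id &
               toupper(ens@atoms$atomName) %in% toupper(atomNames))
    if (!length(i)) return(NA_real_)
    sqrt(mean(vapply(aligned, function(x)
      mean(rowSums((x[i, , drop = FALSE] -
                    meanC[i, , drop = FALSE])^2)), numeric(1))))
  }, numeric(1))
  data.frame(residue_id = ids, rmsd = prof)
}

#' Restraint accounting
#'
#' Totals the restraint classes of a structure determination and the
#' per-residue density.  The per-residue count is rounded to one decimal
#' at report time only.
#'
#' @param t a \linkS4class{RestraintTable}.
#' @return Named numeric vector \code{c(total = , per_residue = )}.
#' @examples
#' tallyRestraints(RestraintTable(1504, c(phi = 71, psi = 71, chi = 19),
#'                                38, 79, 87))
#' @export
tallyRestraints <- function(t) {
  stopifnot(is(t, "RestraintTable"))
  validObject(t)
  if (t@nResidues <= 0) stop("nResidues must be positive")
  total <- t@noeCount + sum(t@dihedralCounts) + t@hbondCount + t@rdcCount
  c(total = total, per_residue = round(total / t@nResidues, 1))
}
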