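## Residual dipolar coupling analysis: bond-vector extraction from
## coordinates, linear (SVD) fitting of the alignment tensor, coupling
## back-calculation and the RDC R-factor quality statistic.

#' Extract unit bond vectors from a structure
#'
#' Computes normalized inter-atom vectors (by default N -> H) for each
#' residue of one model of an ensemble.  Residues lacking either atom are
#' skipped and reported in the \code{skipped} attribute.
#'
#' @param structure a \linkS4class{StructureEnsemble}.
#' @param pairs length-2 character vector of atom names (from, to).
#' @param model 1-based model index used when an ensemble is supplied.
#' @return A \linkS4class{BondVectorSet}; residues with missing atoms are
#'   listed in \code{attr(, "skipped")}.
#' @examples
#' ens <- simulateEnsemble(2, 10, scatterProfile = 0, seed = 1)
#' extractVectors(ens)
#' @export
extractVectors <- function(structure, pairs = c("N", "H"), model = 1L) {
  stopifnot(is(structure, "StructureEnsemble"), length(pairs) == 2)
  atoms <- structure@atoms
  xyz <- structure@coords[, , model, drop = TRUE]
  ids <- unique(atoms$residueId)
  rows <- lapply(ids, function(id) {
    i1 <- which(atoms$residueId == id &
                toupper(atoms$atomName) == toupper(pairs[1]))
    i2 <- which(atoms$residueId == id &
                toupper(atoms$atomName) == toupper(pairs[2]))
    if (length(i1) != 1 || length(i2) != 1) return(NULL)
    v <- xyz[i2, ] - xyz[i1, ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("coincident atoms for residue ", id)
    list(id = id, v = v / nv)
  })
  got <- !vapply(rows, is.null, logical(1))
  bv <- BondVectorSet(
    vapply(rows[got], function(r) r$id, numeric(1)),
    do.call(rbind, lapply(rows[got], function(r) r$v)))
  attr(bv, "skipped") <- ids[!got]
  bv
}

## design-matrix row basis: D = t(v) A v with A traceless symmetric;
## unknowns (Axx, Ayy, Axy, Axz, Ayz), Azz = -(Axx + Ayy)
rdcDesignMatrix <- function(v) {
  cbind(v[, 1]^2 - v[, 3]^2,
        v[, 2]^2 - v[, 3]^2,
        2 * v[, 1] * v[, 2],
        2 * v[, 1] * v[, 3],
        2 * v[, 2] * v[, 3])
}

tensorFromComponents <- function(s) {
  matrix(c(s[1],  s[3], s[4],
           s[3],  s[2], s[5],
           s[4],  s[5], -s[1] - s[2]), 3, 3, byrow = TRUE)
}

## principal-frame parameters with |Azz| >= |Ayy| >= |Axx| ordering;
## Da = Azz/2, Dr = (Axx - Ayy)/3, R = Dr/Da taken non-negative by
## swapping the x and y axes when needed
tensorPrincipal <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  ord <- order(abs(e$values))          # |Axx| <= |Ayy| <= |Azz|
  vals <- e$values[ord]
  vecs <- e$vectors[, ord]
  axx <- vals[1]; ayy <- vals[2]; azz <- vals[3]
  da <- azz / 2
  r <- if (azz == 0) 0 else (axx - ayy) / (3 * da)
  if (r < 0) {                         # relabel x <-> y
    tmp <- axx; axx <- ayy; ayy <- tmp
    vecs <- vecs[, c(2, 1, 3)]
    r <- -r
  }
  if (det(vecs) < 0) vecs[, 3] <- -vecs[, 3]
  ## z-y-z Euler angles of the principal axes in the molecular frame
  beta <- acos(max(-1, min(1, vecs[3, 3])))
  if (abs(sin(beta)) > 1e-12) {
    alpha <- atan2(vecs[2, 3], vecs[1, 3])
    gamma <- atan2(vecs[3, 2], -vecs[3, 1])
  } else {
    alpha <- atan2(vecs[2, 1], vecs[1, 1])
    gamma <- 0
  }
  list(da = da, rhombicity = r,
       euler = c(alpha, beta, gamma) * 180 / pi,
       values = c(axx = axx, ayy = ayy, azz = azz), axes = vecs)
}

#' Fit the alignment tensor to observed couplings by SVD
#'
#' Solves the linear least-squares problem D_i = t(v_i) A v_i for the
#' five independent components of the traceless symmetric order tensor A
#' (in coupling units), using the singular value decomposition of the
#' design matrix.  Da and the rhombicity follow from the
#' eigen-decomposition of A with |Azz| >= |Ayy| >= |Axx| ordering.
#' Parameter uncertainties are estimated by nonparametric bootstrap over
#' records.
#'
#' @param vectors a \linkS4class{BondVectorSet}.
#' @param obs observed couplings: either a numeric vector parallel to
#'   \code{vectors}, or a data.frame with columns \code{residue_id} and
#'   \code{d_obs_hz} (matched to the vector set by residue id).
#' @param nBoot bootstrap resamples for Da/R uncertainties (0 disables).
#' @param seed bootstrap seed.
#' @return An \linkS4class{AlignmentTensor}; the fitted couplings are in
#'   \code{attr(, "dCalc")} and the observed ones in
#'   \code{attr(, "dObs")}.
#' @examples
#' tens <- AlignmentTensor(7.3, 0.35, euler = c(30, 40, 50))
#' bv <- randomBondVectors(79, seed = 11)
#' fit <- svdFit(bv, simulateRdc(tens, bv))
#' Da(fit); rhombicity(fit)
#' @export
svdFit <- function(vectors, obs, nBoot = 500, seed = 1L) {
  stopifnot(is(vectors, "BondVectorSet"))
  validObject(vectors)
  d <- if (is.data.frame(obs)) {
    m <- match(vectors@residueId, obs$residue_id)
    if (anyNA(m)) stop("couplings missing for residues ",
                       paste(vectors@residueId[is.na(m)], collapse = ", "))
    obs$d_obs_hz[m]
  } else as.numeric(obs)
  v <- vectors@vectors
  if (nrow(v) < 5 || length(d) != nrow(v))
    stop("need >= 5 couplings matched to vectors")

  M <- rdcDesignMatrix(v)
  sv <- svd(M)
  if (min(sv$d) < 1e-10 * max(sv$d))
    stop("rank-deficient design matrix: bond-vector geometry is ",
         "degenerate (singular values ", paste(format(sv$d, digits = 3),
                                               collapse = ", "), ")")
  solveLs <- function(y) sv$v %*% ((t(sv$u) %*% y) / sv$d)
  A <- tensorFromComponents(drop(solveLs(d)))
  A <- (A + t(A)) / 2
  A <- A - diag(rep(sum(diag(A)) / 3, 3))

  daSd <- NA_real_; rSd <- NA_real_
  if (nBoot > 0) {
    n <- nrow(v)
    est <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      Mb <- rdcDesignMatrix(v[i, , drop = FALSE])
      sb <- tryCatch(qr.solve(Mb, d[i]), error = function(e) NULL)
      if (is.null(sb)) return(c(NA_real_, NA_real_))
      p <- tensorPrincipal(tensorFromComponents(sb))
      c(p$da, p$rhombicity)
    }, numeric(2)))
    daSd <- stats::sd(est[1, ], na.rm = TRUE)
    rSd <- stats::sd(est[2, ], na.rm = TRUE)
  }
  out <- new("AlignmentTensor", tensor = A, daSd = daSd,
             rhombicitySd = rSd)
  attr(out, "dObs") <- d
  attr(out, "dCalc") <- drop(M %*% drop(solveLs(d)))
  attr(out, "residueId") <- vectors@residueId
  out
}

#' Back-calculate couplings from an alignment tensor
#'
#' Evaluates D_i = t(v_i) A v_i in the molecular frame; equivalent to the
#' principal-frame form
#' \deqn{D = D_a\left[(3\cos^2\theta - 1) +
#'   \tfrac{3}{2} R \sin^2\theta \cos 2\phi\right]}
#' for polar angles (theta, phi) of the bond vector in the tensor
#' principal axis system.
#'
#' @param tensor an \linkS4class{AlignmentTensor}.
#' @param vectors a \linkS4class{BondVectorSet}.
#' @return Numeric vector of couplings (Hz), parallel to \code{vectors}.
#' @export
backCalculate <- function(tensor, vectors) {
  stopifnot(is(tensor, "AlignmentTensor"), is(vectors, "BondVectorSet"))
  drop(rdcDesignMatrix(vectors@vectors) %*%
       c(tensor@tensor[1, 1], tensor@tensor[2, 2], tensor@tensor[1, 2],
         tensor@tensor[1, 3], tensor@tensor[2, 3]))
}

#' RDC R-factor (%)
#'
#' Agreement statistic between observed and back-calculated couplings,
#' \deqn{R = 100 \sqrt{\overline{(D_{obs} - D_{calc})^2} /
#'   (2\,\overline{D_{obs}^2})}}
#' i.e. the rms deviation normalized by sqrt(2 mean D_obs^2).  A perfect
#' fit gives 0; uncorrelated predictions of the right magnitude give
#' about 70.7 (= 100 sqrt(1/2)) when D_calc = 0.
#'
#' @param dObs observed couplings (Hz), or a fitted
#'   \linkS4class{AlignmentTensor} from \code{\link{svdFit}} (its stored
#'   dObs/dCalc are then used).
#' @param dCalc back-calculated couplings (Hz); ignored when \code{dObs}
#'   is a fitted tensor.
#' @return R-factor in percent.
#' @examples
#' rdcRfactor(c(5, -3, 8), c(5, -3, 8))  # 0
#' @export
rdcRfactor <- function(dObs, dCalc = NULL) {
  if (is(dObs, "AlignmentTensor")) {
    dCalc <- attr(dObs, "dCalc")
    dObs <- attr(dObs, "dObs")
    if (is.null(dObs))
      stop("tensor carries no fitted couplings; pass dObs and dCalc")
  }
  if (all(dObs == 0)) stop("all observed couplings are zero")
  100 * sqrt(mean((dObs - dCalc)^2) / (2 * mean(dObs^2)))
}
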