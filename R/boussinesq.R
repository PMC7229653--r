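## Boussinesq half-space elasticity kernels.
##
## A tangential traction field T(x) applied to the surface of a linear-elastic
## half-space (Young's modulus E, Poisson ratio nu < 0.5) produces the surface
## displacement u = G * T (convolution). In Fourier space the kernel is the
## 2 x 2 tensor
##
##   G(k) = 2 (1 + nu) / (E k^3) * [ (1-nu) k^2 + nu ky^2,  -nu kx ky
##                                   -nu kx ky,  (1-nu) k^2 + nu kx^2 ]
##
## and in real space, for a point force at the origin,
##
##   G(r) = (1 + nu) / (pi E r^3) * [ (1-nu) r^2 + nu x^2,  nu x y
##                                    nu x y,  (1-nu) r^2 + nu y^2 ].
##
## The Fourier route is the production forward/inverse model; the real-space
## quadrature is an independent slow reference used for validation.

# Fourier Green's tensor on wavevector grids KX, KY (rad/um). Entries are in
# um/Pa. The k = 0 entry is set to zero: a balanced traction field has no
# zero-frequency component and the half-space solution is undefined there.
greensFourier <- function(KX, KY, substrate) {
  E <- substrate@youngModulusPa
  nu <- substrate@poissonRatio
  k2 <- KX^2 + KY^2
  k <- sqrt(k2)
  pref <- 2 * (1 + nu) / (E * k^3)
  Gxx <- pref * ((1 - nu) * k2 + nu * KY^2)
  Gyy <- pref * ((1 - nu) * k2 + nu * KX^2)
  Gxy <- -pref * nu * KX * KY
  zero <- k2 == 0
  Gxx[zero] <- 0; Gyy[zero] <- 0; Gxy[zero] <- 0
  list(Gxx = Gxx, Gxy = Gxy, Gyy = Gyy)
}

# Wavevector grids (rad/um) for an nr x nc grid with spacing h (um).
# Rows vary along y, columns along x.
waveGrids <- function(nr, nc, h) {
  kx <- 2 * pi * fftFreq(nc, h)
  ky <- 2 * pi * fftFreq(nr, h)
  list(KX = matrix(rep(kx, each = nr), nr),
       KY = matrix(rep(ky, times = nc), nr))
}

#' Forward Boussinesq displacement of a traction field (Fourier route)
#'
#' Computes the surface displacement produced by a known traction field on a
#' linear-elastic half-space by multiplying with the Boussinesq Green's tensor
#' in the frequency domain. The traction grids are zero-padded (default 4x)
#' before the FFT to suppress the periodic images inherent to the discrete
#' transform; the result is cropped back to the input grid.
#'
#' @param truth a [TractionTruth-class] (balanced traction field).
#' @param padFactor integer >= 1; zero-padding factor per dimension.
#' @return A [DisplacementField-class] on the same grid (micrometres).
#' @seealso [boussinesqDirect()] for the real-space quadrature reference,
#'   [invertFTTC()] for the inverse problem.
#' @examples
#' sub <- ElasticSubstrate(1000, 0.45)
#' tt <- tractionDipoleTruth(c(32, 32), 4, sub)
#' fld <- forwardDisplacement(tt)
#' max(abs(displacements(fld)$ux))
#' @export
forwardDisplacement <- function(truth, padFactor = 4) {
  stopifnot(is(truth, "TractionTruth"), padFactor >= 1)
  d <- dim(truth@tx)
  pr <- padFactor * d[1]; pc <- padFactor * d[2]
  padTx <- matrix(0, pr, pc); padTy <- matrix(0, pr, pc)
  padTx[seq_len(d[1]), seq_len(d[2])] <- truth@tx
  padTy[seq_len(d[1]), seq_len(d[2])] <- truth@ty
  kg <- waveGrids(pr, pc, truth@spacingUm)
  G <- greensFourier(kg$KX, kg$KY, truth@substrate)
  ftx <- stats::fft(padTx)
  fty <- stats::fft(padTy)
  fux <- G$Gxx * ftx + G$Gxy * fty
  fuy <- G$Gxy * ftx + G$Gyy * fty
  ux <- Re(stats::fft(fux, inverse = TRUE)) / (pr * pc)
  uy <- Re(stats::fft(fuy, inverse = TRUE)) / (pr * pc)
  DisplacementField(ux[seq_len(d[1]), seq_len(d[2])],
                    uy[seq_len(d[1]), seq_len(d[2])],
                    spacingUm = truth@spacingUm)
}

## Exact integrals of the Boussinesq kernel components over an axis-aligned
## rectangle relative to the probe point, from the closed-form mixed
## antiderivatives d2/dxdy F = f:
##   1/r       -> x log(y + r) + y log(x + r)
##   x^2 / r^3 -> y log(x + r)
##   y^2 / r^3 -> x log(y + r)
##   x y / r^3 -> -r
## This removes the 1/r singularity from the quadrature entirely: the kernel
## is integrated analytically per cell and only the traction is sampled.
kernelCellIntegrals <- function(x1, x2, y1, y2) {
  safeln <- function(v) log(pmax(v, 1e-300))
  fx2 <- function(x, y) {
    r <- sqrt(x^2 + y^2)
    ifelse(y == 0, 0, y * safeln(x + r))
  }
  fy2 <- function(x, y) {
    r <- sqrt(x^2 + y^2)
    ifelse(x == 0, 0, x * safeln(y + r))
  }
  term <- function(f)
    f(x2, y2) - f(x1, y2) - f(x2, y1) + f(x1, y1)
  I1 <- term(function(x, y) fx2(x, y) + fy2(x, y))
  list(I1 = I1, Ix2 = term(fx2), Iy2 = term(fy2),
       Ixy = term(function(x, y) -sqrt(x^2 + y^2)))
}

#' Forward Boussinesq displacement by direct real-space quadrature
#'
#' Independent reference for [forwardDisplacement()]: evaluates the
#' convolution of the traction field with the real-space Boussinesq point
#' response by direct summation over grid cells. The traction is taken as
#' constant over each cell and the kernel tensor is integrated analytically
#' over the cell (the mixed antiderivatives of `1/r`, `x^2/r^3`, `y^2/r^3`
#' and `xy/r^3` are closed-form), so the quadrature has no singularity error
#' and probes may sit anywhere, including on grid nodes.
#'
#' @param truth a [TractionTruth-class].
#' @param probesUm n x 2 matrix of (x, y) probe positions (micrometres).
#' @return n x 2 matrix of displacements (ux_um, uy_um) at the probes.
#' @export
boussinesqDirect <- function(truth, probesUm) {
  stopifnot(is(truth, "TractionTruth"), ncol(probesUm) == 2)
  E <- truth@substrate@youngModulusPa
  nu <- truth@substrate@poissonRatio
  h <- truth@spacingUm
  d <- dim(truth@tx)
  nodeX <- rep((seq_len(d[2]) - 1) * h, each = d[1])
  nodeY <- rep((seq_len(d[1]) - 1) * h, times = d[2])
  tx <- as.vector(truth@tx); ty <- as.vector(truth@ty)
  out <- matrix(0, nrow(probesUm), 2,
                dimnames = list(NULL, c("ux_um", "uy_um")))
  C <- (1 + nu) / (pi * E)
  for (p in seq_len(nrow(probesUm))) {
    dx <- nodeX - probesUm[p, 1]
    dy <- nodeY - probesUm[p, 2]
    ci <- kernelCellIntegrals(dx - h / 2, dx + h / 2, dy - h / 2, dy + h / 2)
    gxx <- C * ((1 - nu) * ci$I1 + nu * ci$Ix2)
    gyy <- C * ((1 - nu) * ci$I1 + nu * ci$Iy2)
    gxy <- C * nu * ci$Ixy
    out[p, 1] <- sum(gxx * tx + gxy * ty)
    out[p, 2] <- sum(gxy * tx + gyy * ty)
  }
  out
}
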