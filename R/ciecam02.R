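## CIECAM02 color appearance model, forward and inverse, vectorized over
## colors (n x 3 matrices).  Used by the fusion step: the topography strip
## takes its lightness J from the grayscale anatomy and its hue quadrature
## H and saturation s from the pseudo-color curvature band.

.MCAT02 <- matrix(c(0.7328, 0.4296, -0.1624,
                    -0.7036, 1.6975, 0.0061,
                    0.0030, 0.0136, 0.9834), 3, 3, byrow = TRUE)
.MHPE <- matrix(c(0.38971, 0.68898, -0.07868,
                  -0.22981, 1.18340, 0.04641,
                  0.00000, 0.00000, 1.00000), 3, 3, byrow = TRUE)
.MsRGB2XYZ <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                       0.2126729, 0.7151522, 0.0721750,
                       0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
## unique-hue data for the hue quadrature interpolation
.hueH <- c(20.14, 90.00, 164.25, 237.53, 380.14)
.hueE <- c(0.8, 0.7, 1.0, 1.2, 0.8)
.hueQ <- c(0, 100, 200, 300, 400)

#' CIECAM02 viewing conditions
#'
#' @param whitePoint XYZ of the adopted white (Y = 100 scale); default D65.
#' @param LA adapting field luminance in cd/m^2.
#' @param Yb relative background luminance (Y of background, white = 100).
#' @param surround `"average"`, `"dim"` or `"dark"`.
#' @param D degree of adaptation.  The default 1 discounts the illuminant
#'   completely (display-referred imagery: neutrals stay exactly
#'   achromatic); `NA` computes the CIE degree-of-adaptation formula from
#'   `LA` and the surround factor.
#' @return list of class `"ViewingConditions"` with all derived constants.
#' @export
viewingConditions <- function(whitePoint = c(95.047, 100, 108.883),
    LA = 60, Yb = 20, surround = c("average", "dim", "dark"), D = 1) {
  surround <- match.arg(surround)
  sp <- switch(surround,
    average = c(F = 1.0, c = 0.69, Nc = 1.0),
    dim     = c(F = 0.9, c = 0.59, Nc = 0.9),
    dark    = c(F = 0.8, c = 0.525, Nc = 0.8))
  Fs <- sp[["F"]]; cc <- sp[["c"]]; Nc <- sp[["Nc"]]
  if (is.na(D)) D <- Fs * (1 - (1 / 3.6) * exp(-(LA + 42) / 92))
  D <- min(max(D, 0), 1)
  k <- 1 / (5 * LA + 1)
  FL <- 0.2 * k^4 * (5 * LA) + 0.1 * (1 - k^4)^2 * (5 * LA)^(1 / 3)
  n <- Yb / whitePoint[2L]
  Nbb <- 0.725 * (1 / n)^0.2
  z <- 1.48 + sqrt(n)
  RGBw <- drop(.MCAT02 %*% whitePoint)
  Dfac <- whitePoint[2L] * D / RGBw + 1 - D
  RGBwc <- Dfac * RGBw
  RGBpw <- drop(.MHPE %*% solve(.MCAT02, RGBwc))
  RGBpaw <- camNonlin(RGBpw, FL)
  Aw <- (2 * RGBpaw[1L] + RGBpaw[2L] + RGBpaw[3L] / 20 - 0.305) * Nbb
  structure(list(whitePoint = whitePoint, LA = LA, Yb = Yb,
    surround = surround, F = Fs, c = cc, Nc = Nc, D = D, FL = FL, n = n,
    Nbb = Nbb, Ncb = Nbb, z = z, Dfac = Dfac, Aw = Aw),
    class = "ViewingConditions")
}

## post-adaptation cone compression (signed), and its inverse
camNonlin <- function(x, FL) {
  t <- (FL * abs(x) / 100)^0.42
  sign(x) * 400 * t / (t + 27.13) + 0.1
}
camNonlinInv <- function(xa, FL) {
  t <- xa - 0.1
  sign(t) * (100 / FL) * ((27.13 * abs(t)) / (400 - abs(t)))^(1 / 0.42)
}

## hue angle (deg) -> hue quadrature H in [0, 400)
hueQuadrature <- function(h) {
  hp <- ifelse(h < .hueH[1L], h + 360, h)
  i <- pmin(findInterval(hp, .hueH), 4L)
  num <- (hp - .hueH[i]) / .hueE[i]
  den <- num + (.hueH[i + 1L] - hp) / .hueE[i + 1L]
  .hueQ[i] + 100 * num / den
}

## hue quadrature H -> hue angle (deg)
hueFromQuadrature <- function(H) {
  i <- pmin(findInterval(H, .hueQ), 4L)
  dH <- H - .hueQ[i]
  h1 <- .hueH[i]; h2 <- .hueH[i + 1L]; e1 <- .hueE[i]; e2 <- .hueE[i + 1L]
  hp <- (dH * (e2 * h1 - e1 * h2) - 100 * h1 * e2) /
    (dH * (e2 - e1) - 100 * e2)
  ifelse(hp > 360, hp - 360, hp)
}

## sRGB [0,1] -> XYZ (Y in 0..100); input n x 3
srgbToXyz <- function(rgb) {
  rgb <- rbind(rgb)
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  100 * lin %*% t(.MsRGB2XYZ)
}

xyzToSrgb <- function(xyz) {
  xyz <- rbind(xyz)
  lin <- (xyz / 100) %*% t(solve(.MsRGB2XYZ))
  ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * pmax(lin, 0)^(1 / 2.4) - 0.055)
}

#' Forward CIECAM02 transform of sRGB colors
#'
#' sRGB -> linear RGB -> XYZ (D65) -> CIECAM02 under the given viewing
#' conditions.
#'
#' @param rgb n x 3 matrix (or length-3 vector) of sRGB values in \[0,1\].
#' @param vc a [viewingConditions()].
#' @return data.frame with lightness `J`, hue quadrature `H`, saturation
#'   `s`, plus hue angle `h`, chroma `C` and colorfulness `M`.
#' @export
srgbToCam <- function(rgb, vc = viewingConditions()) {
  rgb <- rbind(rgb)
  if (ncol(rgb) != 3L) stop("rgb must have 3 columns")
  camForwardXYZ(srgbToXyz(rgb), vc)
}

## forward model from XYZ (Y on the 0..100 scale)
camForwardXYZ <- function(xyz, vc = viewingConditions()) {
  xyz <- rbind(xyz)
  RGB <- xyz %*% t(.MCAT02)
  RGBc <- sweep(RGB, 2L, vc$Dfac, `*`)
  RGBp <- RGBc %*% t(solve(.MCAT02)) %*% t(.MHPE)
  RGBpa <- camNonlin(RGBp, vc$FL)
  Ra <- RGBpa[, 1L]; Ga <- RGBpa[, 2L]; Ba <- RGBpa[, 3L]
  a <- Ra - 12 * Ga / 11 + Ba / 11
  b <- (Ra + Ga - 2 * Ba) / 9
  h <- (atan2(b, a) * 180 / pi) %% 360
  et <- (cos(h * pi / 180 + 2) + 3.8) / 4
  A <- (2 * Ra + Ga + Ba / 20 - 0.305) * vc$Nbb
  J <- 100 * pmax(A / vc$Aw, 0)^(vc$c * vc$z)
  t <- (50000 / 13) * vc$Nc * vc$Ncb * et * sqrt(a^2 + b^2) /
    (Ra + Ga + 21 / 20 * Ba)
  C <- t^0.9 * sqrt(J / 100) * (1.64 - 0.29^vc$n)^0.73
  M <- C * vc$FL^0.25
  Q <- (4 / vc$c) * sqrt(J / 100) * (vc$Aw + 4) * vc$FL^0.25
  s <- ifelse(Q > 0, 100 * sqrt(M / Q), 0)
  data.frame(J = J, H = hueQuadrature(h), s = s, h = h, C = C, M = M)
}

#' Inverse CIECAM02 transform to sRGB
#'
#' Reconstructs sRGB from lightness `J`, hue quadrature `H` and saturation
#' `s` under the given viewing conditions.  Out-of-gamut results are
#' clipped per channel to \[0, 1\]; the fraction of clipped pixels is
#' attached as attribute `"clipFraction"`.
#'
#' @param J,H,s numeric vectors of equal length (CIECAM02 correlates).
#' @param vc a [viewingConditions()].
#' @return n x 3 matrix of sRGB values in \[0, 1\].
#' @export
camToSrgb <- function(J, H, s, vc = viewingConditions()) {
  n <- length(J)
  if (length(H) != n || length(s) != n) stop("J, H, s lengths differ")
  if (any(J < 0 | J > 100 + 1e-9)) stop("J must lie in [0, 100]")
  if (any(H < 0 | H >= 400)) stop("H must lie in [0, 400)")
  h <- hueFromQuadrature(H) * pi / 180
  Q <- (4 / vc$c) * sqrt(J / 100) * (vc$Aw + 4) * vc$FL^0.25
  M <- (s / 100)^2 * Q
  C <- M / vc$FL^0.25
  tt <- ifelse(J > 0,
    (C / (sqrt(J / 100) * (1.64 - 0.29^vc$n)^0.73))^(1 / 0.9), 0)
  et <- (cos(h + 2) + 3.8) / 4
  A <- vc$Aw * (J / 100)^(1 / (vc$c * vc$z))
  p2 <- A / vc$Nbb + 0.305
  a <- b <- numeric(n)
  nz <- tt > 1e-12
  if (any(nz)) {
    p1 <- (50000 / 13) * vc$Nc * vc$Ncb * et[nz] / tt[nz]
    hh <- h[nz]; p2n <- p2[nz]
    sinh <- sin(hh); cosh <- cos(hh)
    p3 <- 21 / 20
    an <- bn <- numeric(sum(nz))
    useSin <- abs(sinh) >= abs(cosh)
    if (any(useSin)) {
      p4 <- p1[useSin] / sinh[useSin]
      bn[useSin] <- p2n[useSin] * (2 + p3) * (460 / 1403) /
        (p4 + (2 + p3) * (220 / 1403) * (cosh[useSin] / sinh[useSin]) -
         (27 / 1403) + p3 * (6300 / 1403))
      an[useSin] <- bn[useSin] * cosh[useSin] / sinh[useSin]
    }
    if (any(!useSin)) {
      p5 <- p1[!useSin] / cosh[!useSin]
      an[!useSin] <- p2n[!useSin] * (2 + p3) * (460 / 1403) /
        (p5 + (2 + p3) * (220 / 1403) -
         ((27 / 1403) - p3 * (6300 / 1403)) * (sinh[!useSin] / cosh[!useSin]))
      bn[!useSin] <- an[!useSin] * sinh[!useSin] / cosh[!useSin]
    }
    a[nz] <- an; b[nz] <- bn
  }
  Ra <- (460 * p2 + 451 * a + 288 * b) / 1403
  Ga <- (460 * p2 - 891 * a - 261 * b) / 1403
  Ba <- (460 * p2 - 220 * a - 6300 * b) / 1403
  RGBp <- camNonlinInv(cbind(Ra, Ga, Ba), vc$FL)
  RGBc <- RGBp %*% t(solve(.MHPE)) %*% t(.MCAT02)
  RGB <- sweep(RGBc, 2L, vc$Dfac, `/`)
  xyz <- RGB %*% t(solve(.MCAT02))
  rgb <- xyzToSrgb(xyz)
  clip <- rowSums(rgb < -1e-9 | rgb > 1 + 1e-9) > 0
  rgb <- pmin(pmax(rgb, 0), 1)
  attr(rgb, "clipFraction") <- mean(clip)
  attr(rgb, "clipped") <- clip
  rgb
}
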