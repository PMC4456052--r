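## Phase symmetry and asymmetry from a log-Gabor quadrature filter bank.
## Symmetry responds where frequency components sit at peaks/valleys of
## their cycles (ridge, delta-like structure); asymmetry where they sit at
## inflections (step edges).  Both measures are energy-normalized, hence
## invariant to global intensity scaling (up to the noise floor term).

#' Configuration of the log-Gabor filter bank
#'
#' @param nScales number of scales (>= 2); wavelengths follow the geometric
#'   progression `minWavelength * scaleMultiplier^(n-1)`.
#' @param nOrientations number of filter orientations (>= 2).
#' @param minWavelength wavelength (px) of the finest scale (>= 2).
#' @param scaleMultiplier ratio between successive wavelengths (> 1).
#' @param sigmaOnF bandwidth parameter: ratio of the log-Gaussian radial
#'   standard deviation to the center frequency (0.55 ~ 2 octaves).
#' @param noiseK multiplier of the scale-specific noise floor `T`
#'   subtracted in the numerator; 0 disables noise compensation.
#' @param epsilon small positive constant guarding the energy
#'   normalization against division by zero.
#' @param dThetaOnSigma ratio of the angular filter spacing to the angular
#'   Gaussian standard deviation.
#' @return list of class `"FilterBankConfig"`.
#' @export
filterBankConfig <- function(nScales = 4L, nOrientations = 6L,
    minWavelength = 4, scaleMultiplier = 2.1, sigmaOnF = 0.55,
    noiseK = 2, epsilon = 1e-4, dThetaOnSigma = 1.3) {
  cfg <- list(nScales = as.integer(nScales),
    nOrientations = as.integer(nOrientations),
    minWavelength = minWavelength, scaleMultiplier = scaleMultiplier,
    sigmaOnF = sigmaOnF, noiseK = noiseK, epsilon = epsilon,
    dThetaOnSigma = dThetaOnSigma)
  if (cfg$nScales < 2L) stop("nScales must be >= 2")
  if (cfg$nOrientations < 2L) stop("nOrientations must be >= 2")
  if (cfg$minWavelength < 2) stop("minWavelength must be >= 2")
  if (cfg$scaleMultiplier <= 1) stop("scaleMultiplier must be > 1")
  if (cfg$epsilon <= 0) stop("epsilon must be positive")
  if (cfg$sigmaOnF <= 0 || cfg$sigmaOnF >= 1)
    stop("sigmaOnF must lie in (0, 1)")
  class(cfg) <- "FilterBankConfig"
  cfg
}

## Frequency coordinates (cycles/px) in fft layout for n samples.
fftFreq <- function(n) {
  if (n %% 2L == 0L) c(0:(n / 2 - 1), -(n / 2):-1) / n
  else c(0:((n - 1) / 2), -((n - 1) / 2):-1) / n
}

#' Build the frequency-domain log-Gabor filter bank
#'
#' One real nonnegative frequency-domain filter per (scale, orientation):
#' a log-Gaussian radial profile about center frequency
#' `1/wavelength_n` times a single-sided angular Gaussian, so that the
#' inverse transform of `fft(frame) * filter` is the complex quadrature
#' (even + i * odd) response.  Every filter is exactly zero at DC.
#'
#' @param config a [filterBankConfig()].
#' @param dim integer(2), frame size (rows, cols).
#' @return list with `filters` (list indexed `[[scale]][[orientation]]`),
#'   `wavelengths`, and the config.
#' @export
buildBank <- function(config, dim) {
  stopifnot(inherits(config, "FilterBankConfig"))
  nr <- as.integer(dim[1L]); nc <- as.integer(dim[2L])
  if (nr <= 0L || nc <= 0L) stop("dim must be positive")
  wl <- config$minWavelength * config$scaleMultiplier^(seq_len(config$nScales) - 1)
  if (max(wl) > max(nr, nc))
    stop(sprintf("coarsest wavelength %.1f px exceeds the image size", max(wl)))
  u <- matrix(fftFreq(nc), nr, nc, byrow = TRUE)
  v <- matrix(fftFreq(nr), nr, nc)
  radius <- sqrt(u^2 + v^2); radius[1L, 1L] <- 1
  theta <- atan2(-v, u)
  sinT <- sin(theta); cosT <- cos(theta)
  thetaSigma <- pi / config$nOrientations / config$dThetaOnSigma
  ## butterworth low-pass keeps the corner frequencies from wrapping
  lp <- 1 / (1 + (radius / 0.45)^30)
  filters <- vector("list", config$nScales)
  for (s in seq_len(config$nScales)) {
    f0 <- 1 / wl[s]
    radial <- exp(-(log(radius / f0))^2 / (2 * log(config$sigmaOnF)^2)) * lp
    radial[1L, 1L] <- 0
    filters[[s]] <- vector("list", config$nOrientations)
    for (o in seq_len(config$nOrientations)) {
      ang <- (o - 1) * pi / config$nOrientations
      ds <- sinT * cos(ang) - cosT * sin(ang)
      dc <- cosT * cos(ang) + sinT * sin(ang)
      spread <- exp(-atan2(ds, dc)^2 / (2 * thetaSigma^2))
      filters[[s]][[o]] <- radial * spread
    }
  }
  structure(list(filters = filters, wavelengths = wl, config = config,
    dim = c(nr, nc)), class = "LogGaborBank")
}

#' Quadrature responses of a frame under a filter bank
#'
#' @param frame numeric matrix with finite values.
#' @param bank from [buildBank()]; must match the frame size.
#' @return a \linkS4class{FilterResponses}.
#' @export
filterResponses <- function(frame, bank) {
  stopifnot(inherits(bank, "LogGaborBank"))
  if (!all(is.finite(frame))) stop("frame must be finite-valued")
  if (!identical(dim(frame), as.integer(bank$dim)))
    stop("frame size does not match the bank")
  nr <- nrow(frame); nc <- ncol(frame)
  S <- bank$config$nScales; O <- bank$config$nOrientations
  ev <- od <- am <- array(0, c(nr, nc, S, O))
  Ff <- stats::fft(frame)
  for (s in seq_len(S)) for (o in seq_len(O)) {
    resp <- stats::fft(Ff * bank$filters[[s]][[o]], inverse = TRUE) / (nr * nc)
    ev[, , s, o] <- Re(resp)
    od[, , s, o] <- Im(resp)
    am[, , s, o] <- Mod(resp)
  }
  new("FilterResponses", even = ev, odd = od, amplitude = am)
}

## Scale-specific noise floor per orientation: the finest scale carries
## mostly noise, so its median amplitude (rescaled to the Rayleigh mean,
## /sqrt(ln 4)) estimates the noise amplitude there; coarser scales see the
## same white noise through proportionally narrower bands, so the floor is
## propagated down the geometric wavelength progression.
noiseFloor <- function(amplitude, config) {
  S <- dim(amplitude)[3L]; O <- dim(amplitude)[4L]
  Tm <- matrix(0, S, O)
  for (o in seq_len(O)) {
    tau1 <- stats::median(amplitude[, , 1L, o]) / sqrt(log(4))
    Tm[, o] <- config$noiseK * tau1 * config$scaleMultiplier^(-(seq_len(S) - 1))
  }
  Tm
}

phaseMeasure <- function(resp, config, which = c("sym", "asym")) {
  which <- match.arg(which)
  ev <- resp@even; od <- resp@odd; am <- resp@amplitude
  S <- dim(ev)[3L]; O <- dim(ev)[4L]
  Tm <- noiseFloor(am, config)
  num <- den <- matrix(0, dim(ev)[1L], dim(ev)[2L])
  for (o in seq_len(O)) for (s in seq_len(S)) {
    diffPart <- if (which == "sym")
      abs(ev[, , s, o]) - abs(od[, , s, o])
    else
      abs(od[, , s, o]) - abs(ev[, , s, o])
    num <- num + pmax(diffPart - Tm[s, o], 0)
    den <- den + am[, , s, o]
  }
  num / (den + config$epsilon)
}

#' Phase symmetry map
#'
#' Per orientation and scale, the clamped even-dominance
#' `max(|e_n| - |o_n| - T_n, 0)` is accumulated and normalized by the total
#' response amplitude (plus `epsilon`); orientations are combined with
#' uniform weights by summing numerators and denominators.
#'
#' @param resp a \linkS4class{FilterResponses}.
#' @param config the [filterBankConfig()] used to build the bank.
#' @return numeric matrix in \[0, 1\].
#' @export
phaseSymmetry <- function(resp, config) phaseMeasure(resp, config, "sym")

#' Phase asymmetry map
#'
#' As [phaseSymmetry()] with odd-dominance `max(|o_n| - |e_n| - T_n, 0)`
#' in the numerator.
#'
#' @inheritParams phaseSymmetry
#' @return numeric matrix in \[0, 1\].
#' @export
phaseAsymmetry <- function(resp, config) phaseMeasure(resp, config, "asym")

#' Phase symmetry and asymmetry of a frame
#'
#' One-call wrapper: builds (or reuses) the bank and accumulates both maps
#' scale-by-scale without materializing the full response arrays, which is
#' what the per-frame pipeline uses.
#'
#' @param frame numeric matrix.
#' @param config a [filterBankConfig()].
#' @param bank optional prebuilt [buildBank()] for this frame size.
#' @return a \linkS4class{PhaseMaps}.
#' @export
phaseMaps <- function(frame, config = filterBankConfig(), bank = NULL) {
  if (is.null(bank)) bank <- buildBank(config, dim(frame))
  if (!all(is.finite(frame))) stop("frame must be finite-valued")
  nr <- nrow(frame); nc <- ncol(frame)
  S <- config$nScales; O <- config$nOrientations
  Ff <- stats::fft(frame)
  numS <- numA <- den <- matrix(0, nr, nc)
  scaleDecay <- config$scaleMultiplier^(-(seq_len(S) - 1))
  for (o in seq_len(O)) {
    e <- vector("list", S); od <- vector("list", S); am <- vector("list", S)
    for (s in seq_len(S)) {
      resp <- stats::fft(Ff * bank$filters[[s]][[o]], inverse = TRUE) / (nr * nc)
      e[[s]] <- Re(resp); od[[s]] <- Im(resp); am[[s]] <- Mod(resp)
    }
    tau1 <- stats::median(am[[1L]]) / sqrt(log(4))
    for (s in seq_len(S)) {
      Tn <- config$noiseK * tau1 * scaleDecay[s]
      numS <- numS + pmax(abs(e[[s]]) - abs(od[[s]]) - Tn, 0)
      numA <- numA + pmax(abs(od[[s]]) - abs(e[[s]]) - Tn, 0)
      den <- den + am[[s]]
    }
  }
  den <- den + config$epsilon
  new("PhaseMaps", sym = numS / den, asym = numA / den)
}
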