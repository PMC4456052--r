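# Independent per-pixel loop oracle for the phase measures: restates the
# symmetry/asymmetry definitions with explicit scale/orientation loops,
# computing the noise floor exactly as documented (finest-scale median
# amplitude / sqrt(ln 4), decayed down the wavelength progression).
naivePhaseMaps <- function(resp, config) {
  ev <- resp@even; od <- resp@odd; am <- resp@amplitude
  d <- dim(ev)
  sym <- asym <- matrix(0, d[1L], d[2L])
  for (r in seq_len(d[1L])) for (cl in seq_len(d[2L])) {
    num <- numa <- den <- 0
    for (o in seq_len(d[4L])) {
      tau1 <- median(am[, , 1L, o]) / sqrt(log(4))
      for (s in seq_len(d[3L])) {
        Tn <- config$noiseK * tau1 * config$scaleMultiplier^(-(s - 1))
        e <- ev[r, cl, s, o]; oo <- od[r, cl, s, o]
        num <- num + max(abs(e) - abs(oo) - Tn, 0)
        numa <- numa + max(abs(oo) - abs(e) - Tn, 0)
        den <- den + am[r, cl, s, o]
      }
    }
    sym[r, cl] <- num / (den + config$epsilon)
    asym[r, cl] <- numa / (den + config$epsilon)
  }
  list(sym = sym, asym = asym)
}
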