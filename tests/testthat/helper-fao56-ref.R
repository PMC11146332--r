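# Independent scalar FAO-56 Penman-Monteith reference, written step by step
# from Allen et al. (1998) and kept deliberately separate from the package's
# vectorised implementation. Used as the cross-check oracle.

ref_fao56_et0 <- function(tmin, tmax, rh, u2, sr, lat_deg, z, doy) {
  e0 <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  tmean <- (tmin + tmax) / 2
  delta <- 4098 * e0(tmean) / (tmean + 237.3)^2
  pressure <- 101.3 * ((293 - 0.0065 * z) / 293)^5.26
  gamma <- 0.000665 * pressure
  es <- (e0(tmax) + e0(tmin)) / 2
  ea <- rh / 100 * es
  phi <- lat_deg * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  omega_s <- acos(max(-1, min(1, -tan(phi) * tan(decl))))
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (omega_s * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(omega_s))
  rso <- (0.75 + 2e-5 * z) * ra
  rns <- (1 - 0.23) * sr
  ratio <- max(0.05, min(1, sr / rso))
  rnl <- 4.903e-9 * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * ratio - 0.35)
  rn <- rns - rnl
  (0.408 * delta * rn + gamma * 900 / (tmean + 273) * u2 * (es - ea)) /
    (delta + gamma * (1 + 0.34 * u2))
}
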