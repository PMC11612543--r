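# Independent oracles used across the suite.

# Explicit piecewise closed form of the polygynous minharmonic function
# (number of harems), written out from the harem-size substitution by
# hand rather than via the package's composition route, so the two can
# cross-check each other.  x = f / (hm + f) is the harem-adjusted OSR.
polygynous_minharmonic_closed <- function(m, f, h, e) {
  if (m + f == 0) return(0)
  x <- f / (h * m + f)
  if (e < 0.5) return(((h * m + f) / h) * 2 * e * x * (1 - x))
  if (e == 1 || x <= e - 0.5 || x >= 1.5 - e) {
    min(f, m * h) / h
  } else {
    (m * f / (h * m + f) - (h * m + f) * (e - 0.5)^2 / h) / (2 * (1 - e))
  }
}

# Single wild boar scenario run, returning lambda only.
scenario_lambda_once <- function(e, h, Hf) {
  sys <- if (h == 1) mating_system() else mating_system("polygyny", h)
  project(wild_boar_init(), wild_boar_rates(Hf = Hf), sys,
          mating_function("minharmonic", e = e))$lambda
}

# Survival/growth-only female and male Leslie blocks of the wild boar
# matrix (no births), for the sanity bound on lambda.
survival_only_lambda <- function(v) {
  Ff <- matrix(0, 3, 3)
  Ff[1, 1] <- (1 - v$G_Mf) * v$SSf * (1 - v$HSf)
  Ff[2, 1] <- v$G_Mf * v$SMf * (1 - v$Hf)
  Ff[2, 2] <- (1 - v$G_Lf) * v$SMf * (1 - v$Hf)
  Ff[3, 2] <- v$G_Lf * v$SLf * (1 - v$Hf)
  Ff[3, 3] <- v$SLf * (1 - v$Hf)
  Fm <- matrix(0, 3, 3)
  Fm[1, 1] <- (1 - v$G_Mm) * v$SSm * (1 - v$HSm)
  Fm[2, 1] <- v$G_Mm * v$SMm * (1 - v$HMm)
  Fm[2, 2] <- (1 - v$G_Lm) * v$SMm * (1 - v$HMm)
  Fm[3, 2] <- v$G_Lm * v$SLm * (1 - v$HLm)
  Fm[3, 3] <- v$SLm * (1 - v$HLm)
  max(abs(eigen(Ff, only.values = TRUE)$values),
      abs(eigen(Fm, only.values = TRUE)$values))
}
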