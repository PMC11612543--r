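#' Mating-function specification
#'
#' A mating function \eqn{U(m, f)} gives the expected number of unions
#' (pairs under monogamy, harems under polygyny) formed in one breeding
#' season from `m` available males and `f` available females.  All
#' families implemented here except the modified harmonic mean are
#' homogeneous of degree one and symmetric in the sexes, so they reduce
#' to a univariate profile \eqn{U^*(f^*)} of the operational sex ratio
#' (OSR) \eqn{f^* = f / (m + f)}: the expected number of unions per
#' individual in the mating pool.
#'
#' Available families:
#' \describe{
#'   \item{`minimum`}{\eqn{U^*(f^*) = p \min(f^*, 1 - f^*)}. With
#'     \eqn{p = 1} every individual of the limiting sex mates:
#'     efficiency 1 at every OSR, with a kink (discontinuous
#'     derivative) at the balanced OSR.}
#'   \item{`harmonic`}{\eqn{U^*(f^*) = p f^* (1 - f^*)}, the harmonic
#'     mean function.  The classical choice \eqn{p = 2} forms more
#'     unions than the limiting sex can supply whenever
#'     \eqn{m \neq f}; \eqn{p \le 1} is logically sound but implies a
#'     low mating efficiency (\eqn{p/2} at balance).}
#'   \item{`modified_harmonic`}{\eqn{U(m, f) = \min(f, 2mf/(m+f))}:
#'     the harmonic mean capped by the number of females.  Not
#'     symmetric in the sexes (the cap only protects the female side),
#'     so it is kept bivariate and used for comparison only.}
#'   \item{`minharmonic`}{the one-parameter blend of the minimum and
#'     harmonic-mean functions described in [ustar_minharmonic()]; its
#'     parameter `e` is the mating efficiency at the balanced OSR.}
#' }
#'
#' Validity is deliberately not enforced at construction: specifications
#' such as `harmonic` with `p = 2`, which violate the Pollak bound
#' \eqn{U \le \min(m, f)}, can still be built, evaluated and compared.
#' Use [validate_mating_function()] to audit a specification.
#'
#' @param family Family name, one of `"minimum"`, `"harmonic"`,
#'   `"modified_harmonic"`, `"minharmonic"`.
#' @param p Non-negative multiplier for the `minimum` (default 1) and
#'   `harmonic` (default 2) families.
#' @param e Mating efficiency at the balanced OSR, in \[0, 1\];
#'   required by (and only by) the `minharmonic` family.
#'
#' @return An object of class `"mating_function"`: a list with elements
#'   `family` and, where applicable, `p` or `e`.
#' @examples
#' mating_function("minharmonic", e = 0.8)
#' mating_function("harmonic")          # classical p = 2
#' mating_function("minimum", p = 0.8)
#' @seealso [unions()], [ustar_minharmonic()], [validate_mating_function()]
#' @export
mating_function <- function(family = c("minimum", "harmonic",
                                       "modified_harmonic", "minharmonic"),
                            p = NULL, e = NULL) {
  family <- match.arg(family)
  if (family %in% c("minimum", "harmonic")) {
    if (!is.null(e))
      stop("'e' is only meaningful for the minharmonic family; use 'p'",
           call. = FALSE)
    if (is.null(p)) p <- if (family == "minimum") 1 else 2
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0)
      stop("'p' must be a single non-negative number", call. = FALSE)
  } else if (family == "modified_harmonic") {
    if (!is.null(p) || !is.null(e))
      stop("the modified harmonic mean function has no free parameter",
           call. = FALSE)
  } else { # minharmonic
    if (!is.null(p))
      stop("the minharmonic family is parameterised by 'e', not 'p'",
           call. = FALSE)
    if (is.null(e) || !is.numeric(e) || length(e) != 1L || is.na(e) ||
        e < 0 || e > 1)
      stop("'e' must be a single number in [0, 1]", call. = FALSE)
  }
  structure(list(family = family, p = p, e = e), class = "mating_function")
}

#' Coerce to a mating-function specification
#'
#' Character input is taken as a family name and built with that
#' family's default parameter.
#'
#' @param x A `"mating_function"` object or a family name.
#' @return A `"mating_function"` object.
#' @export
as_mating_function <- function(x) {
  if (inherits(x, "mating_function")) return(x)
  if (is.character(x) && length(x) == 1L) return(mating_function(x))
  stop("cannot interpret 'x' as a mating function", call. = FALSE)
}

#' @export
format.mating_function <- function(x, ...) {
  par <- if (!is.null(x$e)) sprintf("e = %g", x$e)
         else if (!is.null(x$p)) sprintf("p = %g", x$p)
         else "no parameter"
  sprintf("<mating_function: %s (%s)>", x$family, par)
}

#' @export
print.mating_function <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

check_fstar <- function(fstar) {
  if (any(is.na(fstar)) || any(fstar < 0) || any(fstar > 1))
    stop("'fstar' must lie in [0, 1]", call. = FALSE)
  invisible(fstar)
}

#' Univariate mating-function profiles
#'
#' Pair-formation rate per individual, \eqn{U^*(f^*)}, as a function of
#' the operational sex ratio \eqn{f^*} (proportion of females among
#' available reproductive individuals).
#'
#' `ustar_minimum()` returns \eqn{p \min(f^*, 1 - f^*)} and
#' `ustar_harmonic()` returns \eqn{p f^* (1 - f^*)}.
#'
#' `ustar_minharmonic()` implements the minharmonic profile with
#' efficiency-at-balance parameter `e`:
#' \itemize{
#'   \item for \eqn{e < 0.5} it equals the harmonic mean profile of
#'     parameter \eqn{p = 2e}, i.e. \eqn{2 e f^* (1 - f^*)};
#'   \item for \eqn{0.5 \le e < 1} it equals
#'     \eqn{\min(f^*, 1 - f^*)} on the outer branches
#'     \eqn{f^* \le e - 0.5} and \eqn{f^* \ge 1.5 - e}, and
#'     \eqn{[f^*(1 - f^*) - (e - 0.5)^2] / (2 (1 - e))} in between;
#'   \item for \eqn{e = 1} the middle interval collapses to the single
#'     point 0.5 and the function is \eqn{\min(f^*, 1 - f^*)}
#'     everywhere (the minimum function of parameter 1).
#' }
#' The two branches join with equal value and equal first derivative at
#' \eqn{f^* = e - 0.5} and \eqn{f^* = 1.5 - e}, and the profile
#' satisfies \eqn{2 U^*(0.5) = e}: the mating efficiency at the
#' balanced OSR is exactly `e`.
#'
#' @param fstar OSR value(s) in \[0, 1\]; vectorised.
#' @param p Non-negative multiplier.
#' @param e Mating efficiency at the balanced OSR, in \[0, 1\].
#' @return Numeric vector of unions per individual, same length as
#'   `fstar`.
#' @examples
#' ustar_minimum(0.3, p = 0.8)        # 0.24
#' ustar_harmonic(0.5, p = 1)         # 0.25: half the adults unmated
#' ustar_minharmonic(0.5, e = 0.8)    # 0.40 = e / 2
#' ustar_minharmonic(0.3, e = 0.9)    # 0.30: every female mates
#' @export
ustar_minimum <- function(fstar, p = 1) {
  check_fstar(fstar)
  if (p < 0) stop("'p' must be non-negative", call. = FALSE)
  p * pmin(fstar, 1 - fstar)
}

#' @rdname ustar_minimum
#' @export
ustar_harmonic <- function(fstar, p = 2) {
  check_fstar(fstar)
  if (p < 0) stop("'p' must be non-negative", call. = FALSE)
  p * fstar * (1 - fstar)
}

#' @rdname ustar_minimum
#' @export
ustar_minharmonic <- function(fstar, e) {
  if (!is.numeric(e) || length(e) != 1L || is.na(e) || e < 0 || e > 1)
    stop("'e' must be a single number in [0, 1]", call. = FALSE)
  check_fstar(fstar)
  if (e < 0.5) return(2 * e * fstar * (1 - fstar))
  if (e == 1)  return(pmin(fstar, 1 - fstar))
  out <- pmin(fstar, 1 - fstar)
  mid <- fstar > (e - 0.5) & fstar < (1.5 - e)
  out[mid] <- (fstar[mid] * (1 - fstar[mid]) - (e - 0.5)^2) / (2 * (1 - e))
  out
}

#' Evaluate the univariate profile of a specification
#'
#' Dispatches [ustar_minimum()], [ustar_harmonic()] or
#' [ustar_minharmonic()] according to the family of `fn`.  The modified
#' harmonic mean function is not symmetric in the sexes and has no
#' canonical univariate profile; requesting it is an error (use
#' [unions()] with explicit counts, or [ustar_profile()] for the
#' per-individual rate along the OSR axis).
#'
#' @param fn A [mating_function()] or family name.
#' @inheritParams ustar_minimum
#' @return Numeric vector of unions per individual.
#' @export
ustar <- function(fn, fstar) {
  fn <- as_mating_function(fn)
  switch(fn$family,
    minimum     = ustar_minimum(fstar, fn$p),
    harmonic    = ustar_harmonic(fstar, fn$p),
    minharmonic = ustar_minharmonic(fstar, fn$e),
    stop("the ", fn$family,
         " function has no univariate form; see ?ustar", call. = FALSE)
  )
}

#' Per-individual union rate along the OSR axis, any family
#'
#' `U(1 - fstar, fstar)`: by degree-one homogeneity this equals the
#' univariate profile for the symmetric families and extends the notion
#' to the (asymmetric) modified harmonic mean.  Used by the property
#' checker.
#'
#' @inheritParams ustar
#' @return Numeric vector of unions per individual.
#' @export
ustar_profile <- function(fn, fstar) {
  check_fstar(fstar)
  unions(1 - fstar, fstar, fn)
}

#' Expected number of unions
#'
#' Bivariate evaluation \eqn{U(m, f)} for any registered family.  For
#' the symmetric, homogeneous families this is the homogeneity
#' reduction \eqn{(m + f)\, U^*(f / (m + f))}; for the modified
#' harmonic mean it is \eqn{\min(f, 2mf/(m+f))} directly.  When
#' \eqn{m + f = 0} the result is 0 (an extinct mating pool forms no
#' unions), so projection code needs no special-casing.
#'
#' Counts are continuous expected values, not integers, consistent with
#' deterministic projection.
#'
#' @param m,f Non-negative numbers (or vectors) of available males and
#'   females.
#' @param fn A [mating_function()] or family name.
#' @return Expected number of unions (non-negative numeric).
#' @examples
#' unions(100, 100, mating_function("minharmonic", e = 0.8))  # 80
#' unions(70, 30, mating_function("minharmonic", e = 0.9))    # 30
#' unions(10, 1000, "modified_harmonic")                      # ~19.8
#' @export
unions <- function(m, f, fn) {
  fn <- as_mating_function(fn)
  if (any(is.na(m)) || any(is.na(f)) || any(m < 0) || any(f < 0))
    stop("'m' and 'f' must be non-negative", call. = FALSE)
  len <- max(length(m), length(f))
  m <- rep_len(as.numeric(m), len)
  f <- rep_len(as.numeric(f), len)
  n <- m + f
  out <- numeric(len)
  pos <- n > 0
  if (fn$family == "modified_harmonic") {
    out[pos] <- pmin(f[pos], 2 * m[pos] * f[pos] / n[pos])
  } else {
    out[pos] <- n[pos] * ustar(fn, f[pos] / n[pos])
  }
  out
}

#' Mating efficiency
#'
#' The probability that an individual of the limiting (less numerous)
#' sex meets a mate: \eqn{E(m, f) = U(m, f) / \min(m, f)}, or in OSR
#' form \eqn{E^*(f^*) = U^*(f^*) / \min(f^*, 1 - f^*)}.  For a
#' mathematically valid mating function this lies in \[0, 1\].
#'
#' Efficiency is undefined when either sex is absent; callers handle
#' the absent-sex case separately (no unions form there).
#'
#' @inheritParams unions
#' @return Numeric vector of probabilities (possibly > 1 for invalid
#'   specifications such as `harmonic` with `p = 2`).
#' @examples
#' mating_efficiency(100, 100, mating_function("minharmonic", e = 0.8)) # 0.8
#' mating_efficiency(100, 100, mating_function("harmonic", p = 2))      # 1
#' @export
mating_efficiency <- function(m, f, fn) {
  if (any(is.na(m)) || any(is.na(f)) || any(m <= 0) || any(f <= 0))
    stop("mating efficiency is undefined when either sex is absent",
         call. = FALSE)
  unions(m, f, fn) / pmin(m, f)
}

#' Mating efficiency at the balanced OSR
#'
#' Returns \eqn{e = E^*(0.5) = 2 U^*(0.5)}: `e` for the minharmonic
#' family, `p` for the minimum family and `p / 2` for the harmonic
#' mean family.  This is the quantity used to standardise different
#' families to a common efficiency when comparing them.
#'
#' @inheritParams ustar
#' @return A single number.
#' @examples
#' efficiency_at_balance(mating_function("minimum",  p = 0.8))  # 0.8
#' efficiency_at_balance(mating_function("harmonic", p = 1.6))  # 0.8
#' @export
efficiency_at_balance <- function(fn) {
  mating_efficiency(1, 1, fn)
}
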