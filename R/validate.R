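# Grid-based validity audit for mating functions.
#
# Checks are counterexample searches on fixed deterministic grids, not
# proofs: a "pass" means no violation was found on the grid.  Grids and
# tolerances are chosen to catch the known pathologies (the Pollak
# violation of the harmonic mean of parameter 2, the kink of the
# minimum function at the balanced OSR) without false positives from
# floating-point error.

# default grids
fstar_grid <- function(n = 1e4) seq(1e-4, 1 - 1e-4, length.out = n)
count_grid <- function(n = 25) 10^seq(-2, 4, length.out = n)

prop_row <- function(property, mandatory, status, worst = NA_real_,
                     location = NA_character_) {
  data.frame(property = property, mandatory = mandatory, status = status,
             worst_violation = worst, location = location,
             stringsAsFactors = FALSE)
}

status_of <- function(violation, tol) {
  if (violation <= tol) "pass" else "fail"
}

#' Individual property checks for mating functions
#'
#' Each checker searches a deterministic grid for violations of one of
#' the validity properties a mating function should satisfy, and
#' returns one row (or several, for the grouped checkers) with the
#' status, the worst violation magnitude found and its location.
#'
#' * `check_monotonicity()`: \eqn{U(m, f)} non-decreasing in each of
#'   `m` and `f` (mandatory).
#' * `check_nonneg_absent_homog()`: non-negativity, no unions when one
#'   sex is absent, and degree-one homogeneity
#'   \eqn{U(km, kf) = k U(m, f)} for \eqn{k \in \{0.5, 2, 10\}}
#'   (all mandatory).
#' * `check_pollak()`: the Pollak bound
#'   \eqn{U(m, f) \le \min(m, f)} -- unions involving a sex must not
#'   exceed that sex's abundance (mandatory).  Also reported in
#'   efficiency form (\eqn{E \le 1}) as `efficiency_bounded`.
#' * `check_symmetry_efficiency_smoothness()`: symmetry about the
#'   balanced OSR; mating efficiency smallest at/around the balanced
#'   OSR (non-increasing towards 0.5, non-decreasing away from it,
#'   with genuine variation); continuity of the per-individual rate;
#'   and continuity of its derivative (all desirable).
#'
#' Derivative continuity is assessed on the per-individual profile
#' along the OSR axis (sufficient under homogeneity): central
#' differences with step half the grid spacing, flagging jumps in the
#' local derivative above `deriv_tol` between adjacent grid points.
#' The default 0.02 (unions per individual per unit OSR) cleanly
#' separates genuine kinks, whose jump is of order the multiplier `p`,
#' from smooth-curvature drift, which is of order the grid spacing.
#'
#' @param fn A [mating_function()] or family name.
#' @param n_fstar Number of OSR grid points.
#' @param n_count Number of count grid points per sex (log-spaced in
#'   \eqn{[10^{-2}, 10^4]}).
#' @param tol Relative tolerance for algebraic identities.
#' @param deriv_tol Derivative-jump detection threshold.
#' @return A data frame with columns `property`, `mandatory`, `status`
#'   (`"pass"`/`"fail"`), `worst_violation`, `location`.
#' @seealso [validate_mating_function()]
#' @export
check_monotonicity <- function(fn, n_count = 25, tol = 1e-8) {
  fn <- as_mating_function(fn)
  g <- count_grid(n_count)
  worst <- 0; where <- NA_character_
  for (f in g) {
    u <- unions(g, f, fn)
    d <- diff(u)
    bad <- -min(d, 0) / max(abs(u), 1)
    if (bad > worst) {
      worst <- bad
      where <- sprintf("m = %.3g, f = %.3g", g[which.min(d)], f)
    }
  }
  for (m in g) {
    u <- unions(m, g, fn)
    d <- diff(u)
    bad <- -min(d, 0) / max(abs(u), 1)
    if (bad > worst) {
      worst <- bad
      where <- sprintf("m = %.3g, f = %.3g", m, g[which.min(d)])
    }
  }
  prop_row("monotonicity", TRUE, status_of(worst, tol), worst, where)
}

#' @rdname check_monotonicity
#' @export
check_nonneg_absent_homog <- function(fn, n_count = 25, tol = 1e-8) {
  fn <- as_mating_function(fn)
  g <- count_grid(n_count)
  mm <- rep(g, times = length(g))
  ff <- rep(g, each = length(g))
  u <- unions(mm, ff, fn)

  neg <- max(-u, 0)
  i <- which.min(u)
  r1 <- prop_row("non_negativity", TRUE, status_of(neg, 0), neg,
                 sprintf("m = %.3g, f = %.3g", mm[i], ff[i]))

  ab <- max(abs(c(unions(0, g, fn), unions(g, 0, fn), unions(0, 0, fn))))
  r2 <- prop_row("absent_sex", TRUE, status_of(ab, tol), ab,
                 "one sex absent")

  worst <- 0; where <- NA_character_
  for (k in c(0.5, 2, 10)) {
    uk <- unions(k * mm, k * ff, fn)
    rel <- abs(uk - k * u) / pmax(k * abs(u), 1e-12)
    j <- which.max(rel)
    if (rel[j] > worst) {
      worst <- rel[j]
      where <- sprintf("m = %.3g, f = %.3g, k = %g", mm[j], ff[j], k)
    }
  }
  r3 <- prop_row("homogeneity", TRUE, status_of(worst, tol), worst, where)
  rbind(r1, r2, r3)
}

#' @rdname check_monotonicity
#' @export
check_pollak <- function(fn, n_count = 25, n_fstar = 1e4, tol = 1e-8) {
  fn <- as_mating_function(fn)
  g <- count_grid(n_count)
  mm <- rep(g, times = length(g))
  ff <- rep(g, each = length(g))
  ratio <- unions(mm, ff, fn) / pmin(mm, ff)
  i <- which.max(ratio)
  worst <- max(ratio[i] - 1, 0)
  r1 <- prop_row("pollak", TRUE, status_of(worst, tol), worst,
                 sprintf("m = %.3g, f = %.3g (U/min = %.4g)",
                         mm[i], ff[i], ratio[i]))
  fs <- fstar_grid(n_fstar)
  eff <- ustar_profile(fn, fs) / pmin(fs, 1 - fs)
  j <- which.max(eff)
  worst_e <- max(eff[j] - 1, 0)
  r2 <- prop_row("efficiency_bounded", TRUE, status_of(worst_e, tol),
                 worst_e, sprintf("f* = %.4g (E* = %.4g)", fs[j], eff[j]))
  rbind(r1, r2)
}

#' @rdname check_monotonicity
#' @export
check_symmetry_efficiency_smoothness <- function(fn, n_fstar = 1e4,
                                                 tol = 1e-8,
                                                 deriv_tol = 0.02) {
  fn <- as_mating_function(fn)
  fs <- fstar_grid(n_fstar)
  u <- ustar_profile(fn, fs)

  # symmetry about the balanced OSR
  mir <- ustar_profile(fn, 1 - fs)
  dev <- abs(u - mir) / pmax(abs(u) + abs(mir), 1e-12)
  i <- which.max(dev)
  r1 <- prop_row("symmetry", FALSE, status_of(dev[i], tol), dev[i],
                 sprintf("f* = %.4g", fs[i]))

  # efficiency smallest at/around balance: non-increasing on (0, 0.5],
  # non-decreasing on [0.5, 1), and not flat
  eff <- u / pmin(fs, 1 - fs)
  left <- fs <= 0.5
  inc_l <- max(diff(eff[left]), 0)           # should be <= 0
  dec_r <- max(-diff(eff[!left]), 0)         # should be >= 0
  mono_viol <- max(inc_l, dec_r)
  flat <- diff(range(eff)) <= 1e-6
  eff_status <- if (mono_viol > 1e-6 || flat) "fail" else "pass"
  r2 <- prop_row("efficiency_variation", FALSE, eff_status,
                 if (flat) 0 else mono_viol,
                 if (flat) "efficiency constant across OSR" else
                   "monotonicity about f* = 0.5")

  # continuity: successive jumps bounded by a slope budget
  step <- fs[2] - fs[1]
  jump <- max(abs(diff(u)))
  cont_viol <- max(jump - 10 * step * max(1, max(abs(u)) * 4), 0)
  r3 <- prop_row("continuity", FALSE, status_of(cont_viol, 0), jump,
                 sprintf("max step jump %.3g over spacing %.3g", jump, step))

  # derivative continuity: central differences with half-spacing step,
  # so any kink lies inside some stencil
  dstep <- step / 2
  interior <- fs > dstep & fs < 1 - dstep
  x <- fs[interior]
  d1 <- (ustar_profile(fn, x + dstep) - ustar_profile(fn, x - dstep)) /
    (2 * dstep)
  djump <- max(abs(diff(d1)))
  k <- which.max(abs(diff(d1)))
  r4 <- prop_row("smoothness", FALSE,
                 if (djump <= deriv_tol) "pass" else "fail", djump,
                 sprintf("f* = %.4g", x[k]))

  rbind(r1, r2, r3, r4)
}

#' Audit a mating function against all validity properties
#'
#' Runs the full battery of grid-based checks: the five mandatory
#' properties (monotonicity, non-negativity, no unions when a sex is
#' absent, degree-one homogeneity, the Pollak bound together with its
#' efficiency form \eqn{E \le 1}) and the desirable ones (symmetry
#' about the balanced OSR, efficiency lowest around balance, continuity
#' and derivative continuity of the per-individual rate).
#'
#' The report is a data frame, one row per property; the attribute
#' `overall_valid` (also shown by `print()`) is `TRUE` when every
#' mandatory property passes.  Desirable failures do not invalidate a
#' function but flag ecological implausibility -- e.g. the minimum
#' function of parameter 1 is valid yet has a kinked rate and an
#' OSR-independent efficiency.
#'
#' @inheritParams check_monotonicity
#' @return A data frame of class `"mating_property_report"` with
#'   attribute `overall_valid`.
#' @examples
#' validate_mating_function(mating_function("minharmonic", e = 0.8))
#' r <- validate_mating_function(mating_function("harmonic", p = 2))
#' attr(r, "overall_valid")  # FALSE: Pollak bound violated
#' @export
validate_mating_function <- function(fn, n_fstar = 1e4, n_count = 25,
                                     tol = 1e-8, deriv_tol = 0.02) {
  fn <- as_mating_function(fn)
  rep <- rbind(
    check_monotonicity(fn, n_count, tol),
    check_nonneg_absent_homog(fn, n_count, tol),
    check_pollak(fn, n_count, n_fstar, tol),
    check_symmetry_efficiency_smoothness(fn, n_fstar, tol, deriv_tol)
  )
  rownames(rep) <- NULL
  structure(rep,
            overall_valid = all(rep$status[rep$mandatory] == "pass"),
            spec = fn,
            class = c("mating_property_report", "data.frame"))
}

#' @export
print.mating_property_report <- function(x, ...) {
  cat("Mating-function validity report for", format(attr(x, "spec")), "\n\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("\noverall valid (all mandatory pass):",
      attr(x, "overall_valid"), "\n")
  invisible(x)
}

#' Write a property report to CSV
#'
#' Flat serialisation of a [validate_mating_function()] report:
#' columns `property`, `mandatory`, `status`, `worst_violation`,
#' `location`.
#'
#' @param report A `"mating_property_report"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_property_report <- function(report, path) {
  stopifnot(inherits(report, "mating_property_report"))
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
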