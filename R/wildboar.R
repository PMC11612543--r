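# Harvest-scenario drivers for the intensively hunted wild boar
# population of Chateauvillain-Arc-en-Barrois, France.

#' Built-in wild boar vital rates
#'
#' The estimated annual vital rates of the Chateauvillain wild boar
#' population (three size classes per sex; natural survival, hunting
#' proportions, growth transitions, postnatal survival and litter
#' sizes).  `Hf`, the hunting proportion of mature females, is the
#' harvest-scenario variable and defaults to `NA`; every scenario
#' driver sets it explicitly.
#'
#' @param Hf Optional hunting proportion of medium and large females.
#' @return A [vital_rates()] object.
#' @examples
#' wild_boar_rates()$SSf   # 0.978
#' wild_boar_rates()$HLm   # 0.789
#' @export
wild_boar_rates <- function(Hf = NA_real_) {
  vital_rates(
    SSf = 0.978, SMf = 0.855, SLf = 0.859, HSf = 0.449, Hf = Hf,
    SSm = 0.962, SMm = 0.777, SLm = 0.904,
    HSm = 0.511, HMm = 0.541, HLm = 0.789,
    G_Mf = 0.879, G_Lf = 0.569, G_Mm = 0.747, G_Lm = 0.678,
    G_juvMf = 0.4, G_juvMm = 0.4,
    s0 = 0.75, K_M = 5, K_L = 6
  )
}

#' Built-in wild boar initial census
#'
#' The average post-hunt, pre-birth census observed in the field:
#' 31 small, 92 medium and 154 large individuals of each sex
#' (554 in total).
#'
#' @return A [population_vector()].
#' @export
wild_boar_init <- function() {
  population_vector(fS = 31, fM = 92, fL = 154,
                    mS = 31, mM = 92, mL = 154)
}

scenario_system <- function(h) {
  if (h == 1) mating_system("monogamy")
  else mating_system("polygyny", harem_size = h)
}

scenario_fn <- function(e, fn) {
  if (is.null(fn)) {
    if (is.null(e)) stop("supply either 'e' or 'fn'", call. = FALSE)
    mating_function("minharmonic", e = e)
  } else as_mating_function(fn)
}

scenario_run <- function(Hf, e, h, fn, v, N0, T, clamp_osr = NULL) {
  v$Hf <- Hf
  pr <- project(N0, v, scenario_system(h), scenario_fn(e, fn), T = T,
                clamp_osr = clamp_osr)
  data.frame(e = if (is.null(e)) efficiency_at_balance(scenario_fn(e, fn))
                 else e,
             h = h, Hf = Hf, osr = pr$osr, lambda = pr$lambda)
}

#' Sweep the mature-female harvest proportion
#'
#' Projects the wild boar model across a grid of `Hf` values (default
#' 101 equally spaced points in \[0, 1\]) for one mating efficiency
#' `e` and harem size `h`, recording the equilibrium OSR and
#' \eqn{\lambda_T} of each scenario.  Heavier female harvest shifts
#' the OSR towards males, so `osr` is non-increasing along the sweep.
#'
#' @param e Mating efficiency at the balanced OSR (minharmonic);
#'   ignored when `fn` is supplied.
#' @param h Mean harem size (1 = monogamy).
#' @param hf Grid of female harvest proportions in \[0, 1\].
#' @param fn Optional [mating_function()] overriding the minharmonic
#'   default (used by [compare_functions()]).
#' @param v Vital rates; defaults to [wild_boar_rates()].
#' @param N0 Initial census; defaults to [wild_boar_init()].
#' @param T Projection horizon (years).
#' @return Data frame with columns `e`, `h`, `Hf`, `osr`, `lambda`,
#'   sorted by `Hf`.
#' @examples
#' sw <- sweep_hf(e = 0.9, h = 1, hf = seq(0, 1, by = 0.25))
#' @export
sweep_hf <- function(e = NULL, h = 1, hf = seq(0, 1, length.out = 101),
                     fn = NULL, v = wild_boar_rates(),
                     N0 = wild_boar_init(), T = 20) {
  if (any(hf < 0) || any(hf > 1))
    stop("'hf' values must lie in [0, 1]", call. = FALSE)
  hf <- sort(hf)
  out <- do.call(rbind, lapply(hf, scenario_run, e = e, h = h, fn = fn,
                               v = v, N0 = N0, T = T))
  rownames(out) <- NULL
  out
}

#' Attainable equilibrium OSR range
#'
#' Equilibrium OSR of the wild boar model at the two harvest extremes
#' `Hf = 1` (no mature females survive: OSR 0) and `Hf = 0` (only
#' males harvested among matures: the most female-biased OSR the
#' harvest lever can reach).
#'
#' @inheritParams sweep_hf
#' @return Numeric vector `c(min, max)`.
#' @export
attainable_osr_range <- function(e = NULL, h = 1, fn = NULL,
                                 v = wild_boar_rates(),
                                 N0 = wild_boar_init(), T = 20) {
  lo <- scenario_run(1, e, h, fn, v, N0, T)$osr
  hi <- scenario_run(0, e, h, fn, v, N0, T)$osr
  c(min = lo, max = hi)
}

#' Solve the female harvest proportion for a target OSR
#'
#' Inverts the monotone mapping `Hf -> equilibrium OSR` by bisection:
#' finds the female harvest proportion under which the projected
#' population settles at the requested operational sex ratio, and
#' returns the scenario (including \eqn{\lambda_T}) at the solved
#' `Hf`.  Targets outside the attainable range raise a condition of
#' class `"osr_range_error"` carrying the attainable endpoints.
#'
#' @inheritParams sweep_hf
#' @param target_osr Requested equilibrium OSR in \[0, 1\].
#' @param tol Tolerance on the achieved OSR (default `1e-4`).
#' @param max_iter Bisection iteration cap.
#' @return One-row data frame `e`, `h`, `Hf`, `osr`, `lambda`.
#' @examples
#' solve_hf_for_osr(0.5, e = 0.8, h = 1)
#' @export
solve_hf_for_osr <- function(target_osr, e = NULL, h = 1, tol = 1e-4,
                             fn = NULL, v = wild_boar_rates(),
                             N0 = wild_boar_init(), T = 20,
                             max_iter = 100) {
  if (target_osr < 0 || target_osr > 1)
    stop("'target_osr' must lie in [0, 1]", call. = FALSE)
  r_hi <- scenario_run(0, e, h, fn, v, N0, T)   # most female-biased
  r_lo <- scenario_run(1, e, h, fn, v, N0, T)   # most male-biased
  if (abs(r_hi$osr - target_osr) <= tol) return(r_hi)
  if (abs(r_lo$osr - target_osr) <= tol) return(r_lo)
  if (target_osr > r_hi$osr || target_osr < r_lo$osr)
    stop(errorCondition(
      sprintf(paste0("target OSR %.4g is outside the range [%.4g, %.4g] ",
                     "attainable by the female harvest proportion alone"),
              target_osr, r_lo$osr, r_hi$osr),
      class = c("osr_range_error", "error"),
      range = c(min = r_lo$osr, max = r_hi$osr)))
  lo <- 0; hi <- 1   # osr is non-increasing in Hf
  res <- NULL
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    res <- scenario_run(mid, e, h, fn, v, N0, T)
    if (abs(res$osr - target_osr) <= tol) break
    if (res$osr > target_osr) lo <- mid else hi <- mid
  }
  if (abs(res$osr - target_osr) > tol)
    warning("bisection stopped after ", max_iter,
            " iterations with |osr - target| = ",
            format(abs(res$osr - target_osr)))
  res
}

#' Growth rate at a target equilibrium OSR
#'
#' Convenience wrapper around [solve_hf_for_osr()].  When the target
#' lies outside the range reachable by the female harvest lever (e.g.
#' extremely female-biased sex ratios, which the fixed male hunting
#' pressure caps), the harvest is held at the nearest boundary
#' (`Hf = 0` for targets above the range, `Hf = 1` below) and one of
#' two fallbacks is applied:
#' \describe{
#'   \item{`"boundary"` (default)}{run the boundary scenario as is,
#'     i.e. at the nearest attainable OSR; the achieved `osr` column
#'     shows how far it fell from the target.}
#'   \item{`"clamped"`}{additionally rescale the census to the imposed
#'     OSR each year (the clamped-OSR diagnostic mode of
#'     [project()]); this measures growth under a mating market held
#'     exactly at the target.}
#' }
#' The `mode` column records which route produced the result.
#'
#' @inheritParams solve_hf_for_osr
#' @param fallback Behaviour for unattainable targets; see Details.
#' @return One-row data frame `e`, `h`, `Hf`, `osr`, `lambda`, `mode`
#'   (`"solved"`, `"boundary"` or `"clamped"`).
#' @examples
#' lambda_at_osr(0.75, e = 0.6, h = 1)$lambda
#' @export
lambda_at_osr <- function(target_osr, e = NULL, h = 1, tol = 1e-4,
                          fn = NULL, v = wild_boar_rates(),
                          N0 = wild_boar_init(), T = 20,
                          fallback = c("boundary", "clamped")) {
  fallback <- match.arg(fallback)
  res <- tryCatch(
    cbind(solve_hf_for_osr(target_osr, e = e, h = h, tol = tol, fn = fn,
                           v = v, N0 = N0, T = T),
          mode = "solved"),
    osr_range_error = function(cond) {
      boundary_hf <- if (target_osr > cond$range[["max"]]) 0 else 1
      cbind(scenario_run(boundary_hf, e, h, fn, v, N0, T,
                         clamp_osr = if (fallback == "clamped")
                           target_osr else NULL),
            mode = fallback)
    })
  rownames(res) <- NULL
  res
}

#' Compare mating-function families at equal balanced-OSR efficiency
#'
#' Sweeps the harvest proportion for the minimum, harmonic-mean and
#' minharmonic families standardised to the same mating efficiency at
#' the balanced sex ratio, `e_std`: minimum with `p = e_std`, harmonic
#' with `p = 2 * e_std`, minharmonic with `e = e_std`.  Note that the
#' standardised harmonic function with `p > 1` violates the Pollak
#' bound and is included deliberately for comparison.
#'
#' @param e_std Common efficiency at balance (0.8 and 0.9 are the
#'   values used for the wild boar comparison).
#' @inheritParams sweep_hf
#' @return Long data frame with a `family` column ahead of the sweep
#'   columns.
#' @examples
#' cmp <- compare_functions(0.8, hf = seq(0, 1, by = 0.5))
#' @export
compare_functions <- function(e_std, h = 1,
                              hf = seq(0, 1, length.out = 101),
                              v = wild_boar_rates(),
                              N0 = wild_boar_init(), T = 20) {
  fns <- list(
    minimum     = mating_function("minimum", p = e_std),
    harmonic    = mating_function("harmonic", p = 2 * e_std),
    minharmonic = mating_function("minharmonic", e = e_std)
  )
  out <- do.call(rbind, lapply(names(fns), function(nm) {
    sw <- sweep_hf(h = h, hf = hf, fn = fns[[nm]], v = v, N0 = N0, T = T)
    cbind(family = nm, sw)
  }))
  rownames(out) <- NULL
  out
}
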