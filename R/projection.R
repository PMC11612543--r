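# Nonlinear two-sex size-structured projection.
#
# State: a census vector (fS, fM, fL, mS, mM, mL) of small/medium/large
# females and males, taken post-hunt and before births.  Each year the
# birth rates are recomputed from the current numbers of mature
# (medium + large) females and males through the mating system, the
# 6 x 6 projection matrix is reassembled and the state multiplied
# through.  All rates are degree-one homogeneous in the state, so the
# model is frequency-dependent: growth depends on sex/size structure,
# not abundance.

POP_CLASSES <- c("fS", "fM", "fL", "mS", "mM", "mL")

#' Sex- and size-specific vital rates
#'
#' Container for the annual vital rates of the size-structured two-sex
#' model: natural survival and hunting proportions per sex and size
#' class, size-class growth probabilities, postnatal survival and mean
#' litter sizes.  Within a year, survival acts over the non-hunting
#' period and hunting removes a proportion `H` of each class (an
#' individual escapes hunters with probability `1 - H`).
#'
#' `Hf`, the proportion of mature (medium and large, treated alike)
#' females killed by hunters, is the harvest-scenario variable and may
#' be left `NA` until a scenario sets it.
#'
#' @param SSf,SMf,SLf Natural survival of small/medium/large females.
#' @param SSm,SMm,SLm Natural survival of small/medium/large males.
#' @param HSf Proportion of small females killed by hunting.
#' @param Hf Proportion of medium and large females killed by hunting
#'   (scenario variable; may be `NA`).
#' @param HSm,HMm,HLm Proportions of small/medium/large males killed by
#'   hunting.
#' @param G_Mf,G_Lf Probability for a small (resp. medium) female to
#'   grow into the medium (resp. large) class over one year.
#' @param G_Mm,G_Lm Same for males.
#' @param G_juvMf,G_juvMm Probability for a juvenile female/male to be
#'   of medium size at the end of its first year.
#' @param s0 Postnatal survival of newborns.
#' @param K_M,K_L Mean number of juveniles produced by a medium/large
#'   female per litter.
#' @return An object of class `"vital_rates"` (a named list).
#' @seealso [wild_boar_rates()] for the built-in wild boar set.
#' @export
vital_rates <- function(SSf, SMf, SLf, HSf, Hf = NA_real_,
                        SSm, SMm, SLm, HSm, HMm, HLm,
                        G_Mf, G_Lf, G_Mm, G_Lm, G_juvMf, G_juvMm,
                        s0, K_M, K_L) {
  v <- list(SSf = SSf, SMf = SMf, SLf = SLf, HSf = HSf, Hf = Hf,
            SSm = SSm, SMm = SMm, SLm = SLm,
            HSm = HSm, HMm = HMm, HLm = HLm,
            G_Mf = G_Mf, G_Lf = G_Lf, G_Mm = G_Mm, G_Lm = G_Lm,
            G_juvMf = G_juvMf, G_juvMm = G_juvMm,
            s0 = s0, K_M = K_M, K_L = K_L)
  probs <- setdiff(names(v), c("K_M", "K_L"))
  for (nm in probs) {
    x <- v[[nm]]
    if (!is.numeric(x) || length(x) != 1L)
      stop("'", nm, "' must be a single number", call. = FALSE)
    if (!is.na(x) && (x < 0 || x > 1))
      stop("'", nm, "' must be a probability in [0, 1]", call. = FALSE)
    if (is.na(x) && nm != "Hf")
      stop("'", nm, "' must not be NA", call. = FALSE)
  }
  for (nm in c("K_M", "K_L"))
    if (!is.numeric(v[[nm]]) || length(v[[nm]]) != 1L || is.na(v[[nm]]) ||
        v[[nm]] < 0)
      stop("'", nm, "' must be a single non-negative number", call. = FALSE)
  structure(v, class = "vital_rates")
}

#' @export
print.vital_rates <- function(x, ...) {
  cat("<vital_rates>\n")
  print(unlist(x))
  invisible(x)
}

#' Population census vector
#'
#' Named numeric vector of abundances in the six sex-by-size classes,
#' in the fixed order `fS, fM, fL, mS, mM, mL`.  Abundances are
#' continuous (expected values).  Mature counts are derived as
#' `f = fM + fL` and `m = mM + mL`; small individuals are not sexually
#' mature.
#'
#' @param fS,fM,fL Small/medium/large female abundances.
#' @param mS,mM,mL Small/medium/large male abundances.
#' @return Named numeric vector of length 6.
#' @export
population_vector <- function(fS = 0, fM = 0, fL = 0,
                              mS = 0, mM = 0, mL = 0) {
  N <- c(fS = fS, fM = fM, fL = fL, mS = mS, mM = mM, mL = mL)
  as_population_vector(N)
}

as_population_vector <- function(N) {
  if (!is.numeric(N) || length(N) != 6L)
    stop("a population vector has six classes: ",
         paste(POP_CLASSES, collapse = ", "), call. = FALSE)
  if (is.null(names(N))) names(N) <- POP_CLASSES
  if (!all(POP_CLASSES %in% names(N)))
    stop("population vector must be named with ",
         paste(POP_CLASSES, collapse = ", "), call. = FALSE)
  N <- N[POP_CLASSES]
  if (any(is.na(N)) || any(N < 0))
    stop("abundances must be non-negative", call. = FALSE)
  N
}

mature_counts <- function(N) {
  c(f = unname(N[["fM"]] + N[["fL"]]), m = unname(N[["mM"]] + N[["mL"]]))
}

#' Size-structured birth functions
#'
#' Birth rates for the current census: expected juveniles per medium
#' female (`BfM`), per large female (`BfL`) and per mature male (`Bm`),
#' given the mating system and mating function.  With `f = fM + fL`
#' mature females, `m = mM + mL` mature males and `U` unions from the
#' system (harems under polygyny with harem size `h`),
#' \deqn{B_{fM} = K_M \, h U / f, \quad B_{fL} = K_L \, h U / f, \quad
#'       B_m = \frac{f_M K_M + f_L K_L}{f} \, h U / m,}
#' i.e. females of each size class breed with the common mating
#' probability \eqn{hU/f} and produce their class litter size, while a
#' male sires the class-weighted mean litter of each female in his
#' harem with mating probability \eqn{U/m}.  All three rates are zero
#' when either mature sex is absent.
#'
#' @param N A [population_vector()].
#' @param v A [vital_rates()] (only `K_M`, `K_L` are used here).
#' @param sys A [mating_system()].
#' @param fn A [mating_function()] or family name.
#' @return Named list with `BfM`, `BfL`, `Bm`.
#' @export
birth_functions <- function(N, v, sys, fn) {
  N <- as_population_vector(N)
  fm <- mature_counts(N)
  f <- fm[["f"]]; m <- fm[["m"]]
  if (f <= 0 || m <= 0) return(list(BfM = 0, BfL = 0, Bm = 0))
  U <- unions_system(m, f, sys, fn)
  p_female <- mated_females(U, sys) / f        # probability a female mates
  Kbar <- (N[["fM"]] * v$K_M + N[["fL"]] * v$K_L) / f
  list(BfM = v$K_M * p_female,
       BfL = v$K_L * p_female,
       Bm  = Kbar * mated_females(U, sys) / m)
}

#' Assemble the 6 x 6 two-sex projection matrix
#'
#' Builds the year-`t` projection matrix from the current census (which
#' sets the birth rates through [birth_functions()]) and the vital
#' rates.  Fertility entries carry the factor `0.5 * 0.5 * s0`: the
#' first 0.5 is the balanced birth sex ratio, the second halves the
#' birth rates so that each offspring -- produced jointly by a mother
#' and a father -- is counted once, and `s0` is postnatal survival.
#' Newborns then either stay small (probability `1 - G_juvM.`,
#' surviving as small) or recruit directly to the medium class
#' (probability `G_juvM.`, surviving as medium).  There are no
#' two-class jumps for grown individuals.
#'
#' @inheritParams birth_functions
#' @return A 6 x 6 matrix with rows/columns `fS, fM, fL, mS, mM, mL`.
#' @export
projection_matrix <- function(N, v, sys, fn) {
  stopifnot(inherits(v, "vital_rates"))
  if (is.na(v$Hf))
    stop("'Hf' (mature-female hunting proportion) is unset; ",
         "assign it before projecting", call. = FALSE)
  B <- birth_functions(N, v, sys, fn)
  # 0.5 (birth sex ratio) * 0.5 (offspring counted once) * s0
  fert <- 0.5 * 0.5 * v$s0
  A <- matrix(0, 6, 6, dimnames = list(POP_CLASSES, POP_CLASSES))

  sSf <- v$SSf * (1 - v$HSf)   # annual survival incl. hunting, by class
  sMf <- v$SMf * (1 - v$Hf)
  sLf <- v$SLf * (1 - v$Hf)
  sSm <- v$SSm * (1 - v$HSm)
  sMm <- v$SMm * (1 - v$HMm)
  sLm <- v$SLm * (1 - v$HLm)

  # female rows
  A["fS", "fS"] <- (1 - v$G_Mf) * sSf
  A["fS", "fM"] <- fert * B$BfM * (1 - v$G_juvMf) * sSf
  A["fS", "fL"] <- fert * B$BfL * (1 - v$G_juvMf) * sSf
  A["fS", "mM"] <- A["fS", "mL"] <- fert * B$Bm * (1 - v$G_juvMf) * sSf
  A["fM", "fS"] <- v$G_Mf * sMf
  A["fM", "fM"] <- ((1 - v$G_Lf) + fert * B$BfM * v$G_juvMf) * sMf
  A["fM", "fL"] <- fert * B$BfL * v$G_juvMf * sMf
  A["fM", "mM"] <- A["fM", "mL"] <- fert * B$Bm * v$G_juvMf * sMf
  A["fL", "fM"] <- v$G_Lf * sLf
  A["fL", "fL"] <- sLf

  # male rows
  A["mS", "fM"] <- fert * B$BfM * (1 - v$G_juvMm) * sSm
  A["mS", "fL"] <- fert * B$BfL * (1 - v$G_juvMm) * sSm
  A["mS", "mS"] <- (1 - v$G_Mm) * sSm
  A["mS", "mM"] <- A["mS", "mL"] <- fert * B$Bm * (1 - v$G_juvMm) * sSm
  A["mM", "fM"] <- fert * B$BfM * v$G_juvMm * sMm
  A["mM", "fL"] <- fert * B$BfL * v$G_juvMm * sMm
  A["mM", "mS"] <- v$G_Mm * sMm
  A["mM", "mM"] <- ((1 - v$G_Lm) + fert * B$Bm * v$G_juvMm) * sMm
  A["mM", "mL"] <- fert * B$Bm * v$G_juvMm * sMm
  A["mL", "mM"] <- v$G_Lm * sLm
  A["mL", "mL"] <- sLm

  A
}

clamp_to_osr <- function(N, target) {
  fm <- mature_counts(N)
  f <- fm[["f"]]; m <- fm[["m"]]
  if (f + m <= 0) return(N)
  # rescale one whole sex downwards so that the mature OSR equals the
  # target; never inflate a sex (injecting individuals would corrupt
  # the growth-rate estimate)
  cur <- f / (f + m)
  if (abs(cur - target) < .Machine$double.eps) return(N)
  if (cur < target) {
    if (target >= 1 || f <= 0) return(N)
    k <- f * (1 - target) / (target * m)
    N[c("mS", "mM", "mL")] <- k * N[c("mS", "mM", "mL")]
  } else {
    if (target <= 0 || m <= 0) return(N)
    k <- m * target / ((1 - target) * f)
    N[c("fS", "fM", "fL")] <- k * N[c("fS", "fM", "fL")]
  }
  N
}

#' Project a two-sex population
#'
#' Iterates the nonlinear model \eqn{N_{t+1} = A(N_t) N_t} for
#' `T + 1` steps from `N0`, reassembling the matrix each year from the
#' current census.  The asymptotic growth rate is approximated by the
#' ratio of successive totals after the transients have dissipated,
#' \eqn{\lambda \approx \lambda_T = N_{tot}(T+1) / N_{tot}(T)}, and the
#' equilibrium operational sex ratio as
#' \eqn{f_T / (m_T + f_T)} from the mature counts at time `T`.
#'
#' `clamp_osr` enables a diagnostic mode for sex-ratio targets outside
#' the range reachable by harvest alone: at every census the more
#' abundant sex relative to the target is scaled down (all its size
#' classes alike) so the mature OSR equals `clamp_osr` before the year
#' is projected.  The suppressed sex is then a vanishing share of the
#' total, so \eqn{\lambda_T} measures the growth of the dominant sex
#' under the imposed mating market.
#'
#' With `conv_tol` set, the iteration continues past `T` (up to
#' `max_steps`) until \eqn{|\lambda_t - \lambda_{t-1}|} falls below the
#' tolerance; the summary then reports the extended horizon.
#'
#' @inheritParams birth_functions
#' @param N0 Initial census, a [population_vector()] (not all zero).
#' @param T Projection horizon in years (default 20).
#' @param clamp_osr Optional OSR in (0, 1) to impose at each census.
#' @param conv_tol Optional convergence tolerance on successive
#'   \eqn{\lambda_t} for the extended mode.
#' @param max_steps Step cap for the extended mode.
#' @return An object of class `"two_sex_projection"`: a list with
#'   `trajectory` (data frame with `t`, the six classes, `Ntot`,
#'   `OSR`), `lambda`, `osr`, `T`, `converged`
#'   (\eqn{|\lambda_T - \lambda_{T-1}| < 10^{-4}}), `lambda_diff` and
#'   `extinct`.
#' @examples
#' v <- wild_boar_rates(Hf = 0.3)
#' pr <- project(wild_boar_init(), v, mating_system(),
#'               mating_function("minharmonic", e = 0.8))
#' pr$lambda
#' pr$osr
#' @export
project <- function(N0, v, sys = mating_system(), fn, T = 20,
                    clamp_osr = NULL, conv_tol = NULL, max_steps = 500) {
  N0 <- as_population_vector(N0)
  if (sum(N0) <= 0)
    stop("'N0' must contain at least one individual", call. = FALSE)
  if (!is.numeric(T) || length(T) != 1L || T < 1)
    stop("'T' must be a positive number of years", call. = FALSE)
  T <- as.integer(T)
  if (!is.null(clamp_osr) &&
      (clamp_osr <= 0 || clamp_osr >= 1))
    stop("'clamp_osr' must lie strictly inside (0, 1)", call. = FALSE)

  steps <- T + 1L
  traj <- matrix(NA_real_, steps + 1L, 6,
                 dimnames = list(NULL, POP_CLASSES))
  N <- if (is.null(clamp_osr)) N0 else clamp_to_osr(N0, clamp_osr)
  traj[1L, ] <- N
  for (t in seq_len(steps)) {
    if (sum(N) <= 0) {
      traj[(t + 1L):(steps + 1L), ] <- 0
      break
    }
    A <- projection_matrix(N, v, sys, fn)
    N <- drop(A %*% N)
    names(N) <- POP_CLASSES
    if (!is.null(clamp_osr)) N <- clamp_to_osr(N, clamp_osr)
    traj[t + 1L, ] <- N
  }

  # optional extension until lambda settles
  if (!is.null(conv_tol)) {
    lam_prev <- NA_real_
    repeat {
      ntot <- rowSums(traj)
      n <- nrow(traj)
      lam <- if (ntot[n - 1L] > 0) ntot[n] / ntot[n - 1L] else 0
      if (!is.na(lam_prev) && abs(lam - lam_prev) < conv_tol) break
      if (n - 1L >= max_steps || sum(traj[n, ]) <= 0) break
      lam_prev <- lam
      A <- projection_matrix(traj[n, ], v, sys, fn)
      N <- drop(A %*% traj[n, ])
      names(N) <- POP_CLASSES
      if (!is.null(clamp_osr)) N <- clamp_to_osr(N, clamp_osr)
      traj <- rbind(traj, N)
    }
    T <- nrow(traj) - 2L
  }

  ntot <- rowSums(traj)
  lamT <- if (ntot[T + 1L] > 0) ntot[T + 2L] / ntot[T + 1L] else 0
  lam_prev <- if (T >= 1L && ntot[T] > 0) ntot[T + 1L] / ntot[T] else 0
  fm <- mature_counts(traj[T + 1L, ])
  osr <- if (sum(fm) > 0) fm[["f"]] / sum(fm) else NA_real_
  out <- list(
    trajectory = data.frame(t = 0:(nrow(traj) - 1L), traj,
                            Ntot = ntot,
                            OSR = ifelse(
                              rowSums(traj[, c("fM", "fL", "mM", "mL"),
                                           drop = FALSE]) > 0,
                              (traj[, "fM"] + traj[, "fL"]) /
                                rowSums(traj[, c("fM", "fL", "mM", "mL"),
                                             drop = FALSE]),
                              NA_real_)),
    lambda = lamT,
    osr = osr,
    T = T,
    lambda_diff = abs(lamT - lam_prev),
    converged = is.finite(lamT) && abs(lamT - lam_prev) < 1e-4,
    extinct = ntot[T + 1L] <= 0
  )
  class(out) <- "two_sex_projection"
  out
}

#' @export
print.two_sex_projection <- function(x, ...) {
  cat(sprintf(
    "<two_sex_projection: T = %d, lambda_T = %.4f, OSR_T = %s%s>\n",
    x$T, x$lambda,
    if (is.na(x$osr)) "NA" else sprintf("%.4f", x$osr),
    if (x$extinct) ", extinct" else ""))
  invisible(x)
}

#' @export
as.data.frame.two_sex_projection <- function(x, ...) x$trajectory

#' Growth rate and equilibrium OSR of a projection
#'
#' Convenience accessor returning \eqn{\lambda_T}, the equilibrium
#' operational sex ratio, and the convergence diagnostic
#' \eqn{|\lambda_T - \lambda_{T-1}|}.
#'
#' @param x A `"two_sex_projection"`.
#' @return Named numeric vector `lambda`, `osr`, `lambda_diff`.
#' @export
lambda_and_osr <- function(x) {
  stopifnot(inherits(x, "two_sex_projection"))
  c(lambda = x$lambda, osr = x$osr, lambda_diff = x$lambda_diff)
}
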