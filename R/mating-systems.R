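#' Mating-system configuration
#'
#' A mating system couples a monogamous mating function to a population
#' in which one sex may hold several mates.  Under polygyny each
#' breeding male mates with `harem_size` females (the mean harem size
#' h); under polyandry each breeding female mates with `harem_size`
#' males.  Monogamy is the special case h = 1 of either.  A single
#' population-mean harem size is used; within-population variance in h
#' is not modelled.
#'
#' @param system One of `"monogamy"`, `"polygyny"`, `"polyandry"`.
#' @param harem_size Mean number of mates per individual of the
#'   polygamous sex; must be >= 1, and exactly 1 under monogamy.
#'   Non-integer values are allowed (expected values).
#' @return An object of class `"mating_system"`.
#' @examples
#' mating_system("polygyny", harem_size = 4)
#' mating_system()  # monogamy
#' @export
mating_system <- function(system = c("monogamy", "polygyny", "polyandry"),
                          harem_size = 1) {
  system <- match.arg(system)
  if (!is.numeric(harem_size) || length(harem_size) != 1L ||
      is.na(harem_size) || harem_size < 1)
    stop("'harem_size' must be a single number >= 1", call. = FALSE)
  if (system == "monogamy" && harem_size != 1)
    stop("monogamy implies harem_size = 1", call. = FALSE)
  structure(list(system = system, harem_size = harem_size),
            class = "mating_system")
}

#' @export
format.mating_system <- function(x, ...) {
  if (x$system == "monogamy") "<mating_system: monogamy>"
  else sprintf("<mating_system: %s (harem size %g)>", x$system, x$harem_size)
}

#' @export
print.mating_system <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Unions under polygyny and polyandry
#'
#' A monogamous mating function U extends to polygyny with mean harem
#' size h by treating each harem as the "encounter" of one male with h
#' females: the number of harems is \eqn{U_{pg}(m, f, h) = U(m, f/h)}.
#' Polyandry is the sex mirror, \eqn{U(m/h', f)} unions each joining
#' one female with h' males.  Both reduce to monogamy at h = 1.
#'
#' The harem formulation automatically makes a male already holding a
#' harem of h females unavailable to further females (and mirrored for
#' polyandry); no additional bookkeeping is applied.
#'
#' @param m,f Non-negative counts of available males and females.
#' @param h,h_prime Mean harem size (>= 1).
#' @param fn A [mating_function()] or family name (the monogamous
#'   function being extended).
#' @return Expected number of harems (polygyny) or unions (polyandry).
#' @examples
#' fn <- mating_function("minharmonic", e = 0.9)
#' unions_polygynous(100, 100, 4, fn)   # 25 harems, all females mated
#' unions_polyandrous(100, 25, 4, fn)   # the sex mirror
#' @export
unions_polygynous <- function(m, f, h, fn) {
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h < 1)
    stop("'h' must be a single number >= 1", call. = FALSE)
  unions(m, f / h, fn)
}

#' @rdname unions_polygynous
#' @export
unions_polyandrous <- function(m, f, h_prime, fn) {
  if (!is.numeric(h_prime) || length(h_prime) != 1L || is.na(h_prime) ||
      h_prime < 1)
    stop("'h_prime' must be a single number >= 1", call. = FALSE)
  unions(m / h_prime, f, fn)
}

#' Unions under an arbitrary mating system
#'
#' Dispatches [unions()], [unions_polygynous()] or
#' [unions_polyandrous()] according to the system configuration.
#'
#' @inheritParams unions_polygynous
#' @param sys A [mating_system()].
#' @return Expected number of unions/harems.
#' @export
unions_system <- function(m, f, sys, fn) {
  stopifnot(inherits(sys, "mating_system"))
  switch(sys$system,
    monogamy  = unions(m, f, fn),
    polygyny  = unions_polygynous(m, f, sys$harem_size, fn),
    polyandry = unions_polyandrous(m, f, sys$harem_size, fn)
  )
}

# Expected number of mated females implied by U unions under 'sys':
# each harem holds h females under polygyny, one female otherwise.
mated_females <- function(U, sys) {
  if (sys$system == "polygyny") sys$harem_size * U else U
}

#' Birth rates per available female and per available male
#'
#' Expected offspring attributed to each available individual, given a
#' mean litter size `K` per mated female.  Under polygyny with harem
#' size h, a mated female produces K offspring with probability
#' \eqn{h U_{pg} / f} of being in a harem, and a male sires the K
#' offspring of each of the h females in his harem with mating
#' probability \eqn{U_{pg} / m}:
#' \deqn{B_f = K h U_{pg}(m, f, h) / f, \qquad
#'       B_m = K h U_{pg}(m, f, h) / m.}
#' Both sexes account for the same offspring total,
#' \eqn{f B_f = m B_m}.  An absent sex contributes a zero rate.
#'
#' @inheritParams unions_system
#' @param K Mean number of offspring produced by a mated female
#'   (>= 0).
#' @return A list of class `"birth_rates"` with elements `per_female`
#'   and `per_male`.
#' @examples
#' fn <- mating_function("minharmonic", e = 0.9)
#' birth_rates(100, 100, mating_system("polygyny", 4), fn, K = 5)
#' @export
birth_rates <- function(m, f, sys, fn, K) {
  stopifnot(inherits(sys, "mating_system"))
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K < 0)
    stop("'K' must be a single non-negative number", call. = FALSE)
  U <- unions_system(m, f, sys, fn)
  total <- K * mated_females(U, sys)
  structure(list(
    per_female = ifelse(f > 0, total / f, 0),
    per_male   = ifelse(m > 0, total / m, 0)
  ), class = "birth_rates")
}
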