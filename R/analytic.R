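# Residual of the implicit internal-equilibrium relation:
#   p (1 + r (S/2 + q(1-S)) / (S/2 + p(1-S))) - 1 = 0.
# Zero exactly where the allele-frequency change vanishes for Y > 0.
.eq_implicit_residual <- function(p, S, r) {
  q <- 1 - p
  p * (1 + r * (S / 2 + q * (1 - S)) / (S / 2 + p * (1 - S))) - 1
}

# The printed closed-form radical for the internal equilibrium; 0/0 at r = 1
# and at S = 1. Retained as an independent cross-check of the quadratic route.
.eq_explicit_radical <- function(S, r) {
  disc <- (S - 2)^2 * (1 + r^2) + 2 * r * (S^2 + 4 * S - 4)
  (S * (r - 3) + 2 - 2 * r + sqrt(disc)) / (4 * (r - 1) * (S - 1))
}

#' Internal (unstable) equilibrium allele frequency
#'
#' Solves for the interior allele-frequency equilibrium of the monoecious
#' model, which depends only on the selfing rate `S` and the penetrance
#' ratio r = `k1/k2`. Clearing denominators in the implicit equilibrium
#' relation gives the quadratic
#' `(1-S)(1-r) p^2 + (S(1+r)/2 + (1-S)(r-1)) p - S/2 = 0`,
#' which has exactly one root in `(0, 1)` whenever `S > 0` and the ratio
#' differs from 1.
#' The returned root is always verified against the implicit relation
#' (residual below `1e-10`), with a bracketed root search as fallback.
#'
#' Special cases: r = 1 with `S > 0` returns the symmetric equilibrium
#' `1/2`; `S = 1` returns the limit `1/(1+r)`; `S = 0` (with r away from 1) has no
#' interior equilibrium — the more penetrant allele always sweeps — and
#' `NA` is returned.
#'
#' @param S Selfing rate in `[0, 1]`.
#' @param r Penetrance ratio `k1/k2 > 0`.
#' @return The equilibrium frequency in `(0, 1)`, or `NA` when no interior
#'   equilibrium exists.
#' @examples
#' internal_equilibrium_p(S = 0.6, r = 1.8)  # ~0.28
#' @export
internal_equilibrium_p <- function(S, r) {
  S <- .check_unit(S, "S")
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0) {
    abort("`r` must be a single positive number.", class = "medeadyn_domain_error")
  }
  if (r == 1) {
    if (S == 0) {
      inform("S = 0 with r = 1: allele frequency never changes; every p is an equilibrium.")
      return(NA_real_)
    }
    return(0.5)
  }
  if (S == 0) {
    inform("No interior equilibrium at S = 0 with r != 1: the more penetrant allele always sweeps.")
    return(NA_real_)
  }
  if (S == 1) return(1 / (1 + r))
  a <- (1 - S) * (1 - r)
  b <- S * (1 + r) / 2 + (1 - S) * (r - 1)
  cc <- -S / 2
  disc <- b^2 - 4 * a * cc
  roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
  p_hat <- roots[roots > 0 & roots < 1][1]
  if (is.na(p_hat) || abs(.eq_implicit_residual(p_hat, S, r)) > 1e-10) {
    # fall back to bracketed root-finding on the implicit relation
    f <- function(p) .eq_implicit_residual(p, S, r)
    p_hat <- uniroot(f, c(1e-15, 1 - 1e-15), tol = 1e-14)$root
  }
  p_hat
}

#' Equilibrium heterozygosity at the internal equilibrium
#'
#' At a fixed allele frequency `p_hat`, the heterozygosity recursion has a
#' fixed point solving `(K/2) Y^2 - (1 - S/2) Y + 2 (1-S) p q = 0`, where
#' `K = k1 (S/2 + q(1-S)) + k2 (S/2 + p(1-S))` is the composite selection
#' intensity. The smaller quadratic root (the stable fixed point of the
#' one-dimensional heterozygosity map) is returned; both roots are computed
#' and the returned one is feasibility-checked on the genotype simplex.
#'
#' @param S Selfing rate.
#' @param k1,k2 Penetrances (`k1 + k2 > 0`).
#' @param p_hat Allele frequency in `(0, 1)`, typically from
#'   [internal_equilibrium_p()].
#' @return The equilibrium heterozygosity in `[0, 1]`.
#' @examples
#' p <- internal_equilibrium_p(0.6, 1.8)
#' equilibrium_heterozygosity(0.6, 0.9, 0.5, p)  # ~0.27
#' @export
equilibrium_heterozygosity <- function(S, k1, k2, p_hat) {
  S <- .check_unit(S, "S")
  k1 <- .check_unit(k1, "k1")
  k2 <- .check_unit(k2, "k2")
  p_hat <- .check_unit(p_hat, "p_hat", open_lo = TRUE, open_hi = TRUE)
  q_hat <- 1 - p_hat
  K <- k1 * (S / 2 + q_hat * (1 - S)) + k2 * (S / 2 + p_hat * (1 - S))
  if (K < 1e-14) {
    # no killing: the fixed point is the mixed-mating heterozygosity
    return(2 * (1 - S) * p_hat * q_hat / (1 - S / 2))
  }
  disc <- (1 - S / 2)^2 - 4 * (1 - S) * p_hat * q_hat * K
  stopifnot("heterozygosity discriminant must be non-negative" = disc > -1e-12)
  disc <- max(disc, 0)
  roots <- c((1 - S / 2) - sqrt(disc), (1 - S / 2) + sqrt(disc)) / K
  feasible <- roots >= 0 & roots <= 1 &
    (p_hat - roots / 2) >= -1e-12 & (q_hat - roots / 2) >= -1e-12
  if (!any(feasible)) {
    abort("No feasible equilibrium heterozygosity root (should not occur for valid inputs).",
          class = "medeadyn_domain_error")
  }
  roots[feasible][1]
}

#' Critical selfing rate for invasion
#'
#' For an invading element at frequency `p` with penetrance ratio r above 1
#' relative to the resident, the selfing rate above which the invader is
#' eliminated:
#' `S_C = 2 p (1-p) (1-r) / (2 p^2 r - 2 p^2 - p r + 3 p - 1)`.
#' Below `S_C` the invader sweeps to fixation; above it, the resident
#' excludes the invader.
#'
#' A value outside `[0, 1]` means no threshold exists in the admissible
#' selfing range (e.g. a majority invader fixes at any selfing rate); `NA`
#' is then returned with the raw value attached as attribute `"raw"`.
#'
#' @param p Invader allele frequency in `(0, 1)`.
#' @param r Penetrance ratio invader/resident.
#' @return The critical selfing rate, or `NA` (attribute `"raw"`) when the
#'   formula value falls outside `[0, 1]`.
#' @examples
#' critical_selfing(0.2, 1.8)   # ~0.37
#' critical_selfing(0.01, 50)   # ~0.66
#' @export
critical_selfing <- function(p, r) {
  p <- .check_unit(p, "p", open_lo = TRUE, open_hi = TRUE)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0) {
    abort("`r` must be a single positive number.", class = "medeadyn_domain_error")
  }
  if (r == 1) {
    inform("r = 1: the threshold formula vanishes identically (equally penetrant elements); returning 0.")
    return(0)
  }
  num <- 2 * p * (1 - p) * (1 - r)
  den <- 2 * p^2 * r - 2 * p^2 - p * r + 3 * p - 1
  if (den == 0 && num == 0) {
    abort(sprintf("Critical-selfing formula is indeterminate (0/0) at p = %g, r = %g.", p, r),
          class = "medeadyn_domain_error")
  }
  S_C <- num / den
  if (!is.finite(S_C) || S_C < 0 || S_C > 1) {
    warn(sprintf("No critical selfing rate in [0, 1] for p = %g, r = %g (raw value %.6g): the invader's fate does not change with S.", p, r, S_C))
    return(structure(NA_real_, raw = S_C))
  }
  S_C
}

#' Critical penetrance ratio for invasion
#'
#' For an invader at frequency `p` in a population with selfing rate `S`,
#' the minimum penetrance ratio (invader relative to resident) needed to
#' sweep:
#' `r_C = (S + 2 p (1-p)(1-S) - S p) / (2 p (1-p)(1-S) + S p)`.
#' Under obligate outcrossing (`S = 0`) this is 1: any more-penetrant
#' element invades.
#'
#' @param p Invader allele frequency in `(0, 1)`.
#' @param S Selfing rate in `[0, 1]`.
#' @return The critical ratio `r_C`.
#' @examples
#' critical_ratio(0.01, 0.9)  # ~81.3
#' @export
critical_ratio <- function(p, S) {
  p <- .check_unit(p, "p", open_lo = TRUE, open_hi = TRUE)
  S <- .check_unit(S, "S")
  den <- 2 * p * (1 - p) * (1 - S) + S * p
  if (den <= 0) {
    abort(sprintf("Denominator of the critical-ratio formula vanishes at p = %g, S = %g.", p, S),
          class = "medeadyn_domain_error")
  }
  (S + 2 * p * (1 - p) * (1 - S) - S * p) / den
}

#' Full internal-equilibrium summary
#'
#' Computes the unstable interior equilibrium of the monoecious model:
#' allele frequency `p_hat` (from `S` and r = `k1/k2`), equilibrium
#' heterozygosity `Y_hat`, the composite selection intensity `K`, and the
#' residual of the implicit equilibrium relation at the returned root.
#'
#' @param S Selfing rate.
#' @param k1,k2 Penetrances (`k2 > 0` so the ratio is defined).
#' @return An object of class `drive_equilibrium` with elements `p_hat`,
#'   `Y_hat`, `K`, `residual_eq_implicit`, `stability` (always
#'   `"unstable"`), and the inputs. `tidy()` and `glance()` methods return
#'   one-row tibbles.
#' @examples
#' eq <- equilibrium(S = 0.6, k1 = 0.9, k2 = 0.5)
#' tidy(eq)
#' @export
equilibrium <- function(S, k1, k2) {
  S <- .check_unit(S, "S")
  k1 <- .check_unit(k1, "k1")
  k2 <- .check_unit(k2, "k2", open_lo = TRUE)
  r <- k1 / k2
  p_hat <- internal_equilibrium_p(S, r)
  if (is.na(p_hat)) {
    out <- list(S = S, k1 = k1, k2 = k2, r = r, p_hat = NA_real_,
                Y_hat = NA_real_, K = NA_real_,
                residual_eq_implicit = NA_real_, stability = NA_character_)
    return(structure(out, class = "drive_equilibrium"))
  }
  Y_hat <- equilibrium_heterozygosity(S, k1, k2, p_hat)
  q_hat <- 1 - p_hat
  K <- k1 * (S / 2 + q_hat * (1 - S)) + k2 * (S / 2 + p_hat * (1 - S))
  structure(
    list(S = S, k1 = k1, k2 = k2, r = r, p_hat = p_hat, Y_hat = Y_hat,
         K = K, residual_eq_implicit = .eq_implicit_residual(p_hat, S, r),
         stability = "unstable"),
    class = "drive_equilibrium")
}

#' @export
print.drive_equilibrium <- function(x, ...) {
  if (is.na(x$p_hat)) {
    cat(sprintf("<drive_equilibrium> no interior equilibrium (S = %g, r = %g)\n",
                x$S, x$r))
  } else {
    cat(sprintf("<drive_equilibrium> p_hat = %.6g, Y_hat = %.6g (unstable; S = %g, r = %g, K = %.6g)\n",
                x$p_hat, x$Y_hat, x$S, x$r, x$K))
  }
  invisible(x)
}

#' @rdname equilibrium
#' @param x A `drive_equilibrium` object.
#' @param ... Unused.
#' @export
tidy.drive_equilibrium <- function(x, ...) {
  tibble(S = x$S, k1 = x$k1, k2 = x$k2, r = x$r,
         p_hat = x$p_hat, Y_hat = x$Y_hat, K = x$K,
         stability = x$stability)
}

#' @rdname equilibrium
#' @export
glance.drive_equilibrium <- function(x, ...) {
  tibble(p_hat = x$p_hat, Y_hat = x$Y_hat, K = x$K,
         residual_eq_implicit = x$residual_eq_implicit)
}
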