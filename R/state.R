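.check_simplex <- function(v, names, tol = 1e-8) {
  if (!is.numeric(v) || length(v) != 3L || anyNA(v)) {
    abort(sprintf("(%s) must be three non-missing numbers.",
                  paste(names, collapse = ", ")),
          class = "medeadyn_domain_error")
  }
  if (any(v < -1e-12) || any(v > 1 + 1e-12)) {
    abort(sprintf("(%s) must each lie in [0, 1]; got (%s).",
                  paste(names, collapse = ", "),
                  paste(signif(v, 6), collapse = ", ")),
          class = "medeadyn_domain_error")
  }
  if (abs(sum(v) - 1) > tol) {
    abort(sprintf("(%s) must sum to 1 (tolerance %g); got sum %.15g.",
                  paste(names, collapse = ", "), tol, sum(v)),
          class = "medeadyn_domain_error")
  }
  unname(pmin(pmax(v / sum(v), 0), 1))
}

#' Genotype frequencies in a monoecious population
#'
#' A point on the genotype simplex: frequencies of M1/M1, M1/M2, and M2/M2,
#' which must sum to 1. The M1 allele frequency `p = X + Y/2` is derived.
#'
#' @param X,Y,Z Frequencies of M1M1, M1M2 (heterozygotes), and M2M2.
#' @return An object of class `genotype_state`: a named numeric vector
#'   `c(X, Y, Z)`.
#' @seealso [state_from_pq()] to construct from allele frequency and
#'   heterozygosity; [allele_frequency()].
#' @examples
#' genotype_state(0.25, 0.5, 0.25)
#' @export
genotype_state <- function(X, Y, Z) {
  v <- .check_simplex(c(X, Y, Z), c("X", "Y", "Z"))
  structure(c(X = v[1], Y = v[2], Z = v[3]), class = "genotype_state")
}

#' Construct a genotype state from allele frequency and heterozygosity
#'
#' Maps the `(p, Y)` coordinates used by the compact recursions back to the
#' genotype simplex: `X = p - Y/2`, `Z = 1 - X - Y`. Both implied homozygote
#' frequencies must be non-negative.
#'
#' @param p M1 allele frequency in `[0, 1]`.
#' @param Y Heterozygote frequency; requires `Y/2 <= min(p, 1 - p)`.
#' @return A [genotype_state()].
#' @export
state_from_pq <- function(p, Y = 0) {
  p <- .check_unit(p, "p")
  Y <- .check_unit(Y, "Y")
  X <- p - Y / 2
  Z <- 1 - p - Y / 2
  if (min(X, Z) < -1e-12) {
    abort(sprintf("Heterozygosity Y = %g is infeasible at p = %g (implies a negative homozygote frequency).", Y, p),
          class = "medeadyn_domain_error")
  }
  genotype_state(max(X, 0), Y, max(Z, 0))
}

#' Sex-specific genotype frequencies under androdioecy
#'
#' Hermaphrodite and male genotype-frequency triples; each sex's frequencies
#' form a simplex. Males arise only from outcrossing, so when the selfing
#' rate is 1 the male triple may be all `NA` (no males exist).
#'
#' @param Xh,Yh,Zh Hermaphrodite frequencies of M1M1, M1M2, M2M2.
#' @param Xm,Ym,Zm Male frequencies; may all be `NA` (male pool absent).
#' @return An object of class `sex_state`: named numeric vector of length 6.
#' @examples
#' sex_state(0.04, 0, 0.96, 0.04, 0, 0.96)
#' @export
sex_state <- function(Xh, Yh, Zh, Xm, Ym, Zm) {
  h <- .check_simplex(c(Xh, Yh, Zh), c("Xh", "Yh", "Zh"))
  m <- c(Xm, Ym, Zm)
  if (!all(is.na(m))) m <- .check_simplex(m, c("Xm", "Ym", "Zm"))
  structure(c(Xh = h[1], Yh = h[2], Zh = h[3], Xm = m[1], Ym = m[2], Zm = m[3]),
            class = "sex_state")
}

#' M1 allele frequency of a state
#'
#' For a monoecious state returns `p = X + Y/2`; for a sex-structured state
#' returns the named pair `(ph, pm)`.
#'
#' @param state A [genotype_state()] or [sex_state()].
#' @return A frequency, or a named length-2 vector for `sex_state`.
#' @examples
#' allele_frequency(genotype_state(0.1, 0.36, 0.54))
#' @export
allele_frequency <- function(state) {
  UseMethod("allele_frequency")
}

#' @export
allele_frequency.genotype_state <- function(state) {
  unname(state[["X"]] + state[["Y"]] / 2)
}

#' @export
allele_frequency.sex_state <- function(state) {
  c(ph = unname(state[["Xh"]] + state[["Yh"]] / 2),
    pm = unname(state[["Xm"]] + state[["Ym"]] / 2))
}

#' Sex-weighted population allele frequency
#'
#' Collapses the two sex-specific allele frequencies of an androdioecious
#' state to a single population value. The weighting rule is a reporting
#' choice (the model itself does not track the population sex ratio), so the
#' rule used is always recorded as an attribute of the result.
#'
#' @param state A [sex_state()].
#' @param rule `"equal"` (default), `"hermaphrodite_only"`, or `"custom"`.
#' @param weights For `rule = "custom"`, non-negative weights `c(wh, wm)`
#'   (normalized internally).
#' @return The weighted allele frequency, with attribute `"rule"`.
#' @examples
#' s <- sex_state(0.1, 0.2, 0.7, 0.2, 0.4, 0.4)
#' population_mean_p(s, "custom", c(0.75, 0.25))
#' @export
population_mean_p <- function(state,
                              rule = c("equal", "hermaphrodite_only", "custom"),
                              weights = NULL) {
  stopifnot(inherits(state, "sex_state"))
  rule <- match.arg(rule)
  p <- allele_frequency(state)
  w <- switch(rule,
    equal = c(0.5, 0.5),
    hermaphrodite_only = c(1, 0),
    custom = {
      if (is.null(weights) || length(weights) != 2L || any(weights < 0) ||
          sum(weights) <= 0) {
        abort("`weights` must be two non-negative numbers with a positive sum.",
              class = "medeadyn_domain_error")
      }
      weights / sum(weights)
    })
  if (is.na(p[["pm"]])) {
    # no males in the population (S = 1): the hermaphrodite pool is everyone
    w <- c(1, 0)
    p[["pm"]] <- 0
  }
  structure(unname(sum(w * p)), rule = rule)
}

#' @export
print.genotype_state <- function(x, ...) {
  cat(sprintf("<genotype_state> X = %.6g, Y = %.6g, Z = %.6g (p = %.6g)\n",
              x[["X"]], x[["Y"]], x[["Z"]], allele_frequency(x)))
  invisible(x)
}

#' @export
print.sex_state <- function(x, ...) {
  p <- allele_frequency(x)
  cat(sprintf("<sex_state> herm (%.4g, %.4g, %.4g) ph = %.4g | male (%.4g, %.4g, %.4g) pm = %.4g\n",
              x[["Xh"]], x[["Yh"]], x[["Zh"]], p[["ph"]],
              x[["Xm"]], x[["Ym"]], x[["Zm"]], p[["pm"]]))
  invisible(x)
}
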