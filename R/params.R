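.check_unit <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name), class = "medeadyn_domain_error")
  }
  bad <- x < lo || x > hi || (open_lo && x == lo) || (open_hi && x == hi)
  if (bad) {
    abort(sprintf("`%s` = %g is outside its domain %s%g, %g%s.",
                  name, x, if (open_lo) "(" else "[", lo, hi,
                  if (open_hi) ")" else "]"),
          class = "medeadyn_domain_error")
  }
  as.numeric(x)
}

.check_element <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || !x %in% c("medea", "peel", "none")) {
    abort(sprintf("`%s` must be one of \"medea\", \"peel\", \"none\".", name),
          class = "medeadyn_domain_error")
  }
  x
}

#' Model parameters for the monoecious toxin-antidote model
#'
#' Bundles the selfing rate and the killing penetrances of the two antagonistic
#' alleles at one locus. Allele M1 kills M2/M2 homozygous progeny of exposed
#' broods with penetrance `k1`; allele M2 kills M1/M1 homozygotes with
#' penetrance `k2`. The penetrance ratio r = `k1/k2` is derived, never stored.
#'
#' Element types are accepted for interface uniformity with
#' [andro_params()]; under monoecy, Medea (maternal-effect) and peel
#' (paternal-effect) elements produce identical recursions, so the types do
#' not affect any computation in the monoecious module.
#'
#' @param S Selfing rate, the fixed fraction of broods produced by
#'   self-fertilization each generation, in `[0, 1]`.
#' @param k1,k2 Killing penetrances of M1 and M2, each in `[0, 1]`. A single
#'   (non-antagonistic) element is modelled by setting the other penetrance
#'   to 0.
#' @param element1,element2 `"medea"`, `"peel"`, or `"none"` for each allele.
#' @return An object of class `model_params`.
#' @examples
#' model_params(S = 0.6, k1 = 0.9, k2 = 0.5)
#' @export
model_params <- function(S, k1, k2, element1 = "medea", element2 = "medea") {
  out <- structure(
    list(S = .check_unit(S, "S"),
         k1 = .check_unit(k1, "k1"),
         k2 = .check_unit(k2, "k2"),
         element1 = .check_element(element1, "element1"),
         element2 = .check_element(element2, "element2")),
    class = "model_params")
  if (any(c(out$element1, out$element2) == "peel")) {
    inform("Monoecious dynamics are identical for Medea and peel elements; element types are noted but do not change the recursion.")
  }
  out
}

#' Parameters for the androdioecious (Caenorhabditis) model
#'
#' Extends [model_params()] with the cost-of-males parameter `b`, the ratio
#' of hermaphrodite offspring produced per outcross relative to per
#' self-fertilization. `b = 1/2` is the classical two-fold cost of males
#' (fixed brood size); `b = 1` means outcrossing doubles the brood so the
#' hermaphrodite share is undiminished. Biologically plausible values fall
#' roughly in `[0.5, 2]`.
#'
#' Unlike monoecy, the androdioecious dynamics distinguish Medea from peel:
#' a Medea toxin is deposited by a heterozygous egg parent (always a
#' hermaphrodite), a peel toxin by a heterozygous sperm parent (the
#' hermaphrodite itself under selfing, the male under outcrossing).
#'
#' @inheritParams model_params
#' @param b Hermaphrodite-offspring ratio outcross/selfing, `> 0`.
#' @return An object of class `andro_params` (inherits `model_params`).
#' @examples
#' andro_params(S = 0.5, k1 = 1, k2 = 0, element1 = "peel", element2 = "none")
#' @export
andro_params <- function(S, k1, k2, element1 = "medea", element2 = "medea", b = 1) {
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= 0) {
    abort("`b` must be a single positive number.", class = "medeadyn_domain_error")
  }
  structure(
    list(S = .check_unit(S, "S"),
         k1 = .check_unit(k1, "k1"),
         k2 = .check_unit(k2, "k2"),
         element1 = .check_element(element1, "element1"),
         element2 = .check_element(element2, "element2"),
         b = as.numeric(b)),
    class = c("andro_params", "model_params"))
}

#' Penetrance ratio r = k1/k2
#'
#' @param params A [model_params()] object.
#' @return `k1/k2`, or `NA` with a warning when `k2 = 0` (the ratio is
#'   undefined for a single-element model).
#' @export
penetrance_ratio <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$k2 == 0) {
    warn("Penetrance ratio r = k1/k2 is undefined when k2 = 0; returning NA.")
    return(NA_real_)
  }
  params$k1 / params$k2
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<%s> S = %g, k1 = %g (%s), k2 = %g (%s)",
              class(x)[1], x$S, x$k1, x$element1, x$k2, x$element2))
  if (!is.null(x$b)) cat(sprintf(", b = %g", x$b))
  cat("\n")
  invisible(x)
}
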