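#' Seeded random states and parameters for property testing
#'
#' Draws genotype states uniformly on the simplex (normalized exponentials,
#' equivalent to a flat Dirichlet) and parameters uniformly on their declared
#' ranges. Identical seeds give identical fixtures; the core dynamics are
#' deterministic, so the seed governs fixture generation only.
#'
#' @param n Number of fixtures.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param S_range,k1_range,k2_range Ranges for the uniform parameter draws.
#' @param sex If `TRUE`, draw independent hermaphrodite and male simplex
#'   points plus a cost-of-males value, for the androdioecious model.
#' @param b_range Range for `b` when `sex = TRUE`.
#' @return A tibble; monoecious columns `X, Y, Z, S, k1, k2`, sex-structured
#'   columns `Xh, Yh, Zh, Xm, Ym, Zm, S, k1, k2, b`.
#' @examples
#' generate_fixtures(3, seed = 42)
#' @export
generate_fixtures <- function(n, seed = NULL,
                              S_range = c(0, 1), k1_range = c(0, 1),
                              k2_range = c(0, 1), sex = FALSE,
                              b_range = c(0.5, 2)) {
  stopifnot(n >= 1, n == round(n))
  if (!is.null(seed)) set.seed(seed)
  simplex <- function(n) {
    e <- matrix(rexp(3 * n), ncol = 3)
    e / rowSums(e)
  }
  S <- runif(n, S_range[1], S_range[2])
  k1 <- runif(n, k1_range[1], k1_range[2])
  k2 <- runif(n, k2_range[1], k2_range[2])
  if (sex) {
    h <- simplex(n)
    m <- simplex(n)
    tibble(Xh = h[, 1], Yh = h[, 2], Zh = h[, 3],
           Xm = m[, 1], Ym = m[, 2], Zm = m[, 3],
           S = S, k1 = k1, k2 = k2,
           b = runif(n, b_range[1], b_range[2]))
  } else {
    g <- simplex(n)
    tibble(X = g[, 1], Y = g[, 2], Z = g[, 3], S = S, k1 = k1, k2 = k2)
  }
}
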