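# Iterate the vectorized kernels over a vector of all-homozygote starting
# frequencies; returns final population allele frequency per start.
.final_p_mono <- function(p0, S, k1, k2, n) {
  p <- p0
  Y <- rep(0, length(p0))
  for (t in seq_len(n)) {
    st <- .step_pY(p, Y, S, k1, k2)
    p <- st$p
    Y <- st$Y
  }
  p
}

.final_p_andro <- function(p0, params, n, mean_rule = "equal") {
  ph <- pm <- p0
  Yh <- Ym <- rep(0, length(p0))
  for (t in seq_len(n)) {
    st <- .step_andro(ph, Yh, pm, Ym, params$S, params$k1, params$k2,
                      params$element1, params$element2, params$b)
    ph <- st$ph; Yh <- st$Yh; pm <- st$pm; Ym <- st$Ym
  }
  if (params$S == 1 || mean_rule == "hermaphrodite_only") ph else (ph + pm) / 2
}

#' Classify the fate of an invading allele
#'
#' Runs the deterministic recursion from a starting state and classifies the
#' outcome. The default comparator follows the numerical procedure used for
#' threshold estimation: iterate a fixed number of generations (100 by
#' default) and ask whether the allele frequency ended above or below its
#' starting value. Because the sign of the per-generation change does not
#' depend on heterozygosity in the monoecious model, this directional test is
#' decisive away from the separatrix. An `absorbing` comparator instead runs
#' until the frequency is within `epsilon` of 0 or 1 (or the generation cap).
#'
#' @param state0 Initial [genotype_state()] or [sex_state()].
#' @param params [model_params()] or [andro_params()] (selects the model).
#' @param comparator `"after_n"` (default) or `"absorbing"`.
#' @param n_generations Generations to run (`after_n`) or cap (`absorbing`).
#' @param epsilon Absorption tolerance for the `absorbing` comparator.
#' @param mean_rule Sex-weighting rule used to report a single allele
#'   frequency for androdioecious states (see [population_mean_p()]).
#' @return A one-row tibble: `fate` (`"fix"`, `"loss"`, `"undecided"`),
#'   `p_start`, `p_final`, `generations_run`, `comparator`.
#' @examples
#' classify_fate(state_from_pq(0.2, 0), model_params(0.6, 0.9, 0.5))
#' @export
classify_fate <- function(state0, params,
                          comparator = c("after_n", "absorbing"),
                          n_generations = 100, epsilon = 1e-6,
                          mean_rule = "equal") {
  comparator <- match.arg(comparator)
  andro <- inherits(state0, "sex_state")
  get_p <- function(st) {
    if (andro) unname(population_mean_p(st, mean_rule)) else allele_frequency(st)
  }
  p0 <- get_p(state0)
  st <- state0
  gens <- 0L
  if (comparator == "after_n") {
    for (t in seq_len(n_generations)) {
      st <- if (andro) step_androdioecious(st, params)$state else {
        step_monoecious(st, params)$state
      }
      gens <- t
    }
    pf <- get_p(st)
    fate <- if (pf > p0 + 1e-12) "fix" else if (pf < p0 - 1e-12) "loss" else "undecided"
  } else {
    pf <- p0
    fate <- "undecided"
    while (gens < n_generations) {
      st <- if (andro) step_androdioecious(st, params)$state else {
        step_monoecious(st, params)$state
      }
      gens <- gens + 1L
      pf <- get_p(st)
      if (pf < epsilon) { fate <- "loss"; break }
      if (pf > 1 - epsilon) { fate <- "fix"; break }
    }
  }
  tibble(fate = fate, p_start = p0, p_final = pf,
         generations_run = gens, comparator = comparator)
}

.fate_from_final <- function(p0, pf) {
  dplyr::case_when(pf > p0 + 1e-12 ~ "fix",
                   pf < p0 - 1e-12 ~ "loss",
                   TRUE ~ "undecided")
}

# Locate the loss->fix flip in a fate vector ordered by ascending p0.
.flip_point <- function(p_grid, fate) {
  loss <- fate == "loss"
  fix <- fate == "fix"
  if (!any(fix) || !any(loss)) {
    return(list(threshold = NA_real_, lo = NA_real_, hi = NA_real_,
                flag = "none"))
  }
  hi_i <- min(which(fix))
  lo_i <- max(which(loss))
  # undecided cells may sit between the brackets (starts numerically at the
  # separatrix); any interleaving of fix and loss is a comparator pathology
  if (lo_i > hi_i || any(fix[seq_len(lo_i)]) || any(loss[hi_i:length(loss)])) {
    return(list(threshold = NA_real_, lo = NA_real_, hi = NA_real_,
                flag = "non-monotone"))
  }
  list(threshold = (p_grid[lo_i] + p_grid[hi_i]) / 2,
       lo = p_grid[lo_i], hi = p_grid[hi_i], flag = "ok")
}

#' Grid scan for invasion-threshold frequencies
#'
#' For each selfing rate in `S_grid`, starts the recursion from every
#' all-homozygote mixture `(X = p0, Y = 0, Z = 1 - p0)` on `p_grid` (both
#' sexes identical under androdioecy), classifies each fate, and reports the
#' threshold as the midpoint between the largest starting frequency that is
#' lost and the smallest that fixes. The default grids reproduce the
#' numerical procedure used for the published threshold estimates: starting
#' frequencies 0.001 to 0.999 in steps of 0.001, selfing rates 0 to 0.99 in
#' steps of 0.01, fates judged after 100 generations.
#'
#' Cells where every start shares one fate are reported `flag = "none"`
#' (e.g. obligate outcrossing with unequal penetrances, where the stronger
#' element always sweeps); `S = 1` cells are `"degenerate"` (without
#' outcrossing and starting from homozygotes, every frequency is an
#' equilibrium). A non-monotone fate sequence along `p_grid` is flagged
#' rather than summarized.
#'
#' @param params [model_params()] (monoecious) or [andro_params()].
#' @param S_grid Ascending selfing rates to scan.
#' @param p_grid Ascending starting frequencies to scan.
#' @param comparator Fate comparator, see [classify_fate()].
#' @param n_generations Generations per fate classification.
#' @param refine For monoecious scans, bisect the bracketing pair down to
#'   width `1e-6` (the sign of the frequency change depends only on `p`, so
#'   bisection on the one-generation sign is exact).
#' @return A tibble of class `threshold_grid`, one row per selfing rate:
#'   `model`, `element1`, `element2`, `k1`, `k2`, `b`, `S`, `threshold`,
#'   `bracket_lo`, `bracket_hi`, `comparator`, `flag`.
#' @examples
#' threshold_scan(model_params(S = 0, k1 = 0.9, k2 = 0.5),
#'                S_grid = 0.6, p_grid = seq(0.01, 0.99, 0.01))
#' @export
threshold_scan <- function(params, S_grid = seq(0, 0.99, 0.01),
                           p_grid = seq(0.001, 0.999, 0.001),
                           comparator = c("after_n", "absorbing"),
                           n_generations = 100, refine = FALSE) {
  comparator <- match.arg(comparator)
  stopifnot(!is.unsorted(S_grid), !is.unsorted(p_grid),
            all(p_grid > 0 & p_grid < 1), all(S_grid >= 0 & S_grid <= 1))
  andro <- inherits(params, "andro_params")
  rows <- purrr::map(S_grid, function(S) {
    pars <- params
    pars$S <- S
    if (S == 1) {
      return(tibble(S = S, threshold = NA_real_, bracket_lo = NA_real_,
                    bracket_hi = NA_real_, flag = "degenerate"))
    }
    pf <- if (andro) {
      .final_p_andro(p_grid, pars, n_generations)
    } else {
      .final_p_mono(p_grid, S, pars$k1, pars$k2, n_generations)
    }
    if (comparator == "absorbing") {
      fate <- dplyr::case_when(pf > 1 - 1e-6 ~ "fix", pf < 1e-6 ~ "loss",
                               TRUE ~ "undecided")
      # treat directional-but-unabsorbed runs by their direction
      und <- fate == "undecided"
      fate[und] <- .fate_from_final(p_grid[und], pf[und])
    } else {
      fate <- .fate_from_final(p_grid, pf)
    }
    fl <- .flip_point(p_grid, fate)
    if (refine && !andro && fl$flag == "ok") {
      lo <- fl$lo
      hi <- fl$hi
      while (hi - lo > 1e-6) {
        mid <- (lo + hi) / 2
        pfm <- .final_p_mono(mid, S, pars$k1, pars$k2, n_generations)
        if (pfm > mid + 1e-12) hi <- mid else lo <- mid
      }
      fl$threshold <- (lo + hi) / 2
      fl$lo <- lo
      fl$hi <- hi
    }
    tibble(S = S, threshold = fl$threshold, bracket_lo = fl$lo,
           bracket_hi = fl$hi, flag = fl$flag)
  })
  out <- dplyr::bind_rows(rows)
  out <- tibble(model = if (andro) "androdioecious" else "monoecious",
                element1 = params$element1, element2 = params$element2,
                k1 = params$k1, k2 = params$k2,
                b = if (andro) params$b else NA_real_,
                S = out$S, threshold = out$threshold,
                bracket_lo = out$bracket_lo, bracket_hi = out$bracket_hi,
                comparator = comparator, flag = out$flag)
  class(out) <- c("threshold_grid", class(out))
  out
}

#' One-generation displacement field on the genotype simplex
#'
#' Applies the monoecious step map at every point of a triangular grid on
#' the genotype simplex and returns the displacement `(dX, dY, dZ)` together
#' with planar ternary coordinates for plotting a phase portrait. The
#' displacement components sum to zero at every point.
#'
#' @param params A [model_params()].
#' @param resolution Number of grid divisions per simplex edge (`>= 2`).
#' @return A tibble: `X`, `Y`, `Z`, `dX`, `dY`, `dZ`, `tern_x`, `tern_y`.
#' @examples
#' vector_field(model_params(0.6, 0.9, 0.5), resolution = 5)
#' @export
vector_field <- function(params, resolution = 20) {
  stopifnot(inherits(params, "model_params"), !inherits(params, "andro_params"),
            resolution >= 2)
  grid <- tidyr::expand_grid(i = 0:resolution, j = 0:resolution) |>
    dplyr::filter(.data$i + .data$j <= resolution) |>
    dplyr::mutate(X = .data$i / resolution, Y = .data$j / resolution,
                  Z = 1 - .data$X - .data$Y)
  p <- grid$X + grid$Y / 2
  st <- .step_pY(p, grid$Y, params$S, params$k1, params$k2)
  X2 <- st$p - st$Y / 2
  out <- grid |>
    dplyr::transmute(.data$X, .data$Y, .data$Z,
                     dX = X2 - .data$X, dY = st$Y - .data$Y,
                     dZ = (1 - st$p - st$Y / 2) - .data$Z)
  tc <- ternary_coords(out[, c("X", "Y", "Z")])
  dplyr::bind_cols(out, tc)
}

#' Planar ternary-plot coordinates for genotype frequencies
#'
#' Standard equilateral-triangle embedding of the genotype simplex:
#' `x = Z + Y/2`, `y = (sqrt(3)/2) Y`. Corners: M1M1 at (0, 0) (left), M2M2
#' at (1, 0) (right), heterozygotes at the apex (0.5, sqrt(3)/2).
#'
#' @param state A [genotype_state()], or a data frame with columns
#'   `X`, `Y`, `Z`.
#' @return A tibble with columns `tern_x`, `tern_y`.
#' @examples
#' ternary_coords(genotype_state(0, 1, 0))
#' @export
ternary_coords <- function(state) {
  if (inherits(state, "genotype_state")) {
    state <- tibble(X = state[["X"]], Y = state[["Y"]], Z = state[["Z"]])
  }
  stopifnot(all(c("X", "Y", "Z") %in% names(state)))
  tibble(tern_x = state$Z + state$Y / 2,
         tern_y = sqrt(3) / 2 * state$Y)
}
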