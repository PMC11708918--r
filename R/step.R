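# Vectorized one-generation map in (p, Y) coordinates for the monoecious
# model. Written to expose the per-allele exposure weights:
#   a1 = S/2 + q(1-S) (exposure of M2M2 progeny to the M1 toxin),
#   a2 = S/2 + p(1-S) (exposure of M1M1 progeny to the M2 toxin),
#   wbar = 1 - (Y/2) (k1 a1 + k2 a2),
#   p'   = (p - (Y/2) k2 a2) / wbar,
#   Y'   = (S Y / 2 + (1-S) 2 p q) / wbar.
.step_pY <- function(p, Y, S, k1, k2) {
  q <- 1 - p
  a1 <- S / 2 + q * (1 - S)
  a2 <- S / 2 + p * (1 - S)
  wbar <- 1 - (Y / 2) * (k1 * a1 + k2 * a2)
  list(p = (p - (Y / 2) * k2 * a2) / wbar,
       Y = (S * Y / 2 + (1 - S) * 2 * p * q) / wbar,
       wbar = wbar)
}

# Sign of the per-generation allele-frequency change; independent of Y for
# Y > 0 (so the separatrix is a vertical line in the (p, Y) plane).
.delta_p_sign <- function(p, S, k1, k2) {
  q <- 1 - p
  sign(p * k1 * (S / 2 + q * (1 - S)) - q * k2 * (S / 2 + p * (1 - S)))
}

# Vectorized one-generation map for the androdioecious model, in
# (ph, Yh, pm, Ym). Selfing broods (frequency S) contribute hermaphrodites
# only, with unit weight; outcross broods (frequency 1-S) contribute b
# hermaphrodites per unit and the male pool at unit weight. Toxin exposure
# under outcrossing is keyed to the hermaphrodite (egg) heterozygosity for a
# medea element and to the male (sperm) heterozygosity for a peel element;
# under selfing both roles coincide in the hermaphrodite.
.step_andro <- function(ph, Yh, pm, Ym, S, k1, k2, element1, element2, b) {
  k1s <- if (element1 == "none") 0 else k1
  k2s <- if (element2 == "none") 0 else k2
  qh <- 1 - ph
  # selfing masses (per unit of selfing brood)
  m11_s <- (ph - Yh / 2) + (Yh / 4) * (1 - k2s)
  het_s <- Yh / 2
  m22_s <- (qh - Yh / 2) + (Yh / 4) * (1 - k1s)
  if (S < 1) {
    qm <- 1 - pm
    kill1_o <- if (element1 == "none") 0 else {
      k1 * (if (element1 == "medea") Yh * qm / 2 else qh * Ym / 2)
    }
    kill2_o <- if (element2 == "none") 0 else {
      k2 * (if (element2 == "medea") Yh * pm / 2 else ph * Ym / 2)
    }
    m11_o <- ph * pm - kill2_o
    het_o <- ph * qm + qh * pm
    m22_o <- qh * qm - kill1_o
  } else {
    m11_o <- het_o <- m22_o <- 0 * ph
  }
  n11_h <- S * m11_s + b * (1 - S) * m11_o
  nhet_h <- S * het_s + b * (1 - S) * het_o
  n22_h <- S * m22_s + b * (1 - S) * m22_o
  w_h <- n11_h + nhet_h + n22_h
  w_m <- (1 - S) * (m11_o + het_o + m22_o)
  Yh2 <- nhet_h / w_h
  ph2 <- n11_h / w_h + Yh2 / 2
  if (S < 1) {
    tot_o <- m11_o + het_o + m22_o
    Ym2 <- het_o / tot_o
    pm2 <- m11_o / tot_o + Ym2 / 2
  } else {
    Ym2 <- pm2 <- rep(NA_real_, length(ph))
  }
  list(ph = ph2, Yh = Yh2, pm = pm2, Ym = Ym2, w_h = w_h, w_m = w_m)
}

#' One generation of the monoecious recursion
#'
#' Advances a genotype state one generation under partial selfing with
#' antagonistic toxin-antidote elements, using the compact allele-frequency /
#' heterozygosity recursions. Agrees with the brute-force mating-table oracle
#' ([mating_table()] + [step_from_table()]) to machine precision.
#'
#' @param state A [genotype_state()].
#' @param params A [model_params()].
#' @return A list of class `step_result` with `state` (next generation) and
#'   `mean_fitness` (the normalizing sum of surviving-progeny contributions,
#'   in `(0, 1]`).
#' @examples
#' step_monoecious(genotype_state(0.25, 0.5, 0.25),
#'                 model_params(S = 1, k1 = 1, k2 = 0))
#' @export
step_monoecious <- function(state, params) {
  stopifnot(inherits(state, "genotype_state"),
            inherits(params, "model_params"), !inherits(params, "andro_params"))
  p <- allele_frequency(state)
  r <- .step_pY(p, state[["Y"]], params$S, params$k1, params$k2)
  if (r$wbar <= 0) {
    abort("Mean fitness is zero: all progeny are killed (degenerate extinction).",
          class = "medeadyn_extinction")
  }
  X2 <- r$p - r$Y / 2
  Z2 <- 1 - r$p - r$Y / 2
  drift <- abs(X2 + r$Y + Z2 - 1)
  if (drift > 1e-9) {
    inform(sprintf("Simplex renormalization correction %.3g exceeds 1e-9.", drift))
  }
  structure(list(state = genotype_state(max(X2, 0), min(r$Y, 1), max(Z2, 0)),
                 mean_fitness = r$wbar),
            class = "step_result")
}

#' One generation of the androdioecious recursion
#'
#' Advances sex-specific genotype frequencies one generation under the
#' Caenorhabditis mating system: hermaphrodites self (frequency `S`,
#' hermaphrodite offspring only) or mate with males (frequency `1 - S`,
#' offspring split between the hermaphrodite pool, weighted by the
#' cost-of-males parameter `b`, and the male pool). The two pools are
#' normalized separately; male genotype frequencies are independent of `b`.
#' Agrees with the sex-resolved mating-table oracle to machine precision.
#'
#' When `S = 1` the male pool receives no input: the returned male
#' frequencies are `NA` and `w_m = 0`, and the hermaphrodite dynamics reduce
#' to the monoecious model with `S = 1`.
#'
#' @param state A [sex_state()].
#' @param params An [andro_params()].
#' @return A list of class `step_result` with `state` (next generation),
#'   `w_h`, and `w_m` (hermaphrodite- and male-pool normalizers).
#' @export
step_androdioecious <- function(state, params) {
  stopifnot(inherits(state, "sex_state"), inherits(params, "andro_params"))
  p <- allele_frequency(state)
  if (params$S < 1 && anyNA(state[4:6])) {
    abort("Male genotype frequencies are required when S < 1.",
          class = "medeadyn_domain_error")
  }
  r <- .step_andro(p[["ph"]], state[["Yh"]], p[["pm"]], state[["Ym"]],
                   params$S, params$k1, params$k2,
                   params$element1, params$element2, params$b)
  if (r$w_h <= 0) {
    abort("Hermaphrodite mean fitness is zero (degenerate extinction).",
          class = "medeadyn_extinction")
  }
  st <- sex_state(r$ph - r$Yh / 2, r$Yh, 1 - r$ph - r$Yh / 2,
                  if (is.na(r$pm)) NA_real_ else r$pm - r$Ym / 2,
                  r$Ym,
                  if (is.na(r$pm)) NA_real_ else 1 - r$pm - r$Ym / 2)
  structure(list(state = st, w_h = r$w_h, w_m = r$w_m), class = "step_result")
}

#' Iterate a trajectory of genotype frequencies
#'
#' Applies the one-generation map repeatedly and returns the whole trajectory
#' as a tibble (generation 0 is the initial state; its fitness columns are
#' `NA`). The dynamics are deterministic: identical inputs give identical
#' trajectories.
#'
#' @param state0 Initial [genotype_state()] or [sex_state()].
#' @param params A [model_params()] (monoecious) or [andro_params()].
#' @param n_generations Number of generations to iterate (`>= 0`).
#' @return A tibble of class `drive_trajectory`. Monoecious columns:
#'   `generation`, `X`, `Y`, `Z`, `p`, `mean_fitness`. Androdioecious
#'   columns: `generation`, `Xh`, `Yh`, `Zh`, `Xm`, `Ym`, `Zm`, `ph`, `pm`,
#'   `w_h`, `w_m`.
#' @examples
#' iterate_trajectory(state_from_pq(0.2, 0), model_params(0, 0.9, 0.5), 10)
#' @export
iterate_trajectory <- function(state0, params, n_generations) {
  stopifnot(is.numeric(n_generations), length(n_generations) == 1L,
            n_generations >= 0, n_generations == round(n_generations))
  n <- as.integer(n_generations)
  if (inherits(state0, "sex_state")) {
    stopifnot(inherits(params, "andro_params"))
    out <- matrix(NA_real_, nrow = n + 1L, ncol = 10L)
    st <- state0
    out[1L, ] <- c(unname(st), allele_frequency(st), NA, NA)
    if (n > 0) for (t in seq_len(n)) {
      res <- step_androdioecious(st, params)
      st <- res$state
      out[t + 1L, ] <- c(unname(st), allele_frequency(st), res$w_h, res$w_m)
    }
    tj <- tibble(generation = 0:n,
                 Xh = out[, 1], Yh = out[, 2], Zh = out[, 3],
                 Xm = out[, 4], Ym = out[, 5], Zm = out[, 6],
                 ph = out[, 7], pm = out[, 8],
                 w_h = out[, 9], w_m = out[, 10])
  } else {
    stopifnot(inherits(state0, "genotype_state"),
              inherits(params, "model_params"), !inherits(params, "andro_params"))
    out <- matrix(NA_real_, nrow = n + 1L, ncol = 5L)
    st <- state0
    out[1L, ] <- c(unname(st), allele_frequency(st), NA)
    if (n > 0) for (t in seq_len(n)) {
      res <- step_monoecious(st, params)
      st <- res$state
      out[t + 1L, ] <- c(unname(st), allele_frequency(st), res$mean_fitness)
    }
    tj <- tibble(generation = 0:n,
                 X = out[, 1], Y = out[, 2], Z = out[, 3],
                 p = out[, 4], mean_fitness = out[, 5])
  }
  class(tj) <- c("drive_trajectory", class(tj))
  attr(tj, "params") <- params
  tj
}
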