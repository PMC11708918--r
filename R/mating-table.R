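# Mendelian progeny distribution (M1M1, M1M2, M2M2) for an egg x sperm pair.
.mendel <- function(egg, sperm) {
  ge <- .gamete_p[[egg]]
  gs <- .gamete_p[[sperm]]
  c(ge * gs, ge * (1 - gs) + (1 - ge) * gs, (1 - ge) * (1 - gs))
}

# Survival weights after toxin-mediated killing for one egg x sperm pair.
# Element 1 (penetrance k1) kills M2M2 progeny; element 2 kills M1M1.
# Exposure: a medea toxin requires a heterozygous egg parent, a peel toxin a
# heterozygous sperm parent. Under selfing egg and sperm parent coincide.
# Heterozygous progeny always carry both antidotes and are never killed.
.kill_weights <- function(egg, sperm, params) {
  w <- c(1, 1, 1)
  src1 <- if (params$element1 == "peel") sperm else egg
  src2 <- if (params$element2 == "peel") sperm else egg
  if (params$element1 != "none" && src1 == "M1M2") w[3] <- 1 - params$k1
  if (params$element2 != "none" && src2 == "M1M2") w[1] <- 1 - params$k2
  w
}

#' Cross-by-cross mating table
#'
#' Enumerates every self-fertilization and outcross, with its mating
#' frequency and the surviving-progeny weights (Mendelian share times toxin
#' survival) for each progeny genotype. This is the bookkeeping oracle behind
#' the compact recursions: [step_from_table()] applied to this table must
#' reproduce [step_monoecious()] / [step_androdioecious()] exactly.
#'
#' For a monoecious state the table has 3 selfing rows (total frequency `S`)
#' and 9 outcross rows (total `1 - S`). The monoecious table always uses the
#' maternal exposure rule: under monoecy Medea and peel elements yield
#' identical recursions, so the distinction is immaterial here.
#'
#' For an androdioecious [sex_state()], the egg parent is always a
#' hermaphrodite; outcross sperm parents are drawn from the male genotype
#' frequencies. Columns `herm_factor` (1 for selfing rows, `b` for outcross
#' rows) and `male_factor` (0 / 1) record each row's per-unit contribution to
#' the hermaphrodite and male offspring pools, and exposure follows the
#' element types in `params`.
#'
#' @param state A [genotype_state()] or [sex_state()].
#' @param params Matching [model_params()] or [andro_params()].
#' @return A tibble with columns `egg`, `sperm`, `mating` (`"self"` or
#'   `"cross"`), `frequency`, and surviving-progeny weights `M1M1`, `M1M2`,
#'   `M2M2`; androdioecious tables add `herm_factor` and `male_factor`.
#' @examples
#' mating_table(genotype_state(0.25, 0.5, 0.25),
#'              model_params(S = 0.6, k1 = 0.9, k2 = 0.5))
#' @export
mating_table <- function(state, params) {
  UseMethod("mating_table")
}

#' @export
mating_table.genotype_state <- function(state, params) {
  stopifnot(inherits(params, "model_params"), !inherits(params, "andro_params"))
  # Table rule is maternal exposure for both elements (monoecious canon).
  mono <- params
  mono$element1 <- if (mono$element1 == "none") "none" else "medea"
  mono$element2 <- if (mono$element2 == "none") "none" else "medea"
  freq <- unname(state)
  rows <- vector("list", 12L)
  i <- 0L
  for (g in 1:3) {
    i <- i + 1L
    rows[[i]] <- list(egg = .genotypes[g], sperm = .genotypes[g],
                      mating = "self",
                      frequency = params$S * freq[g],
                      w = .mendel(.genotypes[g], .genotypes[g]) *
                        .kill_weights(.genotypes[g], .genotypes[g], mono))
  }
  for (e in 1:3) {
    for (s in 1:3) {
      i <- i + 1L
      rows[[i]] <- list(egg = .genotypes[e], sperm = .genotypes[s],
                        mating = "cross",
                        frequency = (1 - params$S) * freq[e] * freq[s],
                        w = .mendel(.genotypes[e], .genotypes[s]) *
                          .kill_weights(.genotypes[e], .genotypes[s], mono))
    }
  }
  tibble(
    egg = purrr::map_chr(rows, "egg"),
    sperm = purrr::map_chr(rows, "sperm"),
    mating = purrr::map_chr(rows, "mating"),
    frequency = purrr::map_dbl(rows, "frequency"),
    M1M1 = purrr::map_dbl(rows, ~ .x$w[1]),
    M1M2 = purrr::map_dbl(rows, ~ .x$w[2]),
    M2M2 = purrr::map_dbl(rows, ~ .x$w[3])
  )
}

#' @export
mating_table.sex_state <- function(state, params) {
  stopifnot(inherits(params, "andro_params"))
  h <- unname(state[1:3])
  m <- unname(state[4:6])
  if (params$S < 1 && anyNA(m)) {
    abort("Male genotype frequencies are required when S < 1.",
          class = "medeadyn_domain_error")
  }
  rows <- vector("list", 12L)
  i <- 0L
  for (g in 1:3) {
    i <- i + 1L
    rows[[i]] <- list(egg = .genotypes[g], sperm = .genotypes[g],
                      mating = "self",
                      frequency = params$S * h[g],
                      herm_factor = 1, male_factor = 0,
                      w = .mendel(.genotypes[g], .genotypes[g]) *
                        .kill_weights(.genotypes[g], .genotypes[g], params))
  }
  for (e in 1:3) {
    for (s in 1:3) {
      i <- i + 1L
      f <- if (params$S < 1) (1 - params$S) * h[e] * m[s] else 0
      rows[[i]] <- list(egg = .genotypes[e], sperm = .genotypes[s],
                        mating = "cross",
                        frequency = f,
                        herm_factor = params$b, male_factor = 1,
                        w = .mendel(.genotypes[e], .genotypes[s]) *
                          .kill_weights(.genotypes[e], .genotypes[s], params))
    }
  }
  tibble(
    egg = purrr::map_chr(rows, "egg"),
    sperm = purrr::map_chr(rows, "sperm"),
    mating = purrr::map_chr(rows, "mating"),
    frequency = purrr::map_dbl(rows, "frequency"),
    herm_factor = purrr::map_dbl(rows, "herm_factor"),
    male_factor = purrr::map_dbl(rows, "male_factor"),
    M1M1 = purrr::map_dbl(rows, ~ .x$w[1]),
    M1M2 = purrr::map_dbl(rows, ~ .x$w[2]),
    M2M2 = purrr::map_dbl(rows, ~ .x$w[3])
  )
}

#' One generation by brute-force table summation
#'
#' Sums frequency-weighted surviving-progeny contributions column by column
#' and normalizes by the grand total (the mean fitness). This is the slow,
#' transparent oracle for the compact recursion steps.
#'
#' @param table A tibble from [mating_table()].
#' @return For a monoecious table, a list with `state` ([genotype_state()])
#'   and `mean_fitness`. For an androdioecious table, a list with `state`
#'   ([sex_state()]), `w_h`, and `w_m` (the two pool normalizers).
#' @examples
#' tab <- mating_table(genotype_state(0, 1, 0), model_params(1, 1, 1))
#' step_from_table(tab)
#' @export
step_from_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("frequency", "M1M1", "M1M2", "M2M2") %in% names(table)))
  W <- as.matrix(table[, c("M1M1", "M1M2", "M2M2")])
  if ("herm_factor" %in% names(table)) {
    nh <- colSums(table$frequency * table$herm_factor * W)
    nm <- colSums(table$frequency * table$male_factor * W)
    w_h <- sum(nh)
    w_m <- sum(nm)
    if (w_h <= 0) {
      abort("All hermaphrodite progeny are killed: degenerate extinction.",
            class = "medeadyn_extinction")
    }
    hm <- nh / w_h
    mm <- if (w_m > 0) nm / w_m else rep(NA_real_, 3)
    list(state = sex_state(hm[1], hm[2], hm[3], mm[1], mm[2], mm[3]),
         w_h = w_h, w_m = w_m)
  } else {
    n <- colSums(table$frequency * W)
    wbar <- sum(n)
    if (wbar <= 0) {
      abort("All progeny are killed: degenerate extinction.",
            class = "medeadyn_extinction")
    }
    v <- n / wbar
    list(state = genotype_state(v[1], v[2], v[3]), mean_fitness = wbar)
  }
}
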