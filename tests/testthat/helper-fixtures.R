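# Shared helpers: oracle comparisons and starting-state builders.

# componentwise discrepancy between the compact monoecious step and the
# brute-force mating-table summation
mono_oracle_gap <- function(X, Y, Z, S, k1, k2) {
  st <- genotype_state(X, Y, Z)
  pars <- model_params(S, k1, k2)
  fast <- step_monoecious(st, pars)
  slow <- step_from_table(mating_table(st, pars))
  max(abs(unname(fast$state) - unname(slow$state)),
      abs(fast$mean_fitness - slow$mean_fitness))
}

andro_oracle_gap <- function(Xh, Yh, Zh, Xm, Ym, Zm, S, k1, k2, b,
                             element1 = "medea", element2 = "medea") {
  st <- sex_state(Xh, Yh, Zh, Xm, Ym, Zm)
  pars <- andro_params(S, k1, k2, element1, element2, b)
  fast <- step_androdioecious(st, pars)
  slow <- step_from_table(mating_table(st, pars))
  d <- abs(unname(fast$state) - unname(slow$state))
  max(d[!is.na(d)], abs(fast$w_h - slow$w_h), abs(fast$w_m - slow$w_m))
}

# symmetric all-homozygote androdioecious start at invader frequency p0
sym_start <- function(p0) sex_state(p0, 0, 1 - p0, p0, 0, 1 - p0)

# generations until the sex-averaged allele frequency first reaches target
generations_to <- function(trajectory, target = 0.5) {
  p <- if ("ph" %in% names(trajectory)) {
    (trajectory$ph + trajectory$pm) / 2
  } else {
    trajectory$p
  }
  hit <- which(p >= target)
  if (!length(hit)) Inf else trajectory$generation[min(hit)]
}
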