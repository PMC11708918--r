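.config_keys <- list(
  model = "monoecious | androdioecious",
  element1 = "medea | peel | none",
  element2 = "medea | peel | none",
  S = "selfing rate in [0, 1]",
  k1 = "M1 killing penetrance in [0, 1]",
  k2 = "M2 killing penetrance in [0, 1]",
  b = "hermaphrodite-offspring ratio outcross/selfing, > 0",
  p0 = "initial M1 allele frequency in [0, 1]",
  Y0 = "initial heterozygosity (feasible at p0)",
  generations = "non-negative integer",
  comparator = "after_n | absorbing",
  S_grid = "selfing grid as min:max:step, e.g. 0:0.99:0.01",
  p_grid = "starting-frequency grid as min:max:step, e.g. 0.001:0.999:0.001",
  resolution = "vector-field grid divisions per edge, >= 2",
  n = "number of fixtures, >= 1",
  seed = "integer RNG seed (fixture generation only)",
  mean_rule = "equal | hermaphrodite_only",
  out = "output file path ('' for stdout)"
)

.parse_grid_spec <- function(spec, key) {
  parts <- suppressWarnings(as.numeric(strsplit(spec, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 3L || anyNA(parts) || parts[3] <= 0 || parts[2] < parts[1]) {
    abort(sprintf("`%s` must be min:max:step with max >= min and step > 0; got \"%s\".",
                  key, spec), class = "medeadyn_config_error")
  }
  seq(parts[1], parts[2], by = parts[3])
}

#' Parse and validate a run configuration
#'
#' Configuration comes from a flat `key = value` text file, command-line
#' flags, or both; flags take precedence over the file (with a warning for
#' every overridden key). Unknown keys are rejected with the list of valid
#' keys; domain violations name the offending key.
#'
#' @param file Optional path to a `key = value` config file (`#` comments
#'   and blank lines allowed).
#' @param flags Optional named character vector of `key = value` overrides
#'   (as produced by the command-line front end).
#' @return A validated list of class `run_config`. Unset keys are absent;
#'   defaults are applied by the consuming subcommand.
#' @examples
#' parse_run_config(flags = c(model = "monoecious", S = "0.6",
#'                            k1 = "0.9", k2 = "0.5"))
#' @export
parse_run_config <- function(file = NULL, flags = NULL) {
  kv <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) {
      abort(sprintf("Config file not found: %s", file),
            class = "medeadyn_config_error")
    }
    lines <- trimws(readLines(file))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(m) != 3L) {
        abort(sprintf("Cannot parse config line: \"%s\" (expected key = value).", ln),
              class = "medeadyn_config_error")
      }
      kv[[m[2]]] <- trimws(m[3])
    }
  }
  if (!is.null(flags) && length(flags)) {
    overridden <- intersect(names(flags), names(kv))
    for (key in overridden) {
      warn(sprintf("Flag --%s overrides config-file value \"%s\".", key, kv[[key]]))
    }
    kv[names(flags)] <- unname(flags)
  }
  unknown <- setdiff(names(kv), names(.config_keys))
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s. Valid keys: %s.",
                  paste(unknown, collapse = ", "),
                  paste(names(.config_keys), collapse = ", ")),
          class = "medeadyn_config_error")
  }
  cfg <- kv
  num_keys <- c("S", "k1", "k2", "b", "p0", "Y0", "generations", "resolution",
                "n", "seed")
  for (key in intersect(num_keys, names(cfg))) {
    v <- suppressWarnings(as.numeric(cfg[[key]]))
    if (is.na(v)) {
      abort(sprintf("`%s` must be numeric; got \"%s\".", key, cfg[[key]]),
            class = "medeadyn_config_error")
    }
    cfg[[key]] <- v
  }
  chk <- function(key, ok, domain) {
    if (!is.null(cfg[[key]]) && !ok(cfg[[key]])) {
      abort(sprintf("`%s` = %s is outside its domain: %s.", key,
                    format(cfg[[key]]), domain),
            class = "medeadyn_config_error")
    }
  }
  chk("S", function(x) x >= 0 && x <= 1, .config_keys$S)
  chk("k1", function(x) x >= 0 && x <= 1, .config_keys$k1)
  chk("k2", function(x) x >= 0 && x <= 1, .config_keys$k2)
  chk("b", function(x) x > 0, .config_keys$b)
  chk("p0", function(x) x >= 0 && x <= 1, .config_keys$p0)
  chk("Y0", function(x) x >= 0 && x <= 1, .config_keys$Y0)
  chk("generations", function(x) x >= 0 && x == round(x), .config_keys$generations)
  chk("resolution", function(x) x >= 2 && x == round(x), .config_keys$resolution)
  chk("n", function(x) x >= 1 && x == round(x), .config_keys$n)
  chk("model", function(x) TRUE, "")
  for (key in c("model", "element1", "element2", "comparator", "mean_rule")) {
    valid <- switch(key,
      model = c("monoecious", "androdioecious"),
      element1 = , element2 = c("medea", "peel", "none"),
      comparator = c("after_n", "absorbing"),
      mean_rule = c("equal", "hermaphrodite_only"))
    if (!is.null(cfg[[key]]) && !cfg[[key]] %in% valid) {
      abort(sprintf("`%s` must be one of %s; got \"%s\".", key,
                    paste(valid, collapse = " | "), cfg[[key]]),
            class = "medeadyn_config_error")
    }
  }
  for (key in c("S_grid", "p_grid")) {
    if (!is.null(cfg[[key]])) cfg[[key]] <- .parse_grid_spec(cfg[[key]], key)
  }
  structure(cfg, class = "run_config")
}
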