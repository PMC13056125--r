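# internal helpers: argument checking and seeded evaluation without touching
# the caller's global RNG state

stop_bad <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad(sprintf("`%s` must be a single finite number", name))
  if (strict_lower && x <= lower)
    stop_bad(sprintf("`%s` must be > %g", name, lower))
  if (!strict_lower && x < lower)
    stop_bad(sprintf("`%s` must be >= %g", name, lower))
  if (strict_upper && x >= upper)
    stop_bad(sprintf("`%s` must be < %g", name, upper))
  if (!strict_upper && x > upper)
    stop_bad(sprintf("`%s` must be <= %g", name, upper))
  x
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) stop_bad(sprintf("`%s` must be an integer", name))
  as.integer(x)
}

check_choice <- function(x, name, choices) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices))
    stop_bad(sprintf("`%s` must be one of: %s", name,
                     paste(choices, collapse = ", ")))
  x
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All package randomness funnels through this so generators
# are reproducible without mutating global state.
with_seed <- function(seed, code) {
  seed <- check_count(seed, "seed", lower = 0L)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# trapezoid integral on an arbitrary strictly increasing grid
trapz_grid <- function(x, y) pracma::trapz(x, y)

# nearest multiple of 10 percent, halves rounded away from zero (66.7% -> 70%)
round_to_10pct <- function(fraction) {
  10 * sign(fraction) * floor(abs(fraction) * 10 + 0.5)
}
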