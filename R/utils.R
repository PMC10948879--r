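# Internal condition helpers: every user-facing failure is a classed condition
# so callers (and the CLI) can distinguish configuration mistakes from
# degenerate data and from registration failures.

phq_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "phagoquant_error"),
                      call = call))
}

stop_config <- function(msg) phq_stop(msg, "phagoquant_config_error")
stop_degenerate <- function(msg) phq_stop(msg, "phagoquant_degenerate_error")
stop_registration <- function(msg) phq_stop(msg, "phagoquant_registration_error")

assert_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x) || length(x) == 0L)
    stop_config(sprintf("'%s' must be a non-empty numeric matrix", name))
  invisible(x)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
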