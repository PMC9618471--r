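# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

stop_perfusim <- function(..., class = "perfusim_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_increasing <- function(x, what = "times") {
  if (length(x) < 1L || anyNA(x) || any(diff(x) <= 0))
    stop_perfusim(what, " must be strictly increasing and free of NA")
  invisible(x)
}

# Trapezoidal integral of sampled curve.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
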