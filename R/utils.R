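# internal validators shared across modules

stop_if_not_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    cmp <- if (strict) ">" else ">="
    abort(sprintf("`%s` must be a single finite number %s %s.", name, cmp, format(min)))
  }
  invisible(x)
}

# scoped RNG: generators restore the caller's RNG state
local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    stop_if_not_number(seed, "seed")
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}

new_curve_tbl <- function(displacement, load) {
  tibble(displacement_mm = displacement, load_n = load)
}

is_uniform <- function(x, tol = 1e-8) {
  d <- diff(x)
  length(d) == 0L || all(abs(d - d[1]) <= tol * max(abs(d[1]), 1e-12))
}
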