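# Internal helpers: seeding, error signalling.

# Set the RNG inside the calling function only; the caller's RNG state is
# restored on exit so seeded package calls never disturb user code.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) {
    return(invisible(NULL))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_deathcue("`seed` must be a single finite number.", "bad_param")
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  withr::defer(assign(".Random.seed", old, envir = globalenv()), envir = env)
  set.seed(seed)
  invisible(NULL)
}

# Deterministic per-stage substream: reordering pipeline stages cannot
# silently change the stream another stage sees.
substream_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(as.double(seed)) * 48271 + h * 7919) %% 2147483647)
}

stop_deathcue <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("deathcue_", class), "deathcue_error"), ...)
}

check_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    stop_deathcue(
      sprintf("`%s` must be a probability in %s0, 1%s.", name,
              if (open_left) "(" else "[", if (open_right) ")" else "]"),
      "bad_param"
    )
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_deathcue(sprintf("`%s` must be an integer >= %d.", name, min), "bad_param")
  }
  invisible(as.integer(x))
}
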