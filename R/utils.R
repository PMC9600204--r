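# shared internal helpers: classed conditions, seeded evaluation, validation

ts_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "thalscreen_error"),
                      call = call))
}

ts_warning <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "thalscreen_warning")))
}

# Run `fn()` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fn()
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

stopifnot_rgb <- function(img) {
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L)) {
    ts_error("expected an H x W x 3 RGB array", "thalscreen_format_error")
  }
  invisible(img)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)
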