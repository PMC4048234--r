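# Internal helpers shared across modules.

stop_input <- function(msg, ...) abort(msg, class = "isletscore_error_input", ...)
stop_format <- function(msg, ...) abort(msg, class = "isletscore_error_format", ...)
stop_validation <- function(msg, ...) abort(msg, class = "isletscore_error_validation", ...)
stop_parameter <- function(msg, ...) abort(msg, class = "isletscore_error_parameter", ...)

# Run `code` under a fixed RNG seed, restoring the caller's RNG state afterwards
# so generators do not leak hidden global state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

check_same_dims <- function(a, b, what_a = "first grid", what_b = "second grid") {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop_format(sprintf(
      "%s (%d x %d) and %s (%d x %d) must share dimensions",
      what_a, nrow(a), ncol(a), what_b, nrow(b), ncol(b)
    ))
  }
  invisible(TRUE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE, integer = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(TRUE))
    stop_parameter(sprintf("`%s` must be supplied", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_parameter(sprintf("`%s` must be a single finite number", name))
  }
  if (integer && x != round(x)) {
    stop_parameter(sprintf("`%s` must be a whole number", name))
  }
  if (x < lower || x > upper) {
    stop_parameter(sprintf("`%s` = %s must lie in [%s, %s]", name, format(x),
                           format(lower), format(upper)))
  }
  invisible(TRUE)
}

# Integer offsets of the pixels of a disc of radius r centred at the origin.
disc_offsets <- function(radius) {
  r <- ceiling(radius)
  dr <- rep(-r:r, times = 2L * r + 1L)
  dc <- rep(-r:r, each = 2L * r + 1L)
  keep <- dr * dr + dc * dc <= radius * radius
  cbind(dr = dr[keep], dc = dc[keep])
}
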