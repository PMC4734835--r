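`%||%` <- function(a, b) if (is.null(a)) b else a

gem_stop <- function(..., class = "gem_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

gem_warn <- function(...) warning(paste0(...), call. = FALSE)

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

num_fmt <- function(x) {
  # minimal decimal rendering: integers without ".0", others as-is
  ifelse(x == round(x), format(as.integer(round(x))), format(x, trim = TRUE))
}
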