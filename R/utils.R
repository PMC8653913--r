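# internal helpers shared across modules

# attach class + attributes to a tibble without losing them through printing
new_eda_tbl <- function(x, class, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  class(x) <- c(class, class(x))
  x
}

meta_of <- function(x) attr(x, "meta", exact = TRUE)

stop_edapeaks <- function(msg, class) {
  rlang::abort(msg, class = c(class, "edapeaks_error"))
}

# seed handling: all randomness in the package flows through this so a
# single integer seed gives bitwise-reproducible output without touching
# the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
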