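# small internal helpers

# evaluate expr under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# derive a stream seed below 2^31 from a base seed and stream labels
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), as.character))
  h <- as.double(seed %% 1000003L)
  for (p in parts) {
    for (ch in utf8ToInt(p)) h <- (h * 31 + ch) %% 2147483563
  }
  as.integer(h)
}

config_error <- function(...) {
  stop(structure(class = c("cbgt_config_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# accept a one-row data.frame or a named list/vector as a named list
as_override <- function(x) {
  if (is.null(x)) return(list())
  if (is.data.frame(x)) {
    if (nrow(x) != 1) config_error("parameter override must have one row")
    return(as.list(x))
  }
  as.list(x)
}
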