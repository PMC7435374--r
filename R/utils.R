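# shared internal helpers

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_lesiongan <- function(msg, class) {
  stop(structure(class = c(class, "lesiongan_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_binary_mask <- function(m) {
  (is.logical(m) || all(m %in% c(0, 1))) && !anyNA(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
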