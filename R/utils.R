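# Structured errors: every failure mode raises a condition of class
# lvtraits_<type> / lvtraits_error so callers can branch on the cause.
stop_lv <- function(type, message, data = NULL, call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("lvtraits_", type), "lvtraits_error",
              "error", "condition"),
    list(message = message, call = call, data = data)
  )
  stop(cond)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x
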