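## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.  All stochastic code in the package goes through
# this so that no function perturbs the global random stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  expr
}

# Full-precision number formatting for round-trippable CSV output.
fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

# Fixed 6-significant-digit formatting for human-facing reports, so that
# re-running an analysis yields byte-identical files.
fmt_report <- function(x) {
  if (is.numeric(x)) sprintf("%.6g", x) else as.character(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctx <- function(..., class) {
  stop(structure(class = c(class, "skeletrack_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
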