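#' @keywords internal
"_PACKAGE"

# Clamp to a closed interval.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate code under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb the global stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage child seeds fanned out from one master seed,
# kept inside the 32-bit integer range.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed) %% 1000003L) * 2011L + match(
    stage,
    c("derivation", "validation", "resample", "split", "select",
      "ensemble", "calibrate", "predict", "evaluate", "misc")) * 7919L
}

stop_bg <- function(msg, class, ...) {
  cond <- structure(
    class = c(class, "bloodgas_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...))
  stop(cond)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_bg(sprintf("%s is missing required column(s): %s", what,
                    paste(missing, collapse = ", ")),
            "bg_missing_columns", missing = missing)
  invisible(df)
}
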