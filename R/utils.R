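# Internal helpers: classed error conditions (the CLI maps these to exit
# codes), INFO logging, and RNG-scope management.

stopUsage <- function(...) {
  stop(errorCondition(paste0(...), class = c("plantkgr_usage_error", "error")))
}

stopData <- function(...) {
  stop(errorCondition(paste0(...), class = c("plantkgr_data_error", "error")))
}

stopNumeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("plantkgr_numeric_error", "error")))
}

#' @noRd
logInfo <- function(...) {
  if (isTRUE(getOption("PlantKGR.verbose", FALSE))) {
    message(format(Sys.time(), "%H:%M:%S"), " [INFO] ", ...)
  }
  invisible(NULL)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
# All stochastic operations in the package route through this so that a
# config seed fully determines the result without clobbering the session RNG.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream label; keeps independent
# stochastic components (noise edges, walks, negative draws, ...) decoupled
# while remaining a deterministic function of the user-facing seed.  Plain
# polynomial string hash mod a Mersenne prime; exact in double arithmetic.
deriveSeed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

leakyRelu <- function(x, slope = 0.01) {
  ifelse(x > 0, x, slope * x)
}
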