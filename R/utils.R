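# Internal numerical helpers shared across modules.

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Derive a reproducible 32-bit substream seed from a master seed and a label.
# Keeps every derived seed in [0, 2^31 - 1] so it is a valid R integer.
#' @keywords internal
derive_seed <- function(master, label, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":", index))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h + as.numeric(master) * 2654435) %% 2147483647)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Euclidean distance between 2D points (each a length-2 numeric).
#' @keywords internal
dist2 <- function(p, q) sqrt(sum((p - q)^2))

# Binary entropy in bits of a probability pair (or scalar p).
#' @keywords internal
binary_entropy <- function(p) {
  p <- unname(p[1L])
  if (p <= 0 || p >= 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

# Minimum-jerk time profile on [0, 1].
#' @keywords internal
minjerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards so package internals never perturb user randomness.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", .GlobalEnv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  expr
}

#' @keywords internal
ag_log <- function(..., level = "INFO") {
  if (isTRUE(getOption("activegaze.quiet", TRUE)) && identical(level, "INFO")) {
    return(invisible(NULL))
  }
  message(sprintf("[activegaze %s] %s", level, paste0(...)))
}
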