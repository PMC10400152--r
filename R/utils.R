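# internal helpers shared across modules

#' Trait labels handled by the package
#'
#' The nine leaf traits modeled throughout: macronutrients (percent of dry
#' matter), leaf water content (percent of fresh weight), chlorophyll content
#' (umol m-2) and leaf mass per area (g m-2).
#'
#' @format Character vector of length 9.
#' @export
TRAIT_NAMES <- c("N", "P", "K", "Mg", "Ca", "S", "LWC", "CHL", "LMA")

#' Trait measurement units
#'
#' Named character vector mapping each trait in [TRAIT_NAMES] to its unit.
#'
#' @format Named character vector.
#' @export
TRAIT_UNITS <- c(
  N = "%", P = "%", K = "%", Mg = "%", Ca = "%", S = "%",
  LWC = "%", CHL = "umol m-2", LMA = "g m-2"
)

# unit gaussian bump used for absorption features and smooth curves
gauss_band <- function(wl, center, width) {
  exp(-0.5 * ((wl - center) / width)^2)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards so seeded helpers compose without
# interfering with each other
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a stage seed from a root seed
#'
#' All randomness in pipeline runs flows from one root seed; per-stage seeds
#' are derived deterministically by folding the stage name into the root with
#' a small string hash, so a subcommand rerun reproduces the state of the
#' corresponding stage of a full run. The result is always in
#' `[1, 2^31 - 2]`.
#'
#' @param root integer root seed.
#' @param stage character stage name.
#' @return A single integer seed.
#' @export
derive_seed <- function(root, stage) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(stage))
  m <- 2147483563
  h <- 0
  for (code in utf8ToInt(paste(stage, collapse = "/"))) {
    h <- (h * 31 + code) %% m
  }
  s <- (abs(root) %% m + h) %% m
  as.integer(s + 1L)
}

# FNV-1a 32-bit hash of a character string, returned as 8 hex digits.
# Used to stamp output files with the hash of the run configuration.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  p <- 16777619
  m16 <- 65536
  m32 <- 4294967296
  for (b in bytes) {
    h <- bitwXor32(h, b)
    # (h * p) mod 2^32 without exceeding double precision
    hi <- h %/% m16
    lo <- h %% m16
    h <- (((hi * p) %% m16) * m16 + lo * p) %% m32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor of a 32-bit value (stored in a double) with a byte; bitwXor works on
# 31-bit-safe signed ints and the byte only touches the low bits
bitwXor32 <- function(h, b) {
  hi <- h %/% 2^31
  hi * 2^31 + bitwXor(as.integer(h %% 2^31), as.integer(b))
}

# stop() with call.=FALSE everywhere for clean user-facing messages
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
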