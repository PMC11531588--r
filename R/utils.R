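# internal helpers shared across modules

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code does not disturb the
#' caller's random stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  code
}

#' Centered moving average with edge shrinkage
#' @param x numeric vector
#' @param k window width (odd widths are symmetric); k <= 1 returns x
#' @keywords internal
#' @noRd
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Indices of strict-or-plateau local maxima of a vector
#' @keywords internal
#' @noRd
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      # walk over a possible plateau
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) {
        out <- c(out, as.integer(floor((i + j) / 2)))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Topographic prominence of local maxima
#'
#' For each peak, the height above the highest of the two minimal saddles
#' separating it from higher ground (or from the series edge).
#' @param x numeric series
#' @param peaks indices from [local_maxima()]
#' @return numeric vector of prominences, same length as `peaks`
#' @keywords internal
#' @noRd
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    # walk left until higher ground or edge, tracking minimum
    left_min <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) {
      left_min <- min(left_min, x[i])
      i <- i - 1L
    }
    if (i < 1L) left_min <- min(left_min, min(x[1:p]))
    right_min <- h
    i <- p + 1L
    n <- length(x)
    while (i <= n && x[i] <= h) {
      right_min <- min(right_min, x[i])
      i <- i + 1L
    }
    if (i > n) right_min <- min(right_min, min(x[p:n]))
    h - max(left_min, right_min)
  }, numeric(1))
}

# FNV-1a 32-bit hash of a string, as 8 hex characters. The bitw* family in
# base R is limited to 31-bit signed ints; do the xor in double arithmetic
# with explicit mod-2^32 reduction instead.
config_hash_string <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  m <- 2^32
  for (b in bytes) {
    h <- bitxor_dbl(h, b)
    h <- (h * p) %% m
  }
  # h < 2^32 may exceed integer range; format the hex by hand
  hi <- h %/% 65536
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer(hi), as.integer(lo))
}

bitxor_dbl <- function(a, b) {
  # xor of two non-negative doubles < 2^32
  r <- 0
  bit <- 1
  while (a > 0 || b > 0) {
    if ((a %% 2) != (b %% 2)) r <- r + bit
    a <- a %/% 2
    b <- b %/% 2
    bit <- bit * 2
  }
  r
}

#' Canonical JSON of a nested list with recursively sorted keys
#' @keywords internal
#' @noRd
canonical_json <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v)) {
      nm <- names(v)
      if (!is.null(nm) && any(nzchar(nm))) v <- v[order(nm)]
      lapply(v, sort_rec)
    } else v
  }
  as.character(jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
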