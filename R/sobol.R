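## Sobol' low-discrepancy sequences (unscrambled, Gray-code construction).
##
## Dimension 1 is the van der Corput sequence in base 2. Each further
## dimension is built from a primitive polynomial over GF(2),
##   x^s + a_1 x^{s-1} + ... + a_{s-1} x + 1,
## and odd initial direction numbers m_k < 2^k, extended by the recurrence
##   m_k = 2 a_1 m_{k-1} xor 4 a_2 m_{k-2} xor ... xor 2^s m_{k-s} xor m_{k-s}.
## Points are generated by the Antonov--Saleev Gray-code update, so the
## first point of the unskipped sequence is the origin.

.SOBOL_NBITS <- 30L

## one row per dimension >= 2: polynomial degree s, inner coefficients
## a_1..a_{s-1}, and initial direction numbers m_1..m_s. The polynomials are
## primitive over GF(2) (checked by an LFSR-period oracle in the test
## suite); the initial numbers are admissible (odd, m_k < 2^k).
.sobol_dims <- list(
  list(s = 1L, a = integer(0),       m = c(1L)),
  list(s = 2L, a = c(1L),            m = c(1L, 3L)),
  list(s = 3L, a = c(0L, 1L),        m = c(1L, 3L, 1L)),
  list(s = 3L, a = c(1L, 0L),        m = c(1L, 1L, 1L)),
  list(s = 4L, a = c(0L, 0L, 1L),    m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = c(1L, 0L, 0L),    m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = c(0L, 0L, 1L, 0L), m = c(1L, 1L, 5L, 5L, 17L)),
  list(s = 5L, a = c(0L, 1L, 0L, 0L), m = c(1L, 1L, 5L, 5L, 5L)),
  list(s = 5L, a = c(0L, 1L, 1L, 1L), m = c(1L, 1L, 7L, 11L, 19L)),
  list(s = 5L, a = c(1L, 0L, 1L, 1L), m = c(1L, 3L, 7L, 13L, 25L)),
  list(s = 5L, a = c(1L, 1L, 0L, 1L), m = c(1L, 1L, 5L, 9L, 29L)),
  list(s = 5L, a = c(1L, 1L, 1L, 0L), m = c(1L, 3L, 1L, 7L, 21L)),
  list(s = 6L, a = c(0L, 0L, 0L, 0L, 1L), m = c(1L, 1L, 3L, 13L, 25L, 47L)),
  list(s = 6L, a = c(1L, 0L, 0L, 0L, 0L), m = c(1L, 3L, 5L, 9L, 7L, 59L)),
  list(s = 6L, a = c(1L, 0L, 0L, 1L, 1L), m = c(1L, 1L, 7L, 3L, 29L, 51L)),
  list(s = 6L, a = c(1L, 1L, 0L, 0L, 1L), m = c(1L, 3L, 3L, 11L, 19L, 61L)),
  list(s = 6L, a = c(0L, 1L, 1L, 0L, 1L), m = c(1L, 1L, 5L, 15L, 9L, 37L)),
  list(s = 6L, a = c(1L, 0L, 1L, 1L, 0L), m = c(1L, 3L, 7L, 5L, 21L, 33L))
)

## direction numbers v_k = m_k * 2^(nbits - k) for one dimension
sobol_direction_numbers <- function(dim_index, nbits = .SOBOL_NBITS) {
  if (dim_index == 1L) {
    m <- rep(1L, nbits)
  } else {
    spec <- .sobol_dims[[dim_index - 1L]]
    s <- spec$s
    m <- integer(nbits)
    m[seq_len(s)] <- spec$m
    for (k in seq.int(s + 1L, nbits)) {
      acc <- bitwXor(bitwShiftL(m[k - s], s), m[k - s])
      if (s > 1L) for (i in seq_len(s - 1L)) {
        if (spec$a[i] == 1L)
          acc <- bitwXor(acc, bitwShiftL(m[k - i], i))
      }
      m[k] <- acc
    }
  }
  bitwShiftL(m, nbits - seq_len(nbits))
}

## n x d matrix of Sobol' points in [0,1)^d, after skipping `skip` points
sobol_matrix <- function(n, d, skip = 0L) {
  n <- as.integer(n); d <- as.integer(d); skip <- as.integer(skip)
  stopifnot(n >= 1L, d >= 1L, skip >= 0L)
  if (d > length(.sobol_dims) + 1L)
    stop(sprintf("Sobol' direction numbers available for up to %d dimensions",
                 length(.sobol_dims) + 1L), call. = FALSE)
  if (n + skip >= 2^.SOBOL_NBITS)
    stop("requested sequence length exceeds the generator's 2^30 period",
         call. = FALSE)
  V <- vapply(seq_len(d), sobol_direction_numbers,
              integer(.SOBOL_NBITS))           # nbits x d
  out <- matrix(0, n, d)
  x <- integer(d)
  total <- skip + n
  for (i in seq_len(total)) {
    if (i > skip) out[i - skip, ] <- x
    ## Gray-code position: index of the lowest zero bit of (i - 1)
    k <- i - 1L
    c <- 1L
    while (bitwAnd(k, 1L) == 1L) {
      k <- bitwShiftR(k, 1L)
      c <- c + 1L
    }
    x <- bitwXor(x, V[c, ])
  }
  out / 2^.SOBOL_NBITS
}

## period of the LFSR defined by a polynomial spec; equals 2^s - 1 iff the
## polynomial is primitive. Used by the test suite as an independent oracle.
lfsr_period <- function(s, a) {
  if (s == 1L) return(1L)                # x + 1: the only degree-1 choice
  state <- c(1L, integer(s - 1L))        # oldest bit first
  start <- state
  for (p in seq_len(2L^s)) {
    ## recurrence b_{t+1} = a_1 b_t + ... + a_{s-1} b_{t-s+2} + b_{t-s+1}
    fb <- (state[1L] + sum(a * state[s:2L])) %% 2L
    state <- c(state[-1L], fb)
    if (all(state == start)) return(p)
  }
  NA_integer_
}
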