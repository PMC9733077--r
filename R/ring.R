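#' Default ring modulus: the Mersenne prime 2^127 - 1
#'
#' The share arithmetic operates in the finite ring of integers modulo
#' \eqn{2^{127}-1}. The modulus is held as a decimal string because it
#' exceeds R's native integer and double precision.
#'
#' @return Decimal string `"170141183460469231731687303715884105727"`.
#' @export
ring_default_modulus <- function() {
  "170141183460469231731687303715884105727"
}

#' Ring configuration
#'
#' Bundles the ring modulus with the fixed-point scale used to embed signed
#' decimal values into the ring. Values are encoded as `round(x * scale)`
#' residues; negative values map to `modulus - |scaled x|`, so the
#' representable signed window is `[-(modulus-1)/2, (modulus-1)/2]` ring
#' units.
#'
#' @param modulus Odd integer >= 3, as a decimal string (or a small numeric
#'   for test rings such as 7, 11, 13). Default: the Mersenne prime
#'   \eqn{2^{127}-1}.
#' @param fixpoint_scale Power of ten >= 1 (default `1e6`, i.e. six decimal
#'   digits are carried exactly).
#' @return An object of class `ring_config` with fields `modulus` (string),
#'   `fixpoint_scale` (numeric) and `scale_digits` (integer).
#' @examples
#' cfg <- ring_config()
#' cfg$modulus
#' test_cfg <- ring_config(7, 1)
#' @export
ring_config <- function(modulus = ring_default_modulus(), fixpoint_scale = 1e6) {
  if (is.numeric(modulus)) {
    if (modulus != round(modulus) || modulus > 2^53)
      abort_ss("securesum_config_error",
               "numeric modulus must be an exact integer; pass large moduli as strings")
    modulus <- sprintf("%.0f", modulus)
  }
  if (!is.character(modulus) || length(modulus) != 1L || !grepl("^[0-9]+$", modulus))
    abort_ss("securesum_config_error", "modulus must be a decimal integer string")
  if (nchar(modulus) <= 15) {
    m <- as.numeric(modulus)
    if (m < 3) abort_ss("securesum_config_error", "modulus must be >= 3")
    if (m %% 2 == 0) abort_ss("securesum_config_error", "modulus must be odd")
  } else {
    last <- as.integer(substr(modulus, nchar(modulus), nchar(modulus)))
    if (last %% 2 == 0) abort_ss("securesum_config_error", "modulus must be odd")
  }
  digits <- log10(fixpoint_scale)
  if (length(fixpoint_scale) != 1L || is.na(digits) || digits != round(digits) ||
      digits < 0 || digits > 30)
    abort_ss("securesum_config_error",
             "fixpoint_scale must be a power of ten between 1 and 1e30")
  structure(
    list(modulus = modulus, fixpoint_scale = fixpoint_scale,
         scale_digits = as.integer(round(digits))),
    class = "ring_config"
  )
}

#' @export
print.ring_config <- function(x, ...) {
  cat("<ring_config> modulus =", x$modulus,
      " fixed-point scale = 10^", x$scale_digits, "\n", sep = "")
  invisible(x)
}

ring_same <- function(a, b) {
  identical(a$modulus, b$modulus) && identical(a$scale_digits, b$scale_digits)
}

# coerce numeric input to an exact decimal literal on the fixed-point grid
value_to_decimal_chr <- function(x, cfg) {
  if (is.character(x)) return(x)
  if (!is.numeric(x))
    abort_ss("securesum_encoding_error", "values must be numeric or decimal strings")
  if (any(!is.finite(x)))
    abort_ss("securesum_encoding_error", "values must be finite")
  scaled <- x * cfg$fixpoint_scale
  if (any(abs(scaled) > 2^53))
    abort_ss("securesum_range_error",
             "numeric value too large for exact double conversion; pass it as a decimal string")
  off <- abs(scaled - round(scaled))
  if (any(off > 1e-3))
    abort_ss("securesum_precision_error",
             "value has more fractional digits than the fixed-point scale allows (scale 10^%d)",
             cfg$scale_digits)
  sprintf(paste0("%.", cfg$scale_digits, "f"), x)
}

#' Encode decimal values into the ring
#'
#' Maps a signed decimal value onto its fixed-point ring representative:
#' `x * fixpoint_scale` must be an integer (excess fractional digits are an
#' error, never rounded, so pooled sums cannot depend on party-local
#' rounding) and its magnitude must stay within `(modulus-1)/2`.
#'
#' Values may be given as numerics or, for exact decimal semantics and for
#' magnitudes beyond double precision, as decimal strings like
#' `"-12345.5"`.
#'
#' @param x Numeric vector or character vector of decimal literals.
#' @param cfg A [ring_config()].
#' @return Character vector of ring elements (decimal strings in
#'   `[0, modulus)`).
#' @examples
#' cfg <- ring_config()
#' encode_value(1.5, cfg)    # "1500000"
#' encode_value("-1", cfg)   # modulus - 1000000
#' @seealso [decode_value()]
#' @export
encode_value <- function(x, cfg) {
  stopifnot(inherits(cfg, "ring_config"))
  dec <- value_to_decimal_chr(x, cfg)
  tryCatch(
    fixed_encode_cpp(dec, cfg$modulus, cfg$scale_digits),
    error = function(e) {
      msg <- conditionMessage(e)
      cls <- if (grepl("^precision error", msg)) "securesum_precision_error"
             else if (grepl("^range error", msg)) "securesum_range_error"
             else "securesum_encoding_error"
      abort_ss(cls, "%s", msg)
    }
  )
}

#' Decode ring elements back to decimal values
#'
#' Inverse of [encode_value()] on the representable window: residues above
#' `(modulus-1)/2` decode as negative values.
#'
#' @param e Character vector of ring elements.
#' @param cfg A [ring_config()].
#' @param as `"numeric"` (default) or `"character"` for the exact decimal
#'   string without binary floating-point noise.
#' @return Numeric vector, or exact decimal strings.
#' @export
decode_value <- function(e, cfg, as = c("numeric", "character")) {
  stopifnot(inherits(cfg, "ring_config"))
  as <- match.arg(as)
  chr <- fixed_decode_cpp(as.character(e), cfg$modulus, cfg$scale_digits)
  if (as == "character") chr else as.numeric(chr)
}

#' Add two ring elements locally
#'
#' `(a + b) mod modulus`, elementwise. This is the only arithmetic the
#' protocol ever needs: additions on shares compose locally without
#' interaction.
#'
#' @param a,b Character vectors of ring elements (recycled if scalar).
#' @param cfg A [ring_config()].
#' @return Character vector of ring elements.
#' @export
add_local <- function(a, b, cfg) {
  stopifnot(inherits(cfg, "ring_config"))
  big_mod_add(as.character(a), as.character(b), cfg$modulus)
}

#' Reconstruct a secret from its shares
#'
#' The combination of all shares — their sum modulo the ring size — yields
#' the secret. With fewer than all shares the sum is uniformly distributed
#' and carries no information (full-threshold security).
#'
#' @param shares Character vector of ring elements, one per party.
#' @param cfg A [ring_config()].
#' @return A single ring element (decimal string).
#' @export
reconstruct <- function(shares, cfg) {
  stopifnot(inherits(cfg, "ring_config"))
  if (length(shares) == 0L)
    abort_ss("securesum_share_error", "cannot reconstruct from an empty share list")
  big_mod_sum(as.character(shares), cfg$modulus)
}

#' Split a secret into additive shares
#'
#' Draws `n_parties - 1` shares uniformly from `[0, modulus)` and sets the
#' last share to the remainder, so that the shares sum to the secret modulo
#' the ring size. The first `n_parties - 1` shares are pure randomness,
#' independent of the secret.
#'
#' @param secret A ring element (decimal string).
#' @param n_parties Number of shares, >= 2.
#' @param cfg A [ring_config()].
#' @param rng Randomness source: a `function(k, modulus)` returning `k`
#'   uniform ring elements. Defaults to the cryptographic [secure_rng()];
#'   [insecure_seeded_rng()] is available for reproducible tests only.
#' @return Character vector of `n_parties` ring elements.
#' @examples
#' cfg <- ring_config(7, 1)
#' s <- make_shares("3", 3, cfg, rng = insecure_seeded_rng(1))
#' reconstruct(s, cfg)  # "3"
#' @export
make_shares <- function(secret, n_parties, cfg, rng = secure_rng()) {
  stopifnot(inherits(cfg, "ring_config"))
  if (length(secret) != 1L)
    abort_ss("securesum_share_error", "make_shares takes a single secret; see make_share_matrix")
  if (!is.numeric(n_parties) || n_parties < 2)
    abort_ss("securesum_share_error", "n_parties must be >= 2")
  make_share_matrix(secret, as.integer(n_parties), cfg, rng)[, 1L]
}

#' Share a vector of secrets for n parties at once
#'
#' Vectorised form of [make_shares()]: returns an `n_parties x v` matrix
#' whose column sums (mod modulus) equal the secrets. Rows `1..n-1` are
#' uniform draws; row `n` holds the remainders.
#'
#' @inheritParams make_shares
#' @param secrets Character vector of `v` ring elements.
#' @return `n_parties x v` character matrix; row `i` is party `i`'s share
#'   vector.
#' @export
make_share_matrix <- function(secrets, n_parties, cfg, rng = secure_rng()) {
  stopifnot(inherits(cfg, "ring_config"))
  if (!is.numeric(n_parties) || n_parties < 2)
    abort_ss("securesum_share_error", "n_parties must be >= 2")
  n <- as.integer(n_parties)
  v <- length(secrets)
  secrets <- as.character(secrets)
  if (!all(big_mod_valid(secrets, cfg$modulus)))
    abort_ss("securesum_share_error", "secrets must be valid ring elements")
  draws <- rng((n - 1L) * v, cfg$modulus)
  if (length(draws) != (n - 1L) * v || !all(big_mod_valid(draws, cfg$modulus)))
    abort_ss("securesum_rng_error", "rng returned an invalid draw set")
  r <- matrix(draws, nrow = n - 1L, ncol = v)
  acc <- r[1L, ]
  if (n > 2L) for (i in 2L:(n - 1L)) acc <- big_mod_add(acc, r[i, ], cfg$modulus)
  last <- big_mod_sub(secrets, acc, cfg$modulus)
  rbind(r, last, deparse.level = 0)
}

#' Per-variable share bundle
#'
#' A `share_vector` couples one party's shares (one ring element per
#' variable) with the ring they live in; mixed-ring arithmetic is refused.
#'
#' @param shares Character vector of ring elements.
#' @param ring A [ring_config()].
#' @return A `share_vector` object.
#' @export
share_vector <- function(shares, ring) {
  stopifnot(inherits(ring, "ring_config"))
  shares <- as.character(shares)
  if (!all(big_mod_valid(shares, ring$modulus)))
    abort_ss("securesum_share_error", "invalid element for this ring")
  structure(shares, class = "share_vector", ring = ring)
}

#' @export
print.share_vector <- function(x, ...) {
  cat("<share_vector> ", length(x), " element(s) mod ",
      attr(x, "ring")$modulus, "\n", sep = "")
  invisible(x)
}

#' Add two share vectors elementwise
#'
#' The local aggregation step between communication rounds: each party sums
#' the share vectors it holds, elementwise modulo the ring size.
#'
#' @param a,b `share_vector` objects of equal length over the same ring.
#' @return A `share_vector` of the elementwise sums.
#' @export
add_share_vectors <- function(a, b) {
  if (!inherits(a, "share_vector") || !inherits(b, "share_vector"))
    abort_ss("securesum_share_error", "both arguments must be share_vector objects")
  ra <- attr(a, "ring"); rb <- attr(b, "ring")
  if (!ring_same(ra, rb))
    abort_ss("securesum_share_error", "share vectors live in different rings")
  if (length(a) != length(b))
    abort_ss("securesum_share_error", "share vector length mismatch: %d vs %d",
             length(a), length(b))
  share_vector(big_mod_add(unclass(a), unclass(b), ra$modulus), ra)
}

# ---- randomness sources ----------------------------------------------------

draw_uniform <- function(k, modulus, byte_source) {
  if (k == 0L) return(character(0))
  out <- character(0)
  while (length(out) < k) {
    need <- k - length(out)
    bytes <- byte_source(16L * (need + 8L))
    out <- c(out, big_from_bytes(bytes, modulus))
  }
  out[seq_len(k)]
}

#' Cryptographic randomness source for share generation
#'
#' Returns a `function(k, modulus)` yielding `k` exactly-uniform draws from
#' `[0, modulus)`, fed by the operating system entropy pool
#' (`/dev/urandom`) and de-biased by rejection sampling. Share uniformity is
#' the entire security argument, so this is the default everywhere.
#'
#' @return A drawing function for [make_shares()] and the protocol layer.
#' @export
secure_rng <- function() {
  f <- function(k, modulus) {
    draw_uniform(as.integer(k), modulus, function(nb) {
      con <- file("/dev/urandom", open = "rb", raw = TRUE)
      on.exit(close(con))
      readBin(con, what = "raw", n = nb)
    })
  }
  attr(f, "insecure") <- FALSE
  f
}

#' Deterministic randomness source — insecure, for tests and benchmarks only
#'
#' Draws bytes from R's seeded Mersenne-Twister stream instead of the OS
#' entropy pool. Shares produced this way are reproducible and therefore
#' NOT confidential; the function is deliberately named to flag that.
#'
#' @param seed Integer seed.
#' @return A drawing function with attribute `insecure = TRUE`.
#' @export
insecure_seeded_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$rng_state <- NULL
  f <- function(k, modulus) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    if (is.null(env$rng_state)) set.seed(seed) else assign(".Random.seed", env$rng_state, globalenv())
    out <- draw_uniform(as.integer(k), modulus, function(nb) {
      as.raw(sample.int(256L, nb, replace = TRUE) - 1L)
    })
    env$rng_state <- get(".Random.seed", globalenv())
    out
  }
  attr(f, "insecure") <- TRUE
  f
}

#' Fixed-sequence randomness stub for exhaustive small-ring analyses
#'
#' Yields a preset sequence of draws, erroring when exhausted. Used to
#' enumerate every possible sharing of a secret in a small test ring and so
#' verify the full-threshold privacy property exactly.
#'
#' @param values Character (or numeric) vector of preset draws.
#' @return A drawing function with attribute `insecure = TRUE`.
#' @export
stub_rng <- function(values) {
  values <- as.character(values)
  env <- new.env(parent = emptyenv())
  env$pos <- 0L
  f <- function(k, modulus) {
    k <- as.integer(k)
    if (env$pos + k > length(values))
      abort_ss("securesum_rng_error", "stub rng exhausted")
    out <- values[env$pos + seq_len(k)]
    env$pos <- env$pos + k
    out
  }
  attr(f, "insecure") <- TRUE
  f
}
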