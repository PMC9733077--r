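#' Generate a synthetic secure-summation study
#'
#' Deterministic fixture for scaling studies: `n` parties, `v` variables
#' with 10-random-letter names, and per-party values spanning the
#' magnitude range of single-precision floating-point numbers (bounded to
#' +/- 1e30 so that pooled sums of up to 20 parties stay inside the signed
#' fixed-point window of the default ring). Values are sampled
#' uniform-in-exponent: a 7-significant-digit mantissa times 10^e with e
#' drawn uniformly from -6..23, so every value sits exactly on the 10^-6
#' fixed-point grid. Ground-truth pooled sums are computed by exact
#' (non-modular) 128-bit decimal summation, independently of the ring
#' arithmetic.
#'
#' @param n Number of parties, >= 3.
#' @param v Number of variables, >= 1.
#' @param seed Integer seed; regeneration from `(n, v, seed)` is
#'   byte-identical.
#' @return A `synthetic_study`: `n`, `v`, `seed`, `addresses`,
#'   `variable_names`, `values` (n x v character matrix of exact decimal
#'   literals, rows = parties) and `ground_truth` (exact decimal strings of
#'   the pooled sums).
#' @export
generate_study <- function(n, v, seed = 0L) {
  if (!is.numeric(n) || n < 3) abort_ss("securesum_bench_error", "n must be >= 3")
  if (!is.numeric(v) || v < 1) abort_ss("securesum_bench_error", "v must be >= 1")
  n <- as.integer(n); v <- as.integer(v)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))

  vnames <- character(0)
  while (length(vnames) < v) {
    fresh <- apply(matrix(sample(letters, 10L * (v - length(vnames)), replace = TRUE),
                          ncol = 10L), 1L, paste, collapse = "")
    vnames <- unique(c(vnames, fresh))
  }
  vnames <- vnames[seq_len(v)]

  k <- n * v
  mant <- sprintf("%07d", sample(1000000:9999999, k, replace = TRUE))
  expo <- sample(-6:23, k, replace = TRUE)
  sign <- sample(c("", "-"), k, replace = TRUE)
  lit <- character(k)
  neg_e <- expo < 0
  lit[!neg_e] <- paste0(mant[!neg_e],
                        strrep("0", pmax(expo[!neg_e], 0)))
  if (any(neg_e)) {
    m <- mant[neg_e]; e <- -expo[neg_e]  # e in 1..6, mantissa has 7 digits
    lit[neg_e] <- paste0(substr(m, 1L, 7L - e), ".", substr(m, 8L - e, 7L))
  }
  values <- matrix(paste0(sign, lit), nrow = n, ncol = v,
                   dimnames = list(NULL, vnames))
  ground_truth <- vapply(seq_len(v), function(j) dec_fixed_sum(values[, j], 6L), "")
  structure(
    list(n = n, v = v, seed = as.integer(seed),
         addresses = sprintf("party%02d@study.local", seq_len(n)),
         variable_names = vnames, values = values,
         ground_truth = stats::setNames(ground_truth, vnames)),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> n = %d parties, v = %d variable(s), seed = %d\n",
              x$n, x$v, x$seed))
  invisible(x)
}

#' Run a scaling benchmark over a grid of study sizes
#'
#' For every `(n, v)` cell, generates a synthetic study, executes one full
#' secure-summation cycle over an in-memory bus, verifies the reconstructed
#' sums against the exact ground truth (any mismatch aborts loudly), and
#' records message, chunk and byte counts plus wall-clock time. With `n`
#' participants every cycle delivers exactly `2 * n * (n - 1)` envelopes.
#'
#' @param n_list,v_list Grid of participant and variable counts.
#' @param repeats Repetitions per cell (seeds vary per repeat).
#' @param max_message_size Bus chunk-size limit in bytes.
#' @param seed Base seed; cell `(i, j)`, repeat `r` derives its own.
#' @return Data frame with one row per run: `n`, `v`, `rep`,
#'   `envelopes`, `chunks`, `bytes`, `bytes_per_pair`, `seconds`, `exact`.
#' @export
run_benchmark <- function(n_list, v_list, repeats = 1L,
                          max_message_size = 10 * 2^20, seed = 1L) {
  grid <- expand.grid(n = n_list, v = v_list, rep = seq_len(repeats))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    n <- grid$n[i]; v <- grid$v[i]; r <- grid$rep[i]
    cell_seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    study <- generate_study(n, v, seed = cell_seed)
    bus <- memory_bus(max_message_size = max_message_size)
    values <- lapply(seq_len(n), function(p)
      stats::setNames(study$values[p, ], study$variable_names))
    names(values) <- study$addresses
    t0 <- proc.time()[["elapsed"]]
    out <- run_secure_sum(values, study_name = sprintf("bench-n%d-v%d", n, v),
                          variable_names = study$variable_names,
                          bus = bus, rng = insecure_seeded_rng(cell_seed + 1L))
    secs <- proc.time()[["elapsed"]] - t0
    exact <- identical(unname(out$result$exact), unname(study$ground_truth))
    if (!exact)
      abort_ss("securesum_bench_error",
               "benchmark cell n=%d v=%d: reconstructed sums differ from ground truth",
               n, v)
    st <- out$bus_stats
    data.frame(n = n, v = v, rep = r,
               envelopes = st$envelopes_sent, chunks = st$chunks_sent,
               bytes = st$bytes_sent,
               bytes_per_pair = st$bytes_sent / (st$envelopes_sent * v),
               seconds = secs, exact = exact)
  })
  do.call(rbind, rows)
}
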