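# Shared fixtures and independent oracles, all built in code.

TEST_P <- ring_default_modulus()

# a tiny ring for exhaustive checks
ring7 <- function() ring_config(7, 1)
ring11 <- function() ring_config(11, 1)
ring13 <- function() ring_config(13, 1)

# expand a grouped frequency table back to raw values (brute-force oracle)
expand_freq <- function(counts) rep(names(counts), counts)

# values on the quarter grid are binary-exact in doubles, so plain double
# sums are an independent exact oracle for pooled results
rand_grid_values <- function(k, lo = -100, hi = 100) {
  round(runif(k, lo, hi) * 4) / 4
}

# named party value lists for run_secure_sum
party_values <- function(mat) {
  vals <- lapply(seq_len(nrow(mat)), function(i) mat[i, ])
  names(vals) <- sprintf("p%d@test", seq_len(nrow(mat)))
  vals
}

three_party_def <- function(vars = c("a", "b")) {
  study_definition(
    "unit-study",
    data.frame(name = c("Ann", "Ben", "Cleo"),
               address = c("ann@x", "ben@x", "cleo@x")),
    vars
  )
}

# drive a set of already-joined sessions to completion over a bus,
# buffering early round-2 envelopes like a real deployment would
finish_sessions <- function(sessions, bus) {
  pending <- replicate(length(sessions), list(), simplify = FALSE)
  names(pending) <- names(sessions)
  for (iter in 1:50) {
    if (all(vapply(sessions, function(s) s$state == "FINISHED", TRUE))) break
    for (addr in names(sessions)) {
      if (sessions[[addr]]$state == "FINISHED") next
      envs <- c(pending[[addr]], bus_poll(bus, addr))
      pending[[addr]] <- list()
      for (e in envs) {
        res <- tryCatch(receive_message(sessions[[addr]], e),
                        securesum_wrong_round = function(c) c)
        if (inherits(res, "condition")) pending[[addr]] <- c(pending[[addr]], list(e))
        else sessions[[addr]] <- res
      }
      while (can_advance(sessions[[addr]])) {
        step <- advance(sessions[[addr]])
        sessions[[addr]] <- step$session
        for (e in step$envelopes) bus_send(bus, e)
        if (sessions[[addr]]$state == "RESULT_SENDING")
          sessions[[addr]] <- mark_round_sent(sessions[[addr]])
        envs <- pending[[addr]]; pending[[addr]] <- list()
        for (e in envs) {
          res <- tryCatch(receive_message(sessions[[addr]], e),
                          securesum_wrong_round = function(c) c)
          if (inherits(res, "condition")) pending[[addr]] <- c(pending[[addr]], list(e))
          else sessions[[addr]] <- res
        }
      }
    }
  }
  sessions
}
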