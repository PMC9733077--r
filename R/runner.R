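#' Run one full secure-summation cycle in-process
#'
#' Drives every party of a study through the complete two-round protocol
#' over a store-and-forward bus: the initiator creates the study, the other
#' parties join from their invitation envelopes, and all sessions are
#' polled and advanced until every one is `FINISHED`. Sessions remain
#' strict about rounds — a round-2 envelope that arrives while a party is
#' still collecting round-1 shares is buffered by the runner and
#' redelivered once that party has advanced, as a real store-and-forward
#' deployment must.
#'
#' Intended for tests, benchmarks and the distributed-statistics layer; a
#' real multi-institution study runs one session per process against a
#' shared [maildir_bus()].
#'
#' @param values_by_party Named list: mailbox address -> value vector (one
#'   per variable; numeric or decimal strings; named vectors are matched to
#'   the variable names).
#' @param study_name Study name (default `"study"`).
#' @param variable_names Variable names; defaults to the names of the first
#'   party's value vector, else `v1..vk`.
#' @param ring A [ring_config()].
#' @param bus A bus object; defaults to a fresh [memory_bus()].
#' @param rng Randomness source shared by all in-process parties.
#' @return List with `result` (data frame `variable`, `sum`, `exact`),
#'   `sessions` (per-party finished sessions), `bus`, and `bus_stats`.
#' @examples
#' out <- run_secure_sum(
#'   list("a@x" = c(v = 1), "b@x" = c(v = 2), "c@x" = c(v = 3)),
#'   rng = insecure_seeded_rng(1)
#' )
#' out$result$sum  # 6
#' @export
run_secure_sum <- function(values_by_party, study_name = "study",
                           variable_names = NULL, ring = ring_config(),
                           bus = memory_bus(), rng = secure_rng()) {
  addrs <- names(values_by_party)
  if (is.null(addrs) || any(!nzchar(addrs)))
    abort_ss("securesum_roster_error", "values_by_party must be a named list (address -> values)")
  if (is.null(variable_names)) {
    variable_names <- names(values_by_party[[1]])
    if (is.null(variable_names))
      variable_names <- paste0("v", seq_along(values_by_party[[1]]))
  }
  def <- study_definition(
    study_name,
    data.frame(name = paste("Party", seq_along(addrs)), address = addrs,
               stringsAsFactors = FALSE),
    variable_names
  )

  sessions <- vector("list", length(addrs))
  names(sessions) <- addrs
  pending <- replicate(length(addrs), list(), simplify = FALSE)
  names(pending) <- addrs

  dispatch <- function(envs) for (e in envs) bus_send(bus, e)

  init <- create_study(def, values_by_party[[1]], ring = ring, rng = rng)
  dispatch(init$envelopes)
  sessions[[1]] <- mark_round_sent(init$session)

  deliver <- function(addr, envs) {
    # strict sessions reject early round-2 traffic; buffer and retry later
    for (e in envs) {
      res <- tryCatch(receive_message(sessions[[addr]], e),
                      securesum_wrong_round = function(cond) cond)
      if (inherits(res, "condition")) {
        pending[[addr]] <<- c(pending[[addr]], list(e))
      } else {
        sessions[[addr]] <<- res
      }
    }
  }

  for (addr in addrs[-1]) {
    polled <- bus_poll(bus, addr)
    is_hello <- vapply(polled, function(e)
      grepl("\"type\":\"hello\"", e$payload, fixed = TRUE), TRUE)
    if (!any(is_hello))
      abort_ss("securesum_bus_error", "no study invitation found for %s", addr)
    joined <- join_study(polled[[which(is_hello)[1]]], values_by_party[[addr]],
                         rng = rng)
    dispatch(joined$envelopes)
    sessions[[addr]] <- mark_round_sent(joined$session)
    deliver(addr, polled[!is_hello])
  }

  guard <- 0L
  while (any(!vapply(sessions, function(s) s$state == "FINISHED", TRUE))) {
    guard <- guard + 1L
    if (guard > 10L * length(addrs))
      abort_ss("securesum_protocol_error", "protocol failed to converge")
    for (addr in addrs) {
      if (sessions[[addr]]$state == "FINISHED") next
      retry <- pending[[addr]]
      pending[[addr]] <- list()
      deliver(addr, retry)
      deliver(addr, bus_poll(bus, addr))
      if (can_advance(sessions[[addr]])) {
        step <- advance(sessions[[addr]])
        sessions[[addr]] <- step$session
        dispatch(step$envelopes)
        if (sessions[[addr]]$state == "RESULT_SENDING")
          sessions[[addr]] <- mark_round_sent(sessions[[addr]])
        # an early-buffered round-2 envelope may now be acceptable
        retry <- pending[[addr]]
        pending[[addr]] <- list()
        deliver(addr, retry)
        if (can_advance(sessions[[addr]])) {
          step <- advance(sessions[[addr]])
          sessions[[addr]] <- step$session
          dispatch(step$envelopes)
        }
      }
    }
  }

  results <- lapply(sessions, session_result)
  for (r in results[-1]) {
    if (!identical(r$exact, results[[1]]$exact))
      abort_ss("securesum_protocol_error", "parties reconstructed differing results")
  }
  list(result = results[[1]], sessions = sessions, bus = bus,
       bus_stats = bus_stats(bus))
}
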