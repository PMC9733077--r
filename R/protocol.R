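#' Protocol states
#'
#' A finite state machine guards the two-round secure-summation cycle:
#' `CREATED -> INITIAL_SENDING -> INITIAL_RECEIVING -> RESULT_SENDING ->
#' RESULT_RECEIVING -> FINISHED`, with `ABORTED` reachable from every
#' non-finished state. Any other transition attempt is a protocol error and
#' leaves the session unchanged.
#'
#' @format Character vector of the seven state names.
#' @export
PROTOCOL_STATES <- c("CREATED", "INITIAL_SENDING", "INITIAL_RECEIVING",
                     "RESULT_SENDING", "RESULT_RECEIVING", "FINISHED",
                     "ABORTED")

#' Study participant
#'
#' Participants are identified by a display name and a unique mailbox
#' address.
#'
#' @param display_name Human-readable name.
#' @param address Non-empty mailbox address, unique within a study.
#' @return A `participant` object.
#' @export
participant <- function(display_name, address) {
  if (!is.character(address) || length(address) != 1L || !nzchar(address))
    abort_ss("securesum_roster_error", "participant address must be a non-empty string")
  structure(list(display_name = as.character(display_name), address = address),
            class = "participant")
}

#' Study definition
#'
#' The shared description of one secure-summation study: its name, the
#' ordered participant roster (index 1 is the initiator) and the ordered
#' list of uniquely named variables to be summed. A study needs the
#' initiator plus at least two additional participants, because with only
#' two parties each could derive the other's input from the published sum.
#'
#' @param study_name Non-empty study name.
#' @param participants List of [participant()] objects (or a data frame
#'   with columns `name`, `address`), length >= 3, unique addresses.
#' @param variable_names Character vector of unique, non-empty names.
#' @return A `study_definition` object.
#' @export
study_definition <- function(study_name, participants, variable_names) {
  if (!is.character(study_name) || length(study_name) != 1L || !nzchar(study_name))
    abort_ss("securesum_roster_error", "study name must be a non-empty string")
  if (is.data.frame(participants)) {
    roster <- data.frame(name = as.character(participants$name),
                         address = as.character(participants$address),
                         stringsAsFactors = FALSE)
  } else {
    roster <- data.frame(
      name = vapply(participants, function(p) p$display_name, ""),
      address = vapply(participants, function(p) p$address, ""),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(roster) < 3L)
    abort_ss("securesum_roster_error",
             "a study needs the initiator and two or more additional participants (got %d total)",
             nrow(roster))
  if (any(!nzchar(roster$address)) || anyDuplicated(roster$address))
    abort_ss("securesum_roster_error", "participant addresses must be non-empty and unique")
  variable_names <- as.character(variable_names)
  if (length(variable_names) < 1L || any(!nzchar(variable_names)) ||
      anyDuplicated(variable_names))
    abort_ss("securesum_roster_error", "variable names must be non-empty and unique")
  structure(list(study_name = study_name, participants = roster,
                 variable_names = variable_names),
            class = "study_definition")
}

#' @export
print.study_definition <- function(x, ...) {
  cat(sprintf("<study_definition> '%s': %d participants, %d variable(s)\n",
              x$study_name, nrow(x$participants), length(x$variable_names)))
  invisible(x)
}

#' Digest of a study definition
#'
#' Short CRC-32 digest over the canonical roster, variable list and ring
#' settings; carried in every envelope so that messages from a diverging
#' study definition are rejected.
#'
#' @param def A [study_definition()].
#' @param ring The study's [ring_config()].
#' @return 8-hex-digit digest string.
#' @export
study_digest <- function(def, ring) {
  crc32_hex(paste(
    def$study_name,
    paste(def$participants$name, def$participants$address, collapse = ";"),
    paste(def$variable_names, collapse = ";"),
    ring$modulus, ring$scale_digits,
    sep = "|"
  ))
}

new_session <- function(def, ring, self_index, own_secrets, kept_share) {
  structure(
    list(definition = def, ring = ring, self_index = self_index,
         own_secrets = own_secrets, kept_share = kept_share,
         intermediate = NULL, result_elements = NULL,
         received1 = list(), received2 = list(),
         state = "CREATED", history = "CREATED"),
    class = "study_session"
  )
}

#' @export
print.study_session <- function(x, ...) {
  cat(sprintf("<study_session> '%s' as %s (%d/%d): %s; round-1 %d/%d, round-2 %d/%d\n",
              x$definition$study_name, session_address(x), x$self_index,
              nrow(x$definition$participants), x$state,
              length(x$received1), nrow(x$definition$participants) - 1L,
              length(x$received2), nrow(x$definition$participants) - 1L))
  invisible(x)
}

session_address <- function(session) {
  session$definition$participants$address[session$self_index]
}

set_state <- function(session, to) {
  legal <- list(
    CREATED = c("INITIAL_SENDING", "ABORTED"),
    INITIAL_SENDING = c("INITIAL_RECEIVING", "ABORTED"),
    INITIAL_RECEIVING = c("RESULT_SENDING", "ABORTED"),
    RESULT_SENDING = c("RESULT_RECEIVING", "ABORTED"),
    RESULT_RECEIVING = c("FINISHED", "ABORTED"),
    FINISHED = character(0),
    ABORTED = character(0)
  )
  if (!to %in% legal[[session$state]])
    abort_ss("securesum_protocol_error", "illegal state transition %s -> %s",
             session$state, to)
  session$state <- to
  session$history <- c(session$history, to)
  session
}

encode_own_values <- function(own_values, def, ring) {
  if (length(own_values) != length(def$variable_names))
    abort_ss("securesum_protocol_error",
             "expected %d values (one per variable), got %d",
             length(def$variable_names), length(own_values))
  if (!is.null(names(own_values)))
    own_values <- own_values[def$variable_names]
  encode_value(unname(own_values), ring)
}

# share values are plain digit strings, so the (potentially very long)
# JSON array is assembled directly instead of through a generic serializer
share_payload <- function(type, shares, def = NULL, ring = NULL) {
  shares_json <- if (length(shares) > 0)
    paste0('["', paste(unname(shares), collapse = '","'), '"]') else "[]"
  if (is.null(def))
    return(paste0('{"type":"', type, '","shares":', shares_json, "}"))
  def_json <- jsonlite::toJSON(
    list(study_name = def$study_name,
         participants = def$participants,
         variables = def$variable_names,
         ring = list(modulus = ring$modulus, fixpoint_scale = ring$fixpoint_scale)),
    auto_unbox = TRUE, digits = NA)
  paste0('{"type":"', type, '","definition":', as.character(def_json),
         ',"shares":', shares_json, "}")
}

round1_envelopes <- function(def, ring, self_index, share_rows, include_def) {
  digest <- study_digest(def, ring)
  self_addr <- def$participants$address[self_index]
  others <- setdiff(seq_len(nrow(def$participants)), self_index)
  lapply(others, function(i) {
    message_envelope(
      study_name = def$study_name, sender = self_addr,
      recipient = def$participants$address[i], round = "ROUND1",
      roster_digest = digest,
      payload = share_payload(if (include_def) "hello" else "share1",
                              share_rows[[i]],
                              def = if (include_def) def, ring = ring)
    )
  })
}

# share each variable for n parties; keep the remainder row, send the
# uniform rows (a transmitted round-1 share is then pure randomness)
share_own_secrets <- function(def, ring, self_index, secrets, rng) {
  n <- nrow(def$participants)
  mat <- make_share_matrix(secrets, n, ring, rng)
  others <- setdiff(seq_len(n), self_index)
  rows <- vector("list", n)
  for (k in seq_along(others)) rows[[others[k]]] <- mat[k, , drop = TRUE]
  list(kept = mat[n, , drop = TRUE], rows = rows)
}

#' Create a study (initiator)
#'
#' Encodes the initiator's secret values, splits them into one share vector
#' per participant, keeps one vector and wraps the others in round-1
#' envelopes — each carrying the full study definition and ring settings so
#' recipients can initialize their own sessions.
#'
#' @param def A [study_definition()]; the caller is participant 1.
#' @param own_values Numeric vector or decimal strings, one per variable
#'   (a named vector is matched to the variable names).
#' @param ring A [ring_config()].
#' @param rng Randomness source, see [secure_rng()].
#' @return List with `session` (state `INITIAL_SENDING`) and `envelopes`
#'   (n-1 round-1 envelopes to dispatch).
#' @export
create_study <- function(def, own_values, ring = ring_config(),
                         rng = secure_rng()) {
  stopifnot(inherits(def, "study_definition"), inherits(ring, "ring_config"))
  secrets <- encode_own_values(own_values, def, ring)
  sh <- share_own_secrets(def, ring, 1L, secrets, rng)
  session <- new_session(def, ring, 1L, secrets, sh$kept)
  session <- set_state(session, "INITIAL_SENDING")
  list(session = session,
       envelopes = round1_envelopes(def, ring, 1L, sh$rows, include_def = TRUE))
}

parse_definition_payload <- function(payload) {
  body <- tryCatch(jsonlite::fromJSON(payload, simplifyVector = TRUE),
                   error = function(e)
                     abort_ss("securesum_parse_error", "malformed payload JSON"))
  if (!identical(body$type, "hello") || is.null(body$definition))
    abort_ss("securesum_protocol_error",
             "not an initial study invitation (payload type '%s')",
             body$type %||% "?")
  d <- body$definition
  def <- study_definition(
    d$study_name,
    data.frame(name = d$participants$name, address = d$participants$address,
               stringsAsFactors = FALSE),
    d$variables
  )
  ring <- ring_config(d$ring$modulus, d$ring$fixpoint_scale)
  list(def = def, ring = ring, shares = as.character(body$shares))
}

#' Join a study from an invitation envelope
#'
#' Initializes a session from the study definition embedded in the
#' initiator's round-1 envelope, records the initiator's share, encodes and
#' shares the joiner's own secrets, and produces round-1 envelopes for
#' every other participant (including the initiator).
#'
#' @param initial A round-1 invitation [message_envelope()] addressed to
#'   this party.
#' @param own_values Values for the study's variables, as in
#'   [create_study()].
#' @param rng Randomness source.
#' @param own_address Claimed mailbox address; defaults to the envelope's
#'   recipient and must appear in the roster.
#' @return List with `session` (state `INITIAL_SENDING`, initiator's share
#'   already recorded) and `envelopes`.
#' @export
join_study <- function(initial, own_values, rng = secure_rng(),
                       own_address = initial$recipient) {
  stopifnot(inherits(initial, "message_envelope"))
  parsed <- parse_definition_payload(initial$payload)
  def <- parsed$def; ring <- parsed$ring
  self_index <- match(own_address, def$participants$address)
  if (is.na(self_index))
    abort_ss("securesum_roster_error", "address '%s' is not in the study roster",
             own_address)
  if (!identical(initial$roster_digest, study_digest(def, ring)))
    abort_ss("securesum_protocol_error", "roster digest does not match the embedded definition")
  secrets <- encode_own_values(own_values, def, ring)
  sh <- share_own_secrets(def, ring, self_index, secrets, rng)
  session <- new_session(def, ring, self_index, secrets, sh$kept)
  session <- set_state(session, "INITIAL_SENDING")
  session <- record_share(session, 1L, parsed$shares, "received1")
  list(session = session,
       envelopes = round1_envelopes(def, ring, self_index, sh$rows,
                                    include_def = FALSE))
}

record_share <- function(session, sender_index, shares, slot) {
  if (length(shares) != length(session$definition$variable_names))
    abort_ss("securesum_protocol_error",
             "share vector length %d does not match %d variables",
             length(shares), length(session$definition$variable_names))
  if (!all(big_mod_valid(shares, session$ring$modulus)))
    abort_ss("securesum_protocol_error", "share vector contains invalid ring elements")
  key <- as.character(sender_index)
  existing <- session[[slot]][[key]]
  if (!is.null(existing)) {
    if (!identical(existing, shares))
      abort_ss("securesum_protocol_error",
               "conflicting duplicate message from participant %d", sender_index)
    return(session)  # identical re-delivery is idempotent
  }
  session[[slot]][[key]] <- shares
  session
}

#' Receive a protocol message
#'
#' Validates addressing, study identity and round consistency, then records
#' the sender's share vector for the indicated round. Redelivery of an
#' identical envelope is a no-op; a conflicting duplicate or a message for
#' the wrong round is a protocol error and leaves the session unchanged.
#'
#' @param session A `study_session`.
#' @param env A [message_envelope()].
#' @return The updated session (state unchanged; see [advance()]).
#' @export
receive_message <- function(session, env) {
  stopifnot(inherits(session, "study_session"), inherits(env, "message_envelope"))
  if (!identical(env$recipient, session_address(session)))
    abort_ss("securesum_protocol_error", "envelope addressed to %s, not to this party (%s)",
             env$recipient, session_address(session))
  if (!identical(env$study_name, session$definition$study_name))
    abort_ss("securesum_protocol_error", "envelope belongs to study '%s', not '%s'",
             env$study_name, session$definition$study_name)
  if (!identical(env$roster_digest, study_digest(session$definition, session$ring)))
    abort_ss("securesum_protocol_error", "roster digest mismatch: differing study definitions")
  sender_index <- match(env$sender, session$definition$participants$address)
  if (is.na(sender_index))
    abort_ss("securesum_roster_error", "sender '%s' is not in the study roster", env$sender)
  if (sender_index == session$self_index)
    abort_ss("securesum_protocol_error", "received own message back")
  ok_states <- switch(env$round,
                      ROUND1 = c("INITIAL_SENDING", "INITIAL_RECEIVING"),
                      ROUND2 = c("RESULT_SENDING", "RESULT_RECEIVING"))
  if (!session$state %in% ok_states)
    abort_ss("securesum_wrong_round", "%s message cannot be accepted in state %s",
             env$round, session$state)
  body <- tryCatch(jsonlite::fromJSON(env$payload, simplifyVector = TRUE),
                   error = function(e)
                     abort_ss("securesum_parse_error", "malformed payload JSON"))
  shares <- as.character(body$shares)
  slot <- if (env$round == "ROUND1") "received1" else "received2"
  record_share(session, sender_index, shares, slot)
}

#' Can the session advance to its next phase?
#'
#' `TRUE` when all `n - 1` messages of the current receiving round are
#' present.
#'
#' @param session A `study_session`.
#' @return Logical.
#' @export
can_advance <- function(session) {
  n <- nrow(session$definition$participants)
  switch(session$state,
         INITIAL_RECEIVING = length(session$received1) == n - 1L,
         RESULT_RECEIVING = length(session$received2) == n - 1L,
         FALSE)
}

#' Mark the current sending phase as completed
#'
#' Transitions `INITIAL_SENDING -> INITIAL_RECEIVING` or `RESULT_SENDING ->
#' RESULT_RECEIVING` once the caller has dispatched the envelopes produced
#' by [create_study()], [join_study()] or [advance()].
#'
#' @param session A `study_session`.
#' @return The updated session.
#' @export
mark_round_sent <- function(session) {
  stopifnot(inherits(session, "study_session"))
  to <- switch(session$state,
               INITIAL_SENDING = "INITIAL_RECEIVING",
               RESULT_SENDING = "RESULT_RECEIVING",
               abort_ss("securesum_protocol_error",
                        "no sending phase to complete in state %s", session$state))
  set_state(session, to)
}

#' Advance the protocol after a completed receiving round
#'
#' After round 1 (all `n - 1` input shares received): computes the
#' intermediate share vector — the elementwise ring-sum of the kept share
#' and every received round-1 vector — and emits `n - 1` round-2 envelopes
#' carrying it; the session moves to `RESULT_SENDING`. After round 2 (all
#' intermediates received): reconstructs the pooled result and the session
#' is `FINISHED`.
#'
#' @param session A `study_session` with a complete receiving round.
#' @return List with the updated `session` and `envelopes` to dispatch
#'   (empty after the final round).
#' @export
advance <- function(session) {
  stopifnot(inherits(session, "study_session"))
  if (!session$state %in% c("INITIAL_RECEIVING", "RESULT_RECEIVING"))
    abort_ss("securesum_protocol_error", "cannot advance in state %s", session$state)
  if (!can_advance(session))
    abort_ss("securesum_protocol_error",
             "cannot advance: waiting for %d more message(s) in %s",
             nrow(session$definition$participants) - 1L -
               length(if (session$state == "INITIAL_RECEIVING") session$received1
                      else session$received2),
             session$state)
  mod <- session$ring$modulus
  if (session$state == "INITIAL_RECEIVING") {
    acc <- session$kept_share
    for (sv in session$received1) acc <- big_mod_add(acc, sv, mod)
    session$intermediate <- acc
    session <- set_state(session, "RESULT_SENDING")
    def <- session$definition
    digest <- study_digest(def, session$ring)
    others <- setdiff(seq_len(nrow(def$participants)), session$self_index)
    envs <- lapply(others, function(i) {
      message_envelope(
        study_name = def$study_name, sender = session_address(session),
        recipient = def$participants$address[i], round = "ROUND2",
        roster_digest = digest,
        payload = share_payload("share2", acc)
      )
    })
    list(session = session, envelopes = envs)
  } else {
    acc <- session$intermediate
    for (sv in session$received2) acc <- big_mod_add(acc, sv, mod)
    session$result_elements <- acc
    session <- set_state(session, "FINISHED")
    list(session = session, envelopes = list())
  }
}

#' Abort a session
#'
#' @param session A `study_session` in any non-final state.
#' @return The session in state `ABORTED`.
#' @export
abort_session <- function(session) {
  stopifnot(inherits(session, "study_session"))
  set_state(session, "ABORTED")
}

#' Read the pooled result of a finished session
#'
#' Every party reconstructs the same vector: the sum of all participants'
#' secret values, per variable, decoded from the ring back to decimals.
#'
#' @param session A `study_session` in state `FINISHED`.
#' @return Data frame with columns `variable`, `sum` (numeric) and `exact`
#'   (decimal string free of binary floating-point noise), in definition
#'   order.
#' @export
session_result <- function(session) {
  stopifnot(inherits(session, "study_session"))
  if (session$state != "FINISHED")
    abort_ss("securesum_protocol_error",
             "result is only readable in state FINISHED (currently %s)", session$state)
  exact <- decode_value(session$result_elements, session$ring, as = "character")
  data.frame(variable = session$definition$variable_names,
             sum = as.numeric(exact), exact = exact,
             stringsAsFactors = FALSE)
}

#' Message complexity of one secure-sum cycle
#'
#' Each of the `n` participants sends (and receives) `2 * (n - 1)`
#' messages — one per other party in each of the two rounds — for
#' `2 * n * (n - 1)` deliveries in total.
#'
#' @param n Number of participants, >= 3.
#' @return List with `per_participant` and `total`.
#' @export
expected_message_counts <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 3)
    abort_ss("securesum_protocol_error", "a study has at least 3 participants")
  n <- as.numeric(n)
  list(per_participant = 2 * (n - 1), total = 2 * n * (n - 1))
}

# ---- session persistence ---------------------------------------------------

SESSION_FORMAT <- "securesum-session/1"

#' Save and restore a session
#'
#' Sessions can be persisted at any time — between, not only after, state
#' transitions — and later resumed to complete the protocol. The persisted
#' form is a versioned, self-describing JSON document; secrets and shares
#' are stored exactly as held in memory, i.e. unencrypted, so the file
#' should be protected by filesystem permissions.
#'
#' @param session A `study_session`.
#' @param path File path; if `NULL`, `save_session` returns the JSON text.
#' @return `save_session`: the path (or JSON text), invisibly;
#'   `load_session`: the restored session.
#' @export
save_session <- function(session, path = NULL) {
  stopifnot(inherits(session, "study_session"))
  def <- session$definition
  doc <- list(
    format = SESSION_FORMAT,
    definition = list(study_name = def$study_name,
                      participants = def$participants,
                      variable_names = def$variable_names),
    ring = list(modulus = session$ring$modulus,
                fixpoint_scale = session$ring$fixpoint_scale),
    self_index = session$self_index,
    own_secrets = session$own_secrets,
    kept_share = session$kept_share,
    intermediate = session$intermediate,
    result_elements = session$result_elements,
    received1 = session$received1,
    received2 = session$received2,
    state = session$state,
    history = session$history
  )
  json <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null"))
  if (is.null(path)) return(invisible(json))
  writeLines(json, path)
  invisible(path)
}

#' @param x Path of a persisted session, or the JSON text itself.
#' @rdname save_session
#' @export
load_session <- function(x) {
  text <- if (file.exists(x)) paste(readLines(x, warn = FALSE), collapse = "\n") else x
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e)
                    abort_ss("securesum_persist_error",
                             "corrupt session file: %s", conditionMessage(e)))
  if (!identical(doc$format, SESSION_FORMAT))
    abort_ss("securesum_persist_error", "unrecognized session format '%s'",
             doc$format %||% "?")
  d <- doc$definition
  def <- study_definition(
    d$study_name,
    data.frame(name = vapply(d$participants, `[[`, "", "name"),
               address = vapply(d$participants, `[[`, "", "address"),
               stringsAsFactors = FALSE),
    unlist(d$variable_names)
  )
  ring <- ring_config(doc$ring$modulus, doc$ring$fixpoint_scale)
  session <- new_session(def, ring, as.integer(doc$self_index),
                         as.character(unlist(doc$own_secrets)),
                         as.character(unlist(doc$kept_share)))
  session$intermediate <- if (!is.null(doc$intermediate))
    as.character(unlist(doc$intermediate))
  session$result_elements <- if (!is.null(doc$result_elements))
    as.character(unlist(doc$result_elements))
  session$received1 <- lapply(doc$received1, function(v) as.character(unlist(v)))
  session$received2 <- lapply(doc$received2, function(v) as.character(unlist(v)))
  if (!doc$state %in% PROTOCOL_STATES)
    abort_ss("securesum_persist_error", "unknown protocol state '%s'", doc$state)
  session$state <- doc$state
  session$history <- as.character(unlist(doc$history))
  session
}
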