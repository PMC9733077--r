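test_that("study definitions enforce roster and variable invariants", {
  expect_error(study_definition("s", data.frame(name = c("a", "b"),
                                                address = c("a@x", "b@x")), "v"),
               class = "securesum_roster_error")
  expect_error(study_definition("s", data.frame(name = c("a", "b", "c"),
                                                address = c("a@x", "a@x", "c@x")), "v"),
               class = "securesum_roster_error")
  expect_error(study_definition("s", data.frame(name = c("a", "b", "c"),
                                                address = c("a@x", "b@x", "c@x")),
                                c("v", "v")),
               class = "securesum_roster_error")
  expect_silent(three_party_def())
})

test_that("the initiator keeps one share vector and sends n - 1 others", {
  def <- three_party_def(c("a", "b"))
  out <- create_study(def, c(a = 1.5, b = -2), rng = insecure_seeded_rng(1))
  expect_length(out$envelopes, 2)            # one per other participant
  expect_identical(out$session$state, "INITIAL_SENDING")
  # kept share plus the two transmitted share vectors reconstruct the secrets
  cfg <- out$session$ring
  sent <- lapply(out$envelopes, function(e)
    as.character(unlist(jsonlite::fromJSON(e$payload, simplifyVector = FALSE)$shares)))
  pooled <- out$session$kept_share
  for (sv in sent) pooled <- add_local(pooled, sv, cfg)
  expect_identical(pooled, out$session$own_secrets)
  expect_equal(decode_value(pooled, cfg), c(1.5, -2))
})

test_that("transmitted round-1 shares never equal the encoded secrets", {
  # initiator shares are uniform draws independent of the secret: over an
  # exhaustive small ring the transmitted payload matches the secret only at
  # the uniform-chance rate
  def <- three_party_def("v")
  cfg <- ring11()
  hits <- 0L
  for (r1 in 0:10) for (r2 in 0:10) {
    out <- create_study(def, c(v = 4), ring = cfg, rng = stub_rng(c(r1, r2)))
    sent <- vapply(out$envelopes, function(e)
      unlist(jsonlite::fromJSON(e$payload)$shares), "")
    hits <- hits + sum(sent == out$session$own_secrets)
  }
  expect_equal(hits, 2 * 121 / 11)  # each of the two sent shares uniform
})

test_that("joiners initialize from the invitation and fan out n - 1 envelopes", {
  def <- study_definition("s4", data.frame(name = paste0("P", 1:4),
                                           address = paste0("p", 1:4, "@x")),
                          c("alpha", "beta"))
  init <- create_study(def, c(alpha = 1, beta = 2), rng = insecure_seeded_rng(2))
  invite <- init$envelopes[[1]]
  joined <- join_study(invite, c(alpha = 10, beta = 20), rng = insecure_seeded_rng(3))
  expect_length(joined$envelopes, 3)
  expect_identical(joined$session$definition$variable_names, c("alpha", "beta"))
  expect_identical(joined$session$state, "INITIAL_SENDING")
  # the initiator's share is already recorded
  expect_named(joined$session$received1, "1")
  expect_error(join_study(invite, c(1, 2), own_address = "stranger@x"),
               class = "securesum_roster_error")
})

test_that("message receipt is idempotent, round-guarded and study-guarded", {
  def <- three_party_def("v")
  rng <- insecure_seeded_rng(4)
  init <- create_study(def, c(v = 1), rng = rng)
  ben <- join_study(init$envelopes[[1]], c(v = 2), rng = rng)
  cleo <- join_study(init$envelopes[[2]], c(v = 3), rng = rng)
  s <- mark_round_sent(init$session)
  env_b <- ben$envelopes[[which(vapply(ben$envelopes, `[[`, "", "recipient") == "ann@x")]]
  s1 <- receive_message(s, env_b)
  s2 <- receive_message(s1, env_b)           # identical redelivery: no-op
  expect_identical(s1$received1, s2$received1)
  # conflicting duplicate payload from the same sender is a protocol error
  env_forged <- message_envelope(env_b$study_name, env_b$sender, env_b$recipient,
                                 env_b$round, env_b$roster_digest,
                                 '{"type":"share1","shares":["5"]}')
  expect_error(receive_message(s1, env_forged), class = "securesum_protocol_error")
  # a round-2 envelope cannot be accepted while collecting round-1 shares
  env_r2 <- message_envelope(env_b$study_name, env_b$sender, env_b$recipient,
                             "ROUND2", env_b$roster_digest,
                             '{"type":"share2","shares":["5"]}')
  expect_error(receive_message(s1, env_r2), class = "securesum_wrong_round")
  # wrong recipient and wrong study are rejected
  expect_error(receive_message(ben$session, env_b), class = "securesum_protocol_error")
  # quorum: after both round-1 receipts, advance is enabled
  expect_false(can_advance(s1))
  env_c <- cleo$envelopes[[which(vapply(cleo$envelopes, `[[`, "", "recipient") == "ann@x")]]
  s3 <- receive_message(s1, env_c)
  expect_true(can_advance(s3))
  expect_error(advance(s1), class = "securesum_protocol_error")  # before quorum
})

test_that("the intermediate share is the ring-sum of kept and received vectors", {
  def <- three_party_def(c("a", "b"))
  rng <- insecure_seeded_rng(5)
  init <- create_study(def, c(a = 1, b = 2), rng = rng)
  ben <- join_study(init$envelopes[[1]], c(a = 3, b = 4), rng = rng)
  cleo <- join_study(init$envelopes[[2]], c(a = 5, b = 6), rng = rng)
  s <- mark_round_sent(init$session)
  for (src in list(ben, cleo)) {
    e <- src$envelopes[[which(vapply(src$envelopes, `[[`, "", "recipient") == "ann@x")]]
    s <- receive_message(s, e)
  }
  step <- advance(s)
  expect_identical(step$session$state, "RESULT_SENDING")
  expect_length(step$envelopes, 2)
  cfg <- s$ring
  expected <- s$kept_share
  for (sv in s$received1) expected <- add_local(expected, sv, cfg)
  expect_identical(step$session$intermediate, expected)
})

test_that("a full three-party run pools the secrets for every party", {
  out <- run_secure_sum(list("a@x" = c(v = 1), "b@x" = c(v = 2), "c@x" = c(v = 3)),
                        rng = insecure_seeded_rng(6))
  expect_equal(out$result$sum, 6)
  for (s in out$sessions) {
    expect_identical(s$state, "FINISHED")
    expect_equal(session_result(s)$sum, 6)
  }
  # result is unreadable before FINISHED
  def <- three_party_def("v")
  init <- create_study(def, c(v = 1), rng = insecure_seeded_rng(7))
  expect_error(session_result(init$session), class = "securesum_protocol_error")
})

test_that("signed values keep their signs through a full run", {
  out <- run_secure_sum(list("a@x" = c(u = 1.5, w = -4), "b@x" = c(u = -1.5, w = 1),
                             "c@x" = c(u = 0.25, w = 1)),
                        rng = insecure_seeded_rng(8))
  expect_equal(out$result$sum, c(0.25, -2))
  expect_identical(out$result$exact, c("0.25", "-2"))
})

test_that("random studies agree exactly with the plain pooled-sum oracle", {
  set.seed(123)
  for (trial in 1:6) {
    n <- sample(3:8, 1)
    v <- sample(1:50, 1)
    mat <- matrix(rand_grid_values(n * v), nrow = n,
                  dimnames = list(NULL, paste0("v", seq_len(v))))
    out <- run_secure_sum(party_values(mat), rng = insecure_seeded_rng(trial))
    expect_equal(out$result$sum, unname(colSums(mat)))  # grid values: exact
  }
})

test_that("message counts follow the 2(n-1) per-participant law", {
  expect_equal(expected_message_counts(4)$per_participant, 6)
  expect_equal(expected_message_counts(20)$total, 760)
  expect_error(expected_message_counts(2), class = "securesum_protocol_error")
  totals <- vapply(3:10, function(n) expected_message_counts(n)$total, 0)
  expect_true(all(diff(totals) > 0))
  # cross-check by counting actual bus deliveries on a full run
  for (n in c(3, 5)) {
    mat <- matrix(1, nrow = n, ncol = 2, dimnames = list(NULL, c("x", "y")))
    out <- run_secure_sum(party_values(mat), rng = insecure_seeded_rng(n))
    st <- out$bus_stats
    expect_equal(st$envelopes_sent, expected_message_counts(n)$total)
    expect_equal(st$envelopes_delivered, st$envelopes_sent)
    expect_true(all(unlist(st$sent_by) == expected_message_counts(n)$per_participant))
    expect_true(all(unlist(st$received_by) == expected_message_counts(n)$per_participant))
  }
})

test_that("every illegal state transition is refused", {
  def <- three_party_def("v")
  rng <- insecure_seeded_rng(9)
  init <- create_study(def, c(v = 1), rng = rng)
  s <- init$session                              # INITIAL_SENDING
  expect_error(advance(s), class = "securesum_protocol_error")
  s <- mark_round_sent(s)                        # INITIAL_RECEIVING
  expect_error(mark_round_sent(s), class = "securesum_protocol_error")
  expect_error(advance(s), class = "securesum_protocol_error")  # no quorum
  aborted <- abort_session(s)
  expect_identical(aborted$state, "ABORTED")
  expect_error(mark_round_sent(aborted), class = "securesum_protocol_error")
  expect_error(advance(aborted), class = "securesum_protocol_error")
  expect_error(abort_session(aborted), class = "securesum_protocol_error")
})

test_that("sessions persist and resume mid-protocol with identical results", {
  def <- three_party_def("v")
  rng <- insecure_seeded_rng(10)
  init <- create_study(def, c(v = 1), rng = rng)
  ben <- join_study(init$envelopes[[1]], c(v = 2), rng = rng)
  cleo <- join_study(init$envelopes[[2]], c(v = 3), rng = rng)

  # saving is possible between, not only after, state transitions
  path <- withr::local_tempfile(fileext = ".json")
  save_session(init$session, path)               # still INITIAL_SENDING
  restored <- load_session(path)
  expect_identical(restored$state, "INITIAL_SENDING")
  expect_identical(restored$kept_share, init$session$kept_share)

  # resume and complete the protocol alongside the live sessions
  bus <- memory_bus()
  sessions <- list("ann@x" = mark_round_sent(restored),
                   "ben@x" = mark_round_sent(ben$session),
                   "cleo@x" = mark_round_sent(cleo$session))
  for (e in c(init$envelopes, ben$envelopes, cleo$envelopes)) bus_send(bus, e)
  sessions <- finish_sessions(sessions, bus)
  for (s in sessions) expect_equal(session_result(s)$sum, 6)

  # a second save/load cycle mid-receipt also resumes cleanly
  json <- save_session(sessions[["ann@x"]])
  expect_equal(session_result(load_session(json))$sum, 6)

  # corrupt persisted forms are load errors
  writeLines(substr(readLines(path, warn = FALSE), 1, 50), path)
  expect_error(load_session(path), class = "securesum_persist_error")
})
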