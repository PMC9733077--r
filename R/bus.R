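#' Message buses
#'
#' Store-and-forward transports behind one interface: [bus_send()] splits a
#' serialized envelope into size-limited chunks and deposits them in the
#' recipient's mailbox; [bus_poll()] collects, reassembles and
#' checksum-verifies complete envelopes addressed to the caller and removes
#' them from the mailbox. At-least-once delivery; corrupt entries are
#' reported, skipped, and retained for inspection.
#'
#' `memory_bus()` keeps mailboxes in an R environment (used by tests and
#' benchmarks); `maildir_bus()` keeps one subdirectory per address with one
#' plain-text file per chunk, so independent processes can run a study by
#' sharing a directory.
#'
#' @param max_message_size Maximum serialized chunk size in bytes
#'   (default 10 MiB = `10 * 2^20`, a conservative mail-server limit;
#'   must be >= 1024).
#' @return A bus object.
#' @name bus
NULL

check_max_size <- function(max_message_size) {
  if (!is.numeric(max_message_size) || length(max_message_size) != 1L ||
      max_message_size < 1024)
    abort_ss("securesum_config_error", "max_message_size must be >= 1024 bytes")
  as.numeric(max_message_size)
}

new_bus_counters <- function() {
  e <- new.env(parent = emptyenv())
  e$envelopes_sent <- 0
  e$chunks_sent <- 0
  e$bytes_sent <- 0
  e$envelopes_delivered <- 0
  e$sent_by <- list()
  e$received_by <- list()
  e
}

count_send <- function(ctr, sender, nchunks, nbytes) {
  ctr$envelopes_sent <- ctr$envelopes_sent + 1
  ctr$chunks_sent <- ctr$chunks_sent + nchunks
  ctr$bytes_sent <- ctr$bytes_sent + nbytes
  ctr$sent_by[[sender]] <- (ctr$sent_by[[sender]] %||% 0) + 1
}

count_recv <- function(ctr, address, k) {
  ctr$envelopes_delivered <- ctr$envelopes_delivered + k
  ctr$received_by[[address]] <- (ctr$received_by[[address]] %||% 0) + k
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname bus
#' @export
memory_bus <- function(max_message_size = 10 * 2^20) {
  bus <- new.env(parent = emptyenv())
  bus$max_message_size <- check_max_size(max_message_size)
  bus$boxes <- new.env(parent = emptyenv())
  bus$corrupt <- list()
  bus$counters <- new_bus_counters()
  class(bus) <- c("memory_bus", "securesum_bus")
  bus
}

#' @rdname bus
#' @param root Mailbox root directory (created if absent).
#' @export
maildir_bus <- function(root, max_message_size = 10 * 2^20) {
  if (!dir.exists(root)) dir.create(root, recursive = TRUE)
  bus <- new.env(parent = emptyenv())
  bus$max_message_size <- check_max_size(max_message_size)
  bus$root <- normalizePath(root)
  bus$counters <- new_bus_counters()
  class(bus) <- c("maildir_bus", "securesum_bus")
  bus
}

#' Send an envelope over a bus
#'
#' @param bus A bus object from [memory_bus()] or [maildir_bus()].
#' @param env A [message_envelope()].
#' @return The number of chunks deposited, invisibly.
#' @export
bus_send <- function(bus, env) UseMethod("bus_send")

#' Poll a mailbox for complete envelopes
#'
#' @param bus A bus object.
#' @param address Mailbox address of the caller.
#' @return List of verified [message_envelope()] objects (possibly empty).
#' @export
bus_poll <- function(bus, address) UseMethod("bus_poll")

#' Bus traffic counters
#'
#' @param bus A bus object.
#' @return List with `envelopes_sent`, `chunks_sent`, `bytes_sent`,
#'   `envelopes_delivered`, and per-address `sent_by` / `received_by`
#'   counts.
#' @export
bus_stats <- function(bus) UseMethod("bus_stats")

#' @export
bus_stats.securesum_bus <- function(bus) {
  ctr <- bus$counters
  list(envelopes_sent = ctr$envelopes_sent, chunks_sent = ctr$chunks_sent,
       bytes_sent = ctr$bytes_sent,
       envelopes_delivered = ctr$envelopes_delivered,
       sent_by = ctr$sent_by, received_by = ctr$received_by)
}

prepare_chunks <- function(bus, env) {
  text <- serialize_envelope(env)
  chunks <- split_message(text, bus$max_message_size, id = envelope_id(env, text))
  texts <- vapply(chunks, serialize_chunk, "")
  list(texts = texts, bytes = sum(nchar(texts, type = "bytes")))
}

#' @export
bus_send.memory_bus <- function(bus, env) {
  p <- prepare_chunks(bus, env)
  box <- bus$boxes[[env$recipient]] %||% list()
  bus$boxes[[env$recipient]] <- c(box, as.list(p$texts))
  count_send(bus$counters, env$sender, length(p$texts), p$bytes)
  invisible(length(p$texts))
}

#' @export
bus_send.maildir_bus <- function(bus, env) {
  p <- prepare_chunks(bus, env)
  dir <- file.path(bus$root, sanitize_token(env$recipient))
  if (!dir.exists(dir)) dir.create(dir)
  for (i in seq_along(p$texts)) {
    fn <- file.path(dir, sprintf("%s_%05d.msg", envelope_id(env), i - 1L))
    tmp <- paste0(fn, ".tmp")
    writeLines(p$texts[i], tmp, sep = "")
    file.rename(tmp, fn)  # atomic publish so pollers never see partial files
  }
  count_send(bus$counters, env$sender, length(p$texts), p$bytes)
  invisible(length(p$texts))
}

# Group chunk texts by envelope id, reassemble and verify the complete
# ones. Returns indices consumed, corrupt indices, and the envelopes.
collect_envelopes <- function(texts, address) {
  parsed <- vector("list", length(texts))
  bad <- integer(0)
  for (i in seq_along(texts)) {
    parsed[[i]] <- tryCatch(parse_chunk(texts[[i]]), error = function(e) e)
    if (inherits(parsed[[i]], "error")) bad <- c(bad, i)
  }
  ok <- setdiff(seq_along(texts), bad)
  ids <- vapply(parsed[ok], `[[`, "", "envelope_id")
  envs <- list()
  consumed <- integer(0)
  for (id in unique(ids)) {
    idx <- ok[ids == id]
    res <- tryCatch({
      text <- reassemble(parsed[idx])
      env <- deserialize_envelope(text)
      if (!identical(env$recipient, address))
        abort_ss("securesum_bus_error",
                 "misdelivered envelope: addressed to %s", env$recipient)
      env
    }, securesum_chunk_error = function(e) e, error = function(e) e)
    if (inherits(res, "securesum_chunk_error") &&
        grepl("missing chunk", conditionMessage(res))) {
      next  # incomplete: leave chunks in the mailbox for a later poll
    } else if (inherits(res, "error")) {
      warning(sprintf("corrupt mailbox entry for %s (%s): %s", address, id,
                      conditionMessage(res)), call. = FALSE)
      bad <- c(bad, idx)
    } else {
      envs <- c(envs, list(res))
      consumed <- c(consumed, idx)
    }
  }
  list(envelopes = envs, consumed = consumed, corrupt = bad)
}

#' @export
bus_poll.memory_bus <- function(bus, address) {
  texts <- bus$boxes[[address]] %||% list()
  if (length(texts) == 0L) return(list())
  res <- collect_envelopes(texts, address)
  if (length(res$corrupt) > 0L)
    bus$corrupt <- c(bus$corrupt, texts[res$corrupt])
  bus$boxes[[address]] <- texts[setdiff(seq_along(texts),
                                        c(res$consumed, res$corrupt))]
  count_recv(bus$counters, address, length(res$envelopes))
  res$envelopes
}

#' @export
bus_poll.maildir_bus <- function(bus, address) {
  dir <- file.path(bus$root, sanitize_token(address))
  if (!dir.exists(dir)) return(list())
  files <- list.files(dir, pattern = "\\.msg$", full.names = TRUE)
  if (length(files) == 0L) return(list())
  texts <- lapply(files, function(f)
    readChar(f, file.info(f)$size, useBytes = TRUE))
  res <- collect_envelopes(texts, address)
  # retain corrupt entries under a distinct suffix for inspection
  for (i in res$corrupt) file.rename(files[i], paste0(files[i], ".corrupt"))
  file.remove(files[res$consumed])
  count_recv(bus$counters, address, length(res$envelopes))
  res$envelopes
}
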