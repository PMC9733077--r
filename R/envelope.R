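#' @rdname serialize_envelope
#' @export
ENVELOPE_FORMAT_VERSION <- 1L

# fixed byte budget reserved for a chunk header line; documented constant
CHUNK_HEADER_BYTES <- 128L

b64_line <- function(x) gsub("\n", "", jsonlite::base64_enc(charToRaw(x)), fixed = TRUE)
b64_read <- function(x) rawToChar(jsonlite::base64_dec(x))

#' Construct a message envelope
#'
#' The canonical unit of exchange between parties: routing metadata, a
#' digest of the study roster (so mismatched study definitions are caught
#' early), and the payload serialized as JSON and carried Base64-encoded on
#' the wire with a CRC-32 checksum appended to detect corruption in
#' transit.
#'
#' @param study_name,sender,recipient Routing metadata (non-empty strings).
#' @param round `"ROUND1"` (input-share exchange) or `"ROUND2"`
#'   (intermediate-result exchange).
#' @param roster_digest 8-hex-digit digest of the study definition, see
#'   [study_digest()].
#' @param payload JSON string (already serialized payload body).
#' @param format_version Wire format version, currently 1.
#' @return A `message_envelope` object.
#' @export
message_envelope <- function(study_name, sender, recipient, round,
                             roster_digest, payload,
                             format_version = ENVELOPE_FORMAT_VERSION) {
  for (f in c(study_name, sender, recipient))
    if (!is.character(f) || length(f) != 1L || !nzchar(f))
      abort_ss("securesum_envelope_error", "envelope metadata fields must be non-empty strings")
  if (!round %in% c("ROUND1", "ROUND2"))
    abort_ss("securesum_envelope_error", "round must be ROUND1 or ROUND2")
  structure(
    list(study_name = study_name, sender = sender, recipient = recipient,
         round = round, roster_digest = roster_digest,
         payload = payload, format_version = as.integer(format_version)),
    class = "message_envelope"
  )
}

#' @export
print.message_envelope <- function(x, ...) {
  cat(sprintf("<message_envelope> %s: %s -> %s [%s] payload %d bytes\n",
              x$study_name, x$sender, x$recipient, x$round,
              nchar(x$payload, type = "bytes")))
  invisible(x)
}

envelope_equal <- function(a, b) {
  identical(a[c("study_name", "sender", "recipient", "round",
                "roster_digest", "payload")],
            b[c("study_name", "sender", "recipient", "round",
                "roster_digest", "payload")])
}

#' Serialize / deserialize an envelope
#'
#' The wire form is a deterministic 8-line text block: a version banner,
#' Base64-encoded header fields in fixed order, the Base64-encoded payload,
#' and a CRC-32 checksum over everything above it. Two equal envelopes
#' serialize to byte-identical text.
#'
#' @param env A [message_envelope()].
#' @return `serialize_envelope`: a single string; `deserialize_envelope`:
#'   the verified envelope.
#' @export
serialize_envelope <- function(env) {
  stopifnot(inherits(env, "message_envelope"))
  head <- paste(
    sprintf("SECURESUM/%d", env$format_version),
    paste0("study: ", b64_line(env$study_name)),
    paste0("from: ", b64_line(env$sender)),
    paste0("to: ", b64_line(env$recipient)),
    paste0("round: ", env$round),
    paste0("roster: ", env$roster_digest),
    paste0("payload: ", b64_line(env$payload)),
    sep = "\n"
  )
  paste0(head, "\ncrc32: ", crc32_hex(head))
}

#' @param text Serialized envelope text (possibly corrupted in transit).
#' @rdname serialize_envelope
#' @export
deserialize_envelope <- function(text) {
  # the wire format is pure printable ASCII; any other byte is corruption
  if (grepl("[^\\n\\x20-\\x7e]", text, perl = TRUE, useBytes = TRUE))
    abort_ss("securesum_parse_error", "malformed envelope: non-printable byte")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) != 8L)
    abort_ss("securesum_parse_error", "malformed envelope: expected 8 lines, got %d",
             length(lines))
  if (!grepl("^SECURESUM/[0-9]+$", lines[1]))
    abort_ss("securesum_parse_error", "malformed envelope: missing version banner")
  version <- as.integer(sub("^SECURESUM/", "", lines[1]))
  if (version != ENVELOPE_FORMAT_VERSION)
    abort_ss("securesum_version_error", "unknown envelope format version %d", version)
  field <- function(i, key) {
    prefix <- paste0(key, ": ")
    if (!startsWith(lines[i], prefix))
      abort_ss("securesum_parse_error", "malformed envelope: expected '%s' on line %d", key, i)
    substring(lines[i], nchar(prefix) + 1L)
  }
  stated_crc <- field(8, "crc32")
  head <- paste(lines[1:7], collapse = "\n")
  if (!identical(crc32_hex(head), stated_crc))
    abort_ss("securesum_checksum_error",
             "checksum mismatch: message corrupted in transit")
  dec <- function(x) tryCatch(b64_read(x), error = function(e)
    abort_ss("securesum_parse_error", "malformed envelope: invalid Base64 field"))
  message_envelope(
    study_name = dec(field(2, "study")),
    sender = dec(field(3, "from")),
    recipient = dec(field(4, "to")),
    round = field(5, "round"),
    roster_digest = field(6, "roster"),
    payload = dec(field(7, "payload")),
    format_version = version
  )
}

sanitize_token <- function(x) {
  x <- gsub("[^A-Za-z0-9._-]", "_", x)
  substr(x, 1L, 24L)
}

#' Stable identifier for a serialized envelope
#'
#' Combines sanitized routing fields with a content digest and length so
#' chunks of different envelopes can never be merged into one another.
#'
#' @param env A [message_envelope()].
#' @param text Its serialized text (recomputed if missing).
#' @return Identifier string, safe for use in filenames.
#' @export
envelope_id <- function(env, text = serialize_envelope(env)) {
  paste(sanitize_token(env$sender), sanitize_token(env$recipient),
        env$round, crc32_hex(text), nchar(text, type = "bytes"), sep = "-")
}

#' Split a serialized message into size-limited chunks
#'
#' Store-and-forward transports often cap the size of a single message;
#' larger envelopes are split into chunks of at most `max_size` bytes
#' (including a fixed 128-byte header budget) and reassembled on the
#' receiving side.
#'
#' @param text Serialized envelope text.
#' @param max_size Maximum serialized chunk size in bytes (>= 129).
#' @param id Envelope identifier; defaults to a digest of `text`.
#' @return List of `message_chunk` objects (fields `envelope_id`,
#'   `chunk_index` 0-based, `chunk_count`, `body`).
#' @export
split_message <- function(text, max_size,
                          id = paste0("msg-", crc32_hex(text), "-",
                                      nchar(text, type = "bytes"))) {
  capacity <- as.numeric(max_size) - CHUNK_HEADER_BYTES
  if (capacity < 1)
    abort_ss("securesum_chunk_error",
             "max_size %s too small: need at least %d bytes", max_size,
             CHUNK_HEADER_BYTES + 1L)
  total <- nchar(text, type = "bytes")
  count <- max(1L, as.integer(ceiling(total / capacity)))
  starts <- 1 + (seq_len(count) - 1) * capacity
  lapply(seq_len(count), function(i) {
    body <- substr(text, starts[i], min(total, starts[i] + capacity - 1))
    structure(list(envelope_id = id, chunk_index = i - 1L,
                   chunk_count = count, body = body),
              class = "message_chunk")
  })
}

#' @rdname split_message
#' @param chunk A `message_chunk`.
#' @export
serialize_chunk <- function(chunk) {
  header <- sprintf("SECURESUM-CHUNK/1 %s %d %d", chunk$envelope_id,
                    chunk$chunk_index, chunk$chunk_count)
  if (nchar(header, type = "bytes") + 1L > CHUNK_HEADER_BYTES)
    abort_ss("securesum_chunk_error", "chunk header exceeds the fixed header budget")
  paste0(header, "\n", chunk$body)
}

#' @rdname split_message
#' @export
parse_chunk <- function(text) {
  nl <- regexpr("\n", text, fixed = TRUE)
  if (nl < 0)
    abort_ss("securesum_parse_error", "malformed chunk: missing header delimiter")
  header <- substr(text, 1L, nl - 1L)
  m <- regmatches(header,
                  regexec("^SECURESUM-CHUNK/1 (\\S+) ([0-9]+) ([0-9]+)$", header))[[1]]
  if (length(m) != 4L)
    abort_ss("securesum_parse_error", "malformed chunk header: '%s'", header)
  idx <- as.integer(m[3]); cnt <- as.integer(m[4])
  if (idx < 0L || idx >= cnt)
    abort_ss("securesum_parse_error", "chunk index %d out of range (count %d)", idx, cnt)
  structure(list(envelope_id = m[2], chunk_index = idx, chunk_count = cnt,
                 body = substring(text, nl + 1L)),
            class = "message_chunk")
}

#' Reassemble chunks into the original message text
#'
#' Input order does not matter; chunks are sorted by index. Duplicate
#' chunks are accepted if identical; a missing or conflicting chunk, or a
#' mix of envelope identifiers, is an error.
#'
#' @param chunks List of `message_chunk` objects for one envelope.
#' @return The original serialized message text.
#' @export
reassemble <- function(chunks) {
  if (length(chunks) == 0L)
    abort_ss("securesum_chunk_error", "no chunks to reassemble")
  ids <- unique(vapply(chunks, `[[`, "", "envelope_id"))
  if (length(ids) != 1L)
    abort_ss("securesum_chunk_error", "chunks from multiple envelopes: %s",
             paste(ids, collapse = ", "))
  count <- unique(vapply(chunks, `[[`, 0L, "chunk_count"))
  if (length(count) != 1L)
    abort_ss("securesum_chunk_error", "inconsistent chunk counts for envelope %s", ids)
  bodies <- vector("list", count)
  for (ch in chunks) {
    i <- ch$chunk_index + 1L
    if (!is.null(bodies[[i]]) && !identical(bodies[[i]], ch$body))
      abort_ss("securesum_chunk_error",
               "conflicting duplicate for chunk %d of envelope %s", ch$chunk_index, ids)
    bodies[[i]] <- ch$body
  }
  missing <- which(vapply(bodies, is.null, TRUE))
  if (length(missing) > 0L)
    abort_ss("securesum_chunk_error", "missing chunk(s) %s of envelope %s",
             paste(missing - 1L, collapse = ", "), ids)
  paste(unlist(bodies), collapse = "")
}
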