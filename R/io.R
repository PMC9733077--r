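#' Read a party's variable/value table from CSV
#'
#' Canonical input format: a two-column RFC-4180 CSV with header
#' `variable,value`. CSV is the canonical dialect; spreadsheet exports
#' should be saved as CSV before import. Values are kept as exact decimal strings (no binary
#' floating-point intermediate), so pooled sums cannot depend on the order
#' in which parties' files were parsed. Malformed input is rejected, never
#' coerced, and every error names the offending line.
#'
#' @param path CSV file path.
#' @return Data frame of class `variable_table` with character columns
#'   `variable` and `value`.
#' @export
read_variable_table <- function(path) {
  if (!file.exists(path))
    abort_ss("securesum_io_error", "file not found: %s", path)
  df <- tryCatch(
    read.csv(path, colClasses = "character", check.names = FALSE,
             strip.white = TRUE),
    error = function(e)
      abort_ss("securesum_io_error", "cannot parse %s: %s", path,
               conditionMessage(e))
  )
  if (!identical(names(df), c("variable", "value")))
    abort_ss("securesum_io_error",
             "%s line 1: header must be 'variable,value' (got '%s')",
             path, paste(names(df), collapse = ","))
  lineno <- seq_len(nrow(df)) + 1L
  if (any(!nzchar(df$variable)))
    abort_ss("securesum_io_error", "%s line %d: empty variable name",
             path, lineno[!nzchar(df$variable)][1])
  dup <- duplicated(df$variable)
  if (any(dup))
    abort_ss("securesum_io_error", "%s line %d: duplicate variable name '%s'",
             path, lineno[dup][1], df$variable[dup][1])
  bad <- !grepl("^[+-]?([0-9]+(\\.[0-9]+)?|\\.[0-9]+)$", df$value)
  if (any(bad))
    abort_ss("securesum_io_error", "%s line %d: non-numeric value '%s'",
             path, lineno[bad][1], df$value[bad][1])
  class(df) <- c("variable_table", "data.frame")
  df
}

#' Write pooled results to CSV
#'
#' Writes `variable,global_sum` rows in study-definition order, rendering
#' each sum as its exact fixed-point decimal (column `exact` of
#' [session_result()]), not a rounded double.
#'
#' @param results Data frame from [session_result()] (or any data frame
#'   with `variable` and `exact`/`sum` columns).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_results <- function(results, path) {
  sums <- if (!is.null(results$exact)) results$exact else as.character(results$sum)
  q <- function(x) ifelse(grepl('[",\n]', x), paste0('"', gsub('"', '""', x), '"'), x)
  lines <- c("variable,global_sum", paste(q(results$variable), sums, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

config_fields <- list(
  top = c("study_name", "participants", "variables", "ring", "bus"),
  participant = c("name", "address"),
  ring = c("modulus", "fixpoint_scale"),
  bus = c("transport", "mailbox_root", "max_message_size")
)

check_known <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0L)
    abort_ss("securesum_config_error", "unknown field '%s' in %s",
             unknown[1], where)
}

#' Load and validate a declarative study configuration
#'
#' YAML document with the study definition plus optional `ring` and `bus`
#' sections; defaults are the 2^127-1 modulus, fixed-point scale 10^6 and a
#' 10 MiB message limit. Unknown fields are an explicit error, never
#' silently ignored.
#'
#' @param path YAML file path.
#' @return List with `definition` ([study_definition()]), `ring`
#'   ([ring_config()]) and `bus` (list of `transport`, `mailbox_root`,
#'   `max_message_size`).
#' @export
load_study_config <- function(path) {
  if (!file.exists(path))
    abort_ss("securesum_io_error", "file not found: %s", path)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    abort_ss("securesum_config_error", "cannot parse %s: %s", path,
             conditionMessage(e)))
  check_known(doc, config_fields$top, "study config")
  for (field in c("study_name", "participants", "variables"))
    if (is.null(doc[[field]]))
      abort_ss("securesum_config_error", "missing required field '%s'", field)
  for (i in seq_along(doc$participants))
    check_known(doc$participants[[i]], config_fields$participant,
                sprintf("participants[%d]", i))
  def <- study_definition(
    doc$study_name,
    lapply(doc$participants, function(p) participant(p$name %||% p$address, p$address)),
    unlist(doc$variables)
  )
  ring_doc <- doc$ring %||% list()
  check_known(ring_doc, config_fields$ring, "ring")
  ring <- ring_config(ring_doc$modulus %||% ring_default_modulus(),
                      ring_doc$fixpoint_scale %||% 1e6)
  bus_doc <- doc$bus %||% list()
  check_known(bus_doc, config_fields$bus, "bus")
  transport <- bus_doc$transport %||% "memory"
  if (!transport %in% c("memory", "maildir"))
    abort_ss("securesum_config_error", "bus.transport must be 'memory' or 'maildir'")
  if (transport == "maildir" && is.null(bus_doc$mailbox_root))
    abort_ss("securesum_config_error", "bus.mailbox_root is required for the maildir transport")
  bus <- list(transport = transport,
              mailbox_root = bus_doc$mailbox_root %||% NULL,
              max_message_size = check_max_size(bus_doc$max_message_size %||% (10 * 2^20)))
  list(definition = def, ring = ring, bus = bus)
}
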