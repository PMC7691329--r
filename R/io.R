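# Serialization of session logs: JSON-lines (one trial per line, preceded
# by a header line describing the session) and flat CSV trial summaries.
# Ball traces are omitted from both formats.

#' Write a session log as JSON-lines
#'
#' First line is a session header (mouse, hemisphere, contingency, kind);
#' each following line is one trial. Traces are not serialized.
#'
#' @param session A `session_log`.
#' @param path Output file path.
#' @export
write_session_jsonl <- function(session, path) {
  stopifnot(inherits(session, "session_log"))
  header <- list(record = "session", mouse_id = session$mouse_id,
                 hemisphere = session$hemisphere,
                 contingency = session$contingency, kind = session$kind)
  trials <- session$trials
  trials$trace <- NULL
  lines <- c(
    jsonlite::toJSON(header, auto_unbox = TRUE),
    vapply(seq_len(nrow(trials)), function(i) {
      as.character(jsonlite::toJSON(as.list(trials[i, ]),
                                    auto_unbox = TRUE, na = "null"))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines session log
#'
#' @param path File written by [write_session_jsonl()].
#' @return A `session_log` (without traces or engine config).
#' @export
read_session_jsonl <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  stopifnot(identical(header$record, "session"))
  trials <- list_rbind(map(lines[-1], function(l) {
    rec <- jsonlite::fromJSON(l)
    rec[vapply(rec, is.null, logical(1))] <- NA
    as_tibble(rec)
  }))
  new_session_log(header$mouse_id, header$hemisphere, header$contingency,
                  trials, config = NULL, kind = header$kind)
}

#' Write the trial table of a session as CSV
#'
#' @param session A `session_log`.
#' @param path Output file path.
#' @export
write_trials_csv <- function(session, path) {
  stopifnot(inherits(session, "session_log"))
  trials <- session$trials
  trials$trace <- NULL
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}
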