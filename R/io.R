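#' Write a session log as CSV
#' @param sessions session-log data.frame (see [score_cohort()])
#' @param path output file
#' @export
write_session_log <- function(sessions, path) {
  validate_session_log(sessions)
  utils::write.csv(sessions, path, row.names = FALSE)
  invisible(path)
}

#' Read a session log CSV
#' @param path input file
#' @return validated session-log data.frame
#' @export
read_session_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_session_log(d)
  d
}
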