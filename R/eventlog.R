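# EventLog construction, accessors and file round-trip.

trialSchema <- function() {
  data.frame(trial = integer(0), stimulusPos = integer(0),
             outcome = character(0), respondedPos = integer(0),
             latencyS = numeric(0), tTrialStart = numeric(0),
             tPsiStart = numeric(0), tStimOnset = numeric(0),
             tStimOff = numeric(0), tResponse = numeric(0),
             tFeed = numeric(0), stringsAsFactors = FALSE)
}

commandSchema <- function() {
  data.frame(time_s = numeric(0), kind = character(0), arg = integer(0),
             stringsAsFactors = FALSE)
}

#' Construct an EventLog
#'
#' @param meta named list with at least \code{fishId}, \code{sessionId},
#'   \code{phase}; conventionally also \code{schedule}
#'   (a \linkS4class{SessionSchedule}).
#' @param trials per-trial records (see \linkS4class{EventLog}).
#' @param events raw detection events.
#' @param commands apparatus commands.
#' @return an \linkS4class{EventLog}.
#' @export
EventLog <- function(meta, trials = trialSchema(), events = emptyEvents(),
                     commands = commandSchema()) {
  new("EventLog", meta = meta, trials = trials, events = events,
      commands = commands)
}

#' @rdname logAccessors
#' @export
setGeneric("trialRecords", function(log) standardGeneric("trialRecords"))
#' EventLog accessors
#'
#' \code{trialRecords}: per-trial outcome table; \code{detectionEvents}: raw
#' detection-event stream; \code{apparatusCommands}: time-ordered command
#' stream; \code{logMeta}: session metadata list.
#'
#' @param log an \linkS4class{EventLog}.
#' @return the corresponding component.
#' @name logAccessors
#' @export
setGeneric("detectionEvents", function(log) standardGeneric("detectionEvents"))
#' @rdname logAccessors
#' @export
setGeneric("apparatusCommands", function(log) standardGeneric("apparatusCommands"))
#' @rdname logAccessors
#' @export
setGeneric("logMeta", function(log) standardGeneric("logMeta"))

#' @rdname logAccessors
setMethod("trialRecords", "EventLog", function(log) log@trials)
#' @rdname logAccessors
setMethod("detectionEvents", "EventLog", function(log) log@events)
#' @rdname logAccessors
setMethod("apparatusCommands", "EventLog", function(log) log@commands)
#' @rdname logAccessors
setMethod("logMeta", "EventLog", function(log) log@meta)

# Write a data.frame with full-precision numerics; `classes` is the column
# class vector used to re-read it.
writeExactCsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmtNum(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
}

readExactCsv <- function(path, template) {
  classes <- vapply(template, function(col) class(col)[1], "")
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (!identical(names(df), names(template)))
    stop("unexpected columns in ", path, ": ",
         paste(names(df), collapse = ", "))
  for (j in seq_along(df)) {
    v <- df[[j]]
    v[v == ""] <- NA
    df[[j]] <- switch(classes[j],
                      integer = as.integer(v),
                      numeric = as.numeric(v),
                      character = as.character(v),
                      v)
  }
  df
}

#' Write an EventLog to disk
#'
#' Writes four plain-text files sharing a prefix: \code{<prefix>_trials.csv},
#' \code{<prefix>_events.csv}, \code{<prefix>_commands.csv} and
#' \code{<prefix>_meta.json}. Numeric values keep full precision so that
#' \code{\link{readEventLog}} reproduces the log exactly.
#'
#' @param log an \linkS4class{EventLog}.
#' @param prefix path prefix for the four files.
#' @return \code{prefix}, invisibly.
#' @export
writeEventLog <- function(log, prefix) {
  writeExactCsv(log@trials, paste0(prefix, "_trials.csv"))
  writeExactCsv(log@events, paste0(prefix, "_events.csv"))
  writeExactCsv(log@commands, paste0(prefix, "_commands.csv"))
  meta <- log@meta
  if (!is.null(meta$schedule)) meta$schedule <- scheduleToList(meta$schedule)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read an EventLog written by writeEventLog
#'
#' @param prefix the path prefix used when writing.
#' @return the reconstructed \linkS4class{EventLog};
#'   \code{readEventLog(writeEventLog(log, p))} equals \code{log}.
#' @export
readEventLog <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, "_meta.json"),
                             simplifyDataFrame = FALSE)
  if (!is.null(meta$schedule)) meta$schedule <- scheduleFromList(meta$schedule)
  EventLog(meta,
           trials = readExactCsv(paste0(prefix, "_trials.csv"), trialSchema()),
           events = readExactCsv(paste0(prefix, "_events.csv"), emptyEvents()),
           commands = readExactCsv(paste0(prefix, "_commands.csv"),
                                   commandSchema()))
}

#' Compatibility writer: one file per detection event
#'
#' The original rig handed detection events to the controller by dropping
#' one temporary file per event into a watched directory. The package uses
#' an in-process event stream instead; this writer reproduces the file
#' protocol for integration with external consumers.
#'
#' @param events detection-event data.frame (see \code{\link{processStream}}).
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
writeEventFiles <- function(events, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    paths[i] <- file.path(dir, sprintf("event_%06d_%s.txt", i, events$region[i]))
    writeLines(c(events$region[i],
                 as.character(events$onset_frame[i]),
                 as.character(events$offset_frame[i])), paths[i])
  }
  invisible(paths)
}
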