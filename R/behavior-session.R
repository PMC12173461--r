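#' Construct a behavior session
#'
#' A behavior session is the per-frame record of one mouse in one virtual
#' context: frame times, track position, instantaneous treadmill velocity,
#' and discrete event channels (reward, shock, lick, teleport). All
#' downstream behavioral quantities (laps, freezing, shock responses) are
#' derived from this object.
#'
#' @param time numeric vector of frame timestamps in seconds, strictly
#'   increasing.
#' @param position numeric vector of track positions in cm, within
#'   `[0, track_length]`.
#' @param velocity numeric vector of signed instantaneous velocities in
#'   cm/s; negative values are backward movement.
#' @param context_id single string naming the virtual context (e.g.
#'   `"Familiar"`, `"CFC"`).
#' @param session_label one of `"habituation"`, `"before_cfc"`,
#'   `"during_cfc"`, or `"recall_day_<k>"`.
#' @param events data frame with columns `frame` (1-based frame index) and
#'   `kind` (one of `"reward"`, `"shock"`, `"lick"`, `"teleport"`); defaults
#'   to no events.
#' @param frame_rate sampling rate in Hz. If `NULL`, inferred as the
#'   reciprocal of the median inter-frame interval.
#' @param track_length track length in cm (default 200).
#'
#' @return An object of class `behavior_session`.
#' @export
behavior_session <- function(time, position, velocity, context_id = "unknown",
                             session_label = "unknown",
                             events = NULL, frame_rate = NULL,
                             track_length = 200) {
  n <- length(time)
  if (length(position) != n || length(velocity) != n) {
    stop("time, position and velocity must have equal length")
  }
  if (n < 1L) stop("session must contain at least one frame")
  if (is.unsorted(time, strictly = TRUE)) {
    bad <- which(diff(time) <= 0)
    stop(sprintf("frame_time must be strictly increasing; first violation at frame %d",
                 bad[1L] + 1L))
  }
  if (any(position < -1e-8 | position > track_length + 1e-8)) {
    stop(sprintf("position must lie within [0, %g] cm", track_length))
  }
  if (is.null(events)) {
    events <- data.frame(frame = integer(0), kind = character(0),
                         stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(events), all(c("frame", "kind") %in% names(events)))
  kinds <- c("reward", "shock", "lick", "teleport")
  if (nrow(events) > 0L) {
    if (!all(events$kind %in% kinds)) {
      stop("event kind must be one of: ", paste(kinds, collapse = ", "))
    }
    if (any(events$frame < 1L | events$frame > n)) {
      stop("event frame index out of range")
    }
    events <- events[order(events$frame), , drop = FALSE]
    row.names(events) <- NULL
  }
  if (is.null(frame_rate)) {
    frame_rate <- if (n > 1L) 1 / stats::median(diff(time)) else 30
  }
  if (!is.finite(frame_rate) || frame_rate <= 0) stop("frame_rate must be > 0")
  structure(
    list(time = as.numeric(time), position = as.numeric(position),
         velocity = as.numeric(velocity),
         context_id = as.character(context_id)[1L],
         session_label = as.character(session_label)[1L],
         events = events, frame_rate = frame_rate,
         track_length = track_length, n_frames = n),
    class = "behavior_session")
}

#' @exportS3Method base::print
print.behavior_session <- function(x, ...) {
  cat(sprintf("<behavior_session> %s / %s: %d frames @ %.1f Hz (%.1f s), %d events\n",
              x$context_id, x$session_label, x$n_frames, x$frame_rate,
              x$time[x$n_frames] - x$time[1L], nrow(x$events)))
  invisible(x)
}

#' Number of frames in a session
#' @param session a `behavior_session`.
#' @return integer frame count.
#' @export
n_frames <- function(session) session$n_frames

.default_schema <- list(time = "time", position = "position",
                        velocity = "velocity", context = "context",
                        reward = "reward", shock = "shock", lick = "lick",
                        teleport = "teleport")

#' Read a behavior session from a delimited file
#'
#' Reads a per-frame behavior log (CSV/TSV). Column names are mapped to the
#' canonical fields through `schema`, a named list (or the path of a YAML
#' file holding one) with entries `time`, `position`, `velocity`, `context`,
#' and optionally `reward`, `shock`, `lick`, `teleport` naming 0/1 event
#' columns.
#'
#' @param path path to the delimited file.
#' @param schema named list or YAML file path mapping canonical field names
#'   to column names; defaults to identity names.
#' @param sep field separator (default `","`).
#' @param session_label,frame_rate,track_length passed to
#'   [behavior_session()].
#' @return a `behavior_session`.
#' @export
read_session <- function(path, schema = NULL, sep = ",",
                         session_label = "unknown", frame_rate = NULL,
                         track_length = 200) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(schema) && length(schema) == 1L) {
    schema <- yaml::read_yaml(schema)
  }
  schema <- utils::modifyList(.default_schema, as.list(schema %||% list()))
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("time", "position", "velocity", "context")
  for (f in need) {
    if (!schema[[f]] %in% names(tab)) {
      stop(sprintf("schema error: required column '%s' (field '%s') not found",
                   schema[[f]], f))
    }
  }
  ev <- data.frame(frame = integer(0), kind = character(0))
  for (k in c("reward", "shock", "lick", "teleport")) {
    col <- schema[[k]]
    if (!is.null(col) && col %in% names(tab)) {
      fr <- which(tab[[col]] > 0)
      if (length(fr) > 0L) {
        ev <- rbind(ev, data.frame(frame = fr, kind = k))
      }
    }
  }
  behavior_session(time = tab[[schema$time]],
                   position = tab[[schema$position]],
                   velocity = tab[[schema$velocity]],
                   context_id = as.character(tab[[schema$context]][1L]),
                   session_label = session_label, events = ev,
                   frame_rate = frame_rate, track_length = track_length)
}

#' Write a behavior session to a delimited file
#'
#' Inverse of [read_session()] under the default schema: one row per frame
#' with columns `time`, `position`, `velocity`, `context` and one 0/1 column
#' per event channel present in the session.
#'
#' @param session a `behavior_session`.
#' @param path output file path.
#' @param sep field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, sep = ",") {
  tab <- data.frame(time = session$time, position = session$position,
                    velocity = session$velocity,
                    context = session$context_id)
  for (k in unique(session$events$kind)) {
    col <- integer(session$n_frames)
    col[session$events$frame[session$events$kind == k]] <- 1L
    tab[[k]] <- col
  }
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
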