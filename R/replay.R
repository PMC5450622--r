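# Action scripts: the headless substitute for GUI mouse events. A script is
# an ordered list of actions with non-decreasing timestamps; time accounting
# derives from the timestamps, so replays are fully deterministic.

validKinds <- c("new_object", "select_object", "draw", "undo", "split",
                "pause", "resume")

#' Build one script action
#'
#' @param kind one of new_object, select_object, draw, undo, split, pause,
#'   resume.
#' @param t timestamp in seconds since script start.
#' @param slice 0-based z index (draw/undo/split).
#' @param points n x 2 matrix of (x, y) (draw >= 3, split >= 2, undo exactly 1).
#' @param object 1-based object index (select_object).
#' @return a list representing the action.
#' @export
action <- function(kind, t, slice = NULL, points = NULL, object = NULL) {
  kind <- match.arg(kind, validKinds)
  if (kind == "draw" && (is.null(points) || nrow(as.matrix(points)) < 3L))
    stop("draw requires >= 3 points", call. = FALSE)
  if (kind == "split" && (is.null(points) || nrow(as.matrix(points)) < 2L))
    stop("split requires >= 2 points", call. = FALSE)
  if (kind == "undo" && (is.null(points) || nrow(as.matrix(points)) != 1L))
    stop("undo requires exactly 1 point", call. = FALSE)
  list(kind = kind, t = as.numeric(t), slice = slice,
       points = if (!is.null(points)) as.matrix(points), object = object)
}

#' Replay an action script into a session
#'
#' Applies the actions in order. Each object's \code{elapsedSeconds} is the
#' summed length of its active intervals: an interval opens when the object
#' is created, selected, or the timer resumes while it is active, and closes
#' on pause, on switching away, or at the final timestamp. Edits require a
#' running timer.
#'
#' @param stack an \linkS4class{ImageStack} the script edits.
#' @param script list of actions from \code{\link{action}} or
#'   \code{\link{readActionScript}}.
#' @param session optionally an existing \linkS4class{SegSession} to continue.
#' @return the resulting \linkS4class{SegSession}.
#' @export
replayScript <- function(stack, script, session = NULL) {
  if (is.null(session)) session <- newSession(stack)
  if (length(script) == 0L) return(session)
  tprev <- -Inf
  intervalStart <- NA_real_
  accrue <- function(s, tnow) {
    if (s@timerRunning && s@activeObject > 0L && !is.na(intervalStart)) {
      i <- s@activeObject
      s@objects[[i]]@elapsedSeconds <-
        s@objects[[i]]@elapsedSeconds + (tnow - intervalStart)
    }
    s
  }
  for (a in script) {
    if (!is.list(a) || is.null(a$kind) || is.null(a$t))
      stop("malformed action record", call. = FALSE)
    if (a$t < tprev)
      stop("timestamps must be non-decreasing", call. = FALSE)
    tprev <- a$t
    switch(a$kind,
      new_object = {
        session <- accrue(session, a$t)
        session <- addObject(session)
        session@timerRunning <- TRUE
        intervalStart <- a$t
      },
      select_object = {
        session <- accrue(session, a$t)
        session <- selectObject(session, a$object)
        if (session@timerRunning) intervalStart <- a$t
      },
      pause = {
        session <- accrue(session, a$t)
        session@timerRunning <- FALSE
        intervalStart <- NA_real_
      },
      resume = {
        if (!session@timerRunning) {
          session@timerRunning <- TRUE
          intervalStart <- a$t
        }
      },
      draw = session <- drawRegion(session, a$slice, a$points),
      undo = session <- undoClick(session, a$slice, a$points),
      split = session <- splitLine(session, a$slice, a$points),
      stop("unknown action kind: ", a$kind, call. = FALSE)
    )
  }
  session <- accrue(session, tprev)
  if (session@timerRunning) intervalStart <- tprev
  # times are kept at millisecond resolution
  for (i in seq_along(session@objects))
    session@objects[[i]]@elapsedSeconds <-
      round(session@objects[[i]]@elapsedSeconds, 3)
  session
}

#' Read / write action scripts as JSON
#'
#' The on-disk form is a JSON array of records with fields \code{kind},
#' \code{t} (seconds), and where applicable \code{slice}, \code{points}
#' (array of [x, y]) and \code{object}.
#'
#' @param path JSON file path.
#' @return \code{readActionScript}: list of actions.
#' @export
readActionScript <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    pts <- if (!is.null(r$points))
      do.call(rbind, lapply(r$points, function(p) c(p[[1]], p[[2]])))
    action(r$kind, r$t, slice = r$slice, points = pts, object = r$object)
  })
}

#' @rdname readActionScript
#' @param script list of actions.
#' @export
writeActionScript <- function(script, path) {
  recs <- lapply(script, function(a) {
    r <- list(kind = a$kind, t = a$t)
    if (!is.null(a$slice)) r$slice <- a$slice
    if (!is.null(a$points)) r$points <- unname(apply(a$points, 1, c, simplify = FALSE))
    if (!is.null(a$object)) r$object <- a$object
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
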