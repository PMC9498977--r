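# On-disk formats. A session is JSON-lines, one record per raw sample:
#   {"t": <seconds>, "touch": [[16 ints] x 6], "q": [w, x, y, z]}
# Trial annotations are CSV with columns participant_id, group, trial_index,
# phase, t_start, t_end, response, truth. These two files are the only place
# the dialect is defined; everything downstream works on in-memory objects.

N_FACES <- 6L
N_CELLS <- 16L

#' Construct a raw iCube session
#'
#' A session holds the irregular-rate raw samples of one recording: a strictly
#' increasing time stamp, the 6 x 16 binary touch map, and the unit orientation
#' quaternion of each sample.
#'
#' @param t numeric vector, seconds since session start, strictly increasing.
#' @param touch integer matrix with `length(t)` rows and 96 columns; column
#'   `(face - 1) * 16 + cell` is cell `cell` (1..16, row-major 4 x 4) of face
#'   `face` (1..6, outward normals +X, -X, +Y, -Y, +Z, -Z in the body frame).
#' @param q numeric matrix with `length(t)` rows and 4 columns, scalar-first
#'   unit quaternions (body-to-world). Norm deviations up to 1e-3 are
#'   renormalized; larger deviations are an error.
#' @return An object of class `icube_session`.
#' @export
icube_session <- function(t, touch, q) {
  touch <- as.matrix(touch)
  q <- as.matrix(q)
  n <- length(t)
  if (nrow(touch) != n || nrow(q) != n) {
    stop("t, touch and q must agree in number of samples", call. = FALSE)
  }
  if (ncol(touch) != N_FACES * N_CELLS) {
    stop("touch must have 96 columns (6 faces x 16 cells)", call. = FALSE)
  }
  if (ncol(q) != 4L) stop("q must have 4 columns (w, x, y, z)", call. = FALSE)
  if (n >= 2 && any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1L
    stop(sprintf("timestamps must be strictly increasing (sample %d)", bad),
         call. = FALSE)
  }
  if (!all(touch == 0L | touch == 1L)) {
    stop("touch values must be 0 or 1", call. = FALSE)
  }
  storage.mode(touch) <- "integer"
  if (n > 0) {
    dev <- abs(quat_norm(q) - 1)
    if (any(dev > 1e-3)) {
      stop(sprintf("quaternion norm deviates by %.2g (> 1e-3) at sample %d",
                   max(dev), which.max(dev)), call. = FALSE)
    }
    fix <- dev > 1e-12   # leave already-unit rows bit-identical
    if (any(fix)) q[fix, ] <- quat_normalize(q[fix, , drop = FALSE])
  }
  structure(list(t = as.numeric(t), touch = touch, q = q),
            class = "icube_session")
}

#' @export
print.icube_session <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("<icube_session> %d samples", n))
  if (n > 0) {
    cat(sprintf(", t in [%.3f, %.3f] s, median interval %.3f s",
                x$t[1], x$t[n], stats::median(diff(x$t))))
  }
  cat("\n")
  invisible(x)
}

#' Number of samples in a session
#' @param session An `icube_session`.
#' @return Integer sample count.
#' @export
n_samples <- function(session) length(session$t)

GROUPS <- c("CB", "LB", "SI")
PHASES <- c("memorization", "recall")
RESPONSES <- c("same", "different", "none")

#' Validate a trial-annotation table
#'
#' Checks the contract of the annotations file: known group/phase/response
#' levels, `response = truth = "none"` for memorization phases, and exactly one
#' memorization + recall pair per trial index within each participant.
#'
#' @param annotations data frame with columns participant_id, group,
#'   trial_index, phase, t_start, t_end, response, truth.
#' @return The annotations as a tibble, invisibly valid (errors otherwise).
#' @export
validate_annotations <- function(annotations) {
  annotations <- tibble::as_tibble(annotations)
  need <- c("participant_id", "group", "trial_index", "phase",
            "t_start", "t_end", "response", "truth")
  miss <- setdiff(need, names(annotations))
  if (length(miss)) {
    stop("annotations missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(annotations$group %in% GROUPS)) {
    stop("group must be one of CB, LB, SI", call. = FALSE)
  }
  if (!all(annotations$phase %in% PHASES)) {
    stop("phase must be memorization or recall", call. = FALSE)
  }
  if (!all(annotations$response %in% RESPONSES) ||
      !all(annotations$truth %in% RESPONSES)) {
    stop("response/truth must be same, different or none", call. = FALSE)
  }
  memo <- annotations$phase == "memorization"
  if (any(annotations$response[memo] != "none") ||
      any(annotations$truth[memo] != "none")) {
    stop("memorization phases must have response = truth = \"none\"",
         call. = FALSE)
  }
  key <- split(annotations$phase,
               paste(annotations$participant_id, annotations$trial_index))
  ok <- vapply(key, function(p) length(p) == 2 && setequal(p, PHASES), logical(1))
  if (!all(ok)) {
    stop("each trial_index needs exactly one memorization + recall pair (",
         names(key)[!ok][1], ")", call. = FALSE)
  }
  annotations
}

fmt_num <- function(x) {
  # shortest representation that round-trips a double
  vapply(x, function(v) formatC(v, format = "g", digits = 17), character(1))
}

#' Write a session (and optionally its annotations) to disk
#'
#' The session goes to a JSON-lines file, one record per sample, with
#' timestamps and quaternion components printed at full double precision so
#' that [read_session()] round-trips bit for bit. Annotations, when given, are
#' validated and written as CSV next to the session file (suffix
#' `_annotations.csv`) or at `annotations_path`.
#'
#' @param session An `icube_session`.
#' @param path Output path for the JSON-lines session file.
#' @param annotations Optional annotation data frame (see
#'   [validate_annotations()]).
#' @param annotations_path Optional explicit path for the annotations CSV.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, annotations = NULL,
                          annotations_path = NULL) {
  stopifnot(inherits(session, "icube_session"))
  n <- length(session$t)
  lines <- character(n)
  if (n > 0) {
    tch <- session$touch
    faces <- vapply(seq_len(n), function(i) {
      row <- tch[i, ]
      paste0("[", paste(
        vapply(seq_len(N_FACES), function(f) {
          paste0("[", paste(row[(f - 1) * N_CELLS + seq_len(N_CELLS)],
                            collapse = ","), "]")
        }, character(1)), collapse = ","), "]")
    }, character(1))
    qs <- apply(session$q, 1, function(v) paste(fmt_num(v), collapse = ","))
    lines <- sprintf('{"t":%s,"touch":%s,"q":[%s]}',
                     fmt_num(session$t), faces, qs)
  }
  writeLines(lines, path)
  if (!is.null(annotations)) {
    annotations <- validate_annotations(annotations)
    if (is.null(annotations_path)) {
      annotations_path <- sub("\\.[^.]*$", "", path)
      annotations_path <- paste0(annotations_path, "_annotations.csv")
    }
    utils::write.csv(annotations, annotations_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a trial-annotation table to CSV
#' @inheritParams validate_annotations
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  annotations <- validate_annotations(annotations)
  utils::write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial-annotation CSV
#' @param path CSV path.
#' @return A validated tibble of annotations.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  ann$participant_id <- as.character(ann$participant_id)
  validate_annotations(ann)
}

#' Read a session file (JSON-lines)
#'
#' Parses the session dialect written by [write_session()], reporting the line
#' number of any malformed record, and validates the type invariants (strictly
#' increasing time, binary touch values, unit quaternions; norm deviations up
#' to 1e-3 are silently renormalized, larger ones are an error).
#'
#' @param path Session file path.
#' @param annotations_path Optional annotations CSV; defaults to the
#'   `_annotations.csv` sibling of `path` when that file exists.
#' @return A list with elements `session` (an `icube_session`) and
#'   `annotations` (a tibble, or `NULL` when no annotations file is found).
#' @export
read_session <- function(path, annotations_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  t <- numeric(n)
  touch <- matrix(0L, n, N_FACES * N_CELLS)
  q <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) {
      stop(sprintf("parse error at line %d of %s: %s", i, path,
                   conditionMessage(e)), call. = FALSE)
    })
    if (!all(c("t", "touch", "q") %in% names(rec))) {
      stop(sprintf("parse error at line %d of %s: missing t/touch/q", i, path),
           call. = FALSE)
    }
    tm <- rec$touch
    if (is.list(tm)) tm <- do.call(rbind, tm)
    if (is.null(dim(tm)) || !all(dim(tm) == c(N_FACES, N_CELLS))) {
      stop(sprintf("parse error at line %d of %s: touch must be 6 x 16", i, path),
           call. = FALSE)
    }
    if (length(rec$q) != 4) {
      stop(sprintf("parse error at line %d of %s: q must have 4 components",
                   i, path), call. = FALSE)
    }
    t[i] <- rec$t
    touch[i, ] <- as.integer(t(tm))  # row f of tm -> columns (f-1)*16 + 1:16
    q[i, ] <- rec$q
  }
  session <- icube_session(t, touch, q)
  if (is.null(annotations_path)) {
    cand <- paste0(sub("\\.[^.]*$", "", path), "_annotations.csv")
    if (file.exists(cand)) annotations_path <- cand
  }
  annotations <- if (!is.null(annotations_path)) {
    read_annotations(annotations_path)
  }
  list(session = session, annotations = annotations)
}

#' Extract the samples of one annotation window
#'
#' @param session An `icube_session`.
#' @param t_start,t_end Window bounds in seconds (inclusive).
#' @return An `icube_session` restricted to `t_start <= t <= t_end`.
#' @export
window_session <- function(session, t_start, t_end) {
  keep <- session$t >= t_start & session$t <= t_end
  icube_session(session$t[keep], session$touch[keep, , drop = FALSE],
                session$q[keep, , drop = FALSE])
}
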