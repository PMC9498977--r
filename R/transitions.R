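# Exploration sequences and transition matrices. A trial's classified frames
# reduce to a sequence of exploration episodes (maximal runs of one explored
# physical face, broken by unexplored samples); each episode carries the
# relative orientation label of its face, and consecutive episodes define
# transitions between labels. The 6 x 6 matrix of transition percentages
# yields the maximum diagonal score and the number of different transitions;
# the number of returns counts revisits of physical faces.

#' Build exploration episodes from classified frames
#'
#' Maximal runs of a constant explored face become one episode (tied explored
#' faces are resolved to the lowest face id before run-building; unexplored
#' samples break runs). Each episode's orientation label is the modal relative
#' label over its samples, ties resolved to the label at episode start.
#'
#' @param frames An `exploration_frames` tibble.
#' @param labels Character vector aligned with `frames` rows, the relative
#'   label of the explored face per sample (see
#'   [relative_label_per_sample()]).
#' @return A tibble of class `exploration_episodes` with columns `face`,
#'   `label`, `start_index`, `end_index` (grid indices) and `gap_before`
#'   (whether unexplored samples separate the episode from its predecessor).
#' @export
build_episodes <- function(frames, labels) {
  face <- frames$face
  n <- length(face)
  if (n == 0 || all(is.na(face))) {
    out <- tibble::tibble(face = integer(), label = character(),
                          start_index = integer(), end_index = integer(),
                          gap_before = logical())
    class(out) <- c("exploration_episodes", class(out))
    return(out)
  }
  r <- rle(ifelse(is.na(face), 0L, face))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  ep_start <- starts[keep]
  ep_end <- ends[keep]
  ep_face <- r$values[keep]
  gap_before <- c(TRUE, (ep_start[-1] - ep_end[-length(ep_end)]) > 1L)
  ep_label <- vapply(seq_along(ep_start), function(i) {
    labs <- labels[ep_start[i]:ep_end[i]]
    labs <- labs[!is.na(labs)]
    if (!length(labs)) return(NA_character_)
    tab <- table(labs)
    modal <- names(tab)[tab == max(tab)]
    if (length(modal) == 1) modal else labs[labs %in% modal][1]
  }, character(1))
  out <- tibble::tibble(face = ep_face, label = ep_label,
                        start_index = frames$grid_index[ep_start],
                        end_index = frames$grid_index[ep_end],
                        gap_before = gap_before)
  class(out) <- c("exploration_episodes", class(out))
  out
}

#' Transition matrix over relative orientation labels
#'
#' Counts transitions between consecutive episodes and converts them to
#' percentages of the total. A transition across an unexplored gap is not
#' counted when the same physical face resumes (the cube was set down and
#' picked up again at the same face; the revisit still counts as a return).
#' Diagonal entries arise when consecutive episodes — necessarily different
#' faces — share an orientation label, i.e., the cube was rotated to bring the
#' next face to the same relative position.
#'
#' @param episodes An `exploration_episodes` tibble.
#' @return A 6 x 6 matrix of percentages (rows = from-label, columns =
#'   to-label, label order up, down, front, rear, left, right), of class
#'   `transition_matrix`, with attribute `n_transitions`. All zero with
#'   `n_transitions = 0` when fewer than two episodes qualify.
#' @export
transition_matrix <- function(episodes) {
  m <- matrix(0, 6, 6, dimnames = list(RELATIVE_LABELS, RELATIVE_LABELS))
  n_ep <- nrow(episodes)
  counts <- m
  if (n_ep >= 2) {
    for (i in seq_len(n_ep - 1)) {
      if (episodes$gap_before[i + 1] &&
          episodes$face[i + 1] == episodes$face[i]) next
      from <- episodes$label[i]; to <- episodes$label[i + 1]
      if (is.na(from) || is.na(to)) next
      counts[from, to] <- counts[from, to] + 1
    }
  }
  n_tr <- sum(counts)
  if (n_tr > 0) m <- counts / n_tr * 100
  attr(m, "n_transitions") <- n_tr
  class(m) <- c("transition_matrix", class(m))
  m
}

#' Maximum diagonal score of a transition matrix
#'
#' The highest of the six diagonal percentages; high values indicate a
#' preferred relative orientation of the explored face.
#'
#' @param matrix A `transition_matrix`.
#' @return Percentage.
#' @export
max_diagonal_score <- function(matrix) {
  max(diag(unclass(matrix)))
}

#' Number of different transitions
#'
#' The count of strictly positive cells among the 36; a measure of exploration
#' variability.
#'
#' @inheritParams max_diagonal_score
#' @return Integer count.
#' @export
n_different_transitions <- function(matrix) {
  sum(unclass(matrix) > 0)
}

#' Number of returns to already explored faces
#'
#' Episodes whose physical face already appeared earlier in the trial;
#' equivalently the number of episodes minus the number of distinct faces
#' explored. Depends on faces only, not on orientation labels.
#'
#' @param episodes An `exploration_episodes` tibble.
#' @return Integer count.
#' @export
n_returns <- function(episodes) {
  if (nrow(episodes) == 0) return(0L)
  nrow(episodes) - length(unique(episodes$face))
}
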