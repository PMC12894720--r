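# Fusion-window refinement from per-round observed sperm states.
#
# Four post-fusion temporal landmarks (sperm head disappearance, onset of
# second-polar-body (PB2) protrusion, PB2 contact-angle crossover at 90
# degrees, completed PB2 extrusion) date the fusion event backwards from the
# state a fused spermatozoon shows at an observation time t_obs.  Each state
# yields an interval rule for the fusion time; the refined window is the
# intersection of the rules across all observation rounds.

#' Post-fusion temporal landmarks
#'
#' Mean and standard deviation, in minutes after fusion, of the four
#' morphological landmarks used to date a fusion event: completed
#' disappearance of the sperm head into the ooplasm (24 +/- 3 min), onset of
#' PB2 protrusion (28 +/- 2 min), PB2 contact-angle crossover from >90 to
#' <90 degrees (49 +/- 6 min), completed PB2 extrusion (73 +/- 10 min).
#'
#' @param head_disappearance,pb2_onset,pb2_angle_crossover,pb2_complete
#'   numeric `c(mean, sd)` in minutes after fusion.
#' @return an object of class `"landmark_set"`.
#' @export
landmark_set <- function(head_disappearance = c(24, 3),
                         pb2_onset = c(28, 2),
                         pb2_angle_crossover = c(49, 6),
                         pb2_complete = c(73, 10)) {
  lm <- list(head_disappearance = head_disappearance,
             pb2_onset = pb2_onset,
             pb2_angle_crossover = pb2_angle_crossover,
             pb2_complete = pb2_complete)
  for (nm in names(lm)) {
    v <- lm[[nm]]
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)) || any(v <= 0))
      stop_fk("landmark %s must be c(mean, sd), both positive", nm)
  }
  means <- vapply(lm, `[[`, numeric(1L), 1L)
  if (is.unsorted(means, strictly = TRUE))
    stop_fk("landmark means must be strictly increasing in the order %s",
            paste(names(lm), collapse = " < "))
  structure(lm, class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("  %-20s %g +/- %g min after fusion\n", nm, x[[nm]][1L],
                x[[nm]][2L]))
  invisible(x)
}

#' Observed per-round sperm states
#'
#' The state of one spermatozoon at one observation round, in the order the
#' post-fusion landmarks occur: still motile and unfused; flagellar-beating
#' arrest seen live (fusion observed); fused head still visible on the
#' oolemma; only the flagellum still visible (head internalised); PB2
#' protruding with contact angle >90 degrees; PB2 extracting with contact
#' angle <90 degrees; PB2 extrusion complete.
#'
#' @format character vector of the seven state tokens.
#' @export
observed_states <- c("unfused_motile", "arrest_observed",
                     "head_visible_fused", "flagellum_only",
                     "pb2_protrusion_angle_gt_90",
                     "pb2_extracting_angle_lt_90", "pb2_complete")

#' Penetration window from the gap between observation rounds
#'
#' A penetration that happened between two observation rounds is bounded by
#' the end of the earlier round and the start of the later one.  A
#' penetration seen live is encoded by passing the observed time twice,
#' giving a degenerate window.
#'
#' @param prev_round_end,next_round_start minutes post-insemination.
#' @return a [time_window()] `[prev_round_end, next_round_start]`.
#' @examples
#' penetration_window_from_rounds(30, 75)
#' penetration_window_from_rounds(30, 30)  # observed live at 30 min
#' @export
penetration_window_from_rounds <- function(prev_round_end, next_round_start) {
  if (!is_scalar_num(prev_round_end) || !is_scalar_num(next_round_start))
    stop_fk("round bounds must be single finite numbers")
  if (prev_round_end > next_round_start)
    stop_fk("prev_round_end (%g) is after next_round_start (%g)",
            prev_round_end, next_round_start)
  time_window(prev_round_end, next_round_start)
}

#' Fusion-time interval rule for one observed state
#'
#' Converts the state of a spermatozoon observed at time `t_obs` into an
#' interval for its fusion time, using the landmark means +/- one standard
#' deviation as the earliest/latest landmark completion times.  With the
#' default [landmark_set()] the rules are:
#' \itemize{
#'   \item `unfused_motile`: `[t_obs, horizon]` (fusion, if any, is later);
#'   \item `arrest_observed`: `[t_obs - 1, t_obs + 1]` (fusion seen live);
#'   \item `head_visible_fused`: `[t_obs - 27, t_obs]`;
#'   \item `flagellum_only`: `[0, t_obs - 21]`;
#'   \item `pb2_protrusion_angle_gt_90`: `[t_obs - 55, t_obs - 26]`;
#'   \item `pb2_extracting_angle_lt_90`: `[t_obs - 83, t_obs - 43]`;
#'   \item `pb2_complete`: `[0, t_obs - 63]`.
#' }
#' One-sided rules are closed by clipping at 0 and `horizon`.
#'
#' @param state one of [observed_states].
#' @param t_obs observation time, minutes post-insemination.
#' @param lm a [landmark_set()].
#' @param horizon observation end, minutes.
#' @return a [time_window()] clipped to `[0, horizon]`.
#' @export
rule_window <- function(state, t_obs, lm = landmark_set(), horizon = 240) {
  state <- match.arg(state, observed_states)
  stopifnot(inherits(lm, "landmark_set"))
  if (!is_scalar_num(t_obs) || t_obs < 0 || t_obs > horizon)
    stop_fk("t_obs must lie in [0, horizon] = [0, %g] (got %g)", horizon,
            t_obs)
  hd <- lm$head_disappearance; on <- lm$pb2_onset
  cx <- lm$pb2_angle_crossover; cp <- lm$pb2_complete
  b <- switch(state,
    unfused_motile = c(t_obs, horizon),
    arrest_observed = c(t_obs - 1, t_obs + 1),
    head_visible_fused = c(t_obs - (hd[1L] + hd[2L]), t_obs),
    flagellum_only = c(0, t_obs - (hd[1L] - hd[2L])),
    pb2_protrusion_angle_gt_90 = c(t_obs - (cx[1L] + cx[2L]),
                                   t_obs - (on[1L] - on[2L])),
    pb2_extracting_angle_lt_90 = c(t_obs - (cp[1L] + cp[2L]),
                                   t_obs - (cx[1L] - cx[2L])),
    pb2_complete = c(0, t_obs - (cp[1L] - cp[2L])))
  if (b[2L] < 0)
    stop_fk(
      "state '%s' at t_obs = %g min is inconsistent: implied fusion before insemination",
      state, t_obs)
  w <- clip_interval(b[1L], b[2L], horizon)
  time_window(w[1L], w[2L])
}

as_rounds_frame <- function(rounds) {
  if (is.data.frame(rounds)) {
    need <- c("t_start", "t_end", "state")
    miss <- setdiff(need, names(rounds))
    if (length(miss))
      stop_fk("rounds table is missing column(s): %s",
              paste(miss, collapse = ", "))
    rounds
  } else {
    do.call(rbind, lapply(rounds, function(r)
      data.frame(t_start = r$t_start, t_end = r$t_end, state = r$state,
                 stringsAsFactors = FALSE)))
  }
}

#' Refine a fusion time window from a sequence of observation rounds
#'
#' Intersects the [rule_window()] of every observation round of one
#' spermatozoon (each anchored at the round midpoint) with each other and
#' with `[pen["lower"], horizon]` — the sperm cannot have fused before it
#' could have penetrated.  If the oocyte states were identified correctly
#' the per-round windows always overlap; an empty intersection is reported
#' as an inconsistency naming the conflicting rounds.
#'
#' @param rounds data frame (or list of lists) with columns `t_start`,
#'   `t_end`, `state`; must be non-empty (rounds are sorted internally, so
#'   the result does not depend on their order).
#' @param lm a [landmark_set()].
#' @param pen the sperm's penetration [time_window()] (or numeric
#'   `c(lower, upper)`).
#' @param horizon observation end, minutes.
#' @return the refined fusion [time_window()].
#' @export
refine_fusion_window <- function(rounds, lm = landmark_set(),
                                 pen = time_window(0, 0), horizon = 240) {
  rounds <- as_rounds_frame(rounds)
  if (is.null(rounds) || nrow(rounds) == 0L)
    stop_fk("refine_fusion_window() needs at least one observation round")
  if (any(rounds$t_end < rounds$t_start))
    stop_fk("observation rounds must have t_start <= t_end")
  rounds <- rounds[order(rounds$t_start, rounds$t_end), , drop = FALSE]
  t_obs <- (rounds$t_start + rounds$t_end) / 2
  lo <- numeric(nrow(rounds)); hi <- numeric(nrow(rounds))
  for (i in seq_len(nrow(rounds))) {
    w <- rule_window(rounds$state[i], t_obs[i], lm, horizon)
    lo[i] <- w[[1L]]; hi[i] <- w[[2L]]
  }
  lower <- max(c(lo, pen[[1L]]))
  upper <- min(c(hi, horizon))
  if (lower > upper) {
    i_lo <- which.max(lo); i_hi <- which.min(hi)
    stop_fk(paste0(
      "inconsistent observation rounds: state '%s' at [%g, %g] requires ",
      "fusion >= %g but state '%s' at [%g, %g] requires fusion <= %g"),
      rounds$state[i_lo], rounds$t_start[i_lo], rounds$t_end[i_lo], lower,
      rounds$state[i_hi], rounds$t_start[i_hi], rounds$t_end[i_hi], upper)
  }
  time_window(lower, upper)
}
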