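# Most-probable 3-state path by dynamic programming. Self-transition
# probability is 1 - 2*rho, each switch rho. Log-score differences below
# `tol` are treated as exact ties and resolved in favor of the incumbent
# state (i.e. staying), which makes the path deterministic across
# platforms even when two beta densities are numerically indistinguishable.
viterbi3 <- function(le, rho, tol = 1e-6) {
  stopifnot(rho > 0, rho < 0.5)
  n <- ncol(le)
  stay <- log(1 - 2 * rho)
  sw <- log(rho)
  V <- le[, 1L] + log(1 / 3)
  bp <- matrix(1L, nrow = 3L, ncol = n)
  if (n > 1L) {
    for (t in 2:n) {
      newV <- numeric(3L)
      for (s in 1:3) {
        cand <- V + sw
        cand[s] <- V[s] + stay
        best <- which.max(cand)
        prev <- if (cand[best] > cand[s] + tol) best else s
        bp[s, t] <- prev
        newV[s] <- cand[prev] + le[s, t]
      }
      V <- newV
    }
  }
  end_cands <- which(V >= max(V) - tol)
  end <- end_cands[1L]                       # deterministic tie resolution
  path <- integer(n)
  path[n] <- end
  if (n > 1L) for (t in n:2) path[t - 1L] <- bp[path[t], t]
  path
}

#' Segment a window series into line-origin states
#'
#' Decodes the most probable sequence of genotype states (HH, HET, LL) over
#' the windows of a series, given emission parameters and a per-step state
#' switch probability `rho`, then merges consecutive same-state windows
#' into runs.
#'
#' @param series A `window_series`.
#' @param params An `emission_params` object.
#' @param rho Per-window-step switch probability (0 < rho < 1/2). The
#'   default 1e-3 strongly penalizes single-window excursions while
#'   admitting state changes supported by runs of windows.
#' @param tol Log-density tie tolerance (see [viterbi3] internals).
#' @return `data.frame` with `state`, `first_window`, `last_window`; zero
#'   rows for an empty series.
#' @export
segment_windows <- function(series, params, rho = 1e-3, tol = 1e-6) {
  if (nrow(series) == 0L)
    return(data.frame(state = character(0), first_window = integer(0),
                      last_window = integer(0), stringsAsFactors = FALSE))
  le <- emission_logdens(series$f, params)
  path <- viterbi3(le, rho, tol)
  r <- rle(path)
  last <- cumsum(r$lengths)
  data.frame(state = .state_names[r$values],
             first_window = c(1L, utils::head(last, -1L) + 1L),
             last_window = last, stringsAsFactors = FALSE)
}

#' Refine segment boundaries to base-pair resolution
#'
#' Places each boundary between adjacent segments at the (floored) midpoint
#' between the last covered marker supporting the left state and the first
#' covered marker supporting the right state. With sliding windows the
#' supporting markers of a window run are taken at the window centers, so
#' the two supporting markers are adjacent covered markers.
#'
#' @param runs Output of [segment_windows()] (window-index runs, in the
#'   direction the series was traversed).
#' @param pos Covered marker positions in forward (ascending) order.
#' @param w Window size in markers.
#' @param reverse `TRUE` if `runs` came from traversing the chromosome in
#'   reverse; results are mapped back to forward coordinates.
#' @param counts Optional per-marker counts (`n_h`, `n_l`, rows aligned
#'   with `pos`). When supplied, the pair of supporting markers at each
#'   boundary is chosen by maximizing the marker-level split likelihood in
#'   the window-overlap region around the state change (the windowed state
#'   path localizes a crossover only to within a window, and the Viterbi
#'   switch point carries a systematic offset of up to half a window);
#'   without counts the supporting markers are the adjacent window-center
#'   markers.
#' @return `data.frame` of class `segment_calls`: `start`, `end`, `state`,
#'   tiling the covered span `[pos[1], pos[n]]`, adjacent segments
#'   differing in state. Zero rows if `runs` is empty.
#' @export
refine_breakpoints <- function(runs, pos, w, reverse = FALSE, counts = NULL,
                               rho = 1e-3) {
  if (nrow(runs) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      state = character(0), stringsAsFactors = FALSE))
  n <- length(pos)
  half <- as.integer(floor((w - 1) / 2))
  states <- runs$state
  if (nrow(runs) > 1L) {
    j <- runs$last_window[-nrow(runs)]    # transition after window j
    # supporting marker at the window center; the reverse direction uses
    # the mirrored center so that, for even w too, a transition maps to
    # the same forward marker pair from either direction
    mb <- if (reverse) n - j - (w - 1L - half) else j + half
    if (reverse) {
      states <- rev(states)
      mb <- rev(mb)
    }
  } else {
    mb <- integer(0)
  }

  if (!is.null(counts)) {
    # expected H-read fraction per state (broad error allowance)
    p_state <- c(HH = 0.99, HET = 0.5, LL = 0.01)
    marker_ll <- function(s, rng) {
      counts$n_h[rng] * log(p_state[s]) + counts$n_l[rng] * log(1 - p_state[s])
    }
    for (i in seq_along(mb)) {
      lo <- max(if (i == 1L) 1L else mb[i - 1L] + 1L, mb[i] - w)
      hi <- min(if (i == length(mb)) n - 1L else mb[i + 1L] - 1L, mb[i] + w)
      if (hi <= lo) next
      rng <- lo:hi
      # marker m left of the split contributes loglik under the left
      # state; cumulative difference locates the optimal split
      score <- cumsum(marker_ll(states[i], rng) - marker_ll(states[i + 1L], rng))
      mb[i] <- lo + which.max(score) - 1L
    }
    # terminal crossovers within half a window of a chromosome end never
    # produce a full window of their own state, so the state path cannot
    # see them; search the terminal regions for a split whose likelihood
    # gain exceeds the path's switch penalty
    gain_min <- -log(rho)
    hi <- min(w, (if (length(mb)) mb[1L] else n) - 1L)
    if (hi >= 1L) {
      rng <- 1L:hi
      base <- marker_ll(states[1L], rng)
      best <- lapply(setdiff(.state_names, states[1L]), function(s0) {
        sc <- cumsum(marker_ll(s0, rng) - base)
        k <- which.max(sc)
        list(s = s0, k = k, gain = sc[k])
      })
      b <- best[[which.max(vapply(best, `[[`, numeric(1), "gain"))]]
      if (b$gain > gain_min) {
        mb <- c(b$k, mb)
        states <- c(b$s, states)
      }
    }
    lo <- max(n - w, (if (length(mb)) mb[length(mb)] else 1L) + 1L)
    if (lo <= n - 1L) {
      rng <- lo:n
      base <- marker_ll(states[length(states)], rng)
      best <- lapply(setdiff(.state_names, states[length(states)]),
                     function(s0) {
        sc <- rev(cumsum(rev(marker_ll(s0, rng) - base)))
        # sc[k] = gain when markers rng[k..] switch; boundary precedes
        # rng[k], so k = 1 (no left part) is not a valid split here
        k <- 1L + which.max(sc[-1L])
        list(s = s0, k = k, gain = sc[k])
      })
      b <- best[[which.max(vapply(best, `[[`, numeric(1), "gain"))]]
      if (b$gain > gain_min) {
        mb <- c(mb, lo + b$k - 2L)
        states <- c(states, b$s)
      }
    }
  }

  if (!is.null(counts)) {
    # segments shorter than a window leave no fully-interior window and
    # are invisible to the state path; recover them by searching every
    # called segment for the best-scoring interior sub-segment of another
    # state (maximum-subarray on the per-marker log-likelihood gain, two
    # new breakpoints, so twice the switch penalty)
    gain2 <- 2 * (-log(rho))
    seg_lo <- c(1L, mb + 1L)
    seg_hi <- c(mb, n)
    ins_at <- integer(0); ins_states <- list()
    for (i in seq_along(seg_lo)) {
      if (seg_hi[i] - seg_lo[i] < 2L) next
      rng <- seg_lo[i]:seg_hi[i]
      base <- marker_ll(states[i], rng)
      for (s0 in setdiff(.state_names, states[i])) {
        dll <- marker_ll(s0, rng) - base
        # Kadane with tracked boundaries
        best_gain <- 0; best_a <- 0L; best_b <- 0L
        cur <- 0; cur_a <- 1L
        for (k in seq_along(dll)) {
          if (cur <= 0) { cur <- 0; cur_a <- k }
          cur <- cur + dll[k]
          if (cur > best_gain) { best_gain <- cur; best_a <- cur_a; best_b <- k }
        }
        if (best_gain > gain2 && best_a > 1L && best_b < length(rng)) {
          # boundaries: after marker a-1 (into s0) and after marker b
          # (back); segment i splits into states[i], s0, states[i]
          ins_at <- c(ins_at, i)
          ins_states[[length(ins_states) + 1L]] <-
            list(a = rng[best_a] - 1L, b = rng[best_b], s = s0)
          break    # one insertion per segment is ample at these scales
        }
      }
    }
    for (j in rev(seq_along(ins_at))) {
      i <- ins_at[j]
      ins <- ins_states[[j]]
      mb <- append(mb, c(ins$a, ins$b), after = i - 1L)
      states <- append(states, c(ins$s, states[i]), after = i)
    }
  }

  if (length(mb) == 0L) {
    out <- data.frame(start = pos[1L], end = pos[n], state = states[1L],
                      stringsAsFactors = FALSE)
    class(out) <- c("segment_calls", "data.frame")
    return(out)
  }
  bps <- floor((pos[mb] + pos[mb + 1L]) / 2)
  out <- data.frame(start = c(pos[1L], bps), end = c(bps, pos[n]),
                    state = states, stringsAsFactors = FALSE)
  class(out) <- c("segment_calls", "data.frame")
  out
}

#' Run the segmentation pipeline in both directions
#'
#' Executes window construction, emission fitting and state decoding on one
#' individual-chromosome count table forward and on position-reversed
#' input, mapping the reverse result back to forward coordinates. Forward
#' and reverse windows cover identical marker intervals, so emissions are
#' fitted once and shared.
#'
#' Bidirectional estimation exists to expose incoherent calls in
#' low-information regions, where inferred crossovers get delayed toward
#' the end of the region in the direction of travel.
#'
#' @param counts `data.frame` with `pos`, `n_h`, `n_l` for one individual
#'   and chromosome.
#' @param w Window size in markers.
#' @param rho Switch probability per window step.
#' @param max_tries Emission fitting retry bound.
#' @return List with `forward` and `reverse` (`segment_calls` in forward
#'   coordinates), `params`, and `uncallable` (TRUE when fewer than `w`
#'   markers are covered; both segment tables are then empty).
#' @export
run_bidirectional <- function(counts, w, rho = 1e-3, max_tries = 20) {
  if (is.unsorted(counts$pos)) counts <- counts[order(counts$pos), , drop = FALSE]
  win <- build_windows(counts, w)
  if (nrow(win) == 0L) {
    empty <- refine_breakpoints(
      data.frame(state = character(0), first_window = integer(0),
                 last_window = integer(0)), attr(win, "pos"), w)
    return(list(forward = empty, reverse = empty, params = NULL,
                uncallable = TRUE))
  }
  pos <- attr(win, "pos")
  params <- fit_emissions(win, max_tries = max_tries)
  runs_f <- segment_windows(win, params, rho = rho)
  rev_series <- data.frame(f = rev(win$f))
  runs_r <- segment_windows(rev_series, params, rho = rho)
  list(
    forward = refine_breakpoints(runs_f, pos, w, reverse = FALSE,
                                 counts = counts),
    reverse = refine_breakpoints(runs_r, pos, w, reverse = TRUE,
                                 counts = counts),
    params = params,
    uncallable = FALSE
  )
}
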