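#' Simulate 24 h of break repair and misrepair
#'
#' Discrete-hazard kinetics: in each time step of `dt` seconds an open
#' simple break rejoins properly with probability `dt / tau_simple`; an
#' open complex break attempts repair with probability `dt / tau_complex`.
#' A complex-break attempt is a misrejoin with probability
#' `p_mis = w_mis * (1 - exp(-S))`, where `S` sums the Gaussian proximity
#' kernel over the other complex breaks with open ends; the partner is
#' drawn proportionally to the kernel and one open end of each partner is
#' joined.  Otherwise the attempt rejoins the break properly (both its own
#' ends); a half-joined break can only misrejoin further.  Ends still open
#' at the end of the period are unrepaired.
#'
#' The implementation is event-driven but exactly equivalent to stepping:
#' attempt times are drawn from the geometric distribution of the
#' discrete hazard, so results are independent of `dt` for `dt <<
#' tau_simple`.
#'
#' @param breaks break table from [induce_breaks()] (columns `x`, `y`,
#'   `z`, `complex`).
#' @param params a [repair_params()].
#' @return An object of class `rejoin_graph`: list with `edges`
#'   (data.frame `break_a`, `break_b`, `type` = proper/mis, `t_h`, and the
#'   joined end indices `end_a`, `end_b`), `open_ends` (integer per break
#'   at the end), `breaks` (the input), and `params`.
#' @export
simulate_repair <- function(breaks, params = repair_params()) {
  n <- nrow(breaks)
  edges <- data.frame(break_a = integer(), break_b = integer(),
                      type = character(), t_h = numeric(),
                      end_a = integer(), end_b = integer())
  open_ends <- integer(0)
  if (n > 0) {
    dt_h <- params$dt / 3600
    Tend <- params$duration
    open_ends <- rep(2L, n)
    is_cx <- breaks$complex
    # simple breaks: one geometric proper-rejoin time each
    si <- which(!is_cx)
    if (length(si)) {
      t_s <- dt_h * (rgeom(length(si), dt_h / params$tau_simple) + 1)
      ok <- t_s <= Tend
      if (any(ok))
        edges <- rbind(edges, data.frame(break_a = si[ok], break_b = si[ok],
                                         type = "proper", t_h = t_s[ok],
                                         end_a = 1L, end_b = 2L))
      open_ends[si[ok]] <- 0L
    }
    # complex breaks: chronological attempt processing
    ci <- which(is_cx)
    if (length(ci)) {
      px <- breaks$x; py <- breaks$y; pz <- breaks$z
      p_att <- dt_h / params$tau_complex
      next_t <- rep(Inf, n)
      next_t[ci] <- dt_h * (rgeom(length(ci), p_att) + 1)
      s2 <- 2 * params$sigma_int^2
      repeat {
        i <- which.min(next_t)
        ti <- next_t[i]
        if (!is.finite(ti) || ti > Tend) break
        others <- ci[open_ends[ci] > 0L & ci != i]
        ker <- if (length(others) && s2 > 0) {
          d2 <- (px[others] - px[i])^2 + (py[others] - py[i])^2 +
            (pz[others] - pz[i])^2
          exp(-d2 / s2)
        } else numeric(0)
        S <- sum(ker)
        p_mis <- params$w_mis * (1 - exp(-S))
        u <- stats::runif(1)
        if (length(ker) && u < p_mis) {
          j <- others[sample.int(length(others), 1L, prob = ker)]
          edges <- rbind(edges,
                         data.frame(break_a = i, break_b = j,
                                    type = "mis", t_h = ti,
                                    end_a = 3L - open_ends[i],
                                    end_b = 3L - open_ends[j]))
          open_ends[i] <- open_ends[i] - 1L
          open_ends[j] <- open_ends[j] - 1L
        } else if (open_ends[i] == 2L && u >= p_mis) {
          edges <- rbind(edges,
                         data.frame(break_a = i, break_b = i,
                                    type = "proper", t_h = ti,
                                    end_a = 1L, end_b = 2L))
          open_ends[i] <- 0L
        }
        next_t[i] <- if (open_ends[i] > 0L)
          ti + dt_h * (rgeom(1, p_att) + 1) else Inf
      }
    }
  }
  structure(list(edges = edges, open_ends = open_ends, breaks = breaks,
                 params = params),
            class = "rejoin_graph")
}

#' @export
print.rejoin_graph <- function(x, ...) {
  cat(sprintf(
    "<rejoin_graph> %d breaks, %d proper, %d mis, %d unrepaired ends\n",
    nrow(x$breaks), sum(x$edges$type == "proper"),
    sum(x$edges$type == "mis"), sum(x$open_ends)))
  invisible(x)
}
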