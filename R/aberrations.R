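#' Classify chromosome exchanges
#'
#' Connected components of the rejoin graph restricted to misrepair edges
#' (breaks as nodes) are candidate exchange events.  A component with
#' exactly 2 breaks on exactly 2 distinct chromosomes is a simple exchange
#' (dicentrics and translocations); a component with more than 2 breaks on
#' 2 or more chromosomes is a complex exchange.  Components confined to a
#' single chromosome (ring/inversion analogs) are tallied separately and
#' excluded from both classes.
#'
#' Simple exchanges can optionally be sub-typed as dicentric or
#' translocation.  Break ends carry no strand polarity, so the sub-type is
#' decided by which free ends were misrejoined: joining the like-numbered
#' ends of the two breaks fuses the two centromeric fragments (dicentric),
#' any other pairing gives a balanced translocation.  Because end choice at
#' misrepair is uniform, each outcome occurs with probability 1/2, the
#' combinatorics of unpolarized free-end rejoining.
#'
#' @param graph a [simulate_repair()] result.
#' @param subtype logical; also label simple exchanges as
#'   dicentric/translocation (off by default; totals are the primary
#'   endpoint).
#' @return data.frame of exchange events: `event`, `n_breaks`,
#'   `n_chromosomes`, `class` (`"simple"`, `"complex"` or
#'   `"intra"`), and with `subtype = TRUE` a `subtype` column
#'   (`"dicentric"`, `"translocation"` or `NA`).
#' @export
classify_exchanges <- function(graph, subtype = FALSE) {
  ed <- graph$edges[graph$edges$type == "mis", , drop = FALSE]
  empty <- data.frame(event = integer(), n_breaks = integer(),
                      n_chromosomes = integer(), class = character())
  if (subtype) empty$subtype <- character()
  if (nrow(ed) == 0) return(empty)
  # union-find over the (few) misrejoined breaks
  nodes <- sort(unique(c(ed$break_a, ed$break_b)))
  parent <- seq_along(nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(ed))) {
    a <- find(match(ed$break_a[r], nodes))
    b <- find(match(ed$break_b[r], nodes))
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_along(nodes), find, integer(1))
  fib <- graph$breaks$fiber[nodes]
  out <- do.call(rbind, lapply(split(seq_along(nodes), comp), function(m) {
    nb <- length(m); nc <- length(unique(fib[m]))
    cls <- if (nc == 1L) "intra"
           else if (nb == 2L) "simple"
           else "complex"
    row <- data.frame(n_breaks = nb, n_chromosomes = nc, class = cls)
    if (subtype) {
      row$subtype <- NA_character_
      if (cls == "simple") {
        e <- ed[ed$break_a %in% nodes[m] | ed$break_b %in% nodes[m], ][1, ]
        ea <- if (!is.null(ed$end_a)) e$end_a else 1L
        eb <- if (!is.null(ed$end_b)) e$end_b else 1L
        row$subtype <- if (ea == eb) "dicentric" else "translocation"
      }
    }
    row
  }))
  data.frame(event = seq_len(nrow(out)), out, row.names = NULL)
}

#' Tally exchanges over Monte Carlo histories
#'
#' @param history_events list of [classify_exchanges()] results, one per
#'   history.
#' @param dose dose of the run, Gy.
#' @param contribution contribution label.
#' @return An `aberration_counts` data.frame with one row per endpoint
#'   (`simple`, `complex`, `intra`): mean count per cell and standard
#'   error (`sd / sqrt(histories)`), plus per-history counts in attribute
#'   `per_history`.
#' @export
tally_exchanges <- function(history_events, dose = NA_real_,
                            contribution = "tot") {
  nh <- length(history_events)
  if (nh < 2) stop("need at least 2 histories to form a standard error")
  per <- vapply(history_events, function(ev) {
    c(simple = sum(ev$class == "simple"),
      complex = sum(ev$class == "complex"),
      intra = sum(ev$class == "intra"))
  }, numeric(3))
  out <- data.frame(
    dose_Gy = dose, contribution = contribution,
    endpoint = rownames(per),
    mean = rowMeans(per),
    se = apply(per, 1, sd) / sqrt(nh),
    histories = nh, row.names = NULL)
  structure(out, per_history = per,
            class = c("aberration_counts", "data.frame"))
}
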