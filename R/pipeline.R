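#' Simulate chromosome aberrations at one dose
#'
#' Runs `histories` independent Monte Carlo histories of the full chain
#' (irradiation, voxel scoring against chromatin, DSB induction, 24 h
#' repair, exchange classification) for one contribution at one dose.
#'
#' @param source a [beam_spec()] or [fluence_spectrum()].
#' @param dose absorbed dose, Gy.
#' @param histories number of Monte Carlo histories (>= 2).
#' @param contribution `"tot"`, `"dir"` or `"ind"`.
#' @param geometry,track_params,break_params,rep_params model parameters.
#' @param pool chromatin pool from [chromatin_pool()]; built with defaults
#'   when omitted (and reused across doses when supplied).
#' @param keep_track_energies also return the per-track nucleus energies
#'   of all histories (for microdosimetry spectra).
#' @return list with `counts` ([tally_exchanges()] table), `n_dsb`
#'   (per-history DSB totals), `n_complex_breaks`, `energy` (summed
#'   direct/indirect nucleus energy, eV), and optionally `track_eps`,
#'   `track_cat`.
#' @export
simulate_aberrations <- function(source, dose, histories,
                                 contribution = "tot",
                                 geometry = irradiation_geometry(),
                                 track_params = track_model_params(),
                                 break_params = break_model_params(),
                                 rep_params = repair_params(),
                                 pool = NULL,
                                 keep_track_energies = FALSE) {
  if (histories < 2) stop("histories must be >= 2")
  if (is.null(pool)) pool <- chromatin_pool()
  events <- vector("list", histories)
  n_dsb <- integer(histories)
  n_cx <- integer(histories)
  e_dir <- 0; e_ind <- 0
  eps_all <- if (keep_track_energies) vector("list", histories)
  cat_all <- if (keep_track_energies) vector("list", histories)
  for (h in seq_len(histories)) {
    occ <- pool[[(h - 1L) %% length(pool) + 1L]]
    out <- .kernel_run(source, dose, geometry, track_params, contribution,
                       occupancy = occ, break_params = break_params,
                       want_breaks = TRUE)
    br <- out$breaks
    nb <- length(br$fiber)
    n_dsb[h] <- nb
    n_cx[h] <- sum(br$complex)
    e_dir <- e_dir + out$e_dir; e_ind <- e_ind + out$e_ind
    if (keep_track_energies) {
      eps_all[[h]] <- out$track_eps
      cat_all[[h]] <- out$track_cat
    }
    if (nb > 0) {
      breaks <- data.frame(id = seq_len(nb), fiber = br$fiber,
                           segment = br$segment, x = br$x, y = br$y,
                           z = br$z, complex = br$complex == 1L)
      g <- simulate_repair(breaks, rep_params)
      events[[h]] <- classify_exchanges(g)
    } else {
      events[[h]] <- classify_exchanges(
        structure(list(edges = data.frame(break_a = integer(),
                                          break_b = integer(),
                                          type = character(),
                                          t_h = numeric()),
                       breaks = .empty_breaks()), class = "rejoin_graph"))
    }
  }
  res <- list(counts = tally_exchanges(events, dose, contribution),
              n_dsb = n_dsb, n_complex_breaks = n_cx,
              energy = c(dir = e_dir, ind = e_ind),
              dose = dose, contribution = contribution,
              histories = histories)
  if (keep_track_energies) {
    res$track_eps <- unlist(eps_all)
    res$track_cat <- ifelse(unlist(cat_all) == 0, "direct", "indirect")
  }
  res
}

#' Experiment configuration
#'
#' @param source a [beam_spec()] or [fluence_spectrum()].
#' @param doses dose points in Gy (default the seven points 0.05-1 Gy).
#' @param histories Monte Carlo histories per dose point.
#' @param contributions subset of `c("tot", "dir", "ind")`.
#' @param seed master seed for the run.
#' @param geometry,track_params,break_params,rep_params model parameters.
#' @param n_draws bootstrap draws for the LQ fits.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return A `run_config` list, validated.
#' @export
run_config <- function(source,
                       doses = c(0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1),
                       histories = 200,
                       contributions = c("tot", "dir", "ind"),
                       seed = 1,
                       geometry = irradiation_geometry(),
                       track_params = track_model_params(),
                       break_params = break_model_params(),
                       rep_params = repair_params(),
                       n_draws = 2000,
                       out_dir = NULL) {
  if (!inherits(source, "beam_spec") &&
      !inherits(source, "fluence_spectrum"))
    stop("source must be a beam_spec or fluence_spectrum")
  if (any(doses <= 0) || any(doses > 1))
    stop("doses must lie in (0, 1] Gy")
  if (length(doses) < 3) stop("need at least 3 dose points for the LQ fit")
  if (histories < 2) stop("histories must be >= 2")
  contributions <- match.arg(contributions, c("tot", "dir", "ind"),
                             several.ok = TRUE)
  structure(list(source = source, doses = sort(doses),
                 histories = histories, contributions = contributions,
                 seed = as.integer(seed), geometry = geometry,
                 track_params = track_params, break_params = break_params,
                 rep_params = rep_params, n_draws = n_draws,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run a full experiment
#'
#' Executes one simulation per contribution per dose point, tallies simple
#' and complex exchanges, fits the LQ model per endpoint and contribution,
#' and (when all three contributions are present) compares the total
#' response against the direct + indirect sum with the containment and KS
#' criteria.  Identical configuration and seed give identical outputs.
#'
#' @param config a [run_config()].
#' @param pool optional pre-built [chromatin_pool()].
#' @return A `result_bundle`: list with `counts` (long data.frame),
#'   `fits` (nested list `fits[[contribution]][[endpoint]]`),
#'   `comparisons` (data.frame of m statistics or NULL), `dose_fractions`,
#'   `config`.
#' @export
run_experiment <- function(config, pool = NULL) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  if (is.null(pool)) pool <- chromatin_pool()
  counts <- list()
  fits <- list()
  dfrac <- list()
  for (ctr in config$contributions) {
    rows <- list()
    e_dir <- 0; e_ind <- 0
    for (d in config$doses) {
      sim <- simulate_aberrations(config$source, d, config$histories,
                                  ctr, config$geometry,
                                  config$track_params,
                                  config$break_params, config$rep_params,
                                  pool = pool)
      rows[[length(rows) + 1L]] <- sim$counts
      e_dir <- e_dir + sim$energy["dir"]; e_ind <- e_ind + sim$energy["ind"]
    }
    tab <- do.call(rbind, lapply(rows, as.data.frame))
    counts[[ctr]] <- tab
    dfrac[[ctr]] <- c(dir = unname(e_dir), ind = unname(e_ind))
    fits[[ctr]] <- lapply(c(simple = "simple", complex = "complex"),
                          function(ep) {
      sub <- tab[tab$endpoint == ep, ]
      fit_lq(sub$dose_Gy, sub$mean, pmax(sub$se, 1e-6),
             n_draws = config$n_draws)
    })
  }
  comparisons <- NULL
  if (all(c("tot", "dir", "ind") %in% config$contributions)) {
    comparisons <- do.call(rbind, lapply(
      c(simple = "simple", complex = "complex"), function(ep) {
      ts <- counts[["tot"]][counts[["tot"]]$endpoint == ep, ]
      ds <- counts[["dir"]][counts[["dir"]]$endpoint == ep, ]
      is <- counts[["ind"]][counts[["ind"]]$endpoint == ep, ]
      fit_sum <- fit_lq(ds$dose_Gy, ds$mean + is$mean,
                        pmax(sqrt(ds$se^2 + is$se^2), 1e-6),
                        n_draws = config$n_draws)
      ft <- fits[["tot"]][[ep]]
      data.frame(endpoint = ep,
                 m_t_to_di = m_containment(ft, fit_sum),
                 m_di_to_t = m_containment(fit_sum, ft),
                 m_ks = m_ks(ft, fit_sum))
    }))
    rownames(comparisons) <- NULL
  }
  bundle <- structure(list(counts = do.call(rbind, counts),
                           fits = fits, comparisons = comparisons,
                           dose_fractions = dfrac, config = config),
                      class = "result_bundle")
  if (!is.null(config$out_dir)) .write_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle>\n")
  src <- x$config$source
  if (inherits(src, "beam_spec"))
    cat(sprintf("  beam: %s %g MeV/n (LET %g keV/um)\n",
                src$ion, src$energy, src$LET))
  else
    cat(sprintf("  spectrum: %d components\n", nrow(src)))
  cat(sprintf("  doses: %s Gy, %d histories each\n",
              paste(x$config$doses, collapse = ", "),
              x$config$histories))
  for (ctr in names(x$fits)) {
    for (ep in names(x$fits[[ctr]])) {
      f <- x$fits[[ctr]][[ep]]
      cat(sprintf("  %s/%s: mu_alpha=%.4g mu_beta=%.4g R2=%.3f\n",
                  ctr, ep, f$coef[1], f$coef[2], f$r_squared))
    }
  }
  invisible(x)
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(bundle$counts, file.path(out_dir, "exchange_counts.csv"),
            row.names = FALSE)
  fitrows <- do.call(rbind, lapply(names(bundle$fits), function(ctr) {
    do.call(rbind, lapply(names(bundle$fits[[ctr]]), function(ep) {
      f <- bundle$fits[[ctr]][[ep]]
      data.frame(contribution = ctr, endpoint = ep,
                 mu_alpha = f$coef[1], sigma_alpha = f$sigma[1],
                 mu_beta = f$coef[2], sigma_beta = f$sigma[2],
                 R2 = f$r_squared, row.names = NULL)
    }))
  }))
  write.csv(fitrows, file.path(out_dir, "lq_fits.csv"), row.names = FALSE)
  if (!is.null(bundle$comparisons))
    write.csv(bundle$comparisons, file.path(out_dir, "comparisons.csv"),
              row.names = FALSE)
  cfg <- bundle$config
  meta <- list(seed = cfg$seed, doses = cfg$doses,
               histories = cfg$histories,
               contributions = cfg$contributions,
               track_params = unclass(cfg$track_params),
               break_params = unclass(cfg$break_params),
               repair_params = unclass(cfg$rep_params),
               geometry = unclass(cfg$geometry))
  jsonlite::write_json(meta, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Compare two result bundles
#'
#' Computes the containment and KS criteria between the total-contribution
#' dose responses of two bundles, per endpoint; the standard use is
#' mono-energetic beam vs the matching poly-energetic (tissue-transported)
#' spectrum.
#'
#' @param bundle_a,bundle_b `result_bundle` objects sharing dose points.
#' @return data.frame with one row per endpoint: `m_a_to_b`, `m_b_to_a`,
#'   `m_ks`.
#' @export
compare_runs <- function(bundle_a, bundle_b) {
  stopifnot(inherits(bundle_a, "result_bundle"),
            inherits(bundle_b, "result_bundle"))
  if (!isTRUE(all.equal(bundle_a$config$doses, bundle_b$config$doses)))
    stop("bundles must share dose points")
  ctr <- "tot"
  if (!ctr %in% names(bundle_a$fits) || !ctr %in% names(bundle_b$fits))
    stop("both bundles need a total-contribution fit")
  out <- do.call(rbind, lapply(c("simple", "complex"), function(ep) {
    fa <- bundle_a$fits[[ctr]][[ep]]
    fb <- bundle_b$fits[[ctr]][[ep]]
    if (is.null(fa) || is.null(fb))
      stop("missing endpoint fit: ", ep)
    data.frame(endpoint = ep,
               m_a_to_b = m_containment(fa, fb),
               m_b_to_a = m_containment(fb, fa),
               m_ks = m_ks(fa, fb))
  }))
  rownames(out) <- NULL
  out
}
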