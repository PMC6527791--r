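#' Study plan: a ladder of configurations varying one axis
#'
#' The three study kinds mirror the solution-strategy protocol: a spatial
#' refinement ladder (varying `dx`), a temporal refinement ladder (varying
#' `dt`), and an LES comparison (a fine no-closure reference plus coarser
#' runs with each closure, all at the same `dt` for a fair comparison).
#' Exactly one axis varies; geometry, inlet, stations and seed policy are
#' shared.
#'
#' @param kind `"spatial_refinement"`, `"temporal_refinement"` or
#'   `"les_comparison"`.
#' @param configs named list of [simulation_config()]s.
#' @return Object of class `study_plan`.
#' @export
study_plan <- function(kind = c("spatial_refinement", "temporal_refinement",
                                "les_comparison"),
                       configs) {
  kind <- match.arg(kind)
  stopifnot(length(configs) >= 1,
            all(vapply(configs, inherits, logical(1), "simulation_config")))
  if (is.null(names(configs)) || any(names(configs) == ""))
    stop("study_plan: configs must be named", call. = FALSE)
  geom <- lapply(configs, function(cf)
    unclass(cf$geometry))
  if (length(unique(lapply(geom, identity))) > 1 &&
      !all(vapply(geom[-1], identical, logical(1), geom[[1]])))
    stop("study_plan: all configs must share one geometry", call. = FALSE)
  structure(list(kind = kind, configs = configs), class = "study_plan")
}

#' Execute a study plan
#'
#' Runs every configuration, applies the post-washout analytics (station
#' tke profiles, probe PSD), and assembles a cross-config report. A failed
#' run marks its column incomplete instead of aborting the study.
#'
#' @param plan a [study_plan()].
#' @param method fluctuation extraction for the tke profiles
#'   (`"reynolds"` or `"highpass"`).
#' @param reference name of the config whose profiles the discrepancy
#'   metric is computed against (default: the first config); ignored unless
#'   there are >= 2 configs.
#' @param verbose print per-config progress.
#' @return Object of class `study_report`: per-config `summaries` (station
#'   tke, probe PSD, mean nu_sgs, manifest), `discrepancy` (per config and
#'   station, relative L2 vs the reference), and `provenance`.
#' @export
run_study <- function(plan, method = c("reynolds", "highpass"),
                      reference = names(plan$configs)[1], verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(plan, "study_plan"))
  results <- list(); summaries <- list()
  for (nm in names(plan$configs)) {
    if (verbose) message("run_study: config '", nm, "'")
    res <- run_simulation(plan$configs[[nm]], verbose = verbose)
    results[[nm]] <- res
    ok <- res$manifest$completed
    summaries[[nm]] <- list(
      complete = ok,
      manifest = res$manifest,
      station_tke = if (ok) station_tke(res, method = method),
      psd = if (ok) tryCatch({
        dec <- if (method == "reynolds") reynolds_decompose(res$probe)
               else highpass_modes(res$probe)
        welch_psd(sqrt(rowSums(dec$fluct^2)), dt = res$dt)
      }, error = function(e) NULL),
      mean_nu_sgs = if (!is.null(res$nu_sgs_mean))
        mean(res$nu_sgs_mean[!res$grid$mask]) else 0)
  }
  discrepancy <- NULL
  if (length(summaries) >= 2 && reference %in% names(summaries) &&
      isTRUE(summaries[[reference]]$complete)) {
    others <- setdiff(names(summaries), reference)
    discrepancy <- lapply(others, function(nm) {
      if (!isTRUE(summaries[[nm]]$complete)) return(NULL)
      tke_discrepancy(summaries[[reference]]$station_tke,
                      summaries[[nm]]$station_tke)
    })
    names(discrepancy) <- others
  }
  structure(list(kind = plan$kind, summaries = summaries,
                 discrepancy = discrepancy, results = results,
                 reference = reference,
                 provenance = lapply(summaries, function(s)
                   s$manifest[c("config_hash", "seed")])),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", x$kind, "with", length(x$summaries), "configs:",
      paste(names(x$summaries), collapse = ", "), "\n")
  if (!is.null(x$discrepancy)) {
    cat("station-mean tke discrepancy vs '", x$reference, "':\n", sep = "")
    for (nm in names(x$discrepancy))
      if (!is.null(x$discrepancy[[nm]]))
        cat(sprintf("  %-20s %s\n", nm,
                    paste(sprintf("%.3f", x$discrepancy[[nm]]),
                          collapse = "  ")))
  }
  invisible(x)
}

#' Station-resolved tke discrepancy between two runs
#'
#' Relative L2 difference of the station tke profiles of a model run
#' against a reference run, per station: `||tke_m - tke_r|| / ||tke_r||`
#' over the fluid points of the reference line (the model profile is
#' linearly interpolated onto the reference cross-channel coordinates, so
#' runs on different grids are comparable).
#'
#' @param reference_tke,model_tke outputs of [station_tke()] with matched
#'   station offsets.
#' @return Named numeric vector, one relative discrepancy per station.
#' @export
tke_discrepancy <- function(reference_tke, model_tke) {
  ro <- vapply(reference_tke, `[[`, numeric(1), "offset")
  mo <- vapply(model_tke, `[[`, numeric(1), "offset")
  if (length(ro) != length(mo) || max(abs(ro - mo)) > 1e-9)
    stop("tke_discrepancy: station offsets do not match", call. = FALSE)
  out <- vapply(seq_along(reference_tke), function(s) {
    rs <- reference_tke[[s]]; ms <- model_tke[[s]]
    okr <- !is.na(rs$tke)
    okm <- !is.na(ms$tke)
    mi <- stats::approx(ms$y[okm], ms$tke[okm], xout = rs$y[okr],
                        rule = 2)$y
    rr <- rs$tke[okr]
    denom <- sqrt(sum(rr^2))
    if (denom == 0) return(if (all(mi == 0)) 0 else Inf)
    sqrt(sum((mi - rr)^2)) / denom
  }, numeric(1))
  names(out) <- names(reference_tke)
  out
}
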