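#' Calibration configuration
#'
#' @param calibration_time_years absolute divergence time anchoring the
#'   calibrated pair (final closure of the Central American Seaway: 3e6 or
#'   1e7 years).
#' @param generation_time_years generation time (annual generations: 1).
#' @param calibrated_pair label of the species pair whose tau anchors mu
#'   (the default `"EC"` pair has the best-sequenced individuals).
#' @param mu_mit optional mitochondrial rate (substitutions/site/year) for
#'   the mito/nuclear ratio.
#' @return object of class `calibration_config`.
#' @export
calibration_config <- function(calibration_time_years = 3e6,
                               generation_time_years = 1,
                               calibrated_pair = "EC", mu_mit = NULL) {
  stopifnot(calibration_time_years > 0, generation_time_years > 0)
  structure(list(calibration_time_years = calibration_time_years,
                 generation_time_years = generation_time_years,
                 calibrated_pair = calibrated_pair, mu_mit = mu_mit),
            class = "calibration_config")
}

#' Combine replicate posterior traces
#'
#' Concatenates the (post-burn-in) samples of replicate chains and reports
#' per-parameter means with equal-tailed 95% credible intervals.
#'
#' @param traces list of `posterior_trace` objects sharing columns.
#' @return data frame: `parameter`, `mean`, `lo` (2.5%), `hi` (97.5%).
#' @export
summarize_replicates <- function(traces) {
  if (inherits(traces, "posterior_trace")) traces <- list(traces)
  cols <- colnames(traces[[1]]$trace)
  for (tr in traces)
    if (!identical(colnames(tr$trace), cols))
      stop("replicate traces have mismatched columns")
  pooled <- do.call(rbind, lapply(traces, function(tr) tr$trace))
  data.frame(parameter = cols,
             mean = colMeans(pooled),
             lo = apply(pooled, 2, stats::quantile, 0.025, names = FALSE),
             hi = apply(pooled, 2, stats::quantile, 0.975, names = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Calibrate the substitution rate from a scaled divergence time
#'
#' \eqn{\mu = \tau / T} with `T` the absolute calibration time in years;
#' credible-interval endpoints are transformed through the same map.
#'
#' @param tau mutation-scaled divergence time (may be a vector, e.g.
#'   `c(point, lo, hi)`).
#' @param cfg a [calibration_config()].
#' @return substitutions/site/year, same shape as `tau`.
#' @export
calibrate_mu <- function(tau, cfg = calibration_config()) {
  if (any(tau <= 0)) stop("tau must be positive")
  tau / cfg$calibration_time_years
}

#' Absolute divergence time from a scaled time and a rate
#'
#' @param tau mutation-scaled divergence time.
#' @param mu substitutions/site/year.
#' @return `T = tau / mu` in years.
#' @export
absolute_time <- function(tau, mu) {
  if (any(mu <= 0)) stop("mu must be positive")
  tau / mu
}

#' Effective population size from a mutation-scaled theta
#'
#' \eqn{N_e = \Theta / (4 \mu g)} with `g` the generation time in years.
#'
#' @param theta mutation-scaled population size.
#' @param mu substitutions/site/year.
#' @param cfg a [calibration_config()] (generation time).
#' @return number of individuals.
#' @export
effective_size <- function(theta, mu, cfg = calibration_config()) {
  stopifnot(mu > 0)
  theta / (4 * mu * cfg$generation_time_years)
}

#' Effective number of migrants per generation
#'
#' For a band A -> B this is \eqn{M_{A \to B} \Theta_B}.
#'
#' @param M mutation-scaled migration rate.
#' @param theta_target theta of the receiving population.
#' @return migrants per generation.
#' @export
migrants_per_generation <- function(M, theta_target) {
  stopifnot(all(M >= 0), all(theta_target >= 0))
  M * theta_target
}

#' Migration-band significance rule
#'
#' A band carries significant gene flow iff, in EVERY replicate run, the
#' equal-tailed 95% credible interval of its migration rate excludes 1e-5
#' (two-sided exclusion, judged per replicate, not on the pooled trace).
#'
#' @param traces list of `posterior_trace` objects (the replicates).
#' @param band column name of the band (`m_<src>_<tgt>`).
#' @param threshold excluded value (default 1e-5).
#' @return logical.
#' @export
migration_significant <- function(traces, band, threshold = 1e-5) {
  if (inherits(traces, "posterior_trace")) traces <- list(traces)
  for (tr in traces) {
    if (!band %in% colnames(tr$trace))
      stop("band column not in trace: ", band)
    ci <- stats::quantile(tr$trace[, band], c(0.025, 0.975), names = FALSE)
    if (ci[1] <= threshold && threshold <= ci[2]) return(FALSE)
  }
  TRUE
}

#' Mitochondrial / nuclear substitution-rate ratio
#'
#' @param mu_mit,mu_nuc per-site rates per year (both positive).
#' @return the ratio.
#' @export
mito_nuclear_ratio <- function(mu_mit, mu_nuc) {
  stopifnot(mu_mit > 0, mu_nuc > 0)
  mu_mit / mu_nuc
}

#' Absolute-scale estimates for species pairs
#'
#' Converts mutation-scaled posterior summaries into the calibrated table:
#' per pair, mu at the calibration point (anchored on the calibrated
#' pair's tau), absolute divergence time `T` and ancestral `Ne` (both
#' computed with the calibrated mu), with credible intervals transformed
#' endpoint-wise.
#'
#' @param summary data frame from [summarize_replicates()].
#' @param pairs named character vector mapping pair label -> internal
#'   population label (e.g. `c(WM = "WM", EC = "EC", PF = "PF")`).
#' @param cfg a [calibration_config()].
#' @return data frame of class `calibrated_estimates`, one row per pair:
#'   theta/tau (scaled, with CIs), mu (per year), T (years), Ne
#'   (individuals).
#' @export
calibrated_estimates <- function(summary, pairs, cfg = calibration_config()) {
  row_of <- function(p) {
    i <- match(p, summary$parameter)
    if (is.na(i)) stop("parameter missing from summary: ", p)
    unlist(summary[i, c("mean", "lo", "hi")])
  }
  anchor <- row_of(paste0("tau_", pairs[[cfg$calibrated_pair]]))
  mu_cal <- calibrate_mu(anchor, cfg)           # c(point, lo, hi)
  out <- lapply(names(pairs), function(pl) {
    tau <- row_of(paste0("tau_", pairs[[pl]]))
    th <- row_of(paste0("theta_", pairs[[pl]]))
    mu <- calibrate_mu(tau, cfg)
    Tt <- absolute_time(tau, mu_cal[1])
    Ne <- effective_size(th, mu_cal[1], cfg)
    data.frame(pair = pl,
               theta = th[1], theta_lo = th[2], theta_hi = th[3],
               tau = tau[1], tau_lo = tau[2], tau_hi = tau[3],
               mu = mu[1], mu_lo = mu[2], mu_hi = mu[3],
               T_years = Tt[1], T_lo = Tt[2], T_hi = Tt[3],
               Ne = Ne[1], Ne_lo = Ne[2], Ne_hi = Ne[3],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "mu_calibrated") <- mu_cal
  attr(res, "config") <- cfg
  class(res) <- c("calibrated_estimates", "data.frame")
  res
}
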