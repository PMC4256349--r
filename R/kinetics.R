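# Steady-state and pre-steady-state kinetic fitting: coupled-assay
# slope-to-rate conversion, Michaelis-Menten nonlinear least squares with
# catalytic-efficiency error propagation, and single-exponential
# stopped-flow fits.

#' Coupled-assay configuration
#'
#' Converts photometric slopes to chemical rates. Defaults correspond to a
#' coupled dehydrogenase assay read at 340 nm (NAD+ reduction,
#' delta-epsilon 6220 M^-1 cm^-1) in a 1-cm cuvette.
#'
#' @param epsilon molar absorptivity, M^-1 cm^-1
#' @param path cuvette path length, cm
#' @param enzyme_conc catalytic-site concentration, M (e.g. `100e-9` for
#'   100 nM holoenzyme)
#' @return an object of class `assay_config`
#' @export
assay_config <- function(epsilon = 6220, path = 1, enzyme_conc = 100e-9) {
  if (epsilon <= 0 || path <= 0 || enzyme_conc <= 0)
    stop("epsilon, path and enzyme_conc must all be > 0", call. = FALSE)
  structure(list(epsilon = epsilon, path = path, enzyme_conc = enzyme_conc),
            class = "assay_config")
}

#' Convert an absorbance slope to a reaction rate
#'
#' Beer--Lambert inversion `rate = (dA/dt) / (epsilon * path)` plus the
#' per-enzyme turnover `rate / enzyme_conc`. Negative slopes pass through
#' with their sign and are flagged.
#'
#' @param dA_dt absorbance slope, s^-1 (vectorised)
#' @param config an [assay_config()]
#' @return data.frame with columns `rate_M_s` (M s^-1), `rate_per_enzyme`
#'   (s^-1) and `negative` (logical flag)
#' @export
rate_from_slope <- function(dA_dt, config = assay_config()) {
  stopifnot(inherits(config, "assay_config"))
  rate <- dA_dt / (config$epsilon * config$path)
  data.frame(rate_M_s = rate,
             rate_per_enzyme = rate / config$enzyme_conc,
             negative = dA_dt < 0)
}

#' Assemble a Michaelis--Menten dataset
#'
#' Rates tagged `"per_enzyme"` are used as-is (s^-1); absolute rates
#' (`"M_s"`) are divided by the configured enzyme concentration on
#' ingest, so fitting always happens in turnover units.
#'
#' @param s substrate concentrations, uM (>= 0)
#' @param v observed rates (same length as `s`)
#' @param unit `"per_enzyme"` (s^-1) or `"M_s"` (M s^-1)
#' @param config an [assay_config()]; required for `"M_s"` rates
#' @return an object of class `mm_dataset`
#' @export
mm_dataset <- function(s, v, unit = c("per_enzyme", "M_s"),
                       config = assay_config()) {
  unit <- match.arg(unit)
  if (length(s) != length(v)) stop("s and v must have equal length",
                                   call. = FALSE)
  if (any(s < 0)) stop("substrate concentrations must be >= 0",
                       call. = FALSE)
  if (length(unique(s)) < 4)
    stop("need at least 4 distinct substrate concentrations", call. = FALSE)
  if (unit == "M_s") v <- v / config$enzyme_conc
  structure(list(s = as.numeric(s), v = as.numeric(v), config = config),
            class = "mm_dataset")
}

#' Fit the Michaelis--Menten model
#'
#' Levenberg--Marquardt least squares of `v = kcat * s / (Km + s)` in
#' per-enzyme units. Starting values are deterministic: `kcat0 = max(v)`
#' and `Km0` the substrate concentration at half-maximal rate by linear
#' interpolation, so identical data give bit-identical fits. Standard
#' errors come from the parameter covariance at the optimum; the
#' catalytic efficiency and its first-order propagated error (including
#' the kcat--Km covariance term) are attached via
#' [efficiency_with_error()].
#'
#' @param data an [mm_dataset()]
#' @return an object of class `mm_fit`: list with `kcat`, `kcat_se`,
#'   `Km_uM`, `Km_se`, `covariance` (2x2), `efficiency` (M^-1 s^-1, with
#'   `efficiency_se` and the conventional `efficiency_1e3` scale),
#'   `residuals`, and the underlying `nls` object
#' @export
fit_mm <- function(data) {
  stopifnot(inherits(data, "mm_dataset"))
  s <- data$s; v <- data$v
  if (all(abs(v) < .Machine$double.eps) || max(v) <= 0)
    stop("rates are identically zero or non-positive; nothing to fit",
         call. = FALSE)
  kcat0 <- max(v)
  half <- kcat0 / 2
  o <- order(s)
  Km0 <- tryCatch(stats::approx(v[o], s[o], xout = half, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(Km0) || Km0 <= 0) Km0 <- stats::median(s[s > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ kcat * s / (Km + s),
                      data = data.frame(s = s, v = v),
                      start = list(kcat = kcat0, Km = Km0),
                      lower = c(kcat = 0, Km = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit failed: ",
                             conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  if (any(est <= 0))
    stop("Michaelis-Menten fit pinned at a parameter boundary (kcat = ",
         signif(est[1], 3), ", Km = ", signif(est[2], 3), ")",
         call. = FALSE)
  vc <- stats::vcov(fit)
  out <- structure(list(
    kcat = unname(est["kcat"]), kcat_se = sqrt(vc["kcat", "kcat"]),
    Km_uM = unname(est["Km"]), Km_se = sqrt(vc["Km", "Km"]),
    covariance = vc,
    residuals = summary(stats::resid(fit)),
    fit = fit
  ), class = "mm_fit")
  eff <- efficiency_with_error(out)
  out$efficiency <- eff$value
  out$efficiency_se <- eff$se
  out$efficiency_1e3 <- eff$value_1e3
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> kcat = %.3g +/- %.2g s^-1, Km = %.3g +/- %.2g uM\n",
              x$kcat, x$kcat_se, x$Km_uM, x$Km_se))
  cat(sprintf("  kcat/Km = %.3g +/- %.2g M^-1 s^-1 (%.3g x10^3)\n",
              x$efficiency, x$efficiency_se, x$efficiency_1e3))
  invisible(x)
}

#' Catalytic efficiency with propagated error
#'
#' `kcat / Km` with Km converted from uM to M, and its first-order error
#' \deqn{\sigma_E = E \sqrt{(\sigma_k/k)^2 + (\sigma_K/K)^2
#'       - 2\,\mathrm{cov}(k, K)/(kK)},}
#' including the parameter covariance when a full [fit_mm()] object is
#' supplied. `value_1e3` reports the conventional x10^3 M^-1 s^-1 scale to
#' three significant figures.
#'
#' @param fit an `mm_fit`, or a list/vector with elements `kcat`,
#'   `kcat_se`, `Km_uM`, `Km_se` (and optionally `cov_kcat_Km`)
#' @return list with `value`, `se` (M^-1 s^-1) and `value_1e3`
#' @examples
#' efficiency_with_error(list(kcat = 2.97, kcat_se = 0.01,
#'                            Km_uM = 189, Km_se = 14))$value_1e3  # 15.7
#' @export
efficiency_with_error <- function(fit) {
  kcat <- fit$kcat; Km <- fit$Km_uM
  kse <- fit$kcat_se %||% 0
  Kse <- fit$Km_se %||% 0
  cv <- if (!is.null(fit$covariance)) fit$covariance["kcat", "Km"]
        else fit$cov_kcat_Km %||% 0
  if (kcat <= 0 || Km <= 0) stop("kcat and Km must be > 0", call. = FALSE)
  value <- kcat / (Km * 1e-6)
  rel2 <- (kse / kcat)^2 + (Kse / Km)^2 - 2 * cv / (kcat * Km)
  se <- value * sqrt(max(rel2, 0))
  list(value = value, se = se, value_1e3 = signif(value / 1e3, 3))
}

#' Fit a single-exponential absorbance transient
#'
#' Levenberg--Marquardt least squares of
#' `A(t) = a0 + amplitude * exp(-kobs * t)`, as used to extract observed
#' rate constants from stopped-flow transients. A configurable dead-time
#' prefix is discarded first (stopped-flow mixing artefacts; default
#' 1 ms). Starting values are deterministic: `a0` from the tail mean,
#' `amplitude` from the first retained point, and `kobs` from a
#' log-linear regression on the baseline-subtracted decay. Fits implying
#' less than one half-life inside the observation window are flagged
#' low-confidence.
#'
#' @param time time axis, s (strictly increasing, >= 5 points after
#'   dead-time removal)
#' @param A absorbance values, same length
#' @param dead_time prefix to discard, s (default 1e-3)
#' @return an object of class `exp_fit`: list with `a0`, `amplitude`,
#'   `kobs`, `kobs_se`, `low_confidence`, `residuals` and the underlying
#'   `nls` object
#' @export
fit_exponential <- function(time, A, dead_time = 1e-3) {
  if (length(time) != length(A)) stop("time and A must have equal length",
                                      call. = FALSE)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing",
                                 call. = FALSE)
  keep <- time >= time[1] + dead_time
  time <- time[keep]; A <- A[keep]
  if (length(time) < 5)
    stop("need at least 5 points after dead-time removal", call. = FALSE)
  if (stats::sd(A) < .Machine$double.eps * max(1, abs(mean(A))) * 10)
    stop("trace is constant; no transient to fit", call. = FALSE)
  ntail <- max(5L, length(A) %/% 10L)
  a0_0 <- mean(utils::tail(A, ntail))
  amp0 <- A[1] - a0_0
  if (abs(amp0) < .Machine$double.eps)
    stop("no resolvable amplitude relative to the baseline", call. = FALSE)
  d <- (A - a0_0) / amp0
  # log-linear rate guess from the contiguous early decay, up to where
  # the signal first falls below 5% of the amplitude; later points are
  # baseline noise and would corrupt the log
  below <- which(d <= 0.05)
  pos <- seq_len(if (length(below)) max(below[1] - 1L, 0L) else length(d))
  pos <- pos[d[pos] > 0]
  k0 <- if (length(pos) >= 3) {
    sl <- unname(stats::lm.fit(cbind(1, time[pos]),
                               log(d[pos]))$coefficients[2])
    if (is.finite(sl) && sl < 0) -sl else 1 / diff(range(time))
  } else 1 / diff(range(time))
  fit <- tryCatch(
    minpack.lm::nlsLM(A ~ a0 + amplitude * exp(-kobs * time),
                      data = data.frame(time = time, A = A),
                      start = list(a0 = a0_0, amplitude = amp0, kobs = k0),
                      lower = c(a0 = -Inf, amplitude = -Inf, kobs = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit failed: ",
                             conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  if (!is.finite(est["kobs"]) || est["kobs"] <= 0)
    stop("exponential fit returned a non-positive rate", call. = FALSE)
  vc <- stats::vcov(fit)
  window <- diff(range(time))
  structure(list(
    a0 = unname(est["a0"]), amplitude = unname(est["amplitude"]),
    kobs = unname(est["kobs"]), kobs_se = sqrt(vc["kobs", "kobs"]),
    low_confidence = unname(est["kobs"]) * window < log(2),
    residuals = summary(stats::resid(fit)),
    fit = fit
  ), class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> kobs = %.4g +/- %.2g s^-1, amplitude = %.3g, a0 = %.3g%s\n",
              x$kobs, x$kobs_se, x$amplitude, x$a0,
              if (x$low_confidence) "  [low confidence: < 1 half-life observed]"
              else ""))
  invisible(x)
}

#' Average replicate traces on a common time grid
#'
#' Pointwise mean of equal-grid series, the standard noise-reduction step
#' before fitting stopped-flow transients (white-noise SD shrinks by
#' about `1/sqrt(n)`).
#'
#' @param traces list of data.frames, each with columns `time` and `A`
#'   on identical time grids
#' @return data.frame with columns `time` and `A`
#' @export
average_traces <- function(traces) {
  if (!length(traces)) stop("no traces supplied", call. = FALSE)
  t0 <- traces[[1]]$time
  for (tr in traces) {
    if (length(tr$time) != length(t0) || any(tr$time != t0))
      stop("all traces must share an identical time grid", call. = FALSE)
  }
  data.frame(time = t0,
             A = rowMeans(sapply(traces, function(tr) tr$A)))
}
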