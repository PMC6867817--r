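#' Canonical response kernels
#'
#' Fixed-shape response basis functions used both by the forward simulator and
#' by the fitters: a response is modeled as amplitude x kernel, so estimation
#' reduces to (possibly latency-shifted) regression. Four families are
#' provided:
#'
#' * `"sebr"` — startle eye-blink EMG envelope: gamma density, default mode
#'   40 ms, support ~200 ms.
#' * `"scrf"` — skin conductance response function: bi-exponential
#'   (Bateman-type), default rise 0.75 s, decay 3 s.
#' * `"psrf"` — pupil size response function: gamma density peaking ~2 s.
#' * `"hprf"` — heart period response function: difference of gammas spanning
#'   ~10 s with peak ~4 s (positive amplitude = heart-period lengthening,
#'   i.e. bradycardia).
#'
#' All kernels are peak-normalized to 1 so fitted coefficients are amplitudes
#' in channel units. Parameters are exposed so simulations can deliberately
#' mis-specify the kernel (shifted peak, different dispersion) in robustness
#' tests.
#'
#' @param type Kernel family.
#' @param rate Sampling rate in Hz.
#' @param peak_s Peak (mode) latency in seconds; family default if `NULL`.
#' @param shape Gamma shape (gamma-family kernels); controls dispersion.
#' @param rise_s,decay_s Time constants of the bi-exponential SCRF.
#' @param duration_s Support length in seconds; family default if `NULL`.
#'
#' @return A `canonical_kernel`: list with elements `type`, `rate`, `y`
#'   (sampled, peak-normalized waveform), `t` (sample times) and `params`.
#' @examples
#' k <- canonical_kernel("scrf", rate = 10)
#' max(k$y) # 1
#' @export
canonical_kernel <- function(type = c("sebr", "scrf", "psrf", "hprf"),
                             rate,
                             peak_s = NULL, shape = NULL,
                             rise_s = 0.75, decay_s = 3,
                             duration_s = NULL) {
  type <- match.arg(type)
  defaults <- switch(type,
    sebr = list(peak_s = 0.040, shape = 3, duration_s = 0.25),
    scrf = list(peak_s = NA, shape = NA, duration_s = 30),
    psrf = list(peak_s = 2.0, shape = 4, duration_s = 15),
    hprf = list(peak_s = 4.0, shape = 5, duration_s = 25)
  )
  peak_s <- peak_s %||% defaults$peak_s
  shape <- shape %||% defaults$shape
  duration_s <- duration_s %||% defaults$duration_s
  t <- seq(0, duration_s, by = 1 / rate)
  y <- switch(type,
    sebr = ,
    psrf = stats::dgamma(t, shape = shape, rate = (shape - 1) / peak_s),
    scrf = exp(-t / decay_s) - exp(-t / rise_s),
    hprf = {
      g1 <- stats::dgamma(t, shape = shape, rate = (shape - 1) / peak_s)
      # late negative lobe: slower gamma peaking past the positive peak
      g2 <- stats::dgamma(t, shape = 2 * shape, rate = (2 * shape - 1) / (2 * peak_s))
      g1 / max(g1) - 0.4 * g2 / max(g2)
    }
  )
  y <- y / max(y)
  structure(
    list(type = type, rate = rate, t = t, y = y,
         params = list(peak_s = peak_s, shape = shape,
                       rise_s = rise_s, decay_s = decay_s,
                       duration_s = duration_s)),
    class = "canonical_kernel"
  )
}

#' @export
print.canonical_kernel <- function(x, ...) {
  cat(sprintf("<canonical_kernel> %s @ %g Hz, %d samples, peak at %.3g s\n",
              x$type, x$rate, length(x$y), x$t[which.max(x$y)]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian bump of fixed SD centred at `center_s`, area 1 (a fixed-dispersion
# input function; convolved with the SCRF it yields the anticipatory response).
gaussian_bump <- function(center_s, sd_s, rate, duration_s) {
  t <- seq(0, duration_s, by = 1 / rate)
  y <- stats::dnorm(t, mean = center_s, sd = sd_s)
  y / sum(y) * rate  # unit area in continuous time
}

# Place `wave` into a zero vector of length n starting at sample index
# `at` (1-based), truncating at the end; additive.
add_wave_at <- function(x, wave, at) {
  if (at > length(x)) return(x)
  if (at < 1) {
    wave <- wave[(2 - at):length(wave)]
    at <- 1
  }
  idx <- at:min(length(x), at + length(wave) - 1)
  x[idx] <- x[idx] + wave[seq_along(idx)]
  x
}
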