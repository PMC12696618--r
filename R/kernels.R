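#' Parameters of one biphasic VEP component kernel
#'
#' A component is modelled as a negative Gaussian lobe (the trough that
#' defines component latency) optionally followed by a positive Gaussian
#' lobe (the re-polarising positivity). Latencies are milliseconds after the
#' onset of the driving stimulus; amplitudes are microvolts; widths are the
#' Gaussian sigma in milliseconds. Lobes are truncated at 4 sigma so every
#' kernel has finite support.
#'
#' @param neg_latency_ms Latency of the negative trough, ms.
#' @param neg_amplitude_uv Depth of the negative lobe, uV (>= 0).
#' @param neg_width_ms Sigma of the negative lobe, ms (> 0).
#' @param pos_latency_ms Latency of the positive lobe, ms; must exceed
#'   `neg_latency_ms` when `pos_amplitude_uv > 0`.
#' @param pos_amplitude_uv Height of the positive lobe, uV (>= 0, default 0).
#' @param pos_width_ms Sigma of the positive lobe, ms (> 0 when used).
#'
#' @return A `kernel_params` list.
#' @export
component_kernel_params <- function(neg_latency_ms, neg_amplitude_uv,
                                    neg_width_ms,
                                    pos_latency_ms = NA_real_,
                                    pos_amplitude_uv = 0,
                                    pos_width_ms = NA_real_) {
  assert_scalar_number(neg_latency_ms, "neg_latency_ms")
  assert_scalar_number(neg_amplitude_uv, "neg_amplitude_uv")
  assert_scalar_number(neg_width_ms, "neg_width_ms", positive = TRUE)
  if (neg_amplitude_uv < 0) stop_veptime("neg_amplitude_uv must be >= 0")
  if (pos_amplitude_uv < 0) stop_veptime("pos_amplitude_uv must be >= 0")
  if (pos_amplitude_uv > 0) {
    assert_scalar_number(pos_latency_ms, "pos_latency_ms")
    assert_scalar_number(pos_width_ms, "pos_width_ms", positive = TRUE)
    if (pos_latency_ms <= neg_latency_ms)
      stop_veptime("pos_latency_ms must exceed neg_latency_ms")
  }
  structure(
    list(
      neg_latency_ms = neg_latency_ms,
      neg_amplitude_uv = neg_amplitude_uv,
      neg_width_ms = neg_width_ms,
      pos_latency_ms = pos_latency_ms,
      pos_amplitude_uv = pos_amplitude_uv,
      pos_width_ms = pos_width_ms
    ),
    class = "kernel_params"
  )
}

# unit-peak Gaussian bump truncated at 4 sigma
gauss_bump <- function(t, mu, sigma) {
  g <- exp(-(t - mu)^2 / (2 * sigma^2))
  g[abs(t - mu) > 4 * sigma] <- 0
  g
}

#' Evaluate a component kernel on a time grid
#'
#' @param params A [component_kernel_params()] object.
#' @param t_ms Numeric vector of times (ms after driving-stimulus onset).
#' @return Voltage in uV at each time:
#'   `-neg_amplitude * G(t; neg_latency, neg_width) +
#'    pos_amplitude * G(t; pos_latency, pos_width)`
#'   with `G` a unit-peak Gaussian truncated at 4 sigma.
#' @examples
#' kp <- component_kernel_params(60, 30, 10)
#' min(component_kernel(kp, 0:200)) # -30 at t = 60
#' @export
component_kernel <- function(params, t_ms) {
  stopifnot(inherits(params, "kernel_params"))
  v <- -params$neg_amplitude_uv *
    gauss_bump(t_ms, params$neg_latency_ms, params$neg_width_ms)
  if (params$pos_amplitude_uv > 0) {
    v <- v + params$pos_amplitude_uv *
      gauss_bump(t_ms, params$pos_latency_ms, params$pos_width_ms)
  }
  v
}

# time (ms after stimulus onset) beyond which a kernel is identically zero
kernel_support_end <- function(params) {
  end <- params$neg_latency_ms + 4 * params$neg_width_ms
  if (params$pos_amplitude_uv > 0)
    end <- max(end, params$pos_latency_ms + 4 * params$pos_width_ms)
  end
}
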