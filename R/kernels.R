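# Ground-truth evoked-response kernels for the forward simulator.

#' Construct an evoked-response kernel
#'
#' Builds a sampled single-component response shape supported on
#' `[0, 0.75]` s with unit peak magnitude. `"gamma"` gives a single
#' sign-consistent lobe peaking at `latency` and decaying to (numerically)
#' zero by `latency + width`; `"windowed_sine"` gives a biphasic Hann-windowed
#' full sine cycle over `[latency, latency + width]`. A width below two sample
#' periods degenerates to a unit impulse at `latency`.
#'
#' @param shape `"gamma"` or `"windowed_sine"`.
#' @param latency Seconds; peak position (gamma) or support start
#'   (windowed_sine). Must satisfy `latency >= 0`.
#' @param width Seconds; `latency + width` must not exceed 0.75 s.
#' @param polarity +1 or -1; multiplies the kernel.
#' @param samplingRate Hz.
#' @return An [ErpKernel-class].
#' @examples
#' k <- makeErpKernel("gamma", latency = 0.1, width = 0.3, samplingRate = 128)
#' @export
makeErpKernel <- function(shape = c("gamma", "windowed_sine"), latency = 0.1,
                          width = 0.3, polarity = 1, samplingRate = 128) {
  shape <- match.arg(shape)
  if (latency < 0) stop("latency must be >= 0")
  if (latency + width > 0.75 + 1e-9)
    stop("kernel support [0, latency + width] must lie within [0, 0.75] s")
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  fs <- samplingRate
  nK <- round(0.75 * fs)
  t <- (seq_len(nK) - 1L) / fs
  if (width <= 2 / fs) {
    k <- numeric(nK)
    k[timeToSample(latency, fs) + 1L] <- 1
    shape <- "impulse"
  } else if (shape == "gamma") {
    if (latency <= 0) stop("gamma kernel needs latency > 0 (peak position)")
    # shape parameter chosen so the lobe has decayed to 1% at latency + width
    a <- log(0.01) / (log(1 + width / latency) - width / latency)
    k <- (t / latency)^a * exp(a * (1 - t / latency))
    k[t > latency + width] <- 0
  } else {
    u <- (t - latency) / width
    k <- sin(2 * pi * u) * 0.5 * (1 - cos(2 * pi * u))
    k[u < 0 | u > 1] <- 0
    k <- k / max(abs(k))
  }
  new("ErpKernel", samples = polarity * k / max(abs(k)), samplingRate = fs,
      shape = shape, latency = latency, width = width, polarity = polarity)
}

# Shift a kernel by a (possibly fractional) latency jitter, clamped so the
# support stays inside [0, 0.75] s. Integer-sample shift.
.shiftKernel <- function(kernel, jitter) {
  k <- kernel@samples
  d <- as.integer(round(jitter * kernel@samplingRate))
  n <- length(k)
  out <- numeric(n)
  if (d >= 0) out[(1 + d):n] <- k[1:(n - d)]
  else out[1:(n + d)] <- k[(1 - d):n]
  new("ErpKernel", samples = out, samplingRate = kernel@samplingRate,
      shape = kernel@shape, latency = kernel@latency + d / kernel@samplingRate,
      width = kernel@width, polarity = kernel@polarity)
}
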