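# Presynaptic glutamate pulse train: the model's only time-varying input.

#' Glutamate stimulation protocol
#'
#' A periodic rectangular pulse train of synaptic glutamate. Pulses start at
#' t = 0, occupy the half-open window `[onset, onset + pulse_width)`, and must
#' not overlap (`pulse_width <= 1000/frequency`).
#'
#' @param frequency Pulse rate (Hz).
#' @param pulse_width Duration of each pulse (ms).
#' @param amplitude Glutamate concentration during a pulse (mM).
#' @param duration Total stimulation time (s); the signal is zero afterwards.
#' @return An object of class `stimulus_protocol`.
#' @examples
#' stim <- stimulus_protocol()        # 5 Hz, 4 ms, 0.2 mM, 10 s
#' glutamate_at(stim, c(0, 2, 3.999, 4, 100, 200))
#' @export
stimulus_protocol <- function(frequency = 5, pulse_width = 4,
                              amplitude = 0.2, duration = 10) {
  stopifnot(frequency > 0, pulse_width > 0, amplitude >= 0, duration > 0)
  if (pulse_width > 1000 / frequency)
    stop("pulse_width must not exceed the pulse period 1000/frequency ",
         "(pulses must not overlap)", call. = FALSE)
  structure(list(frequency = frequency, pulse_width = pulse_width,
                 amplitude = amplitude, duration = duration),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "Glutamate pulse train: %g Hz, %g ms pulses, %g mM, %g s\n",
    x$frequency, x$pulse_width, x$amplitude, x$duration))
  invisible(x)
}

#' Glutamate concentration at a given time
#'
#' Evaluates the pulse train: `amplitude` when `t mod (1000/frequency)` lies
#' in `[0, pulse_width)` and `t` is within the stimulation duration, else 0.
#' Piecewise constant and exactly periodic within the duration.
#'
#' @param protocol A [stimulus_protocol()].
#' @param t Time(s) since stimulation onset (ms); vectorized.
#' @return Glutamate concentration(s) (mM).
#' @export
glutamate_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  period <- 1000 / protocol$frequency
  phase <- t %% period
  out <- ifelse(phase < protocol$pulse_width & t < protocol$duration * 1000,
                protocol$amplitude, 0)
  as.numeric(out)
}
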