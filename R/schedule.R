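# Linear annealing temperature schedule: 300 -> 800 K at 1 K per 10 ps by
# default, i.e. a 5000 ps (5 ns) NVT ramp.

#' Annealing temperature schedule
#'
#' @param t_start,t_end Ramp endpoints in K (defaults 300 and 800).
#' @param rate Heating rate in K/ps (default 0.1, i.e. 1 K per 10 ps).
#' @param frame_interval Trajectory frame spacing in ps (default 10).
#' @return An `annealing_schedule` list.
#' @examples
#' sched <- annealing_schedule()
#' temperature_at(sched, c(0, 1000, 6000))
#' ramp_duration(sched)
#' @export
annealing_schedule <- function(t_start = 300, t_end = 800, rate = 0.1,
                               frame_interval = 10) {
  assert_scalar_number(t_start, "t_start")
  assert_scalar_number(t_end, "t_end")
  assert_scalar_number(rate, "rate", positive = TRUE)
  assert_scalar_number(frame_interval, "frame_interval", positive = TRUE)
  if (t_end <= t_start) abort("`t_end` must exceed `t_start`")
  structure(
    list(t_start = t_start, t_end = t_end, rate = rate,
         frame_interval = frame_interval),
    class = "annealing_schedule"
  )
}

#' @rdname annealing_schedule
#' @param schedule An `annealing_schedule`.
#' @param t Simulation time(s) in ps, non-negative.
#' @return `temperature_at()`: temperature(s) in K,
#'   `min(t_start + rate * t, t_end)`.
#' @export
temperature_at <- function(schedule, t) {
  if (any(t < 0)) abort("time must be non-negative")
  pmin(schedule$t_start + schedule$rate * t, schedule$t_end)
}

#' @rdname annealing_schedule
#' @return `ramp_duration()`: time in ps at which the ramp reaches `t_end`.
#' @export
ramp_duration <- function(schedule) {
  (schedule$t_end - schedule$t_start) / schedule$rate
}
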