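#' Radiotherapy beam-on time from machine factors
#'
#' Beam-on time = dose / (base_rate * output_factor * pdd).  The optional
#' percent-depth-dose factor defaults to 1; target depth is carried as
#' metadata only, since small-animal platform irradiation times are set by
#' the collimator output factor at the shallow depths involved.
#'
#' @param dose prescribed dose in Gy.
#' @param base_rate base output dose rate in Gy/min.
#' @param output_factor collimator output factor in (0, 1].
#' @param pdd optional percent-depth-dose factor (fraction, default 1).
#' @return beam-on time in min.
#' @export
beam_on_time <- function(dose, base_rate = 4.1, output_factor = 0.79,
                         pdd = 1) {
  if (any(dose <= 0)) stop("dose must be positive")
  if (any(base_rate <= 0)) stop("base_rate must be positive")
  if (any(output_factor <= 0) || any(output_factor > 1))
    stop("output_factor must be in (0, 1]")
  if (any(pdd <= 0) || any(pdd > 1)) stop("pdd must be in (0, 1]")
  dose / (base_rate * output_factor * pdd)
}

#' Radiotherapy plan record
#'
#' @param dose prescribed dose in Gy.
#' @param base_rate base output dose rate in Gy/min.
#' @param output_factor collimator output factor.
#' @param depth_mm informational target depth in mm.
#' @return object of class `rt_plan` with the raw beam-on time and its
#'   0.1-min rounding.
#' @export
rt_plan <- function(dose, base_rate = 4.1, output_factor = 0.79,
                    depth_mm = 3) {
  t <- beam_on_time(dose, base_rate, output_factor)
  structure(list(dose_gy = dose, base_rate_gy_min = base_rate,
                 output_factor = output_factor, depth_mm = depth_mm,
                 beam_on_min = t, beam_on_min_rounded = round(t, 1)),
            class = "rt_plan")
}

#' @export
print.rt_plan <- function(x, ...) {
  cat(sprintf(
    "rt_plan: %.3g Gy at %.2f Gy/min x OF %.2f -> %.3f min (%.1f min)\n",
    x$dose_gy, x$base_rate_gy_min, x$output_factor,
    x$beam_on_min, x$beam_on_min_rounded))
  invisible(x)
}
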