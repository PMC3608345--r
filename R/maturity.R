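#' Somatic maturity offset (years from peak height velocity) for boys
#'
#' Anthropometric maturity-offset equation for boys: predicted years from
#' peak height velocity (PHV) computed from chronological age, stature,
#' sitting height, and body mass. Negative values are pre-PHV. Leg length is
#' derived as stature minus sitting height.
#'
#' The offset is
#' \deqn{-9.236 + 0.0002708\,(L_h S_h) - 0.001663\,(A L_h) + 0.007216\,(A S_h)
#'       + 0.02292\,(100\,W_t/H_t)}
#' with \eqn{L_h} leg length (cm), \eqn{S_h} sitting height (cm), \eqn{A} age
#' (years), \eqn{W_t} body mass (kg) and \eqn{H_t} stature (cm).
#'
#' @param age chronological age, decimal years.
#' @param height stature, cm.
#' @param seating_height sitting height, cm; must be positive and below
#'   `height`.
#' @param weight body mass, kg.
#' @return maturity offset in years (vectorised over the inputs).
#' @examples
#' maturity_offset(age = 13, height = 150, seating_height = 80, weight = 45)
#' @export
maturity_offset <- function(age, height, seating_height, weight) {
  n <- max(length(age), length(height), length(seating_height), length(weight))
  args <- list(age = age, height = height, seating_height = seating_height, weight = weight)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || !all(is.finite(x))) {
      stop_input("`", nm, "` must be finite numeric")
    }
    args[[nm]] <- rep_len(x, n)
  }
  if (any(args$height <= 0)) stop_input("`height` must be positive")
  if (any(args$seating_height <= 0)) stop_input("`seating_height` must be positive")
  if (any(args$seating_height >= args$height)) {
    stop_input("`seating_height` must be smaller than `height`")
  }
  if (any(args$age <= 0)) stop_input("`age` must be positive")
  with(args, {
    leg <- height - seating_height
    -9.236 +
      0.0002708 * (leg * seating_height) -
      0.001663 * (age * leg) +
      0.007216 * (age * seating_height) +
      0.02292 * (weight / height * 100)
  })
}
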