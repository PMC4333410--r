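# internal validation helpers

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive (got %g).", name, x))
  }
  invisible(x)
}

stop_if_not_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != trunc(x)) {
    abort(sprintf("`%s` must be a single non-negative integer.", name))
  }
  if (x < min) {
    abort(sprintf("`%s` must be >= %d (got %d).", name, min, as.integer(x)))
  }
  invisible(as.integer(x))
}

# geometric-mean / CV parameterisation of the log-normal: draws have
# geometric mean `gm` and coefficient of variation `cv` on the natural scale
rlnorm_gm_cv <- function(n, gm, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(gm), sdlog = sdlog)
}

#' Canonical time-point labels of the starvation design
#'
#' The sampling design measures each strain in histidine-rich medium and at
#' three times after transfer to histidine-free medium. These labels are used
#' throughout the package; failure strains (no detectable growth) lack the
#' late (`-His >10 h`) time point.
#'
#' @return Character vector of the four time-point labels, in temporal order.
#' @export
#' @examples
#' timepoint_levels()
timepoint_levels <- function() {
  c("+His", "-His 10 min", "-His 2 h", "-His >10 h")
}

TP_PLUS <- "+His"
TP_10MIN <- "-His 10 min"
TP_2H <- "-His 2 h"
TP_LATE <- "-His >10 h"

fcm_channels <- function() c("FSC", "SSC", "GFP", "RFP")

default_instrument_range <- function() {
  # 18-bit acquisition scale typical of the cytometer class used
  lapply(setNames(fcm_channels(), fcm_channels()), function(ch) c(1, 262144))
}
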