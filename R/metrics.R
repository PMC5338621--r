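#' Forward-solution comparison measures
#'
#' Relative difference measure and magnitude measure between two voltage
#' topographies, in percent:
#' `RDM(u1, u2) = 100 || u1/||u1|| - u2/||u2|| ||_2` (0 for proportional
#' patterns, 200 for antipodal ones) and
#' `MAG(u1, u2) = 100 ||u2|| / ||u1|| - 100`.
#'
#' @param u1,u2 voltage vectors of equal length (u1 is the reference for MAG).
#' @return scalar, percent.
#' @export
#' @examples
#' rdm(c(1, 0), c(1, 1)) # 100 * sqrt(2 - sqrt(2))
#' mag(c(1, 1), 2 * c(1, 1)) # 100
rdm <- function(u1, u2) {
  u1 <- as.numeric(u1); u2 <- as.numeric(u2)
  if (length(u1) != length(u2)) stop("voltage vectors differ in length")
  n1 <- sqrt(sum(u1^2)); n2 <- sqrt(sum(u2^2))
  if (n1 == 0 || n2 == 0) stop("RDM undefined for a zero voltage vector")
  100 * sqrt(sum((u1 / n1 - u2 / n2)^2))
}

#' @rdname rdm
#' @export
mag <- function(u1, u2) {
  u1 <- as.numeric(u1); u2 <- as.numeric(u2)
  if (length(u1) != length(u2)) stop("voltage vectors differ in length")
  n1 <- sqrt(sum(u1^2))
  if (n1 == 0) stop("MAG undefined for a zero reference vector")
  100 * sqrt(sum(u2^2)) / n1 - 100
}

#' Source localization difference measures
#'
#' Position difference `PD = ||r_true - r_est||_2`, angular difference
#' `AD = arccos(q_true . q_est / (||q_true|| ||q_est||))` in degrees (the dot
#' product is clamped to \[-1, 1\]), and norm (depth) difference
#' `ND = ||r_true|| - ||r_est||`. Positive ND means the estimate lies deeper
#' than the truth; the experiments additionally report the depth bias `-ND`
#' to keep the sign semantics explicit. PD and ND are returned in the units
#' of the inputs (use meters; the experiment tables convert to mm).
#'
#' @param r_true,r_est positions (length-3).
#' @param q_true,q_est moments (length-3, any positive scale).
#' @return scalar.
#' @export
pd <- function(r_true, r_est) {
  sqrt(sum((as.numeric(r_true) - as.numeric(r_est))^2))
}

#' @rdname pd
#' @export
ad <- function(q_true, q_est) {
  q1 <- as.numeric(q_true); q2 <- as.numeric(q_est)
  n1 <- sqrt(sum(q1^2)); n2 <- sqrt(sum(q2^2))
  if (n1 == 0 || n2 == 0) stop("AD undefined for a zero moment")
  c_ <- sum(q1 * q2) / (n1 * n2)
  acos(min(1, max(-1, c_))) * 180 / pi
}

#' @rdname pd
#' @export
nd <- function(r_true, r_est) {
  sqrt(sum(as.numeric(r_true)^2)) - sqrt(sum(as.numeric(r_est)^2))
}

#' Five-number box-plot summary
#'
#' Median, interquartile range and extremes, the statistics drawn in the
#' experiment box plots. Quartiles use linear interpolation between order
#' statistics (type 7, the R default).
#'
#' @param values nonempty numeric vector.
#' @return tibble with `median`, `iqr_low`, `iqr_high`, `min`, `max`, `n`.
#' @export
#' @examples
#' boxplot_summary(1:5)
boxplot_summary <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values)) {
    stop("`values` must be a nonempty numeric vector without NAs")
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(median = q[2], iqr_low = q[1], iqr_high = q[3],
                 min = min(values), max = max(values), n = length(values))
}
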