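#' Analytic dipole potential on a homogeneous conducting sphere
#'
#' Closed-form (Legendre series) surface potential of a current dipole inside
#' a homogeneous sphere with an insulating boundary: for a dipole of moment
#' `q` (A m) at radius `f` along an axis `e_z'`, the potential at a surface
#' point with polar angle `theta` from that axis is
#'
#' `u = 1/(4 pi sigma R^2) sum_{n>=1} (2n+1)/n (f/R)^(n-1)
#'      [ n q_r P_n(cos theta) + q_t P_n^1(cos theta) cos phi ]`
#'
#' with `q_r`, `q_t` the radial and tangential moment components and
#' `P_n^1(cos theta) cos phi = sin theta cos phi P_n'(cos theta)` (no
#' Condon-Shortley phase). The series is truncated when the radial factor
#' falls below `tol`. Used as the independent oracle for the point-electrode
#' FEM solution on the homogeneous sphere head.
#'
#' @param points P x 3 matrix of observation points on (or near) the surface;
#'   only their directions are used.
#' @param r_dipole dipole position (length-3, |r| < radius).
#' @param q dipole moment (length-3, A m).
#' @param radius sphere radius (m).
#' @param sigma conductivity (S/m).
#' @param tol truncation tolerance on `(f/R)^(n-1)`.
#' @param n_max hard cap on the series order.
#' @return numeric vector of potentials (V), zero-mean not enforced (apply
#'   [average_reference()] to compare with referenced FEM voltages).
#' @export
analytic_dipole_potential <- function(points, r_dipole, q, radius, sigma,
                                      tol = 1e-14, n_max = 400L) {
  points <- as.matrix(points)
  r_dipole <- as.numeric(r_dipole); q <- as.numeric(q)
  f <- sqrt(sum(r_dipole^2))
  if (f >= radius) stop("dipole must lie strictly inside the sphere")
  rb <- points / sqrt(rowSums(points^2))  # unit observation directions

  if (f / radius < .Machine$double.eps) {
    # central dipole: only the n = 1 term survives
    return(3 * as.numeric(rb %*% q) / (4 * pi * sigma * radius^2))
  }
  ez <- r_dipole / f
  qr_ <- sum(q * ez)
  qt_vec <- q - qr_ * ez
  qt <- sqrt(sum(qt_vec^2))
  ex <- if (qt > 0) qt_vec / qt else c(0, 0, 0)

  ct <- as.numeric(rb %*% ez)                 # cos theta
  sc <- as.numeric(rb %*% ex)                 # sin theta cos phi
  x <- pmin(1, pmax(-1, ct))

  # Legendre P_n and derivative P_n' by Bonnet recurrences
  p_nm1 <- rep(1, length(x))   # P_0
  p_n <- x                     # P_1
  dp_n <- rep(1, length(x))    # P_1'
  dp_nm1 <- rep(0, length(x))  # P_0'
  s <- f / radius
  pref <- 1 / (4 * pi * sigma * radius^2)
  u <- pref * 3 * (qr_ * p_n + qt * sc * dp_n)  # n = 1 term, (f/R)^0
  fac <- 1
  for (n in 2:n_max) {
    fac <- fac * s
    if (fac < tol) break
    # P_n from P_{n-1}, P_{n-2}
    p_np <- ((2 * n - 1) * x * p_n - (n - 1) * p_nm1) / n
    dp_np <- dp_nm1 + (2 * n - 1) * p_n  # P_n' = P_{n-2}' + (2n-1) P_{n-1}
    p_nm1 <- p_n; p_n <- p_np
    dp_nm1 <- dp_n; dp_n <- dp_np
    u <- u + pref * (2 * n + 1) / n * fac * (n * qr_ * p_n + qt * sc * dp_n)
  }
  u
}
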