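#' Map electronic coefficients to the Bloch spin vector
#'
#' For a normalized coefficient pair \eqn{(c_-, c_+)} on the lower/upper
#' adiabats, the spin components are
#' \eqn{S_x = 2\,\mathrm{Re}(c_+^* c_-)}, \eqn{S_y = 2\,\mathrm{Im}(c_+^* c_-)},
#' \eqn{S_z = |c_+|^2 - |c_-|^2}; the result is a unit 3-vector.
#'
#' @param c complex vector of length 2, `c(c_minus, c_plus)`, normalized.
#' @param tol tolerance on the input norm.
#' @return Numeric vector `c(Sx, Sy, Sz)`.
#' @export
coeffs_to_spin <- function(c, tol = 1e-10) {
  stopifnot(length(c) == 2L)
  c <- as.complex(c)
  n2 <- sum(Mod(c)^2)
  if (abs(n2 - 1) > tol)
    stop("coefficient pair is not normalized: |c|^2 = ", format(n2))
  z <- Conj(c[2L]) * c[1L]
  c(2 * Re(z), 2 * Im(z), Mod(c[2L])^2 - Mod(c[1L])^2)
}

#' Map a Bloch spin vector to electronic coefficients
#'
#' Inverts the spin mapping up to a global phase; the convention here makes
#' \eqn{c_-} real and non-negative (at the north pole, where \eqn{c_- = 0},
#' \eqn{c_+} is taken real positive).  The round trip through
#' [coeffs_to_spin()] is the identity on the sphere.
#'
#' @param S numeric unit 3-vector `c(Sx, Sy, Sz)`.
#' @param tol tolerance on `|S| - 1`.
#' @return Complex vector `c(c_minus, c_plus)`.
#' @export
spin_to_coeffs <- function(S, tol = 1e-10) {
  stopifnot(length(S) == 3L)
  r <- sqrt(sum(S^2))
  if (abs(r - 1) > tol)
    stop("spin vector is not on the unit sphere: |S| = ", format(r))
  cm <- sqrt((1 - S[3L]) / 2)
  if (cm < .Machine$double.eps^0.5)
    return(as.complex(c(0, 1)))
  # with c_minus real >= 0: Sy = 2 Im(c_plus^* c_minus) = -2 c_minus Im(c_plus),
  # so c_plus = (Sx - i Sy) / (2 c_minus)
  cp <- complex(real = S[1L], imaginary = -S[2L]) / (2 * cm)
  out <- c(as.complex(cm), cp)
  # renormalize: roundoff in S is amplified near the poles
  out / sqrt(sum(Mod(out)^2))
}

#' Phase-space point of the extended nuclear-electronic system
#'
#' A point \eqn{\Gamma = (q, p, \vec S)} carrying the complex coefficient
#' pair as the stored electronic representation (the spin vector is derived
#' on demand).  Supply either `S` or `c`.
#'
#' @param q position (bohr).
#' @param p momentum (m_e bohr / a.t.u.).
#' @param S unit spin 3-vector (used if `c` is missing).
#' @param c complex coefficient pair `c(c_minus, c_plus)`.
#' @param t time label (a.t.u.).
#' @return An object of class `phase_point` with elements `q`, `p`, `c`, `t`.
#' @export
phase_point <- function(q, p, S = NULL, c = NULL, t = 0) {
  stopifnot(length(q) == 1L, length(p) == 1L)
  if (is.null(c)) {
    if (is.null(S)) stop("supply either S or c")
    c <- spin_to_coeffs(S)
  } else {
    c <- as.complex(c)
    n <- sqrt(sum(Mod(c)^2))
    if (abs(n - 1) > 1e-10)
      stop("coefficient pair is not normalized")
  }
  structure(list(q = as.numeric(q), p = as.numeric(p), c = c,
                 t = as.numeric(t)),
            class = "phase_point")
}

#' @export
print.phase_point <- function(x, ...) {
  S <- coeffs_to_spin(x$c)
  cat(sprintf("phase point at t = %g a.t.u.\n", x$t))
  cat(sprintf("  q = %.6g bohr, p = %.6g, S = (%.4f, %.4f, %.4f), state = %s\n",
              x$q, x$p, S[1], S[2], S[3],
              if (S[3] > 0) "upper" else "lower"))
  invisible(x)
}

# spin of a phase point
spin_of <- function(gamma) coeffs_to_spin(gamma$c)

# active-surface sign with the deterministic tie-break Sz == 0 -> lower
active_sign <- function(gamma) {
  sz <- coeffs_to_spin(gamma$c)[3L]
  if (sz > 0) 1 else -1
}

#' Time reversal of a phase point
#'
#' Positions are even and momenta odd under time reversal; for the spin,
#' the x- and z-components are even and the y-component is odd, which for
#' the coefficients is complex conjugation, \eqn{c_i \to c_i^*}.  The map
#' is an involution.
#'
#' @param gamma a [phase_point()].
#' @return The time-reversed `phase_point` (same time label).
#' @export
time_reverse <- function(gamma) {
  stopifnot(inherits(gamma, "phase_point"))
  phase_point(q = gamma$q, p = -gamma$p, c = Conj(gamma$c), t = gamma$t)
}

#' Propagate electronic coefficients across one nuclear segment
#'
#' Unitary propagation of the adiabatic-basis coefficient pair along the
#' in-step nuclear drift path from `q_start` to `q_end` (linear in time, as
#' in the velocity-Verlet drift), using the diabatic-frame Magnus scheme of
#' the integrator core.  The norm is conserved to machine precision and the
#' map is exactly time-reversal symmetric.
#'
#' @param c complex coefficient pair `c(c_minus, c_plus)` at `q_start`.
#' @param q_start,q_end segment endpoints (bohr).
#' @param p_mid drift momentum over the segment (consistent with
#'   `q_end = q_start + p_mid/m * dt`; if it is not, the linear path implied
#'   by `q_start`, `q_end` and `dt` is used).
#' @param dt segment duration (a.t.u.), > 0.
#' @param model a [two_state_model()].
#' @param n_sub number of Magnus substeps.
#' @return Complex coefficient pair at `q_end` (adiabatic basis at `q_end`).
#' @export
propagate_electronic <- function(c, q_start, q_end, p_mid = NULL, dt,
                                 model, n_sub = 32L) {
  stopifnot(dt > 0, length(c) == 2L)
  v <- (q_end - q_start) / dt
  if (!is.null(p_mid)) {
    v_mid <- p_mid / model$mass
    if (abs(v_mid - v) > 1e-8 * max(1, abs(v)))
      v <- (q_end - q_start) / dt  # endpoint-consistent path takes precedence
  }
  c <- as.complex(c)
  out <- cpp_electronic_step(c(Re(c[1L]), Im(c[1L]), Re(c[2L]), Im(c[2L])),
                             q_start, v, dt, as.integer(n_sub),
                             model_pars(model))
  complex(real = out[c(1L, 3L)], imaginary = out[c(2L, 4L)])
}
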