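#' Coupled-harmonic two-state diabatic model
#'
#' Constructs the one-dimensional avoided-crossing model of two displaced
#' harmonic diabats with a constant off-diagonal coupling,
#' \deqn{H_{11} = \epsilon\left(\frac{q-x_0}{x_0}\right)^2,\quad
#'       H_{22} = \epsilon\left(\frac{q+x_0}{x_0}\right)^2,\quad
#'       H_{12} = H_{21} = V_c,}
#' in atomic units.  The adiabatic surfaces are
#' \eqn{\bar V(q) \pm V_z(q)} with \eqn{\bar V = (H_{11}+H_{22})/2} and
#' \eqn{V_z = \sqrt{((H_{11}-H_{22})/2)^2 + V_c^2}}; the coupling forbids an
#' exact degeneracy, so the minimum adiabatic splitting is \eqn{2V_c} at the
#' crossing seam \eqn{q = 0}.
#'
#' The object carries only the four constants; all derived quantities are
#' computed by [diabatic_hamiltonian()], [adiabatize()], [barrier_height()]
#' and [mash_force()].  Other one-dimensional two-state models can implement
#' the same generics to plug into the integrator interface.
#'
#' @param epsilon energy scale of the harmonic diabats (Hartree), > 0.
#' @param x0 well displacement (bohr), > 0.
#' @param Vc diabatic coupling (Hartree), >= 0.  Default `0.2 * epsilon`.
#' @param mass nuclear mass (electron masses).  Default is the mass of a
#'   hydrogen atom, 1836.15.
#' @return An object of class `two_state_model`.
#' @examples
#' m <- two_state_model()
#' diabatic_hamiltonian(m, 0)
#' barrier_height(m)
#' @export
two_state_model <- function(epsilon = 0.05, x0 = 1.0, Vc = 0.01,
                            mass = 1836.15) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            is.numeric(x0), length(x0) == 1L, x0 > 0,
            is.numeric(Vc), length(Vc) == 1L, Vc >= 0,
            is.numeric(mass), length(mass) == 1L, mass > 0)
  structure(list(epsilon = epsilon, x0 = x0, Vc = Vc, mass = mass),
            class = "two_state_model")
}

#' @export
print.two_state_model <- function(x, ...) {
  cat("Coupled-harmonic two-state model (atomic units)\n")
  cat(sprintf("  epsilon = %g Ha, x0 = %g bohr, Vc = %g Ha (%.3g epsilon), mass = %g m_e\n",
              x$epsilon, x$x0, x$Vc, x$Vc / x$epsilon, x$mass))
  cat(sprintf("  minimum adiabatic splitting 2 Vc = %g Ha, barrier Ea = %g Ha\n",
              2 * x$Vc, barrier_height(x)))
  invisible(x)
}

#' Diabatic Hamiltonian matrix
#'
#' @param model a [two_state_model()].
#' @param q nuclear position (bohr), scalar.
#' @return A 2x2 symmetric numeric matrix of energies (Hartree).
#' @export
diabatic_hamiltonian <- function(model, q) {
  stopifnot(inherits(model, "two_state_model"), length(q) == 1L)
  h11 <- model$epsilon * ((q - model$x0) / model$x0)^2
  h22 <- model$epsilon * ((q + model$x0) / model$x0)^2
  matrix(c(h11, model$Vc, model$Vc, h22), 2, 2)
}

#' Adiabatic representation at given positions
#'
#' Computes the mean potential, half-gap, their analytic derivatives and the
#' nonadiabatic coupling \eqn{\langle\psi_-|\partial_q \psi_+\rangle} from
#' the 2x2 eigenproblem in closed form.  The eigenvector branch is fixed by
#' the mixing half-angle \eqn{\theta = \tfrac12\,\mathrm{atan2}(V_c,\Delta)}
#' with \eqn{\Delta = (H_{11}-H_{22})/2}, which is continuous in `q` and
#' free of sign flips.
#'
#' @param model a [two_state_model()].
#' @param q numeric vector of positions (bohr).
#' @return A data.frame with columns `q`, `Vbar`, `Vz`, `dVbar`, `dVz`,
#'   `nac`, `lower`, `upper` (energies in Hartree, `nac` in 1/bohr).
#' @export
adiabatize <- function(model, q) {
  stopifnot(inherits(model, "two_state_model"), is.numeric(q))
  eps <- model$epsilon; x0 <- model$x0; Vc <- model$Vc
  h11 <- eps * ((q - x0) / x0)^2
  h22 <- eps * ((q + x0) / x0)^2
  Vbar <- (h11 + h22) / 2
  Delta <- (h11 - h22) / 2
  Vz <- sqrt(Delta^2 + Vc^2)
  dVbar <- 2 * eps * q / x0^2
  dDelta <- -2 * eps / x0
  dVz <- Delta * dDelta / Vz
  nac <- -0.5 * Vc * dDelta / Vz^2
  data.frame(q = q, Vbar = Vbar, Vz = Vz, dVbar = dVbar, dVz = dVz,
             nac = nac, lower = Vbar - Vz, upper = Vbar + Vz)
}

#' Adiabatic barrier height of the lower surface
#'
#' Returns \eqn{E_a = (1 - V_c/\epsilon)\,\epsilon}, the energy of the
#' lower adiabat at the crossing seam referenced to the diabatic well
#' minima (which sit at energy zero).  The true well-to-top barrier on the
#' lower adiabat is larger by exactly \eqn{V_c^2/(4\epsilon)}, because the
#' adiabatic minima are pushed below zero by the coupling; at the default
#' `Vc = 0.2 epsilon` this residual is 1.25% of \eqn{E_a}.
#'
#' @param model a [two_state_model()].
#' @return Barrier energy in Hartree.
#' @export
barrier_height <- function(model) {
  stopifnot(inherits(model, "two_state_model"))
  if (model$Vc > model$epsilon)
    stop("barrier formula requires Vc <= epsilon (outside its validity regime)")
  (1 - model$Vc / model$epsilon) * model$epsilon
}

#' Force on an adiabatic surface
#'
#' Negative gradient of the active surface
#' \eqn{\bar V(q) + s\,V_z(q)}, where `active_sign` \eqn{s = -1} selects the
#' lower and \eqn{s = +1} the upper adiabat.
#'
#' @param model a [two_state_model()].
#' @param q numeric vector of positions (bohr).
#' @param active_sign -1 (lower adiabat) or +1 (upper adiabat).
#' @return Force in Hartree/bohr.
#' @export
mash_force <- function(model, q, active_sign) {
  stopifnot(active_sign %in% c(-1, 1))
  a <- adiabatize(model, q)
  -a$dVbar - active_sign * a$dVz
}

# model parameters as a plain list for the C++ core
model_pars <- function(model) {
  list(epsilon = model$epsilon, x0 = model$x0, Vc = model$Vc,
       mass = model$mass)
}
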