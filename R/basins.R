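#' Define a configurational basin
#'
#' A basin is a half-line in position restricted to one adiabatic state:
#' a phase point belongs to it iff its active-surface sign equals
#' `required_state_sign` and `q` lies on the given side of `q_bound`.
#'
#' @param name basin label, `"A"` or `"B"`.
#' @param q_bound position threshold (bohr).
#' @param side `"below"` (q < q_bound) or `"above"` (q > q_bound).
#' @param required_state_sign adiabatic state sign required for membership;
#'   -1 restricts the basin to the lower surface (default).
#' @return An object of class `basin_spec`.
#' @export
basin_spec <- function(name, q_bound, side = c("below", "above"),
                       required_state_sign = -1) {
  side <- match.arg(side)
  stopifnot(is.numeric(q_bound), length(q_bound) == 1L,
            required_state_sign %in% c(-1, 1))
  structure(list(name = name, q_bound = q_bound, side = side,
                 required_state_sign = required_state_sign),
            class = "basin_spec")
}

#' Default reactant/product basins
#'
#' Basin A is the lower adiabat with `q < -0.8` bohr; basin B the lower
#' adiabat with `q > 0.8` bohr.
#'
#' @return A named list `list(A = ..., B = ...)` of [basin_spec()] objects.
#' @export
default_basins <- function() {
  list(A = basin_spec("A", -0.8, "below"),
       B = basin_spec("B",  0.8, "above"))
}

#' Basin membership of a phase point
#'
#' @param gamma a [phase_point()].
#' @param basin a [basin_spec()].
#' @return Logical flag.
#' @export
in_basin <- function(gamma, basin) {
  stopifnot(inherits(gamma, "phase_point"), inherits(basin, "basin_spec"))
  if (active_sign(gamma) != basin$required_state_sign) return(FALSE)
  if (basin$side == "below") gamma$q < basin$q_bound else gamma$q > basin$q_bound
}

# vectorized membership over trajectory rows (q, active columns)
basin_label_rows <- function(q, active, basins) {
  lab <- rep(NA_character_, length(q))
  for (nm in names(basins)) {
    b <- basins[[nm]]
    ok <- active == b$required_state_sign &
      (if (b$side == "below") q < b$q_bound else q > b$q_bound)
    lab[ok] <- b$name
  }
  lab
}

# arguments for the C++ basin check
basin_args <- function(basins) {
  A <- basins$A; B <- basins$B
  stopifnot(A$required_state_sign == B$required_state_sign)
  list(boundA = A$q_bound, sideA = if (A$side == "below") -1L else 1L,
       boundB = B$q_bound, sideB = if (B$side == "below") -1L else 1L,
       req_sign = as.integer(A$required_state_sign))
}
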