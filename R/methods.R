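#' @export
print.natps_ensemble <- function(x, ...) {
  n <- length(x$chain)
  cat(sprintf("NATPS path ensemble: %d MC steps (%d burn-in), %d accepted paths\n",
              n, x$burn_in, length(x$paths) - 1L))
  cat(sprintf("  T = %g K, alpha = %g, dt = %g a.t.u.\n",
              x$config$temperature, x$config$alpha, x$config$dt))
  cat(sprintf("  acceptance rate %.3f, total steps generated %g\n",
              mean(x$records$accepted), x$total_steps))
  invisible(x)
}

#' Summarize a TPS ensemble
#'
#' Headline post-burn-in statistics: mean/sd of the transition time, the
#' decorrelation length of the chain, hop statistics, and the efficiency
#' ratio under both step-accounting conventions (per MC sample and per
#' distinct accepted path).
#'
#' @param object a `natps_ensemble`.
#' @param n_max_acf largest autocorrelation lag.
#' @param ... unused.
#' @return A list of class `summary.natps_ensemble`.
#' @export
summary.natps_ensemble <- function(object, n_max_acf = 100L, ...) {
  tau <- transition_times(object)
  n_max_acf <- min(n_max_acf, length(tau) - 1L)
  C <- tt_autocorrelation(tau, n_max_acf)
  hs <- hop_statistics(object)
  n_chain <- length(object$chain)
  structure(list(
    n_chain = n_chain,
    burn_in = object$burn_in,
    acceptance = mean(object$records$accepted),
    tau_mean = mean(tau), tau_sd = sd(tau),
    decorrelation = decorrelation_length(C),
    hop_stats = hs,
    er_per_sample = efficiency_ratio(object$total_steps, n_chain),
    er_per_accepted = efficiency_ratio(object$total_steps,
                                       sum(object$records$accepted)),
    temperature = object$config$temperature),
    class = "summary.natps_ensemble")
}

#' @export
print.summary.natps_ensemble <- function(x, ...) {
  cat(sprintf("NATPS ensemble at %g K: %d MC steps (%d burn-in), acceptance %.3f\n",
              x$temperature, x$n_chain, x$burn_in, x$acceptance))
  cat(sprintf("  <tau> = %.1f a.t.u. (sd %.1f); decorrelation length %d MC steps\n",
              x$tau_mean, x$tau_sd, as.integer(x$decorrelation)))
  cat(sprintf("  paths with >=2 hops: %.1f%%; mean hop position %.4f bohr\n",
              100 * x$hop_stats$fraction_ge[[">=2"]],
              x$hop_stats$mean_position))
  cat(sprintf("  efficiency ratio: %.1f steps per MC sample (%.1f per accepted path)\n",
              x$er_per_sample, x$er_per_accepted))
  invisible(x)
}

#' Plot a TPS ensemble
#'
#' Histogram of post-burn-in transition times, split into adiabatic
#' (hop-free) and nonadiabatic paths.
#'
#' @param x a `natps_ensemble`.
#' @param breaks histogram breaks.
#' @param ... passed to [graphics::hist()].
#' @export
plot.natps_ensemble <- function(x, breaks = 40, ...) {
  tau <- transition_times(x)
  nh <- hop_statistics(x)$hops_per_path
  h <- hist(tau, breaks = breaks, plot = FALSE)
  hist(tau, breaks = h$breaks, col = "grey80", border = "white",
       xlab = expression(tau ~ "(a.t.u.)"),
       main = sprintf("transition times at %g K", x$config$temperature),
       ...)
  if (any(nh > 0))
    hist(tau[nh > 0], breaks = h$breaks, col = "darkorange",
         border = "white", add = TRUE)
  legend("topright", fill = c("grey80", "darkorange"),
         legend = c("all paths", "nonadiabatic"), bty = "n")
  invisible(x)
}
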