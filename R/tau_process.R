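# Trial-to-trial evolution of the control time constant: a stationary AR(1)
# process on phi = log(tau), constructed so that ~95% of the marginal mass
# (the central two-sigma band) lies between the stated bounds.

#' Parameters of the log-domain AR(1) time-constant process
#'
#' Builds the parameters of the stationary first-order autoregression on
#' \eqn{\phi = \log\tau}: \deqn{\phi_{t+1} = c\,\phi_t + \eta_t, \quad
#' \eta \sim N(\mu_\eta, \sigma_\eta^2),}
#' with marginal mean \eqn{\mu_\phi = \tfrac12(\log\tau_- + \log\tau_+)},
#' marginal SD \eqn{\sigma_\phi = \tfrac14(\log\tau_+ - \log\tau_-)} (so the
#' bounds sit two marginal SDs from the mean), update coefficient
#' \eqn{c = e^{-1/\tau_\phi}}, and innovation moments
#' \eqn{\mu_\eta = \mu_\phi(1-c)}, \eqn{\sigma_\eta^2 = \sigma_\phi^2(1-c^2)}.
#'
#' @param tau_minus,tau_plus Lower and upper timescale bounds in seconds
#'   (defaults 0.6 and 3.0 s, spanning velocity-like to acceleration-like
#'   control).
#' @param tau_phi Timescale of the walk in trials (default 2).
#' @return An object of class `tau_walk_params`.
#' @examples
#' walk_params()$c  # exp(-1/2)
#' @export
walk_params <- function(tau_minus = 0.6, tau_plus = 3.0, tau_phi = 2) {
  if (!(tau_minus > 0 && tau_plus >= tau_minus))
    stop("require 0 < tau_minus <= tau_plus")
  stopifnot(tau_phi > 0)
  c_upd <- exp(-1 / tau_phi)
  mu_phi <- 0.5 * (log(tau_minus) + log(tau_plus))
  sigma_phi <- 0.25 * (log(tau_plus) - log(tau_minus))
  structure(list(
    tau_minus = tau_minus, tau_plus = tau_plus, tau_phi = tau_phi,
    c = c_upd, mu_phi = mu_phi, sigma_phi = sigma_phi,
    mu_eta = mu_phi * (1 - c_upd),
    sigma_eta = sigma_phi * sqrt(1 - c_upd^2)
  ), class = "tau_walk_params")
}

#' Sample a sequence of time constants
#'
#' Draws `n` trials of \eqn{\tau = e^\phi} from the stationary AR(1) process
#' of [walk_params()]: the first \eqn{\phi} comes from the stationary normal
#' marginal, subsequent ones from the recursion with i.i.d. normal
#' innovations. With `clamp = TRUE`, \eqn{\phi} is additionally hard-clipped
#' to `[log tau_minus, log tau_plus]` (a sensitivity-check variant; the
#' default process bounds the sequence only probabilistically).
#'
#' @param params A `tau_walk_params` object.
#' @param n Number of trials.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param clamp Hard-clip phi to the bounds (default `FALSE`).
#' @return Numeric vector of `n` time constants in seconds.
#' @export
sample_tau_sequence <- function(params, n, seed = NULL, clamp = FALSE) {
  stopifnot(inherits(params, "tau_walk_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (params$sigma_phi == 0) {
    phi <- rep(params$mu_phi, n)
  } else {
    phi1 <- rnorm(1, params$mu_phi, params$sigma_phi)
    if (n == 1L) {
      phi <- phi1
    } else {
      eta <- rnorm(n - 1, params$mu_eta, params$sigma_eta)
      phi <- c(phi1, as.numeric(
        stats::filter(eta, params$c, method = "recursive", init = phi1)))
    }
    if (clamp)
      phi <- pmin(pmax(phi, log(params$tau_minus)), log(params$tau_plus))
  }
  exp(phi)
}
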