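#' Corticothalamic model parameters
#'
#' Constructs and validates the parameter set of the corticothalamic neural
#' mass model: sigmoid firing-rate constants, synaptodendritic filter rates,
#' cortical damping, the corticothalamic loop delay, and the eight synaptic
#' coupling strengths. Defaults are the normative resting-state values of the
#' model (eyes-closed adult EEG regime), under which the output spectrum shows
#' a prominent alpha (8--12 Hz) peak over a 1/f background.
#'
#' Coupling subscripts follow the target-source convention: `nu_es` is the
#' strength of the relay (specific, s) to cortical-excitatory (e) projection.
#' Inhibitory couplings (`nu_ei`, `nu_sr`) are negative. The cortical
#' inhibitory population is assumed to receive the same afferents as the
#' excitatory one (random-connectivity assumption), so no separate `nu_i*`
#' couplings exist.
#'
#' @param theta Mean firing threshold (mV).
#' @param sigma Threshold standard deviation (mV).
#' @param q_max Maximum firing rate (1/s).
#' @param gamma Cortical damping rate (1/s): conduction velocity over mean
#'   axonal range.
#' @param alpha Inverse decay time of the membrane potential (1/s).
#' @param beta Inverse rise time of the membrane potential (1/s).
#' @param t0 Corticothalamic return (loop) time in seconds; the one-way
#'   conduction delay is `t0/2`.
#' @param nu_ee,nu_ei,nu_es,nu_se,nu_sr,nu_sn,nu_re,nu_rs Synaptic coupling
#'   strengths (mV s), signed.
#' @return An object of class `ct_params` (a validated named list).
#' @examples
#' p <- ct_params()
#' firing_rate(p$theta, p)  # sigmoid midpoint: q_max / 2
#' @export
ct_params <- function(theta = 15, sigma = 6, q_max = 250, gamma = 100,
                      alpha = 50, beta = 240, t0 = 0.08,
                      nu_ee = 1.06, nu_ei = -1.8, nu_es = 2.2,
                      nu_se = 2.28, nu_sr = -0.845, nu_sn = 1.2,
                      nu_re = 0.91, nu_rs = 0.41) {
  p <- list(theta = theta, sigma = sigma, q_max = q_max, gamma = gamma,
            alpha = alpha, beta = beta, t0 = t0,
            nu_ee = nu_ee, nu_ei = nu_ei, nu_es = nu_es, nu_se = nu_se,
            nu_sr = nu_sr, nu_sn = nu_sn, nu_re = nu_re, nu_rs = nu_rs)
  validate_ct_params(p)
  structure(p, class = "ct_params")
}

validate_ct_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite scalar")
  }
  if (p$q_max <= 0) stop("q_max must be positive")
  if (p$sigma <= 0) stop("sigma must be positive")
  if (p$gamma <= 0) stop("gamma must be positive")
  if (p$t0 <= 0) stop("t0 must be positive")
  if (!(p$beta > p$alpha && p$alpha > 0))
    stop("rates must satisfy beta > alpha > 0")
  invisible(p)
}

#' @export
print.ct_params <- function(x, ...) {
  cat("Corticothalamic model parameters\n")
  cat(sprintf("  sigmoid: q_max = %g 1/s, theta = %g mV, sigma = %g mV\n",
              x$q_max, x$theta, x$sigma))
  cat(sprintf("  filters: alpha = %g 1/s, beta = %g 1/s, gamma = %g 1/s\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  loop delay t0 = %g ms (one-way %g ms)\n",
              1000 * x$t0, 500 * x$t0))
  nu <- unlist(x[ct_coupling_names()])
  cat("  couplings (mV s):\n")
  cat(sprintf("    %s = %g\n", names(nu), nu), sep = "")
  invisible(x)
}

#' Names of the synaptic coupling parameters
#' @return Character vector of the eight coupling names.
#' @export
ct_coupling_names <- function() {
  c("nu_ee", "nu_ei", "nu_es", "nu_se", "nu_sr", "nu_sn", "nu_re", "nu_rs")
}

#' Read or write model parameters as a flat key-value YAML file
#'
#' One key per model symbol, in the model's SI-consistent units (mV, 1/s, s,
#' mV s). Unknown keys are rejected so unit mistakes (e.g. `t0` in ms) cannot
#' pass silently as extra entries.
#'
#' @param path File path.
#' @return `read_ct_params()` returns a `ct_params` object;
#'   `write_ct_params()` returns `path` invisibly.
#' @export
read_ct_params <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(ct_params))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown parameter key(s) in ", path, ": ", paste(bad, collapse = ", "))
  do.call(ct_params, raw)
}

#' @param params A `ct_params` object.
#' @rdname read_ct_params
#' @export
write_ct_params <- function(params, path) {
  stopifnot(inherits(params, "ct_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
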