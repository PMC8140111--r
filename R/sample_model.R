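#' Ground-truth mechanical models of the aspirated sample
#'
#' Three constitutive variants drive the forward simulator:
#' \describe{
#'   \item{elastic}{a single Young's modulus `E` (Pa); the aspirated length is
#'     proportional to the suction pressure at all times.}
#'   \item{fixed complex}{a per-frequency table of storage (`E'`) and loss
#'     (`E''`) moduli; oscillatory response has amplitude `|E*|` and phase lag
#'     `arg E*` at each tabulated frequency.}
#'   \item{power law}{a two-term power-law complex modulus
#'     `E*(w) = A (i w)^alpha + B (i w)^(3/4)`, the soft-matter rheology form
#'     with a weak low-frequency dispersion and a 3/4-exponent high-frequency
#'     term.}
#' }
#' The sample is assumed incompressible (Poisson ratio 0.5, not settable);
#' `sample_radius` is the radius R_c of the aspirated body, `Inf` for the
#' half-space limit.
#'
#' @param E Young's modulus (Pa), > 0.
#' @param sample_radius Radius R_c of the aspirated body (m) or `Inf`.
#' @return An object of class `sample_model`.
#' @export
elastic_sample <- function(E, sample_radius = Inf) {
  if (!is.finite(E) || E <= 0) stop("elastic modulus must be > 0")
  new_sample_model("elastic", sample_radius, E = E)
}

#' @rdname elastic_sample
#' @param frequency_hz Tabulated test frequencies (Hz).
#' @param E_prime,E_loss Storage and loss moduli (Pa) at `frequency_hz`.
#' @export
complex_sample <- function(frequency_hz, E_prime, E_loss,
                           sample_radius = Inf) {
  stopifnot(length(frequency_hz) == length(E_prime),
            length(frequency_hz) == length(E_loss))
  if (any(frequency_hz <= 0)) stop("frequencies must be > 0")
  if (any(E_prime <= 0) || any(E_loss < 0)) {
    stop("require E' > 0 and E'' >= 0")
  }
  o <- order(frequency_hz)
  new_sample_model("fixed_complex", sample_radius,
                   table = data.frame(frequency_hz = frequency_hz[o],
                                      E_prime = E_prime[o],
                                      E_loss = E_loss[o]))
}

#' @rdname elastic_sample
#' @param A,alpha,B Power-law parameters: amplitudes `A`, `B` in Pa
#'   (non-negative) and exponent `alpha` in \[0, 1\].
#' @param convention Unit in which the angular frequency enters the power
#'   law: `"rad_s"` (default) or `"hz"`.
#' @export
power_law_sample <- function(A, alpha, B, sample_radius = Inf,
                             convention = c("rad_s", "hz")) {
  convention <- match.arg(convention)
  if (A < 0 || B < 0) stop("power-law amplitudes must be >= 0")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  new_sample_model("power_law", sample_radius,
                   A = A, alpha = alpha, B = B, convention = convention)
}

new_sample_model <- function(variant, sample_radius, ...) {
  if (!(is.infinite(sample_radius) || sample_radius > 0)) {
    stop("sample radius must be > 0 or Inf")
  }
  structure(
    c(list(variant = variant, sample_radius = sample_radius,
           poisson_ratio = 0.5), list(...)),
    class = "sample_model"
  )
}

#' @export
print.sample_model <- function(x, ...) {
  rc <- if (is.infinite(x$sample_radius)) "half-space" else
    sprintf("R_c = %g um", x$sample_radius * 1e6)
  hdr <- switch(x$variant,
    elastic = sprintf("elastic, E = %g kPa", x$E / 1e3),
    fixed_complex = sprintf("fixed complex modulus at %d frequencies",
                            nrow(x$table)),
    power_law = sprintf("power law, A = %g kPa, alpha = %g, B = %g kPa (%s)",
                        x$A / 1e3, x$alpha, x$B / 1e3, x$convention))
  cat(sprintf("<sample_model> %s | %s, nu = 0.5\n", hdr, rc))
  invisible(x)
}

#' Complex modulus of a sample model at a frequency
#'
#' @param model A [sample_model()] object (see [elastic_sample()]).
#' @param frequency_hz Test frequency (Hz), > 0 for viscoelastic variants.
#' @return Complex modulus `E*` (Pa) as a complex number; for the
#'   fixed-complex variant the frequency must match a tabulated one.
#' @export
modulus_at <- function(model, frequency_hz) {
  stopifnot(inherits(model, "sample_model"))
  switch(model$variant,
    elastic = complex(real = rep(model$E, length(frequency_hz)),
                      imaginary = 0),
    fixed_complex = {
      idx <- vapply(frequency_hz, function(f) {
        j <- which(abs(model$table$frequency_hz - f) <=
                     1e-9 * pmax(1, abs(f)))
        if (length(j) != 1L) {
          stop(sprintf("frequency %g Hz not defined in the modulus table", f))
        }
        j
      }, 1L)
      complex(real = model$table$E_prime[idx],
              imaginary = model$table$E_loss[idx])
    },
    power_law = power_law_eval(frequency_hz, model$A, model$alpha, model$B,
                               convention = model$convention)
  )
}
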