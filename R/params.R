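#' @useDynLib ikrfit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim optimize rnorm runif setNames coef lm sd
#' @importFrom utils read.csv write.table modifyList
NULL

## Physical constants (CODATA 2018), monovalent cation.
R_GAS <- 8.314462618    # J K^-1 mol^-1
FARADAY <- 96485.33212  # C mol^-1

#' Kinetic parameters of the two-gate IKr model
#'
#' The model has four voltage-dependent transition rates
#' \eqn{k_1 = p_1 e^{p_2 V}}, \eqn{k_2 = p_3 e^{-p_4 V}},
#' \eqn{k_3 = p_5 e^{p_6 V}}, \eqn{k_4 = p_7 e^{-p_8 V}}
#' (activation: k1 forward / k2 backward; inactivation: k3 forward /
#' k4 backward), and a maximal conductance \eqn{p_9 = g_{Kr}} so that
#' \eqn{I = p_9\, a\, r\,(V - E_K)}. Units are ms^-1 for the rate
#' pre-factors, mV^-1 for the voltage sensitivities, and the conductance
#' unit fixes the current unit (nanoamps when gKr is in microsiemens and
#' V in millivolts).
#'
#' @param p1,p2,p3,p4,p5,p6,p7,p8,p9 strictly positive scalars, or a single
#'   numeric vector of length 9 passed as `p1`.
#' @return a named numeric vector of class `ikr_params`.
#' @export
ikr_params <- function(p1, p2, p3, p4, p5, p6, p7, p8, p9) {
  if (length(p1) == 9 && missing(p2)) {
    p <- as.numeric(p1)
  } else {
    p <- c(p1, p2, p3, p4, p5, p6, p7, p8, p9)
  }
  names(p) <- paste0("p", 1:9)
  validate_params(p)
  structure(p, class = "ikr_params")
}

validate_params <- function(p) {
  if (length(p) != 9) stop("expected 9 parameters p1..p9")
  if (!all(is.finite(p))) stop("parameters must be finite")
  if (any(p <= 0)) stop("all parameters must be strictly positive")
  invisible(p)
}

#' @export
print.ikr_params <- function(x, ...) {
  cat("IKr model parameters (p1..p8 kinetics, p9 = gKr):\n")
  print(signif(unclass(x), 6))
  invisible(x)
}

#' Read / write parameter sets as JSON
#'
#' Plain-text serialization with keys `p1`..`p9`.
#'
#' @param params an [ikr_params] vector.
#' @param path file path.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  jsonlite::write_json(as.list(unclass(params)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ikr_params(as.numeric(x[paste0("p", 1:9)]))
}

#' Nernst reversal potential for potassium
#'
#' \eqn{E_K = (RT/F)\,\ln([K^+]_o/[K^+]_i)}, returned in millivolts.
#'
#' @param K_out,K_in external / internal potassium concentration (mM).
#' @param T_kelvin absolute temperature (K).
#' @export
nernst <- function(K_out, K_in, T_kelvin) {
  if (any(c(K_out, K_in, T_kelvin) <= 0))
    stop("concentrations and temperature must be positive")
  1000 * (R_GAS * T_kelvin / FARADAY) * log(K_out / K_in)
}

#' Ionic conditions for a recording
#'
#' The defaults give E_K of about -88.4 mV (room-temperature CHO-cell
#' recording solutions); all values are configuration, not asserted truth.
#'
#' @param K_out,K_in potassium concentrations in mM.
#' @param T_kelvin absolute temperature in K.
#' @export
ionic_conditions <- function(K_out = 4, K_in = 130, T_kelvin = 294.65) {
  structure(list(K_out = K_out, K_in = K_in, T_kelvin = T_kelvin,
                 E_K = nernst(K_out, K_in, T_kelvin)),
            class = "ikr_conditions")
}
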