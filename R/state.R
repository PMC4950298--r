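#' Heritable cytotype frequency state
#'
#' A population state is a frequency vector over the four heritable
#' cytoplasm types: `A1`/`A2` (singly infected, haplotype HT1/HT2) and
#' `B1`/`B2` (doubly infected, haplotype HT1/HT2). Frequencies must be
#' non-negative and sum to 1 (checked to `tol`, then renormalized exactly).
#'
#' @param a1,a2,b1,b2 Frequencies of the four heritable cytotypes.
#' @param tol Tolerance on the input sum; default `1e-8`.
#' @return A named numeric vector of class `"cyto_state"` with components
#'   `a1`, `a2`, `b1`, `b2`.
#' @examples
#' cytotype_state(a1 = 0.99, b2 = 0.01)
#' @export
cytotype_state <- function(a1 = 0, a2 = 0, b1 = 0, b2 = 0, tol = 1e-8) {
  x <- c(a1 = a1, a2 = a2, b1 = b1, b2 = b2)
  if (any(!is.finite(x)) || any(x < -tol))
    stop("cytotype frequencies must be finite and non-negative", call. = FALSE)
  s <- sum(x)
  if (abs(s - 1) > tol)
    stop(sprintf("cytotype frequencies must sum to 1 (got %.10g)", s),
         call. = FALSE)
  structure(pmax(x, 0) / s, class = "cyto_state")
}

#' Observed (PCR-visible) cytotype frequencies of a state
#'
#' Somatic infections are PCR-detectable but not heritable: under a somatic
#' acquisition rate a fraction of singly infected individuals scores as
#' doubly infected at census time without entering the mating dynamics.
#' The observed overlay moves `s * A_h` from each singly infected class to
#' the doubly infected class of the same haplotype, where
#' `s = beta * (1 - alpha)` for constant-rate acquisition and
#' `s = beta * (1 - alpha) * (b1 + b2)` for contact-dependent acquisition.
#'
#' @param state A [cytotype_state()].
#' @param params A [model_params()] object.
#' @return Named numeric vector `c(a1, a2, b1, b2)` of observed frequencies
#'   (summing to 1).
#' @examples
#' observed_frequencies(cytotype_state(a1 = 1),
#'                      model_params(beta = 0.3, alpha = 0))
#' @export
observed_frequencies <- function(state, params) {
  stopifnot(inherits(state, "cyto_state"), inherits(params, "cyto_params"))
  x <- unclass(state)
  s <- params$beta * (1 - params$alpha)
  if (params$acquisition == "contact") s <- s * (x[["b1"]] + x[["b2"]])
  c(a1 = x[["a1"]] * (1 - s),
    a2 = x[["a2"]] * (1 - s),
    b1 = x[["b1"]] + s * x[["a1"]],
    b2 = x[["b2"]] + s * x[["a2"]])
}

#' @export
print.cyto_state <- function(x, ...) {
  cat("Cytotype state (heritable frequencies)\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Fraction of individuals showing the mismatched infection--haplotype
#' combination
#'
#' The mismatch is the doubly infected state co-occurring with haplotype
#' HT1 -- the combination not expected under strict maternal co-inheritance
#' when the invading strain entered linked to HT2. Computed on the observed
#' (somatic-inclusive) frequencies.
#'
#' @param state A [cytotype_state()].
#' @param params A [model_params()] object (supplies the somatic overlay).
#' @param denominator `"all"`: fraction of all individuals; `"infected"`:
#'   fraction of observed doubly infected individuals.
#' @return A single number in \[0, 1\], or `NA_real_` when the chosen
#'   denominator is zero.
#' @examples
#' st <- cytotype_state(b1 = 0.2, b2 = 0.8)
#' mismatch_fraction(st, model_params())              # 0.2
#' mismatch_fraction(st, model_params(), "infected")  # 0.2
#' @export
mismatch_fraction <- function(state, params,
                              denominator = c("all", "infected")) {
  denominator <- match.arg(denominator)
  o <- observed_frequencies(state, params)
  if (denominator == "all") return(o[["b1"]])
  den <- o[["b1"]] + o[["b2"]]
  if (den == 0) return(NA_real_)
  o[["b1"]] / den
}
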