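#' Model parameters for the cytotype invasion recursions
#'
#' Bundles every dynamical parameter of the discrete-generation model in one
#' validated record. The host population carries two heritable infection
#' states -- singly infected (resident strain only, "A") and doubly infected
#' (resident plus invading strain, "B") -- crossed with two mitochondrial
#' haplotypes (HT1, HT2). Crosses of doubly infected males with singly
#' infected females are incompatible: a fraction `l_ci` of their eggs die.
#'
#' @param l_ci Level of cytoplasmic incompatibility: fraction of eggs dying
#'   in incompatible crosses, in \[0, 1\].
#' @param mu Maternal transmission leakage of the invading strain, in
#'   \[0, 1\]; the maternal transmission rate is `1 - mu`.
#' @param f_a Relative fecundity of singly infected females (> 0).
#' @param f_b Relative fecundity of doubly infected females (> 0).
#' @param tau Paternal transmission probability, in \[0, 1\]: offspring that
#'   did not inherit the invading strain maternally acquire it from a doubly
#'   infected father with this probability.
#' @param alpha Probability that a horizontally acquired infection reaches
#'   the germline and becomes heritable, in \[0, 1\]. Acquisitions with
#'   probability `1 - alpha` remain somatic: PCR-detectable at census but
#'   neither transmitted nor CI-active.
#' @param beta Per-generation horizontal acquisition probability for singly
#'   infected individuals, in \[0, 1\].
#' @param acquisition Either `"constant"` (default): every singly infected
#'   individual acquires with probability `beta` per generation; or
#'   `"contact"`: the per-capita acquisition probability is `beta` times the
#'   current frequency of heritably doubly infected individuals (mass
#'   action, acquisition requires an infected donor).
#'
#' @return An object of class `"cyto_params"` (a named list).
#' @seealso [scenario_params()] for the three named transmission scenarios.
#' @examples
#' model_params(l_ci = 0.98, tau = 0.3)
#' @export
model_params <- function(l_ci = 0.98, mu = 0, f_a = 1, f_b = 1,
                         tau = 0, alpha = 0, beta = 0,
                         acquisition = c("constant", "contact")) {
  acquisition <- match.arg(acquisition)
  probs <- c(l_ci = l_ci, mu = mu, tau = tau, alpha = alpha, beta = beta)
  for (nm in names(probs)) {
    v <- probs[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a single number in [0, 1]", nm), call. = FALSE)
  }
  for (nm in c("f_a", "f_b")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  }
  structure(
    list(l_ci = l_ci, mu = mu, f_a = f_a, f_b = f_b,
         tau = tau, alpha = alpha, beta = beta, acquisition = acquisition),
    class = "cyto_params"
  )
}

#' Parameter sets for the three named transmission scenarios
#'
#' Returns the parameterization of the three model extensions used for the
#' joint infection--haplotype dynamics: paternal transmission
#' (`tau = 0.3, beta = 0`), heritable horizontal transmission
#' (`tau = 0, alpha = 1, beta = 0.015`) and somatic horizontal transmission
#' (`tau = 0, alpha = 0, beta = 0.3`), each with `l_ci = 0.98`, `mu = 0`
#' and no fecundity effects (`f_a = f_b = 1`).
#'
#' @param scenario One of `"paternal"`, `"heritable"`, `"somatic"`.
#' @param ... Overrides passed on to [model_params()] (e.g. `acquisition`).
#' @return A `"cyto_params"` object.
#' @examples
#' scenario_params("paternal")
#' @export
scenario_params <- function(scenario = c("paternal", "heritable", "somatic"),
                            ...) {
  scenario <- match.arg(scenario)
  base <- switch(scenario,
    paternal  = list(tau = 0.3, alpha = 0, beta = 0),
    heritable = list(tau = 0, alpha = 1, beta = 0.015),
    somatic   = list(tau = 0, alpha = 0, beta = 0.3)
  )
  args <- utils::modifyList(
    c(list(l_ci = 0.98, mu = 0, f_a = 1, f_b = 1), base),
    list(...)
  )
  do.call(model_params, args)
}

#' @export
print.cyto_params <- function(x, ...) {
  cat("Cytotype model parameters\n")
  cat(sprintf("  l_CI = %g, mu = %g, F_A = %g, F_B = %g\n",
              x$l_ci, x$mu, x$f_a, x$f_b))
  cat(sprintf("  tau = %g, alpha = %g, beta = %g (%s acquisition)\n",
              x$tau, x$alpha, x$beta, x$acquisition))
  invisible(x)
}
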