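#' Advance the cytotype state by one generation
#'
#' One generation applies, in order: (1) horizontal acquisition -- a
#' fraction of each singly infected class acquires the invading strain; the
#' heritable share (`alpha`) converts to the doubly infected class of the
#' same haplotype, the somatic remainder appears only in the observed
#' overlay; (2) random mating over heritable types through the mating
#' table; (3) renormalization by mean reproductive output.
#'
#' @param state A [cytotype_state()] (normalized).
#' @param params A [model_params()] object.
#' @param mating_table Optional precomputed [build_mating_table()] result
#'   for `params` (recomputed when omitted).
#' @return The next generation's `"cyto_state"`.
#' @examples
#' step_cytotypes(cytotype_state(a1 = 0.5, b2 = 0.5),
#'                model_params(l_ci = 0.98))
#' @export
step_cytotypes <- function(state, params, mating_table = NULL) {
  stopifnot(inherits(state, "cyto_state"), inherits(params, "cyto_params"))
  if (is.null(mating_table)) mating_table <- build_mating_table(params)
  x <- unclass(state)

  # (1) heritable horizontal acquisition
  rate <- params$beta
  if (params$acquisition == "contact") rate <- rate * (x[["b1"]] + x[["b2"]])
  conv <- params$alpha * rate
  x <- c(a1 = x[["a1"]] * (1 - conv),
         a2 = x[["a2"]] * (1 - conv),
         b1 = x[["b1"]] + conv * x[["a1"]],
         b2 = x[["b2"]] + conv * x[["a2"]])

  # (2) random mating over heritable types
  pair <- x[mating_table$mother] * x[mating_table$father] * mating_table$weight
  off <- c(a1 = sum(pair * mating_table$off_a1),
           a2 = sum(pair * mating_table$off_a2),
           b1 = sum(pair * mating_table$off_b1),
           b2 = sum(pair * mating_table$off_b2))

  # (3) normalize by mean reproductive output
  tot <- sum(off)
  if (tot <= 0)
    stop("total reproductive output is zero (all matings incompatible)",
         call. = FALSE)
  structure(off / tot, class = "cyto_state")
}

#' Classic single-strain CI invasion recursion
#'
#' The haplotype-free reduction of the model: frequency dynamics of a
#' CI-inducing strain in a panmictic population under imperfect maternal
#' transmission and a relative fecundity effect,
#' `p' = F p (1 - mu) / (F p + (1 - p) (1 - l_ci p))`.
#' With `tau = beta = 0`, aggregating [step_cytotypes()] over haplotypes
#' reproduces this map exactly (with `F = f_b / f_a`).
#'
#' @param p Current infection frequency (vectorized), in \[0, 1\].
#' @param l_ci CI level in \[0, 1\].
#' @param mu Maternal transmission leakage in \[0, 1\].
#' @param f Relative fecundity of infected females (> 0).
#' @return Next-generation frequency (same length as `p`).
#' @examples
#' classic_ci_recursion(0.5, l_ci = 0.98)  # 0.6623
#' @export
classic_ci_recursion <- function(p, l_ci, mu = 0, f = 1) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("'p' must be in [0, 1]", call. = FALSE)
  den <- f * p + (1 - p) * (1 - l_ci * p)
  if (any(den <= 0)) stop("non-positive mean fitness", call. = FALSE)
  f * p * (1 - mu) / den
}

#' Iterate the cytotype recursion to convergence
#'
#' Runs [step_cytotypes()] from an initial state until the maximum
#' component-wise change falls below `tol` or `max_gens` generations have
#' been computed, recording every generation.
#'
#' @param initial A [cytotype_state()]; defaults to a rare doubly infected
#'   HT2-linked founder entering a singly infected HT1 population
#'   (`b2 = p0`, `a1 = 1 - p0` with `p0 = 0.01`).
#' @param params A [model_params()] object.
#' @param max_gens Maximum number of generations (default 10000).
#' @param tol Convergence tolerance on the component-wise change
#'   (default `1e-10`).
#' @return An object of class `"cyto_trajectory"`: a list with `states`
#'   (list of `"cyto_state"`, generation 0 first), `params`, `converged`,
#'   and a data-frame view via [as.data.frame()].
#' @examples
#' run_scenario(params = scenario_params("paternal"))
#' @export
run_scenario <- function(initial = cytotype_state(a1 = 0.99, b2 = 0.01),
                         params = model_params(),
                         max_gens = 10000L, tol = 1e-10) {
  stopifnot(inherits(initial, "cyto_state"), inherits(params, "cyto_params"))
  if (max_gens < 1L) stop("'max_gens' must be >= 1", call. = FALSE)
  mt <- build_mating_table(params)
  states <- vector("list", max_gens + 1L)
  states[[1L]] <- initial
  converged <- FALSE
  n <- 1L
  x <- initial
  for (g in seq_len(max_gens)) {
    xn <- step_cytotypes(x, params, mt)
    n <- n + 1L
    states[[n]] <- xn
    if (max(abs(unclass(xn) - unclass(x))) < tol) {
      converged <- TRUE
      x <- xn
      break
    }
    x <- xn
  }
  structure(list(states = states[seq_len(n)], params = params,
                 converged = converged, tol = tol),
            class = "cyto_trajectory")
}

#' @export
print.cyto_trajectory <- function(x, ...) {
  ng <- length(x$states) - 1L
  fin <- unclass(x$states[[length(x$states)]])
  cat(sprintf("Cytotype trajectory: %d generations, %s\n", ng,
              if (x$converged) "converged" else "not converged"))
  cat("  final state:", paste(sprintf("%s=%.4g", names(fin), fin),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate a trajectory generation by generation
#'
#' @param x A `"cyto_trajectory"` from [run_scenario()].
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A data frame with columns `generation`, heritable frequencies
#'   `x_a1 ... x_b2`, observed doubly infected frequencies `o_b1`, `o_b2`,
#'   `wcer2_freq` (observed doubly infected total), and the mismatch
#'   fraction under both denominators (`mismatch_all`,
#'   `mismatch_infected`).
#' @export
as.data.frame.cyto_trajectory <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  h <- do.call(rbind, lapply(x$states, unclass))
  o <- do.call(rbind, lapply(x$states, observed_frequencies,
                             params = x$params))
  inf <- o[, "b1"] + o[, "b2"]
  data.frame(
    generation = seq_len(nrow(h)) - 1L,
    x_a1 = h[, "a1"], x_a2 = h[, "a2"], x_b1 = h[, "b1"], x_b2 = h[, "b2"],
    o_b1 = o[, "b1"], o_b2 = o[, "b2"],
    wcer2_freq = inf,
    mismatch_all = o[, "b1"],
    mismatch_infected = ifelse(inf == 0, NA_real_, o[, "b1"] / inf)
  )
}

#' Peak of the mismatch fraction along a trajectory
#'
#' @param traj A `"cyto_trajectory"` from [run_scenario()].
#' @param denominator `"all"` or `"infected"` (see [mismatch_fraction()]).
#' @return A list with `generation` (0-based, earliest in case of ties) and
#'   `value`. `NA` mismatch values (empty denominator) are skipped; if all
#'   are `NA` the peak value is `NA_real_` at generation 0.
#' @examples
#' peak_mismatch(run_scenario(params = scenario_params("somatic")))
#' @export
peak_mismatch <- function(traj, denominator = c("all", "infected")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(traj, "cyto_trajectory"))
  v <- vapply(traj$states, mismatch_fraction, numeric(1),
              params = traj$params, denominator = denominator)
  if (all(is.na(v))) return(list(generation = 0L, value = NA_real_))
  i <- which.max(v)   # first maximum; NAs never selected
  list(generation = i - 1L, value = v[[i]])
}
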