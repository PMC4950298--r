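#' Build the mating table for the four-cytotype model
#'
#' Enumerates all 16 mother x father cytotype pairs with their relative
#' reproductive output and the distribution of offspring cytotypes,
#' encoding the model's transmission rules:
#' \itemize{
#'   \item mitochondrial haplotype is strictly maternal;
#'   \item doubly infected (B) mothers transmit the invading strain to each
#'     offspring with probability `1 - mu`;
#'   \item crosses of singly infected (A) mothers with B fathers are
#'     incompatible: output is weighted by `f_a * (1 - l_ci)`;
#'   \item offspring of a B father that did not inherit the invading strain
#'     maternally acquire it paternally with probability `tau`, keeping the
#'     maternal haplotype;
#'   \item all other crosses are fully compatible, weighted by the mother's
#'     fecundity (`f_a` or `f_b`).
#' }
#'
#' @param params A [model_params()] object.
#' @return A data frame of class `"cyto_mating_table"` with one row per
#'   (mother, father) pair and columns `mother`, `father`, `weight`, and
#'   offspring probabilities `off_a1`, `off_a2`, `off_b1`, `off_b2`
#'   (each row's offspring distribution sums to 1).
#' @examples
#' build_mating_table(scenario_params("paternal"))
#' @export
build_mating_table <- function(params) {
  stopifnot(inherits(params, "cyto_params"))
  types <- c("a1", "a2", "b1", "b2")
  hap   <- c(a1 = 1L, a2 = 2L, b1 = 1L, b2 = 2L)
  inf   <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  rows <- vector("list", 16L)
  k <- 0L
  for (m in types) for (f in types) {
    h <- hap[[m]]                       # offspring haplotype: maternal
    off <- c(a1 = 0, a2 = 0, b1 = 0, b2 = 0)
    if (inf[[m]] == "A") {
      if (inf[[f]] == "A") {
        w <- params$f_a
        off[h] <- 1                     # A mother, compatible: A offspring
      } else {
        w <- params$f_a * (1 - params$l_ci)   # incompatible cross
        off[2L + h] <- params$tau             # paternal rescue of survivors
        off[h]      <- 1 - params$tau
      }
    } else {
      w <- params$f_b
      p_double <- 1 - params$mu
      if (inf[[f]] == "B")              # maternal leak can be repaired
        p_double <- p_double + params$mu * params$tau
      off[2L + h] <- p_double
      off[h]      <- 1 - p_double
    }
    k <- k + 1L
    rows[[k]] <- data.frame(mother = m, father = f, weight = w,
                            off_a1 = off[["a1"]], off_a2 = off[["a2"]],
                            off_b1 = off[["b1"]], off_b2 = off[["b2"]],
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("cyto_mating_table", "data.frame")
  tab
}
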