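# Survey tables: one row per genotyped fly with categorical columns
# population, period, zone, host_plant, infection, haplotype.

.survey_levels <- list(
  period    = c("1998/1999", "2000/2001", "2008", "2014"),
  zone      = c("fixed", "transition"),
  host_plant = c("Prunus", "Lonicera", "unknown"),
  infection = c("single", "double"),
  haplotype = c("HT1", "HT2", "untyped")
)

#' Validate an individual-level survey table
#'
#' Checks that a data frame has the survey columns (`population`,
#' `period`, `zone`, `host_plant`, `infection`, `haplotype`) and that
#' every categorical column is restricted to its allowed levels.
#' Individuals may be haplotype-`untyped` (e.g. collections screened for
#' infection only); they are kept in infection denominators but excluded
#' from haplotype denominators by the summary functions.
#'
#' @param records A data frame of individual records.
#' @return The validated data frame (invisibly unchanged), with character
#'   columns.
#' @export
validate_survey <- function(records) {
  need <- c("population", names(.survey_levels))
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("survey lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in names(.survey_levels)) {
    v <- as.character(records[[col]])
    bad <- setdiff(unique(v), .survey_levels[[col]])
    if (length(bad))
      stop(sprintf("invalid %s value(s): %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    records[[col]] <- v
  }
  records$population <- as.character(records$population)
  records
}

#' Round a percentage half-up to one decimal
#'
#' Reporting convention for survey percentages (e.g. 14/64 -> 21.9);
#' half-way cases round away from zero rather than to even.
#'
#' @param x Percentages.
#' @param digits Decimal places (default 1).
#' @return Rounded values.
#' @export
percent_round <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Stratified infection-by-haplotype association summary
#'
#' Counts, per stratum, the association between infection status and
#' mitochondrial haplotype: totals, doubly infected individuals, the
#' mismatched doubly infected/HT1 class, singly infected individuals and
#' the reciprocal single/HT2 class, with percentages on haplotyped
#' denominators. Haplotype-`untyped` individuals count towards `n` and the
#' infection totals but never towards haplotype denominators.
#'
#' @param records A survey data frame (see [validate_survey()]).
#' @param strata Character vector of stratifying columns (default
#'   `"zone"`); use `character(0)` for a single pooled stratum.
#' @return A data frame with one row per stratum (deterministic order:
#'   sorted by the stratum columns) and columns `n`, `n_double`,
#'   `n_double_typed`, `n_double_ht1`, `pct_double_ht1`, `n_single`,
#'   `n_single_typed`, `n_single_ht2`, `pct_single_ht2`. Percentages are
#'   `NA` where the haplotyped denominator is empty.
#' @examples
#' summarize_association(transition_zone_survey(), strata = "period")
#' @export
summarize_association <- function(records, strata = "zone") {
  records <- validate_survey(records)
  ok <- c("population", names(.survey_levels))
  bad <- setdiff(strata, ok)
  if (length(bad))
    stop("unknown stratum field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  key <- if (length(strata)) {
    interaction(records[strata], drop = TRUE, sep = "\r", lex.order = TRUE)
  } else {
    factor(rep("all", nrow(records)))
  }
  groups <- split(records, key)
  out <- lapply(names(groups), function(k) {
    g <- groups[[k]]
    typed <- g$haplotype != "untyped"
    dbl <- g$infection == "double"
    sgl <- g$infection == "single"
    n_dt <- sum(dbl & typed)
    n_st <- sum(sgl & typed)
    n_d1 <- sum(dbl & g$haplotype == "HT1")
    n_s2 <- sum(sgl & g$haplotype == "HT2")
    stats <- data.frame(
      n = nrow(g),
      n_double = sum(dbl), n_double_typed = n_dt, n_double_ht1 = n_d1,
      pct_double_ht1 = if (n_dt > 0)
        percent_round(100 * n_d1 / n_dt) else NA_real_,
      n_single = sum(sgl), n_single_typed = n_st, n_single_ht2 = n_s2,
      pct_single_ht2 = if (n_st > 0)
        percent_round(100 * n_s2 / n_st) else NA_real_
    )
    if (!length(strata)) return(stats)
    lab <- stats::setNames(as.list(strsplit(k, "\r", fixed = TRUE)[[1L]]),
                           strata)
    cbind(as.data.frame(lab, stringsAsFactors = FALSE), stats)
  })
  res <- do.call(rbind, out)
  if (length(strata))
    res <- res[do.call(order, res[strata]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact hypergeometric p-value (probability-based tail
#' aggregation: the sum over tables whose conditional probability does not
#' exceed the observed table's). The reported odds ratio is the sample
#' odds ratio with a 0.5 continuity value added to every cell; it plays no
#' role in the p-value.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return A list with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact(matrix(c(9, 3, 20, 63), nrow = 2))
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("'table' must be 2x2", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("a margin of the table is all zero", call. = FALSE)
  or <- (table[1, 1] + 0.5) * (table[2, 2] + 0.5) /
        ((table[1, 2] + 0.5) * (table[2, 1] + 0.5))
  p <- stats::fisher.test(table, alternative = "two.sided")$p.value
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Host-plant contrast of the mismatched class among doubly infected flies
#'
#' Among haplotyped doubly infected individuals with a known host plant,
#' tabulates the HT1 (mismatch) percentage per host plant and tests the
#' 2x2 host-plant x haplotype table with [fisher_exact()].
#'
#' @param records A survey data frame; rows with `host_plant = "unknown"`
#'   or untyped haplotype are dropped from the contrast.
#' @return A list with `summary` (one row per host plant: `n_double_typed`,
#'   `n_double_ht1`, `pct_double_ht1`), `odds_ratio` and `p_value`.
#' @examples
#' host_plant_contrast(transition_zone_survey())
#' @export
host_plant_contrast <- function(records) {
  records <- validate_survey(records)
  keep <- records$infection == "double" & records$haplotype != "untyped" &
    records$host_plant != "unknown"
  d <- records[keep, , drop = FALSE]
  plants <- c("Lonicera", "Prunus")
  if (!all(plants %in% d$host_plant))
    stop("both host-plant classes must be present among typed doubly ",
         "infected individuals", call. = FALSE)
  tab <- vapply(plants, function(pl) {
    g <- d[d$host_plant == pl, ]
    c(n = nrow(g), ht1 = sum(g$haplotype == "HT1"))
  }, numeric(2))
  summ <- data.frame(
    host_plant = plants,
    n_double_typed = tab["n", ],
    n_double_ht1 = tab["ht1", ],
    pct_double_ht1 = percent_round(100 * tab["ht1", ] / tab["n", ]),
    row.names = NULL
  )
  m <- matrix(c(tab["ht1", ], tab["n", ] - tab["ht1", ]), nrow = 2,
              dimnames = list(plants, c("HT1", "HT2")))
  ft <- fisher_exact(m)
  list(summary = summ, odds_ratio = ft$odds_ratio, p_value = ft$p_value)
}

#' Read / write individual-level survey tables
#'
#' Tab-separated with a header row is the canonical on-disk form; comma-
#' separated input is accepted (the delimiter is sniffed from the header).
#'
#' @param path File path.
#' @return `read_survey()` returns a validated data frame.
#' @export
read_survey <- function(path) {
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  validate_survey(utils::read.table(path, header = TRUE, sep = sep,
                                    stringsAsFactors = FALSE))
}

#' @rdname read_survey
#' @param records A survey data frame.
#' @export
write_survey <- function(records, path) {
  utils::write.table(validate_survey(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
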