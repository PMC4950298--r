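# Synthetic data: survey generators with the statistical structure the
# analysis assumes (spatial infection cline, conditional haplotypes) and
# sequence fixtures for the PCR-RFLP assay, so every stage runs without
# any external download.

#' Logistic infection cline along a transect
#'
#' The expected doubly infected frequency at position `x` of a travelling
#' invasion front whose 5%-to-95% transition zone has width
#' `3 sigma / sqrt(l_ci)` (the wave-width relation):
#' a logistic curve centred at `centre` scaled so the 5% and 95% crossings
#' are that far apart.
#'
#' @param position Positions along the transect (km).
#' @param centre Cline centre (km).
#' @param sigma Dispersal standard deviation (km).
#' @param l_ci CI level in (0, 1\].
#' @param decreasing Front falling (rather than rising) with position.
#' @return Frequencies in (0, 1).
#' @examples
#' cline_frequency(seq(0, 200, 20), centre = 100, sigma = 25, l_ci = 0.98)
#' @export
cline_frequency <- function(position, centre, sigma, l_ci = 0.98,
                            decreasing = FALSE) {
  width <- 3 * sigma / sqrt(l_ci)
  k <- 2 * log(19) / width        # logistic 5-95% width = 2 log(19) / k
  p <- stats::plogis(k * (position - centre))
  if (decreasing) 1 - p else p
}

#' Build a survey design along a north--south transect
#'
#' Lays out sampling sites on a 1-D transect, assigns each the expected
#' doubly infected frequency from [cline_frequency()] (or explicit
#' frequencies), and attaches the conditional haplotype model: doubly
#' infected individuals carry the mismatched HT1 with probability
#' `p_mismatch` inside the declared transition interval (frequency between
#' `lo` and `hi`) and `p_mismatch_fixed` outside it; singly infected
#' individuals carry the reciprocal HT2 with probability `p_leak`.
#' Latitude is synthesized from position at 111.2 km/degree so the survey
#' and wave geometry stay consistent.
#'
#' @param positions Site positions (km), strictly increasing.
#' @param n_per_site Individuals genotyped per site (recycled).
#' @param centre,sigma,l_ci Cline parameters (see [cline_frequency()]).
#' @param freq_double Optional explicit per-site frequencies overriding
#'   the cline.
#' @param p_mismatch P(HT1 | double) inside the transition interval
#'   (default 0.2, the elevated level seen mid-invasion).
#' @param p_mismatch_fixed P(HT1 | double) outside it (default 0.01).
#' @param p_leak P(HT2 | single) everywhere (default 0.005).
#' @param lo,hi Frequency bounds declaring the transition interval.
#' @param period,host_plant Labels applied to all sites (recycled).
#' @param lat0 Latitude of position 0 (default 47).
#' @return A data frame of class `"survey_design"`, one row per site.
#' @export
survey_design <- function(positions, n_per_site = 30,
                          centre = NULL, sigma = 25, l_ci = 0.98,
                          freq_double = NULL,
                          p_mismatch = 0.2, p_mismatch_fixed = 0.01,
                          p_leak = 0.005, lo = 0.05, hi = 0.95,
                          period = "2008", host_plant = "Prunus",
                          lat0 = 47) {
  if (any(diff(positions) <= 0))
    stop("'positions' must be strictly increasing", call. = FALSE)
  if (is.null(freq_double)) {
    if (is.null(centre)) centre <- stats::median(positions)
    freq_double <- cline_frequency(positions, centre, sigma, l_ci)
  }
  if (length(freq_double) != length(positions))
    stop("one frequency per site is required", call. = FALSE)
  if (any(freq_double < 0 | freq_double > 1))
    stop("frequencies must be in [0, 1]", call. = FALSE)
  trans <- freq_double > lo & freq_double < hi
  d <- data.frame(
    site = sprintf("s%02d", seq_along(positions)),
    position = positions,
    lat = lat0 + positions / 111.2,
    lon = 10,
    period = rep_len(period, length(positions)),
    host_plant = rep_len(host_plant, length(positions)),
    n = rep_len(as.integer(n_per_site), length(positions)),
    freq_double = freq_double,
    zone = ifelse(trans, "transition", "fixed"),
    p_mismatch = ifelse(trans, p_mismatch, p_mismatch_fixed),
    p_leak = p_leak,
    stringsAsFactors = FALSE
  )
  class(d) <- c("survey_design", "data.frame")
  d
}

#' Draw an individual-level survey from a design
#'
#' For each site, the number of doubly infected individuals is binomial in
#' the site's cline frequency; haplotypes are then drawn conditionally on
#' infection status from the design's mismatch and leakage probabilities.
#' Fully reproducible for a given seed.
#'
#' @param design A [survey_design()] data frame.
#' @param seed Integer RNG seed (recorded in the result's attributes).
#' @return A survey data frame (see [validate_survey()]) with one row per
#'   individual; sites with `n = 0` contribute no rows but remain listed
#'   in the `design` attribute. Attributes: `seed`, `design`.
#' @examples
#' d <- survey_design(seq(0, 200, by = 25), n_per_site = 20)
#' head(generate_survey(d, seed = 1))
#' @export
generate_survey <- function(design, seed = 1L) {
  stopifnot(is.data.frame(design))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(nrow(design)), function(i) {
    s <- design[i, ]
    if (s$n <= 0) return(NULL)
    dbl <- stats::rbinom(1L, s$n, s$freq_double)
    sgl <- s$n - dbl
    hap_d <- if (dbl > 0)
      ifelse(stats::rbinom(dbl, 1L, s$p_mismatch) == 1L, "HT1", "HT2")
      else character(0)
    hap_s <- if (sgl > 0)
      ifelse(stats::rbinom(sgl, 1L, s$p_leak) == 1L, "HT2", "HT1")
      else character(0)
    data.frame(
      population = s$site,
      period = s$period,
      zone = s$zone,
      host_plant = s$host_plant,
      infection = c(rep("double", dbl), rep("single", sgl)),
      haplotype = c(hap_d, hap_s),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$population, out$infection, out$haplotype), ]
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  attr(out, "design") <- design
  validate_survey(out)
}

#' Synthetic COI amplicon pair for the PCR-RFLP assay
#'
#' Generates two 546-bp amplicon-like sequences that emulate the two real
#' mitochondrial haplotypes: identical except for a single transition at
#' the restriction site. The HT2-like sequence carries exactly one HaeIII
#' site (`GGCC`) cut after base 342 (fragments 342 + 204); the HT1-like
#' sequence has the site destroyed by a C-to-T transition and no `GGCC`
#' anywhere. These are synthetic stand-ins, not the real GenBank
#' sequences.
#'
#' @param seed Integer RNG seed (default 1).
#' @param length Amplicon length in bp (default 546).
#' @param cut_after Base after which the single cut falls (default 342).
#' @return A [Biostrings::DNAStringSet] with sequences `HT1_synthetic`
#'   and `HT2_synthetic`.
#' @examples
#' digest_amplicon(generate_fixture_amplicons()[["HT2_synthetic"]])
#' @export
generate_fixture_amplicons <- function(seed = 1L, length = 546L,
                                       cut_after = 342L) {
  if (cut_after < 2L || cut_after > length - 2L)
    stop("'cut_after' must leave room for the motif", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  base <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  # scrub any chance GGCC (breaking a C cannot create a new site)
  repeat {
    s <- paste(base, collapse = "")
    hit <- regexpr("GGCC", s, fixed = TRUE)
    if (hit == -1L) break
    base[as.integer(hit) + 2L] <- "A"
  }
  ht2 <- base
  ht2[(cut_after - 1L):(cut_after + 2L)] <- c("G", "G", "C", "C")
  ht1 <- ht2
  ht1[cut_after + 1L] <- "T"            # site-destroying C->T transition
  out <- Biostrings::DNAStringSet(c(
    HT1_synthetic = paste(ht1, collapse = ""),
    HT2_synthetic = paste(ht2, collapse = "")
  ))
  stopifnot(
    length(gregexpr("GGCC", as.character(out[[2]]), fixed = TRUE)[[1L]]) ==
      1L,
    gregexpr("GGCC", as.character(out[[1]]),
             fixed = TRUE)[[1L]][1L] == -1L
  )
  out
}

# Printed stratum counts from the German field survey, used to synthesize
# individual-level tables whose margins reproduce them exactly. Counts are
# sufficient statistics here; the joint period x host-plant split inside
# the transition zone is an arbitrary consistent completion.
.transition_doubles <- data.frame(
  period = c("2000/2001", "2000/2001", "2008", "2008", "2014", "2014"),
  host_plant = c("Lonicera", "Prunus", "Lonicera", "Prunus",
                 "Lonicera", "Prunus"),
  n = c(21L, 8L, 24L, 7L, 2L, 2L),
  n_ht1 = c(8L, 1L, 3L, 1L, 1L, 0L),
  stringsAsFactors = FALSE
)
.transition_singles <- data.frame(
  period = c("2000/2001", "2008", "2014"),
  n = c(100L, 90L, 8L),
  n_ht2 = c(0L, 1L, 0L),
  stringsAsFactors = FALSE
)
.outside_doubles <- data.frame(
  period = c("2000/2001", "2008", "2014"),
  n = c(66L, 200L, 10L),
  n_ht1 = c(3L, 1L, 0L),
  stringsAsFactors = FALSE
)

.expand_records <- function(zone, period, host_plant, infection,
                            n, n_alt, alt_hap) {
  main_hap <- if (alt_hap == "HT1") "HT2" else "HT1"
  hap <- c(rep(alt_hap, n_alt), rep(main_hap, n - n_alt))
  data.frame(
    population = sprintf("%s_%s", substr(zone, 1, 5), period),
    period = period, zone = zone, host_plant = host_plant,
    infection = infection, haplotype = hap, stringsAsFactors = FALSE
  )
}

#' Packaged survey tables reproducing the printed field counts
#'
#' Deterministic individual-level tables synthesized so that every
#' stratum margin matches the counts printed for the German survey:
#' within the transition zone 29, 31 and 4 haplotyped doubly infected
#' individuals across 2000/2001, 2008 and 2014 with 9, 4 and 1 carrying
#' the mismatched HT1 (pooled 14 of 64, 21.9%), split 47 from Lonicera
#' (12 HT1) and 17 from Prunus (2 HT1), plus 198 singly infected
#' individuals of which 197 carry HT1; outside the transition zone 66,
#' 200 and 10 doubly infected with 3, 1 and 0 HT1 (pooled 4 of 276).
#' Within-stratum record order is arbitrary and sorted for determinism.
#'
#' `outside_zone_survey()` contains only the doubly infected class (the
#' singly infected totals outside the zone are not tabulated per period
#' in the source counts).
#'
#' @return A survey data frame (see [validate_survey()]).
#' @examples
#' summarize_association(transition_zone_survey(), strata = character(0))
#' @export
transition_zone_survey <- function() {
  dbl <- do.call(rbind, lapply(seq_len(nrow(.transition_doubles)),
    function(i) {
      r <- .transition_doubles[i, ]
      .expand_records("transition", r$period, r$host_plant, "double",
                      r$n, r$n_ht1, "HT1")
    }))
  sgl <- do.call(rbind, lapply(seq_len(nrow(.transition_singles)),
    function(i) {
      r <- .transition_singles[i, ]
      .expand_records("transition", r$period, "unknown", "single",
                      r$n, r$n_ht2, "HT2")
    }))
  out <- rbind(dbl, sgl)
  out <- out[order(out$period, out$infection, out$host_plant,
                   out$haplotype), ]
  rownames(out) <- NULL
  validate_survey(out)
}

#' @rdname transition_zone_survey
#' @export
outside_zone_survey <- function() {
  out <- do.call(rbind, lapply(seq_len(nrow(.outside_doubles)),
    function(i) {
      r <- .outside_doubles[i, ]
      .expand_records("fixed", r$period, "unknown", "double",
                      r$n, r$n_ht1, "HT1")
    }))
  out <- out[order(out$period, out$haplotype), ]
  rownames(out) <- NULL
  validate_survey(out)
}

#' @rdname transition_zone_survey
#' @export
paper_survey_fixtures <- function() {
  rbind(transition_zone_survey(), outside_zone_survey())
}
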