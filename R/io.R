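# Tabular and config I/O tying the stages into a reproducible pipeline.
# TSV (tab, UTF-8, header row) is the canonical tabular dialect.

#' Write / read a trajectory table
#'
#' Serializes the generation-by-generation view of a trajectory (see
#' [as.data.frame.cyto_trajectory()]) as TSV.
#'
#' @param traj A `"cyto_trajectory"` or its data-frame view.
#' @param path File path.
#' @return `read_trajectory()` returns a data frame.
#' @export
write_trajectory <- function(traj, path) {
  if (inherits(traj, "cyto_trajectory")) traj <- as.data.frame(traj)
  utils::write.table(traj, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write / read a flat key-value scenario configuration
#'
#' A minimal `key = value` text format holding the model parameters,
#' initial state and run controls of a scenario, so a run can be restated
#' exactly.
#'
#' @param params A [model_params()] object.
#' @param initial A [cytotype_state()].
#' @param max_gens,tol Run controls (see [run_scenario()]).
#' @param denominator Mismatch denominator to report (`"all"` or
#'   `"infected"`).
#' @param path File path.
#' @return `read_scenario_config()` returns a list with `params`,
#'   `initial`, `max_gens`, `tol`, `denominator`.
#' @export
write_scenario_config <- function(params, initial, path,
                                  max_gens = 10000L, tol = 1e-10,
                                  denominator = "all") {
  stopifnot(inherits(params, "cyto_params"),
            inherits(initial, "cyto_state"))
  x <- unclass(initial)
  kv <- c(
    l_ci = params$l_ci, mu = params$mu, f_a = params$f_a, f_b = params$f_b,
    tau = params$tau, alpha = params$alpha, beta = params$beta,
    acquisition = params$acquisition,
    x_a1 = x[["a1"]], x_a2 = x[["a2"]], x_b1 = x[["b1"]], x_b2 = x[["b2"]],
    max_gens = max_gens, tol = tol, denominator = denominator
  )
  writeLines(sprintf("%s = %s", names(kv), as.character(kv)), path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), value = TRUE, invert = TRUE)
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  kv <- stats::setNames(trimws(vapply(parts, `[`, "", 2L)),
                        trimws(vapply(parts, `[`, "", 1L)))
  num <- function(k, default) if (k %in% names(kv))
    as.numeric(kv[[k]]) else default
  params <- model_params(
    l_ci = num("l_ci", 0.98), mu = num("mu", 0),
    f_a = num("f_a", 1), f_b = num("f_b", 1),
    tau = num("tau", 0), alpha = num("alpha", 0), beta = num("beta", 0),
    acquisition = if ("acquisition" %in% names(kv)) kv[["acquisition"]]
      else "constant"
  )
  initial <- cytotype_state(num("x_a1", 0.99), num("x_a2", 0),
                            num("x_b1", 0), num("x_b2", 0.01))
  list(params = params, initial = initial,
       max_gens = as.integer(num("max_gens", 10000)),
       tol = num("tol", 1e-10),
       denominator = if ("denominator" %in% names(kv))
         kv[["denominator"]] else "all")
}

#' Machine-readable provenance record for a pipeline run
#'
#' Collects parameters, seed and package version into a named list,
#' optionally written as JSON (when the jsonlite package is installed)
#' or as flat `key = value` text.
#'
#' @param params Named list of run parameters.
#' @param seed Integer seed used (or `NA`).
#' @param path Optional output path.
#' @return The provenance list, invisibly when written.
#' @export
run_provenance <- function(params = list(), seed = NA_integer_,
                           path = NULL) {
  prov <- list(
    package = "cytosweep",
    version = as.character(utils::packageVersion("cytosweep")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    params = params
  )
  if (is.null(path)) return(prov)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    flat <- c(package = prov$package, version = prov$version,
              timestamp = prov$timestamp, seed = as.character(seed),
              vapply(params, function(v) paste(as.character(v),
                                               collapse = ","), ""))
    writeLines(sprintf("%s = %s", names(flat), flat), path)
  }
  invisible(prov)
}
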