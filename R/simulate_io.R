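# Run configuration, seeded fixtures, and file output.
#
# A run is described by a flat YAML file (or an equivalent in-memory list):
#
#   n: 15
#   m: 3
#   scheme:
#     kind: classification        # single | n4m3 | n5m3 | classification
#     d: -5.9                     # number, per-type map, or lower_offset
#   p0: [0.48, 0.501, 0.019]      # or p0: random
#   generations: 10000
#   seed: 1                       # used only when p0 is random
#
# run_simulation() iterates the recursion and writes a trajectory CSV plus a
# JSON summary embedding the resolved configuration for provenance.

#' Draw a uniform random point on the simplex
#'
#' Symmetric Dirichlet(1) draw via normalised exponentials. When `seed` is
#' given the draw is fully determined by it (the global RNG state is left
#' untouched).
#'
#' @param m Number of variants (>= 2).
#' @param seed Optional integer seed.
#' @return A frequency vector of length `m`, all entries positive.
#' @examples
#' random_simplex_point(3, seed = 1)
#' @export
random_simplex_point <- function(m, seed = NULL) {
  m <- check_count(m, "m")
  if (m < 2L) stop("`m` must be at least 2", call. = FALSE)
  draw <- function() {
    x <- stats::rexp(m)
    x / sum(x)
  }
  if (is.null(seed)) {
    draw()
  } else {
    with_preserved_rng(seed, draw())
  }
}

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG.
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Read and validate a run configuration
#'
#' @param path Path to a YAML run-configuration file.
#' @return A validated configuration list (class `"run_config"`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  as_run_config(yaml::read_yaml(path))
}

#' Validate an in-memory run configuration
#'
#' @param config A list with elements `n`, `m`, `scheme`, `p0`,
#'   `generations` and optionally `seed` (see the package file-format notes).
#' @return The normalised configuration, class `"run_config"`.
#' @export
as_run_config <- function(config) {
  stopifnot(is.list(config))
  # YAML 1.1 parses an unquoted key `n` as the boolean FALSE; accept it
  names(config)[names(config) == "FALSE"] <- "n"
  required <- c("n", "m", "scheme", "p0", "generations")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("run config is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  config$n <- check_count(config$n, "n")
  config$m <- check_count(config$m, "m")
  config$generations <- check_count(config$generations, "generations")
  if (!is.list(config$scheme) || is.null(config$scheme$kind)) {
    stop("`scheme` must be a list with at least a `kind` field", call. = FALSE)
  }
  if (is.character(config$p0) && identical(config$p0, "random")) {
    if (is.null(config$seed)) {
      stop("`p0: random` requires a `seed`", call. = FALSE)
    }
  } else {
    config$p0 <- check_simplex(as.numeric(unlist(config$p0)), m = config$m)
  }
  structure(config, class = c("run_config", "list"))
}

#' Build a conformity scheme from a configuration entry
#'
#' Dispatches on `spec$kind`:
#' `"single"` (field `D`), `"n4m3"` (`D_prime`, `D`), `"n5m3"`
#' (`D_ppp`, `D_pp`, `D_p`, `D`), or `"classification"` with either a
#' numeric `d` (constant), a map `d_table` keyed by sorted-descending
#' configuration type, or `lower_offset` giving `d(x) = lower_bound(x) +
#' offset` per configuration.
#'
#' @param n,m Role-model sample size and number of variants.
#' @param spec A list describing the scheme (see Details).
#' @return A `"conformity_scheme"`.
#' @export
scheme_from_spec <- function(n, m, spec) {
  kind <- spec$kind
  if (identical(kind, "single")) {
    if (n != 3L) stop("kind 'single' requires n = 3", call. = FALSE)
    single_coefficient_scheme(spec$D, m = m)
  } else if (identical(kind, "n4m3")) {
    if (n != 4L || m != 3L) stop("kind 'n4m3' requires n = 4, m = 3",
                                 call. = FALSE)
    two_coefficient_scheme_n4_m3(spec$D_prime, spec$D)
  } else if (identical(kind, "n5m3")) {
    if (n != 5L || m != 3L) stop("kind 'n5m3' requires n = 5, m = 3",
                                 call. = FALSE)
    four_coefficient_scheme_n5_m3(spec$D_ppp, spec$D_pp, spec$D_p, spec$D)
  } else if (identical(kind, "classification")) {
    if (!is.null(spec$lower_offset)) {
      off <- spec$lower_offset
      classification_scheme(n, m, d = function(x) d_bounds(x)[1L] + off)
    } else if (!is.null(spec$d_table)) {
      classification_scheme(n, m, d = unlist(spec$d_table))
    } else if (!is.null(spec$d)) {
      classification_scheme(n, m, d = spec$d)
    } else {
      stop("kind 'classification' needs `d`, `d_table` or `lower_offset`",
           call. = FALSE)
    }
  } else {
    stop("unknown scheme kind: ", kind, call. = FALSE)
  }
}

#' Run a configured simulation and write its outputs
#'
#' Iterates the recursion described by `config` and writes two files:
#' `<basename>_trajectory.csv` with columns `generation, p_1, ..., p_m`
#' (floats at 17 significant digits, so rows round-trip bit-faithfully) and
#' `<basename>_summary.json` with the long-run classification, cycle points,
#' ergodic mean, the fully resolved configuration and the package version.
#' On failure any partially written file is removed.
#'
#' @param config A `"run_config"`, a plain list, or a path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @param basename Stem for the two output file names.
#' @return Invisibly, a list with `trajectory` (the `"trajectory"` object)
#'   and the two file paths.
#' @export
run_simulation <- function(config, out_dir = ".", basename = "run") {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  } else {
    config <- as_run_config(config)
  }
  scheme <- scheme_from_spec(config$n, config$m, config$scheme)
  p0 <- if (is.character(config$p0)) {
    random_simplex_point(config$m, seed = config$seed)
  } else {
    config$p0
  }

  traj <- iterate_frequencies(p0, scheme, config$generations)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  csv_path <- file.path(out_dir, paste0(basename, "_trajectory.csv"))
  json_path <- file.path(out_dir, paste0(basename, "_summary.json"))
  ok <- FALSE
  on.exit(if (!ok) unlink(c(csv_path, json_path)))

  df <- data.frame(generation = traj$generation,
                   apply(traj$history, 2L,
                         function(col) formatC(col, digits = 17,
                                               format = "g")),
                   stringsAsFactors = FALSE)
  names(df) <- c("generation", colnames(traj$history))
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)

  summary <- list(
    classification = traj$classification,
    period = if (!is.null(traj$summary) && !is.na(traj$summary$period)) {
      traj$summary$period
    },
    cycle_points = if (!is.null(traj$summary) &&
                       !is.null(traj$summary$cycle_points)) {
      unname(apply(traj$summary$cycle_points, 1L, as.numeric,
                   simplify = FALSE))
    },
    final = as.numeric(traj$history[nrow(traj$history), ]),
    ergodic_mean = if (!is.null(traj$summary)) {
      as.numeric(traj$summary$ergodic_mean)
    },
    config = list(n = config$n, m = config$m, scheme = config$scheme,
                  p0 = as.numeric(p0), generations = config$generations,
                  seed = config$seed),
    package_version = as.character(utils::packageVersion("polyconform"))
  )
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  ok <- TRUE
  invisible(list(trajectory = traj, trajectory_csv = csv_path,
                 summary_json = json_path))
}
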