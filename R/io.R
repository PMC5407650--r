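#' Canonical parameter sets of the model family
#'
#' Named fixtures packaging the parameter sets used throughout the
#' model's standard illustrations, in reduced rates (`k4 = 1`). Sets
#' with a sweep axis (`fig2`, `fig4a`, `fig4b`, `fig4c`) leave that
#' rate `NA` and name it in `sweep`; complete sets carry a default
#' burst-size list.
#'
#' @param name One of `"fig2"`, `"fig3"`, `"fig4a"`, `"fig4b"`,
#'   `"fig4c"`, `"fig6"`.
#' @return A list of class `schlogl_fixture` with elements `name`,
#'   `k1`, `k2`, `k3`, `k4`, `sweep` (`NULL` or the swept rate's name),
#'   `r_list` (default burst sizes) and, for complete sets, `params`
#'   (a [schlogl_params()] built at `r_list[1]`).
#' @examples
#' schlogl_fixture("fig6")$params
#' @export
schlogl_fixture <- function(name) {
  sets <- list(
    fig2  = list(k1 = 8e6,    k2 = 1.33e5, k3 = NA,   sweep = "k3",
                 r_list = 1L),
    fig3  = list(k1 = 9e6,    k2 = 1.5e5,  k3 = 720,  sweep = NULL,
                 r_list = c(1L, 5L, 10L)),
    fig4a = list(k1 = NA,     k2 = 1.65e5, k3 = 720,  sweep = "k1",
                 r_list = c(1L, 11L, 21L, 31L, 41L)),
    fig4b = list(k1 = 5.33e6, k2 = NA,     k3 = 800,  sweep = "k2",
                 r_list = c(1L, 11L, 21L, 31L, 41L)),
    fig4c = list(k1 = 8e6,    k2 = 1e5,    k3 = NA,   sweep = "k3",
                 r_list = c(1L, 11L, 21L, 31L, 41L)),
    fig6  = list(k1 = 3e6,    k2 = 77518,  k3 = 601,  sweep = NULL,
                 r_list = c(1L, 25L))
  )
  if (!name %in% names(sets)) {
    stop("unknown fixture `", name, "`; available: ",
         paste(names(sets), collapse = ", "), call. = FALSE)
  }
  s <- sets[[name]]
  s$k4 <- 1
  s$name <- name
  if (is.null(s$sweep)) {
    s$params <- schlogl_params(s$k1, s$k2, s$k3, s$k4, r = s$r_list[1])
  }
  structure(s, class = "schlogl_fixture")
}

#' @export
print.schlogl_fixture <- function(x, ...) {
  cat("<schlogl_fixture '", x$name, "'>  k1 = ", format(x$k1),
      ", k2 = ", format(x$k2), ", k3 = ", format(x$k3),
      ", k4 = ", format(x$k4),
      if (!is.null(x$sweep)) paste0("  (sweep axis: ", x$sweep, ")") else "",
      "\n  default r: ", paste(x$r_list, collapse = ", "), "\n", sep = "")
  invisible(x)
}

run_config_keys <- c("k1", "k2", "k3", "k4", "r",
                     "ktilde1", "ktilde2", "ktilde3",
                     "fixture", "seed", "x0", "t_max", "x_max",
                     "grid_step", "burn_in", "method", "source", "out",
                     "log_level")

#' Load and validate a run configuration
#'
#' Merges a structured config file (YAML or JSON, by extension) with a
#' list of flag values -- flags override file values -- and validates
#' the result. Rates may be given directly (`k1..k4`) or reduced
#' (`ktilde1..ktilde3`, implying `k4 = 1`); a `fixture` name fills in
#' any rates not supplied explicitly. Unknown keys and invalid values
#' (non-positive rates, non-integer or zero burst size) are descriptive
#' errors.
#'
#' @param file Optional path to a `.yaml`/`.yml`/`.json` config file.
#' @param flags Named list of overriding values (e.g. parsed CLI
#'   flags).
#' @return A list of class `run_config`: `params`
#'   ([schlogl_params()]) plus any run settings (`seed`, `t_max`,
#'   `x_max`, `grid_step`, `burn_in`, `x0`, `method`, `source`, `out`,
#'   `log_level`) that were supplied.
#' @export
load_run_config <- function(file = NULL, flags = list()) {
  cfg <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file, call. = FALSE)
    cfg <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
      yaml::read_yaml(file)
    } else if (grepl("\\.json$", file, ignore.case = TRUE)) {
      jsonlite::read_json(file, simplifyVector = TRUE)
    } else {
      stop("config file must be .yaml/.yml or .json: ", file, call. = FALSE)
    }
  }
  flags <- flags[!vapply(flags, is.null, logical(1))]
  cfg[names(flags)] <- flags

  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; known keys: ", paste(run_config_keys, collapse = ", "),
         call. = FALSE)
  }
  if (any(c("ktilde1", "ktilde2", "ktilde3") %in% names(cfg))) {
    if (!is.null(cfg$k4) && cfg$k4 != 1) {
      stop("reduced rates (ktilde*) imply k4 = 1; do not also set k4",
           call. = FALSE)
    }
    cfg$k1 <- cfg$ktilde1 %||% cfg$k1
    cfg$k2 <- cfg$ktilde2 %||% cfg$k2
    cfg$k3 <- cfg$ktilde3 %||% cfg$k3
    cfg$k4 <- 1
  }
  if (!is.null(cfg$fixture)) {
    fx <- schlogl_fixture(cfg$fixture)
    for (nm in c("k1", "k2", "k3", "k4")) {
      if (is.null(cfg[[nm]]) && !is.na(fx[[nm]])) cfg[[nm]] <- fx[[nm]]
    }
    if (is.null(cfg$r)) cfg$r <- fx$r_list[1]
  }
  for (nm in c("k1", "k2", "k3")) {
    if (is.null(cfg[[nm]])) {
      stop("missing rate `", nm, "` (supply it, a ktilde value, or a fixture)",
           call. = FALSE)
    }
  }
  params <- schlogl_params(cfg$k1, cfg$k2, cfg$k3, cfg$k4 %||% 1,
                           cfg$r %||% 1)
  if (!is.null(cfg$burn_in) && (cfg$burn_in < 0 || cfg$burn_in >= 1)) {
    stop("`burn_in` must be in [0, 1)", call. = FALSE)
  }
  out <- c(list(params = params),
           cfg[intersect(names(cfg), c("seed", "x0", "t_max", "x_max",
                                       "grid_step", "burn_in", "method",
                                       "source", "out", "log_level",
                                       "fixture"))])
  structure(out, class = "run_config")
}

provenance_lines <- function(params = NULL, seed = NULL, extra = character(0)) {
  ln <- paste0("# burstbif ",
               as.character(utils::packageVersion("burstbif")))
  if (!is.null(params)) {
    ln <- c(ln, paste0("# params: k1=", format_full(params$k1),
                       " k2=", format_full(params$k2),
                       " k3=", format_full(params$k3),
                       " k4=", format_full(params$k4),
                       " r=", params$r))
  }
  if (!is.null(seed)) ln <- c(ln, paste0("# seed: ", seed))
  c(ln, extra)
}

write_table_commented <- function(df, path, sep, comments) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comments, con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], format_full)
  utils::write.table(df, con, sep = sep, row.names = FALSE,
                     quote = FALSE)
}

read_table_commented <- function(path, sep) {
  tibble::as_tibble(utils::read.table(path, sep = sep, header = TRUE,
                                      comment.char = "#"))
}

#' Tabular writers and readers with provenance headers
#'
#' CSV is used for densities, distributions and trajectories, TSV for
#' phase-diagram grids, JSON for extremum reports. Every file starts
#' with `#`-prefixed provenance comment lines (package version,
#' parameters, seed where applicable); numbers are written as full
#' 17-significant-digit decimals so a read round-trips losslessly.
#'
#' @param x The object to write ([stationary_density()],
#'   [stationary_distribution()], [simulate_schlogl()],
#'   [scan_phase_diagram()] or [find_extrema()] result).
#' @param path Output file path.
#' @return `write_*` return `path` invisibly; `read_*` return a
#'   tibble (or list for JSON) with the provenance comments skipped.
#' @name io_tables
NULL

#' @rdname io_tables
#' @export
write_density_csv <- function(x, path) {
  stopifnot(inherits(x, "stationary_density"))
  write_table_commented(
    x[, c("x", "density", "log_density")], path, ",",
    provenance_lines(attr(x, "params"),
                     extra = paste0("# method: ", attr(x, "method"))))
  invisible(path)
}

#' @rdname io_tables
#' @export
read_density_csv <- function(path) read_table_commented(path, ",")

#' @rdname io_tables
#' @export
write_distribution_csv <- function(x, path) {
  stopifnot(inherits(x, "cme_distribution") ||
              inherits(x, "occupancy_histogram"))
  write_table_commented(as.data.frame(x), path, ",",
                        provenance_lines(attr(x, "params"),
                                         seed = attr(x, "seed")))
  invisible(path)
}

#' @rdname io_tables
#' @export
read_distribution_csv <- function(path) read_table_commented(path, ",")

#' @rdname io_tables
#' @export
write_trajectory_csv <- function(x, path) {
  stopifnot(inherits(x, "ssa_trajectory"))
  write_table_commented(x$events, path, ",",
                        provenance_lines(x$params, seed = x$seed,
                                         extra = paste0("# x0: ", x$x0)))
  invisible(path)
}

#' @rdname io_tables
#' @export
read_trajectory_csv <- function(path) read_table_commented(path, ",")

#' @rdname io_tables
#' @export
write_phase_tsv <- function(x, path) {
  stopifnot(inherits(x, "phase_diagram"))
  write_table_commented(as.data.frame(x), path, "\t",
                        provenance_lines(extra = paste0(
                          "# fixed: ",
                          paste(names(attr(x, "fixed")),
                                vapply(attr(x, "fixed"), format_full, ""),
                                sep = "=", collapse = " "),
                          " source: ", attr(x, "source"))))
  invisible(path)
}

#' @rdname io_tables
#' @export
read_phase_tsv <- function(path) read_table_commented(path, "\t")

#' @rdname io_tables
#' @export
write_extrema_json <- function(x, path) {
  stopifnot(inherits(x, "extrema_report"))
  p <- attr(x, "params")
  jsonlite::write_json(list(
    params = list(k1 = p$k1, k2 = p$k2, k3 = p$k3, k4 = p$k4, r = p$r),
    maxima = x$location[x$type == "maximum"],
    minima = x$location[x$type == "minimum"],
    n_maxima = attr(x, "n_maxima"),
    bifurcation_points = attr(x, "merged_pairs")$location,
    boundary_mode = attr(x, "boundary_mode"),
    version = as.character(utils::packageVersion("burstbif"))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_extrema_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
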