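#' Parse a run configuration file
#'
#' Reads a YAML configuration describing either a lattice experiment
#' (`kind: equilibrium` or `kind: invasion`) or a reaction-diffusion front
#' run (`kind: rdfront`). Missing fields take the standard single-type
#' defaults (200x200 interior, side-10 cells, `lambda_area = 10`,
#' `lambda_cont = 0.5`, `lambda_adh = -10`, `A0 = 100`, `T = 50`,
#' `B = 0.03`, `M = 0.001`); unknown keys are rejected with an error naming
#' the key.
#'
#' Recognised top-level keys: `kind`, `domain` (`width`, `height`),
#' `temperature`, `initial_cell_side`, `barrier_width`, `seed`, `max_mcs`,
#' `measure_mcs`, `stages` (`stage1_mcs`, `stage2_max_mcs`, `stage3_max_mcs`),
#' `stationarity` (`window`, `tol`), `cell_types` (list of records with the
#' [cell_type()] fields), `rd` (`b1`, `b2`, `m1`, `m2`, `D`).
#'
#' @param path Path to a YAML file; alternatively pass `text`.
#' @param text YAML text (used when `path` is `NULL`).
#' @return For lattice kinds, an [experiment_config()] with attribute
#'   `kind`; for `rdfront`, an [rd_params()] with attribute `kind`.
#' @export
parse_config <- function(path = NULL, text = NULL) {
  raw <- if (!is.null(path)) yaml::read_yaml(path)
         else if (!is.null(text)) yaml::read_yaml(text = text)
         else list()
  if (is.null(raw)) raw <- list()
  known <- c("kind", "domain", "temperature", "initial_cell_side",
             "barrier_width", "seed", "max_mcs", "measure_mcs", "stages",
             "stationarity", "cell_types", "rd")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  kind <- raw$kind %||% "equilibrium"
  if (!kind %in% c("equilibrium", "invasion", "rdfront"))
    stop("kind must be one of equilibrium, invasion, rdfront")
  if (kind == "rdfront") {
    rd <- raw$rd %||% list()
    bad <- setdiff(names(rd), c("b1", "b2", "m1", "m2", "D"))
    if (length(bad)) stop("unknown rd key(s): ", paste(bad, collapse = ", "))
    out <- rd_params(b1 = rd$b1 %||% 1, b2 = rd$b2 %||% 1,
                     m1 = rd$m1 %||% 0.25, m2 = rd$m2 %||% 0.5,
                     D = rd$D %||% 1)
    attr(out, "kind") <- kind
    attr(out, "seed") <- raw$seed
    return(out)
  }
  dom <- raw$domain %||% list()
  bad <- setdiff(names(dom), c("width", "height"))
  if (length(bad)) stop("unknown domain key(s): ", paste(bad, collapse = ", "))
  stg <- raw$stages %||% list()
  bad <- setdiff(names(stg), c("stage1_mcs", "stage2_max_mcs", "stage3_max_mcs"))
  if (length(bad)) stop("unknown stages key(s): ", paste(bad, collapse = ", "))
  stat <- raw$stationarity %||% list()
  bad <- setdiff(names(stat), c("window", "tol"))
  if (length(bad)) stop("unknown stationarity key(s): ",
                        paste(bad, collapse = ", "))
  cts <- raw$cell_types
  types <- if (is.null(cts)) {
    list(cell_type(1, lambda_area = 10, lambda_cont = 0.5, lambda_adh = -10,
                   A0 = 100, birth_prob = 0.03, death_prob = 0.001))
  } else {
    lapply(cts, function(ct) {
      bad <- setdiff(names(ct), c("type_id", "lambda_area", "lambda_cont",
                                  "lambda_adh", "A0", "birth_prob",
                                  "death_prob"))
      if (length(bad)) stop("unknown cell_type key(s): ",
                            paste(bad, collapse = ", "))
      cell_type(type_id = ct$type_id,
                lambda_area = ct$lambda_area %||% 10,
                lambda_cont = ct$lambda_cont %||% 0.5,
                lambda_adh = ct$lambda_adh %||% -10,
                A0 = ct$A0 %||% 100,
                birth_prob = ct$birth_prob %||% 0,
                death_prob = ct$death_prob %||% 0)
    })
  }
  cfg <- experiment_config(
    width = dom$width %||% 200, height = dom$height %||% 200,
    cell_types = types,
    initial_cell_side = raw$initial_cell_side %||% 10,
    temperature = raw$temperature %||% 50,
    stage1_mcs = stg$stage1_mcs %||% 500,
    stage2_max_mcs = stg$stage2_max_mcs %||% 3000,
    stage3_max_mcs = stg$stage3_max_mcs %||% 50000,
    window = stat$window %||% 500, tol = stat$tol %||% 0.02,
    max_mcs = raw$max_mcs %||% 5000,
    measure_mcs = raw$measure_mcs %||% 1500,
    barrier_width = raw$barrier_width,
    seed = raw$seed)
  attr(cfg, "kind") <- kind
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a configuration back to YAML
#'
#' Writes the resolved configuration in the same dialect [parse_config()]
#' reads, so parse -> write -> parse is the identity on resolved values.
#'
#' @param config An [experiment_config()] (with optional `kind` attribute).
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_config <- function(config, path) {
  kind <- attr(config, "kind") %||%
    (if (length(config$cell_types) == 2) "invasion" else "equilibrium")
  out <- list(
    kind = kind,
    domain = list(width = config$width, height = config$height),
    temperature = config$temperature,
    initial_cell_side = config$initial_cell_side,
    barrier_width = config$barrier_width,
    max_mcs = config$max_mcs,
    measure_mcs = config$measure_mcs,
    stages = list(stage1_mcs = config$stage1_mcs,
                  stage2_max_mcs = config$stage2_max_mcs,
                  stage3_max_mcs = config$stage3_max_mcs),
    stationarity = list(window = config$window, tol = config$tol),
    cell_types = lapply(config$cell_types, function(ct) {
      list(type_id = ct$type_id, lambda_area = ct$lambda_area,
           lambda_cont = ct$lambda_cont, lambda_adh = ct$lambda_adh,
           A0 = ct$A0, birth_prob = ct$birth_prob,
           death_prob = ct$death_prob)
    }))
  if (!is.null(config$seed)) out$seed <- config$seed
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write and read time-series CSV
#'
#' Columns `mcs`, `type_id`, `live`, `dead`, `stage` in stable order;
#' integer counts round-trip losslessly.
#'
#' @param series Time-series data frame.
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
write_timeseries <- function(series, path) {
  cols <- c("mcs", "type_id", "live", "dead", "stage")
  if (is.null(series$stage)) series$stage <- 1L
  out <- series[, cols]
  for (cl in cols) out[[cl]] <- as.integer(out[[cl]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  read.csv(path, colClasses = rep("integer", 5))
}

#' Write a run manifest
#'
#' Records the fully resolved configuration, the seed, the package version
#' and an inventory of output files with MD5 checksums, so a run can be
#' reproduced bit-identically from its manifest.
#'
#' @param config The [experiment_config()] used.
#' @param seed The seed used.
#' @param files Character vector of output files to checksum.
#' @param path Output YAML path.
#' @return Invisibly `path`.
#' @export
write_manifest <- function(config, seed, files, path) {
  sums <- tools::md5sum(files)
  out <- list(
    package = "cpmcompete",
    version = as.character(packageVersion("cpmcompete")),
    seed = seed,
    config = yaml::yaml.load(yaml::as.yaml(unclass(config))),
    outputs = mapply(function(f, s) list(file = f, md5 = unname(s)),
                     files, sums, SIMPLIFY = FALSE, USE.NAMES = FALSE))
  yaml::write_yaml(out, path)
  invisible(path)
}
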