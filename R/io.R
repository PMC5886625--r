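## File formats: matrices and time series as delimited text (TSV, no
## header, full precision) or the native binary container (RDS); run
## configurations as YAML or JSON.

fmt_from_path <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "tsv"
}

#' Write / read a numeric matrix
#'
#' TSV is headerless, row-major, written at full precision (17 significant
#' digits, round-trips within 1e-15); `.rds` files use the native binary
#' container and round-trip losslessly.  An optional metadata list is
#' stored as a JSON sidecar next to the file.
#'
#' @param M numeric matrix.
#' @param path output path; extension `.rds` selects the binary container.
#' @param meta optional list written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(M, path, meta = NULL) {
  stopifnot(is.matrix(M))
  if (fmt_from_path(path) == "rds") {
    saveRDS(M, path)
  } else {
    utils::write.table(format(M, digits = 17, trim = TRUE, scientific = TRUE),
                       path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (fmt_from_path(path) == "rds") return(readRDS(path))
  lines <- readLines(path)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1)
    stop("ragged matrix file: row ", which(ncols != ncols[1])[1],
         " has ", ncols[which(ncols != ncols[1])[1]], " cells, expected ",
         ncols[1])
  vals <- suppressWarnings(lapply(rows, as.numeric))
  for (i in seq_along(vals)) {
    bad <- which(is.na(vals[[i]]))
    if (length(bad))
      stop("non-numeric cell at row ", i, ", column ", bad[1])
  }
  do.call(rbind, vals)
}

#' Write / read a time series with its sampling interval
#'
#' Delimited text: one comment header line `#dt <seconds>` followed by the
#' headerless node x time matrix.  `.rds` stores the full [zlconn_ts()]
#' object.
#'
#' @param ts a [zlconn_ts()].
#' @param path output path.
#' @return `path` invisibly (write) or a [zlconn_ts()] (read).
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "zlconn_ts"))
  if (fmt_from_path(path) == "rds") { saveRDS(ts, path); return(invisible(path)) }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#dt %.17g", ts$dt), con)
  utils::write.table(format(ts$values, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  if (fmt_from_path(path) == "rds") {
    out <- readRDS(path)
    stopifnot(inherits(out, "zlconn_ts"))
    return(out)
  }
  first <- readLines(path, n = 1)
  if (!grepl("^#dt ", first))
    stop("missing '#dt <seconds>' header line")
  dt <- as.numeric(sub("^#dt ", "", first))
  lines <- readLines(path)[-1]
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(lines, tmp)
  zlconn_ts(read_matrix(tmp), dt = dt)
}

modifyList_strict <- function(base, upd, where) {
  extra <- setdiff(names(upd), names(base))
  if (length(extra))
    stop("unknown ", where, " setting(s): ", paste(extra, collapse = ", "))
  utils::modifyList(base, upd)
}

#' Run configuration with reference defaults
#'
#' Bundles all tunables of a simulation/estimation run.  Unspecified
#' settings fall back to the reference defaults: optimizer tolerances
#' xtol = 0.7e-2, ftol = 0.7e-4, gtol = 0.7e-2, kappa = 500; simulation
#' N = 100, p = 0.1, T = 350000 s, dt = 0.1 s, tau = 0.1 s, rho = 0.3,
#' 20 repetitions.
#'
#' @param network,simulation,optimizer,noise,evaluation named lists
#'   overriding individual defaults within each section.
#' @param repetitions repetitions for benchmark sweeps.
#' @param seed master seed from which per-run seeds are derived.
#' @return a nested list of class `zlconn_config`.
#' @export
zlconn_config <- function(network = list(), simulation = list(),
                          optimizer = list(), noise = list(),
                          evaluation = list(), repetitions = 20, seed = 1) {
  base <- list(
    network = list(n_nodes = 100, connection_prob = 0.1,
                   spectral_radius = 0.7, inhibitory_fraction = 0.5,
                   background_prob = 0, background_radius_fraction = 0.2),
    simulation = list(tau = 0.1, dt = 0.1, T = 350000,
                      spectral_radius = 0.3, hrf = TRUE,
                      noise_model = "exact"),
    optimizer = unclass(unitary_control()),
    noise = list(sigma_obs = 0, observed_fraction = 1),
    evaluation = list(keep_fraction = 0.1, threshold = NA),
    repetitions = repetitions, seed = seed)
  cfg <- base
  cfg$network <- modifyList_strict(base$network, network, "network")
  cfg$simulation <- modifyList_strict(base$simulation, simulation,
                                      "simulation")
  cfg$optimizer <- modifyList_strict(base$optimizer, optimizer, "optimizer")
  cfg$noise <- modifyList_strict(base$noise, noise, "noise")
  cfg$evaluation <- modifyList_strict(base$evaluation, evaluation,
                                      "evaluation")
  class(cfg) <- "zlconn_config"
  cfg
}

#' Named simulation presets
#'
#' `"table"` is the tabulated parameter set (spectral radius 0.3);
#' `"results"` the default used for the worked OU examples (spectral
#' radius 0.74); `"ci"` the same at one tenth of the duration
#' (T = 35000 s) for quick continuous-integration runs.
#'
#' @param name preset name.
#' @return a `zlconn_config`.
#' @export
ou_preset <- function(name = c("table", "results", "ci")) {
  name <- match.arg(name)
  switch(name,
    table = zlconn_config(),
    results = zlconn_config(simulation = list(spectral_radius = 0.74)),
    ci = zlconn_config(simulation = list(spectral_radius = 0.74, T = 35000)))
}

#' Read a configuration file (YAML or JSON)
#'
#' Sections `network`, `simulation`, `optimizer`, `noise`, `evaluation`
#' plus scalar `repetitions` and `seed`; anything unspecified keeps its
#' default.  Unknown keys are an error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `zlconn_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("network", "simulation", "optimizer", "noise", "evaluation",
             "repetitions", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config section(s): ", paste(extra, collapse = ", "))
  zlconn_config(network = raw$network %||% list(),
                simulation = raw$simulation %||% list(),
                optimizer = raw$optimizer %||% list(),
                noise = raw$noise %||% list(),
                evaluation = raw$evaluation %||% list(),
                repetitions = raw$repetitions %||% 20,
                seed = raw$seed %||% 1)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_provenance <- function(path, cfg, seed, extra = list()) {
  prov <- c(list(package = "zlconn",
                 version = as.character(utils::packageVersion("zlconn")),
                 config_hash = config_hash(cfg), seed = seed,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            extra)
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
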