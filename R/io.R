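#' Write a force-extension trace as TSV (with JSON sidecar)
#'
#' The trace file is tab-separated with header columns `time_s`,
#' `stage_nm`, `extension_nm`, `force_pN`, values formatted to 6
#' decimals so that write-then-read is exact at that precision. Protocol
#' metadata, seed and the generator event log go to a JSON sidecar
#' (`<path>.json`).
#'
#' @param trace An `fe_trace` (or any tibble with the four columns).
#' @param path Output path for the TSV.
#' @param sidecar Write the JSON metadata sidecar?
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, sidecar = TRUE) {
  check_trace(trace)
  out <- tibble::tibble(
    time_s = sprintf("%.6f", trace$time_s),
    stage_nm = sprintf("%.6f", trace$stage_nm),
    extension_nm = sprintf("%.6f", trace$extension_nm),
    force_pN = sprintf("%.6f", trace$force_pN)
  )
  readr::write_tsv(out, path)
  if (sidecar) {
    protocol <- attr(trace, "protocol")
    meta <- list(
      seed = attr(trace, "seed"),
      protocol = if (!is.null(protocol)) {
        list(
          segments = protocol$segments,
          sampling_rate = protocol$sampling_rate,
          cantilever_stiffness = protocol$cantilever_stiffness,
          force_noise_sd = protocol$force_noise_sd
        )
      },
      params = attr(trace, "params")[c("persistence_length", "temperature",
                                       "folded_compliance", "helix_mode")],
      events = trace_events(trace),
      helix_toggles = as.list(attr(trace, "helix_toggles"))
    )
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a force-extension trace written by [write_trace()]
#'
#' @param path Path to the TSV file.
#' @return An `fe_trace` tibble; if the JSON sidecar exists, `events`,
#'   `seed` and `params` attributes are restored.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()))
  req <- c("time_s", "stage_nm", "extension_nm", "force_pN")
  miss <- setdiff(req, names(tr))
  if (length(miss)) stop("trace file missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(tr) == 0) stop("trace file has no samples")
  if (any(diff(tr$time_s) <= 0)) stop("time column is not strictly increasing")
  tr <- tibble::as_tibble(tr)
  class(tr) <- c("fe_trace", class(tr))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(tr, "seed") <- meta$seed
    attr(tr, "params") <- meta$params
    ev <- meta$events
    attr(tr, "events") <- if (is.data.frame(ev)) {
      tibble::as_tibble(ev)
    } else {
      tibble::tibble(time_s = numeric(0), label = character(0),
                     kind = character(0), transition = character(0),
                     force_pN = numeric(0))
    }
  }
  tr
}

#' Write a distance distribution as TSV
#'
#' Columns `r_lo`, `r_hi`, `count` (Angstrom / counts).
#'
#' @param dd A `distance_distribution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_distribution <- function(dd, path) {
  readr::write_tsv(tibble::as_tibble(dd)[, c("r_lo", "r_hi", "count")], path)
  invisible(path)
}

#' JSON geometry report for a structure model
#'
#' Writes centroids, consecutive tilt/twist arrangements, neighbor
#' distance statistics, rg and Dmax for a domain-annotated model.
#'
#' @param model A [structure_model()] with domains.
#' @param path Output JSON path.
#' @param bin_width p(r) bin width, Angstrom.
#' @param orders Neighbor orders for the distance statistics.
#' @return The report list, invisibly.
#' @export
write_geometry_report <- function(model, path, bin_width = 2,
                                  orders = c(1, 3, 4)) {
  cent <- domain_centroids(model)
  orders <- orders[orders <= nrow(cent) - 1]
  dd <- pair_distance_distribution(model, bin_width = bin_width)
  report <- list(
    centroids = cent,
    neighbor_distances = neighbor_distance_stats(cent, order = orders),
    arrangements = consecutive_arrangements(model),
    rg = attr(dd, "rg"),
    dmax = attr(dd, "dmax")
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Run manifest for a reproducible analysis
#'
#' Collects everything needed to reproduce a run: the configuration (and
#' its MD5 hash), seed, package version, input file checksums, and MD5
#' checksums of result files.
#'
#' @param config A named list describing the run (subcommand, parameter
#'   overrides, seed, paths). A `seed` entry is required.
#' @param inputs,results Character vectors of file paths to checksum.
#' @param path Optional path to also write the manifest as JSON.
#' @return The manifest as a named list.
#' @export
run_manifest <- function(config, inputs = character(0),
                         results = character(0), path = NULL) {
  if (is.null(config$seed)) stop("`config` must record a seed")
  cfg_file <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_file), add = TRUE)
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "myoelastica",
    version = as.character(utils::packageVersion("myoelastica")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config,
    config_md5 = unname(tools::md5sum(cfg_file)),
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    result_md5 = as.list(tools::md5sum(results[file.exists(results)]))
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  }
  manifest
}
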