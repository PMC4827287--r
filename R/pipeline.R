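# Pipeline orchestration: a single YAML/JSON config drives the four
# analysis stages (mechanics -> bioreactor -> staining -> association);
# stage outputs land in the configured output directory and a run manifest
# with input hashes and per-stage status is written atomically at the end.

config_keys <- list(
  top = c("seed", "output_dir", "force_N", "ring", "mechanics", "bioreactor",
          "staining", "association", "log_level"),
  ring = c("thickness_um", "modulus_MPa", "contact_area_mm2",
           "plunger_diameter_mm", "footprint_diameter_mm"),
  mechanics = c("traces", "strains", "fit_lo", "fit_hi", "n_cycles",
                "keep_last", "tare_N", "frequency"),
  staining = c("images", "alpha", "beta", "n_bins", "target"),
  bioreactor = c("states"),
  association = c("records", "metric"))

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0L)
    stop_quant("unknown config key(s) in %s: %s", where,
               paste(unknown, collapse = ", "), class = "invalid_config")
  invisible(x)
}

#' Read and validate a pipeline configuration
#'
#' YAML (or JSON) file with per-stage sections; unknown keys are rejected
#' so typos fail loudly rather than silently falling back to defaults.
#'
#' @param path Config file path.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, config_keys$top, "top level")
  for (sec in c("ring", "mechanics", "staining", "bioreactor", "association"))
    if (!is.null(cfg[[sec]])) check_keys(cfg[[sec]], config_keys[[sec]], sec)
  cfg
}

pipeline_log <- function(level, cfg_level, msg, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[cfg_level %||% "info"]])
    message(sprintf("[%s] %s", level, sprintf(msg, ...)))
}

stage_mechanics <- function(cfg, outdir, log_level) {
  mc <- cfg$mechanics
  strains <- as.numeric(mc$strains %||% c(0.10, 0.12, 0.15, 0.18))
  rows <- lapply(mc$traces, function(tr) {
    trace <- read_trace(tr$path, start_gap_um = tr$start_gap_um %||% NA_real_,
                        specimen_id = tr$specimen_id %||% NULL)
    th <- detect_thickness(trace, tare_N = mc$tare_N %||% 0.02)
    curve <- extract_cycles(trace, diameter_mm = tr$diameter_mm %||% 5,
                            frequency = mc$frequency %||% 1,
                            n_cycles = mc$n_cycles %||% 10L,
                            keep_last = mc$keep_last %||% 4L,
                            thickness_um = th, tare_N = mc$tare_N %||% 0.02)
    fit <- fit_exponential(curve, mc$fit_lo %||% 0, mc$fit_hi %||% 0.2)
    mods <- tangent_moduli(fit, strains)
    out <- data.frame(specimen_id = trace$specimen_id, thickness_um = th,
                      A_MPa = fit$A, B = fit$B, rss = fit$rss)
    for (i in seq_along(strains))
      out[[sprintf("modulus_%gpct_MPa", 100 * strains[i])]] <- mods$modulus_MPa[i]
    pipeline_log("info", log_level, "mechanics: %s A=%.4g B=%.4g",
                 trace$specimen_id, fit$A, fit$B)
    out
  })
  res <- do.call(rbind, rows)
  utils::write.csv(res, file.path(outdir, "mechanics.csv"), row.names = FALSE)
  res
}

stage_bioreactor <- function(cfg, outdir, log_level) {
  ring <- do.call(ring_spec, cfg$ring %||% list())
  states <- read_table_strict(cfg$bioreactor$states,
                              c("day", "thickness_um", "diameter_mm", "A_MPa", "B"),
                              c("day", "thickness_um", "diameter_mm", "A_MPa", "B"))
  traj <- strain_trajectory(cfg$force_N %||% 5, ring, states)
  utils::write.csv(traj, file.path(outdir, "strains.csv"), row.names = FALSE)
  traj
}

stage_staining <- function(cfg, outdir, log_level) {
  sc <- cfg$staining
  target <- sc$target %||% "alcian_blue"
  rows <- lapply(sc$images, function(im) {
    if (!file.exists(im$path))
      stop_quant("image file not found: %s", im$path, class = "missing_input")
    img <- read_image(im$path)
    od <- to_od(img)
    basis <- estimate_stain_basis(od, alpha = sc$alpha %||% 1,
                                  beta = sc$beta %||% 0.15)
    maps <- deconvolve(od, basis)
    thr <- otsu_threshold(maps$concentrations[, , target],
                          n_bins = sc$n_bins %||% 256L)
    roi <- load_roi(im$roi, dim(img))
    m <- quantify_stain(maps, target = target, roi = roi, threshold = thr)
    pipeline_log("info", log_level, "staining: %s coverage %.2f%%",
                 basename(im$path), m$coverage_pct)
    data.frame(image = basename(im$path),
               specimen_id = im$specimen_id %||% basename(im$path),
               coverage_pct = m$coverage_pct, mean_intensity = m$mean_intensity,
               threshold = m$threshold, n_roi = m$n_roi,
               n_positive = m$n_positive)
  })
  res <- do.call(rbind, rows)
  utils::write.csv(res, file.path(outdir, "staining.csv"), row.names = FALSE)
  res
}

stage_association <- function(cfg, outdir, log_level) {
  rec <- read_records(cfg$association$records)
  metrics <- cfg$association$metric %||% c("mean_intensity", "coverage_pct")
  res <- lapply(metrics, function(m)
    unclass(regress_metric_on_log_modulus(rec, metric = m)))
  names(res) <- metrics
  write_metrics(res, file.path(outdir, "association.json"))
  res
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order (mechanics, bioreactor,
#' staining, association), writes each stage's outputs into the output
#' directory and finishes with a `manifest.json` recording tool version,
#' config hash, input file hashes and per-stage status. A stage failure is
#' recorded (status `"failed"`) and subsequent stages still run; the
#' returned manifest carries `ok = FALSE` in that case. Identical config
#' and inputs yield byte-identical stage outputs.
#'
#' @param config Path to a YAML config or a validated config list.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  outdir <- cfg$output_dir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))
  log_level <- cfg$log_level %||% "info"
  input_files <- c(
    vapply(cfg$mechanics$traces %||% list(), function(tr) tr$path, character(1)),
    cfg$bioreactor$states,
    unlist(lapply(cfg$staining$images %||% list(),
                  function(im) c(im$path, im$roi))),
    cfg$association$records)
  input_files <- unique(unlist(input_files))
  hashes <- vapply(input_files, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_,
    character(1))
  stages <- c("mechanics", "bioreactor", "staining", "association")
  status <- stats::setNames(rep("skipped", length(stages)), stages)
  msgs <- stats::setNames(rep(NA_character_, length(stages)), stages)
  runners <- list(mechanics = stage_mechanics, bioreactor = stage_bioreactor,
                  staining = stage_staining, association = stage_association)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  for (st in stages) {
    if (is.null(cfg[[st]])) next
    r <- tryCatch({
      runners[[st]](cfg, outdir, log_level)
      "ok"
    }, error = function(e) e)
    if (inherits(r, "error")) {
      status[[st]] <- "failed"
      msgs[[st]] <- conditionMessage(r)
      pipeline_log("error", log_level, "stage %s failed: %s", st, msgs[[st]])
    } else {
      status[[st]] <- "ok"
    }
  }
  manifest <- list(
    tool = "chondroquant",
    version = as.character(utils::packageVersion("chondroquant")),
    config_hash = config_hash(cfg),
    inputs = as.list(hashes),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = as.list(status),
    messages = as.list(msgs[!is.na(msgs)]),
    ok = !any(status == "failed"))
  tmp <- tempfile(tmpdir = outdir, fileext = ".json")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, file.path(outdir, "manifest.json"))
  invisible(manifest)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
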