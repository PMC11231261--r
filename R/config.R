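#' Analysis configuration
#'
#' Validated bundle of every tunable the pipelines use. Defaults are the
#' published values of the original assays: a fixed raw-scale MD threshold
#' of 1200 (250 in the alternate-microscope dialect), 15 px egg-mask
#' erosion, 35 px rolling-ball radius, 10 distance shells of 1 um, the
#' smallest-40% object filter, the 15 um^3 vesicle volume floor, and the
#' guard/background envelope thicknesses (vesicle assay 0.2/0.3 um,
#' MD-proximal assay 0.5/1.0 um). Thresholds are interpreted on the raw
#' camera scale (16-bit class).
#'
#' @param ... named overrides of the defaults listed above.
#' @return an \code{analysis_config} (named list).
#' @export
analysis_config <- function(...) {
  cfg <- config_defaults()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("config overrides must be named")
    cfg <- apply_overrides(cfg, over)
  }
  validate_config(cfg)
}

config_defaults <- function() {
  list(
    threshold_md            = 1200,   # raw-scale MD intensity cutoff
    erosion_px              = 15L,
    rolling_ball_radius_px  = 35L,
    rolling_ball_presmooth_sigma = 0, # optional Gaussian pre-smooth, px
    min_component_area_px   = NA_integer_, # NA = 5% of largest component
    shell_count             = 10L,
    shell_width_um          = 1.0,
    object_filter_fraction  = 0.40,
    vesicle_min_volume_um3  = 15.0,
    guard_um                = 0.2,    # vesicle assay guard envelope
    background_um           = 0.3,    # vesicle assay background envelope
    md_guard_um             = 0.5,    # MD-proximal assay guard
    md_background_um        = 1.0,    # MD-proximal assay background
    touch_um                = NA_real_, # NA = one-voxel (26-conn) adjacency
    seed                    = 1L
  )
}

apply_overrides <- function(cfg, over) {
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

validate_config <- function(cfg) {
  chk_num <- function(key, lo = 0, allow_na = FALSE, strict = TRUE) {
    v <- cfg[[key]]
    if (allow_na && length(v) == 1L && is.na(v)) return(invisible())
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        (strict && v <= lo) || (!strict && v < lo))
      stop("config key '", key, "' out of range")
  }
  chk_num("threshold_md", strict = FALSE)
  chk_num("erosion_px", strict = FALSE)
  chk_num("rolling_ball_radius_px")
  chk_num("rolling_ball_presmooth_sigma", strict = FALSE)
  chk_num("min_component_area_px", allow_na = TRUE, strict = FALSE)
  chk_num("shell_count")
  chk_num("shell_width_um")
  if (!is.numeric(cfg$object_filter_fraction) ||
      cfg$object_filter_fraction < 0 || cfg$object_filter_fraction >= 1)
    stop("config key 'object_filter_fraction' out of range (need [0, 1))")
  chk_num("vesicle_min_volume_um3", strict = FALSE)
  chk_num("guard_um", strict = FALSE)
  chk_num("background_um")
  chk_num("md_guard_um", strict = FALSE)
  chk_num("md_background_um")
  chk_num("touch_um", allow_na = TRUE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    stop("config key 'seed' must be an integer")
  cfg$seed <- as.integer(cfg$seed)
  for (k in c("erosion_px", "rolling_ball_radius_px", "shell_count"))
    cfg[[k]] <- as.integer(cfg[[k]])
  structure(cfg, class = "analysis_config")
}

#' Load an analysis configuration from a flat key-value file
#'
#' Accepts a flat JSON or YAML document (dialect chosen by file extension,
#' \code{.json} vs \code{.yml}/\code{.yaml}) whose keys are configuration
#' names. Unspecified keys take the published defaults; \code{overrides}
#' win over file values. Unknown keys and out-of-range values are hard
#' errors, so a silent typo in a threshold name cannot corrupt an analysis.
#'
#' @param path path to the config file; an empty or absent-key file yields
#'   pure defaults.
#' @param overrides named list applied after the file.
#' @return an \code{analysis_config}.
#' @export
load_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") {
    if (file.info(path)$size == 0) list() else
      jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    v <- yaml::read_yaml(path)
    if (is.null(v)) list() else v
  } else stop("config must be .json, .yml or .yaml")
  if (!is.list(vals)) stop("config file must be a flat key-value document")
  cfg <- apply_overrides(config_defaults(), vals)
  if (length(overrides)) cfg <- apply_overrides(cfg, overrides)
  validate_config(cfg)
}

#' Stable short hash of a configuration, recorded as result provenance
#' @param cfg an \code{analysis_config}
#' @return character scalar
#' @export
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v, digits = 15),
                                                       collapse = ","), ""),
             sep = "=", collapse = ";")
  # FNV-1a over the serialized key=value string; provenance only.
  # 32-bit state kept in a double; xor/multiply done in double-safe pieces.
  h <- 2166136261
  m <- 16777619
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * m + ((h1 * m) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
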