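#' Read a TIFF / OME-TIFF image into an image_stack
#'
#' Pages are interpreted channel-fastest: a file with \code{nz * nc} pages
#' holds \code{nz} z-planes of \code{nc} channels each (plain 2D images
#' have one page per channel). Physical spacing is taken, in order of
#' precedence, from (1) an OME-XML \code{PhysicalSizeX/Y/Z} block in the
#' TIFF ImageDescription, (2) a JSON sidecar written by
#' \code{\link{write_image}}, (3) the \code{spacing} override. Assays that
#' need physical units error out later if none of these is available.
#'
#' @param path TIFF file.
#' @param channel_roles ordered channel role labels; must match the file's
#'   channel count.
#' @param spacing optional per-axis override in micrometres
#'   (\code{c(y, x)} or \code{c(z, y, x)}).
#' @param n_channels number of interleaved channels in the file (default:
#'   taken from the sidecar if present, else 1).
#' @param dtype_max raw intensity scale of the file (default 65535; the
#'   \pkg{tiff} reader returns [0, 1] values which are mapped back to raw
#'   scale).
#' @return an \code{image_stack}.
#' @export
read_image <- function(path, channel_roles, spacing = NULL,
                       n_channels = NULL, dtype_max = 65535) {
  if (!file.exists(path)) stop("image file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- read_sidecar(path)
  meta <- list()
  if (is.null(n_channels))
    n_channels <- if (!is.null(side$n_channels)) side$n_channels else 1L
  if (length(channel_roles) != n_channels)
    stop("channel count (", n_channels, ") does not match role list (",
         length(channel_roles), ")")
  if (length(pages) %% n_channels != 0L)
    stop("page count not divisible by channel count")
  nz <- length(pages) %/% n_channels

  ome_spacing <- parse_ome_spacing(attr(pages[[1L]], "description"),
                                   three_d = nz > 1L)
  if (is.null(spacing)) {
    spacing <- if (!is.null(ome_spacing)) ome_spacing
               else if (!is.null(side$spacing)) as.numeric(side$spacing)
               else NULL
  }
  if (!is.null(side$metadata)) meta <- side$metadata

  raw <- lapply(pages, function(p) {
    p <- as.array(p)
    if (length(dim(p)) == 3L) p <- p[, , 1L] # drop accidental RGB planes
    p <- round(p * dtype_max)
    attributes(p) <- list(dim = dim(p)) # shed TIFF tag attributes
    p
  })
  data <- vector("list", n_channels)
  for (c in seq_len(n_channels)) {
    planes <- raw[seq(c, length(raw), by = n_channels)]
    data[[c]] <- if (nz == 1L) planes[[1L]] else {
      a <- array(0, dim = c(nz, nrow(planes[[1L]]), ncol(planes[[1L]])))
      for (z in seq_len(nz)) a[z, , ] <- planes[[z]]
      a
    }
  }
  names(data) <- channel_roles
  image_stack(data, spacing = spacing, channels = channel_roles,
              metadata = meta, dtype_max = dtype_max)
}

#' Write an image_stack as a 16-bit multi-page TIFF with a JSON sidecar
#'
#' Pages are channel-fastest (see \code{\link{read_image}}); spacing,
#' channel roles and metadata go to \code{<path>.meta.json}, since the
#' available TIFF writer does not persist an ImageDescription tag. The
#' write/read roundtrip is bit-exact for integer intensities within the
#' declared scale.
#'
#' @param stack an \code{image_stack}; intensities must lie in
#'   \code{[0, dtype_max]}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(stack, path) {
  stopifnot(is_image_stack(stack))
  dmax <- stack$dtype_info$max
  d <- dim(stack$data[[1L]])
  nz <- if (length(d) == 3L) d[1L] else 1L
  pages <- list()
  for (z in seq_len(nz)) {
    for (ch in stack$channels) {
      a <- stack$data[[ch]]
      plane <- if (length(d) == 3L) a[z, , ] else a
      if (any(plane > dmax)) stop("intensities exceed dtype_max")
      pages[[length(pages) + 1L]] <- plane / dmax
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  side <- list(n_channels = length(stack$channels),
               channels = stack$channels,
               spacing = if (is.null(stack$spacing)) NULL
                         else unname(stack$spacing),
               metadata = stack$metadata)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(list())
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

# OME-XML PhysicalSizeX/Y/Z (micrometre default unit) -> spacing vector
parse_ome_spacing <- function(description, three_d = FALSE) {
  if (is.null(description) || !nzchar(description)) return(NULL)
  if (!grepl("OME", description, fixed = TRUE)) return(NULL)
  doc <- tryCatch(xml2::read_xml(description), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, "//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  g <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NA_real_ else as.numeric(v)
  }
  sx <- g("PhysicalSizeX"); sy <- g("PhysicalSizeY"); sz <- g("PhysicalSizeZ")
  if (is.na(sx) && is.na(sy) && is.na(sz)) return(NULL)
  if (is.na(sy)) sy <- sx
  if (three_d) {
    if (is.na(sz)) return(NULL)
    c(z = sz, y = sy, x = sx)
  } else c(y = sy, x = sx)
}

#' Result table: keyed measurements with provenance
#'
#' Rows are keyed by (egg id, assay, measurement name) and carry a numeric
#' value, units, the configuration hash and the seed, so identical inputs
#' reproduce byte-identical CSV output.
#'
#' @param egg_id,assay,measurement,value,units vectors of equal length.
#' @param config_hash,seed provenance scalars (recycled).
#' @return a \code{result_table} data.frame.
#' @export
result_table <- function(egg_id = character(), assay = character(),
                         measurement = character(), value = numeric(),
                         units = character(), config_hash = "", seed = NA) {
  n <- length(egg_id)
  df <- data.frame(egg_id = as.character(egg_id),
                   assay = rep_len(as.character(assay), n),
                   measurement = as.character(measurement),
                   value = as.numeric(value),
                   units = rep_len(as.character(units), n),
                   config_hash = rep_len(as.character(config_hash), n),
                   seed = rep_len(as.integer(seed), n),
                   stringsAsFactors = FALSE)
  key <- paste(df$egg_id, df$assay, df$measurement, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (egg_id, assay, measurement) keys in result table")
  class(df) <- c("result_table", "data.frame")
  df
}

#' Combine result tables, enforcing key uniqueness
#' @param ... \code{result_table}s
#' @export
bind_results <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  result_table(df$egg_id, df$assay, df$measurement, df$value, df$units,
               df$config_hash, df$seed)
}

#' Write a result table as CSV (fixed column order, full precision)
#' @param table a \code{result_table}
#' @param path output CSV path
#' @export
write_results <- function(table, path) {
  stopifnot(inherits(table, "result_table"))
  df <- as.data.frame(table)
  df$value <- vapply(df$value, function(v) format(v, digits = 17,
                                                  scientific = FALSE), "")
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a result table written by \code{write_results}
#' @param path CSV path
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$value <- as.numeric(df$value)
  result_table(df$egg_id, df$assay, df$measurement, df$value, df$units,
               df$config_hash, df$seed)
}
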