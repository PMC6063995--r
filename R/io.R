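# JSON / image interchange ----------------------------------------------------

#' Write a tile set as TIFF rasters plus a JSON tile specification
#'
#' The sidecar lists, per tile: tileId, sectionId, stageX_nm, stageY_nm,
#' width, height, pixelSize_nm, path.
#'
#' @param tileset \code{em_tileset}.
#' @param dir output directory (created if needed).
#' @param spec_name name of the JSON sidecar (default \code{"tilespec.json"}).
#' @return path of the JSON spec, invisibly.
#' @export
write_tilespec <- function(tileset, dir, spec_name = "tilespec.json") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- lapply(tileset$tiles, function(t) {
    img <- file.path(dir, paste0(t$tile_id, ".tiff"))
    write_raster(t$raster, img)
    list(tileId = t$tile_id, sectionId = t$section_id,
         stageX_nm = t$stage_xy[1], stageY_nm = t$stage_xy[2],
         width = ncol(t$raster), height = nrow(t$raster),
         pixelSize_nm = t$pixel_size, path = basename(img))
  })
  path <- file.path(dir, spec_name)
  jsonlite::write_json(unname(specs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tile set from a JSON tile specification
#' @param spec_path path to the JSON sidecar written by
#'   \code{\link{write_tilespec}}.
#' @return \code{em_tileset}.
#' @export
read_tilespec <- function(spec_path) {
  specs <- jsonlite::read_json(spec_path)
  dir <- dirname(spec_path)
  tiles <- lapply(specs, function(sp) {
    em_tile(read_raster(file.path(dir, sp$path)), sp$tileId, sp$sectionId,
            c(sp$stageX_nm, sp$stageY_nm), sp$pixelSize_nm)
  })
  em_tileset(tiles, section_id = specs[[1]]$sectionId)
}

#' Write solved transforms as JSON (tileId -> 6 coefficients)
#'
#' Coefficients are row-major \code{(a11, a12, a13, a21, a22, a23)} of the 2x3
#' affine matrix.
#'
#' @param transforms named list of \code{affine2d}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_transforms <- function(transforms, path) {
  obj <- lapply(transforms, function(tf) as.numeric(t(tf$m)))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Read transforms written by \code{\link{write_transforms}}
#' @param path JSON path.
#' @return named list of \code{affine2d}.
#' @export
read_transforms <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, affine2d)
}
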