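# Tiles and point matches ----------------------------------------------------

#' Construct a camera tile
#'
#' The unit of stitching: one grayscale raster plus the stage metadata needed
#' to seed matching (stage coordinates are priors, not truth).
#'
#' @param raster numeric matrix, gray levels.
#' @param tile_id unique string id.
#' @param section_id integer section index.
#' @param stage_xy recorded stage position (x, y) in nm.
#' @param pixel_size nominal pixel size in nm.
#' @return object of class \code{em_tile}.
#' @export
em_tile <- function(raster, tile_id, section_id, stage_xy, pixel_size) {
  if (!is.matrix(raster) || length(raster) == 0) stopf("tile raster must be a non-empty matrix")
  check_number(pixel_size, "pixel_size", positive = TRUE)
  structure(list(raster = raster, tile_id = as.character(tile_id),
                 section_id = as.integer(section_id),
                 stage_xy = as.numeric(stage_xy), pixel_size = pixel_size),
            class = "em_tile")
}

#' Construct a tile set
#' @param tiles list of \code{em_tile}.
#' @param section_id integer section index shared by the tiles.
#' @return object of class \code{em_tileset}.
#' @export
em_tileset <- function(tiles, section_id = tiles[[1]]$section_id) {
  ids <- vapply(tiles, function(t) t$tile_id, "")
  if (anyDuplicated(ids)) stopf("duplicate tile ids")
  structure(list(tiles = setNames(tiles, ids), section_id = as.integer(section_id)),
            class = "em_tileset")
}

#' @export
print.em_tileset <- function(x, ...) {
  cat(sprintf("<em_tileset> section %d, %d tiles\n", x$section_id, length(x$tiles)))
  invisible(x)
}

#' Stage-coordinate prior transforms for a tile set
#'
#' Converts recorded stage coordinates (nm) into per-tile translation priors
#' in section pixels, the initialization and regularization target of
#' \code{\link{solve_montage}}.
#'
#' @param tileset \code{em_tileset}.
#' @return named list of \code{affine2d}, one per tile.
#' @export
stage_priors <- function(tileset) {
  lapply(tileset$tiles, function(t) translate2d(t$stage_xy / t$pixel_size))
}

#' Construct a point-match set
#'
#' The currency of all registration stages: paired pixel locations asserted to
#' show the same content, one in each of two tiles (or sections).
#'
#' @param tile_id_a,tile_id_b distinct ids of the matched images.
#' @param pa,pb n x 2 matrices of (x, y) positions in the respective local frames.
#' @param weights non-negative per-match weights (default 1).
#' @param provenance \code{"intra-section"} or \code{"cross-section"}.
#' @return object of class \code{point_match_set}.
#' @export
point_match_set <- function(tile_id_a, tile_id_b, pa, pb, weights = NULL,
                            provenance = c("intra-section", "cross-section")) {
  provenance <- match.arg(provenance)
  if (identical(tile_id_a, tile_id_b)) stopf("matched ids must be distinct")
  pa <- matrix(as.numeric(pa), ncol = 2); pb <- matrix(as.numeric(pb), ncol = 2)
  if (nrow(pa) != nrow(pb)) stopf("pa and pb must have the same number of rows")
  if (is.null(weights)) weights <- rep(1, nrow(pa))
  if (any(weights < 0)) stopf("weights must be non-negative")
  structure(list(tile_id_a = as.character(tile_id_a), tile_id_b = as.character(tile_id_b),
                 pa = pa, pb = pb, weights = as.numeric(weights), provenance = provenance),
            class = "point_match_set")
}

n_matches <- function(ms) nrow(ms$pa)

#' @export
print.point_match_set <- function(x, ...) {
  cat(sprintf("<point_match_set> %s ~ %s: %d matches (%s)%s\n", x$tile_id_a,
              x$tile_id_b, n_matches(x), x$provenance,
              if (isTRUE(attr(x, "rejected"))) " [rejected]" else ""))
  invisible(x)
}
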