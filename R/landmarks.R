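#' Named anatomical landmark set
#'
#' The three bony landmarks anchoring the ET longitudinal-axis viewing
#' plane — the medial pterygoid plate, the hamulus of the opposite medial
#' pterygoid plate, and the sphenoid spine — plus optional balloon-derived
#' points (balloon tip, torus tip, and the two radiopaque marker beads at
#' the ends of the balloon's cylindrical segment). All points are 0-based
#' voxel-center coordinates in `(slice, row, col)` order.
#'
#' @param medial_pterygoid_plate,opposite_pterygoid_plate,sphenoid_spine
#'   numeric 3-vectors; must be pairwise distinct.
#' @param balloon_tip,torus_tip,marker_a,marker_b optional numeric
#'   3-vectors.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(medial_pterygoid_plate, opposite_pterygoid_plate,
                         sphenoid_spine, balloon_tip = NULL, torus_tip = NULL,
                         marker_a = NULL, marker_b = NULL) {
  pts <- list(medial_pterygoid_plate = medial_pterygoid_plate,
              opposite_pterygoid_plate = opposite_pterygoid_plate,
              sphenoid_spine = sphenoid_spine)
  for (nm in names(pts)) stop_if_not_point3(pts[[nm]], nm)
  opt <- list(balloon_tip = balloon_tip, torus_tip = torus_tip,
              marker_a = marker_a, marker_b = marker_b)
  for (nm in names(opt)) if (!is.null(opt[[nm]])) stop_if_not_point3(opt[[nm]], nm)
  dists <- c(vnorm(pts[[1]] - pts[[2]]), vnorm(pts[[1]] - pts[[3]]),
             vnorm(pts[[2]] - pts[[3]]))
  if (any(dists == 0))
    stop("plane landmarks must be pairwise distinct")
  structure(c(pts, opt[!vapply(opt, is.null, logical(1))]),
            class = "landmark_set")
}

LANDMARK_CONVENTION <- "voxel-0based-slice-row-col"

#' Write landmarks to a JSON annotation file
#'
#' The file carries an explicit coordinate-convention string
#' (`"voxel-0based-slice-row-col"`); [read_landmarks()] refuses files
#' without it, so annotations can never be silently misinterpreted.
#'
#' @param lm a [landmark_set()].
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_landmarks <- function(lm, path) {
  if (!inherits(lm, "landmark_set")) stop("'lm' must be a landmark_set")
  jsonlite::write_json(list(coordinate_convention = LANDMARK_CONVENTION,
                            points = unclass(lm)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a JSON landmark annotation file
#' @param path JSON file written in the package's landmark dialect.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  conv <- obj$coordinate_convention
  if (is.null(conv))
    stop("landmark file lacks a coordinate_convention field")
  if (!identical(conv, LANDMARK_CONVENTION))
    stop("unsupported coordinate convention: ", conv)
  do.call(landmark_set, lapply(obj$points, as.numeric))
}
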