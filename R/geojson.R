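# Minimal GeoJSON reading/writing for detection polygons and training
# annotations (FeatureCollection of Polygons with a "classification"
# property, the convention annotation viewers use).

#' Write cell polygons as GeoJSON
#'
#' @param polygons list of two-column (x, y) um matrices.
#' @param classes optional character vector (one per polygon) stored as the
#'   `classification` property.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cells_geojson <- function(polygons, classes = NULL, path) {
  features <- lapply(seq_along(polygons), function(i) {
    poly <- polygons[[i]]
    ring <- rbind(poly, poly[1L, , drop = FALSE])   # closed ring
    props <- if (!is.null(classes))
      list(classification = list(name = jsonlite::unbox(classes[i])))
    else stats::setNames(list(), character(0))
    list(type = jsonlite::unbox("Feature"),
         geometry = list(type = jsonlite::unbox("Polygon"),
                         coordinates = list(unname(as.matrix(ring)))),
         properties = props)
  })
  fc <- list(type = jsonlite::unbox("FeatureCollection"), features = features)
  jsonlite::write_json(fc, path, digits = 3, auto_unbox = FALSE)
  invisible(path)
}

#' Read training annotations from GeoJSON
#'
#' Reads a FeatureCollection of Polygon features whose `classification`
#' property (string, or object with a `name` field) names the tissue class.
#'
#' @param path GeoJSON file.
#' @return List of `list(polygon, tissue_class)`.
#' @export
read_annotations_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  lapply(fc$features, function(ft) {
    if (!identical(ft$geometry$type, "Polygon"))
      stop("only Polygon annotations are supported", call. = FALSE)
    ring <- ft$geometry$coordinates[[1L]]
    poly <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
    colnames(poly) <- c("x", "y")
    cls <- ft$properties$classification
    if (is.list(cls)) cls <- cls$name
    list(polygon = poly, tissue_class = as.character(cls))
  })
}
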