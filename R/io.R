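#' Flatten plants into a segment table
#'
#' @param plants A [init_plant()] object or a list of them.
#' @return A data frame with one row per segment: \code{plant_id},
#'   \code{branch_id}, \code{order}, \code{x0, y0, z0, x1, y1, z1} (mm).
#' @export
segments_df <- function(plants) {
  if (inherits(plants, "plant")) plants <- list(plants)
  do.call(rbind, lapply(plants, function(p) {
    data.frame(plant_id = p$id,
               branch_id = p$seg_branch,
               order = p$br_order[p$seg_branch],
               x0 = p$seg_start[, 1L], y0 = p$seg_start[, 2L],
               z0 = p$seg_start[, 3L],
               x1 = p$seg_end[, 1L], y1 = p$seg_end[, 2L],
               z1 = p$seg_end[, 3L])
  }))
}

#' Write root segments as CSV
#'
#' @param plants A [init_plant()] object or list of them.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_segments_csv <- function(plants, path) {
  utils::write.csv(segments_df(plants), path, row.names = FALSE)
  invisible(path)
}

#' Export a root system as RSML
#'
#' Writes the plant's branch topology and segment polylines in Root System
#' Markup Language. Each branch becomes a \code{<root>} element (nested under
#' its parent) whose geometry is the polyline of its segment endpoints.
#'
#' @param plant A [init_plant()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_rsml <- function(plant, path) {
  doc <- xml2::xml_new_root("rsml", version = "1.0")
  meta <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(meta, "version", "1")
  xml2::xml_add_child(meta, "unit", "mm")
  xml2::xml_add_child(meta, "resolution", "1")
  xml2::xml_add_child(meta, "software", "rootarch")
  scene <- xml2::xml_add_child(doc, "scene")
  plant_node <- xml2::xml_add_child(scene, "plant",
                                    id = as.character(plant$id))

  nb <- length(plant$br_order)
  branch_nodes <- vector("list", nb)
  # polyline of each branch: origin of its first segment, then segment ends
  polylines <- lapply(seq_len(nb), function(b) {
    rows <- which(plant$seg_branch == b)
    if (!length(rows)) return(NULL)
    rbind(plant$seg_start[rows[1L], ], plant$seg_end[rows, , drop = FALSE])
  })
  for (b in seq_len(nb)) {
    parent <- plant$br_parent[b]
    host <- if (is.na(parent)) plant_node else branch_nodes[[parent]]
    if (is.null(host)) host <- plant_node
    node <- xml2::xml_add_child(host, "root", id = as.character(b),
                                label = sprintf("order%d", plant$br_order[b]))
    branch_nodes[[b]] <- node
    pl <- polylines[[b]]
    if (is.null(pl)) next
    geom <- xml2::xml_add_child(node, "geometry")
    poly <- xml2::xml_add_child(geom, "polyline")
    for (r in seq_len(nrow(pl))) {
      xml2::xml_add_child(poly, "point",
                          x = format(pl[r, 1L], digits = 10),
                          y = format(pl[r, 2L], digits = 10),
                          z = format(pl[r, 3L], digits = 10))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a biomass time series as CSV
#'
#' @param result A [run_simulation()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_biomass_csv <- function(result, path) {
  np <- ncol(result$shoot)
  days <- nrow(result$shoot) - 1L
  df <- data.frame(plant_id = rep(seq_len(np), each = days + 1L),
                   day = rep(0:days, np),
                   shoot_g = as.vector(result$shoot),
                   root_g = as.vector(result$root))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
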