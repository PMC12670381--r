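#' Define a well-mixed zone
#'
#' A zone is a room, hallway, stairwell or attic space treated as a single
#' well-mixed volume.
#'
#' @param zone_id Character label, unique within a floorplan.
#' @param volume Zone air volume, m3 (> 0).
#' @param zone_kind One of `"kitchen"`, `"bedroom"`, `"living"`, `"hallway"`,
#'   `"attic"`, `"other"`.
#' @param has_window Does the zone have an operable exterior window?
#' @return A `zone` object.
#' @export
zone <- function(zone_id, volume,
                 zone_kind = c("kitchen", "bedroom", "living", "hallway",
                               "attic", "other"),
                 has_window = FALSE) {
  zone_kind <- match.arg(zone_kind)
  stopifnot(is.character(zone_id), length(zone_id) == 1L, nzchar(zone_id))
  if (identical(zone_id, OUTDOORS))
    stop("'OUTDOORS' is a reserved zone label", call. = FALSE)
  if (!is.finite(volume) || volume <= 0)
    stop("zone volume must be positive", call. = FALSE)
  structure(list(zone_id = zone_id, volume = volume, zone_kind = zone_kind,
                 has_window = isTRUE(has_window)),
            class = "zone")
}

#' Define an airflow path
#'
#' Paths connect two zones, or a zone and the outdoor node, and carry
#' bi-directional airflow. `reference_flow` is the flow (m3/h) each way at
#' reference driving conditions: for `"leakage"` paths the flow is scaled by
#' the wind/stack driver computed in [compute_flows()]; `"open_window"` and
#' `"interzone_opening"` paths carry their reference flow unscaled (window
#' paths only while the window is open).
#'
#' @param from_zone,to_zone Zone labels, or `"OUTDOORS"`.
#' @param kind One of `"leakage"`, `"open_window"`, `"interzone_opening"`.
#' @param reference_flow Flow each way, m3/h (>= 0).
#' @return A `flow_path` object.
#' @export
flow_path <- function(from_zone, to_zone,
                      kind = c("leakage", "open_window", "interzone_opening"),
                      reference_flow) {
  kind <- match.arg(kind)
  if (identical(from_zone, to_zone))
    stop("a flow path must connect two distinct nodes", call. = FALSE)
  if (!is.finite(reference_flow) || reference_flow < 0)
    stop("reference_flow must be non-negative", call. = FALSE)
  structure(list(from_zone = from_zone, to_zone = to_zone, kind = kind,
                 reference_flow = reference_flow),
            class = "flow_path")
}

#' Assemble a floorplan
#'
#' A floorplan is a connected network of well-mixed zones with exactly one
#' kitchen and at least one path to the outdoor node, plus the housing-stock
#' attributes used for ZIP-level weighting.
#'
#' @param floorplan_id Character label.
#' @param zones List of [zone()] objects.
#' @param paths List of [flow_path()] objects.
#' @param stories Number of stories (1 or more).
#' @param home_type One of `"mobile"`, `"single_detached"`, `"single_attached"`,
#'   `"multifamily"`.
#' @param floor_area_class One of `"0-1499"`, `"1500-2499"`, `"2500-3999"`,
#'   `">=4000"` (square feet).
#' @param has_forced_air Does the home have a central forced-air system?
#' @return A validated `floorplan` object.
#' @export
floorplan <- function(floorplan_id, zones, paths, stories = 1L,
                      home_type = c("mobile", "single_detached",
                                    "single_attached", "multifamily"),
                      floor_area_class = c("0-1499", "1500-2499", "2500-3999",
                                           ">=4000"),
                      has_forced_air = FALSE) {
  home_type <- match.arg(home_type)
  floor_area_class <- match.arg(floor_area_class)
  fp <- structure(
    list(floorplan_id = floorplan_id, zones = zones, paths = paths,
         stories = as.integer(stories), home_type = home_type,
         floor_area_class = floor_area_class,
         has_forced_air = isTRUE(has_forced_air)),
    class = "floorplan"
  )
  validate_floorplan(fp)
  fp
}

zone_ids <- function(fp) vapply(fp$zones, `[[`, "", "zone_id")
zone_volumes <- function(fp) {
  setNames(vapply(fp$zones, `[[`, 0, "volume"), zone_ids(fp))
}
zone_kinds <- function(fp) {
  setNames(vapply(fp$zones, `[[`, "", "zone_kind"), zone_ids(fp))
}
zone_windows <- function(fp) {
  setNames(vapply(fp$zones, `[[`, NA, "has_window"), zone_ids(fp))
}

#' Validate a floorplan
#'
#' Checks the structural invariants: unique zone labels, exactly one kitchen,
#' every path endpoint resolvable, full connectivity (every zone reachable from
#' every other through paths, including via the outdoor node is NOT counted),
#' and at least one path to the outdoor node.
#'
#' @param fp A `floorplan` object.
#' @return `fp`, invisibly; errors on violation.
#' @export
validate_floorplan <- function(fp) {
  stopifnot(inherits(fp, "floorplan"))
  ids <- zone_ids(fp)
  if (anyDuplicated(ids)) stop("duplicate zone labels", call. = FALSE)
  kinds <- zone_kinds(fp)
  if (sum(kinds == "kitchen") != 1L)
    stop("floorplan must have exactly one kitchen zone", call. = FALSE)
  ends <- unlist(lapply(fp$paths, function(p) c(p$from_zone, p$to_zone)))
  unknown <- setdiff(ends, c(ids, OUTDOORS))
  if (length(unknown))
    stop("flow path references unknown zone(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!any(ends == OUTDOORS))
    stop("floorplan must have at least one path to OUTDOORS", call. = FALSE)
  # connectivity among indoor zones via indoor-indoor paths
  if (length(ids) > 1L) {
    adj <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
    for (p in fp$paths) {
      if (p$from_zone != OUTDOORS && p$to_zone != OUTDOORS) {
        adj[p$from_zone, p$to_zone] <- TRUE
        adj[p$to_zone, p$from_zone] <- TRUE
      }
    }
    seen <- ids[1L]
    repeat {
      nxt <- unique(c(seen, ids[colSums(adj[seen, , drop = FALSE]) > 0]))
      if (length(nxt) == length(seen)) break
      seen <- nxt
    }
    if (length(seen) < length(ids))
      stop("floorplan is disconnected: zones ",
           paste(setdiff(ids, seen), collapse = ", "),
           " are unreachable", call. = FALSE)
  }
  invisible(fp)
}

#' @exportS3Method base::print
print.floorplan <- function(x, ...) {
  cat(sprintf("<floorplan %s> %s, %s ft2, %d story(ies), forced air: %s\n",
              x$floorplan_id, x$home_type, x$floor_area_class, x$stories,
              x$has_forced_air))
  cat(sprintf("  %d zones (%.0f m3 total), %d flow paths\n",
              length(x$zones), sum(zone_volumes(x)), length(x$paths)))
  invisible(x)
}

fp_to_list <- function(fp) {
  list(
    floorplan_id = fp$floorplan_id,
    stories = fp$stories, home_type = fp$home_type,
    floor_area_class = fp$floor_area_class,
    has_forced_air = fp$has_forced_air,
    zones = lapply(fp$zones, function(z) z[c("zone_id", "volume", "zone_kind",
                                             "has_window")]),
    paths = lapply(fp$paths, function(p) p[c("from_zone", "to_zone", "kind",
                                             "reference_flow")])
  )
}

#' Write floorplans to JSON
#'
#' Serializes a list of floorplans as a versioned JSON document.
#'
#' @param fps A list of `floorplan` objects (or a single one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_floorplans_json <- function(fps, path) {
  if (inherits(fps, "floorplan")) fps <- list(fps)
  doc <- list(schema = "no2home/floorplans", schema_version = "1.0",
              floorplans = lapply(fps, fp_to_list))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read floorplans from JSON
#'
#' @param path A file written by [write_floorplans_json()].
#' @return A list of validated `floorplan` objects.
#' @export
read_floorplans_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$schema, "no2home/floorplans"))
    stop("not a floorplan document", call. = FALSE)
  lapply(doc$floorplans, function(f) {
    floorplan(
      floorplan_id = f$floorplan_id,
      zones = lapply(f$zones, function(z)
        zone(z$zone_id, z$volume, z$zone_kind, z$has_window)),
      paths = lapply(f$paths, function(p)
        flow_path(p$from_zone, p$to_zone, p$kind, p$reference_flow)),
      stories = f$stories, home_type = f$home_type,
      floor_area_class = f$floor_area_class,
      has_forced_air = f$has_forced_air
    )
  })
}
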