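# Centerline geometry: axisymmetric lumen profiles and coronary trees.
#
# Geometry is held as centerline arc length s (mm) plus lumen radius r (mm);
# the reduced-order solver needs only d(s), so no 3-D surface is stored.

#' Centerline lumen profile
#'
#' A vessel segment described by arc length from the segment origin and the
#' lumen radius at each sample. Arc length must be strictly increasing and
#' all radii positive; at least two samples are required.
#'
#' @param s_mm numeric vector, arc length from segment origin (mm),
#'   strictly increasing
#' @param r_mm numeric vector, lumen radius (mm) at each `s_mm`, all > 0
#' @return an object of class `centerline_profile`
#' @examples
#' p <- centerline_profile(seq(0, 100, 5), rep(1.5, 21))
#' profile_length(p)
#' @export
centerline_profile <- function(s_mm, r_mm) {
  s_mm <- as.numeric(s_mm)
  r_mm <- as.numeric(r_mm)
  if (length(s_mm) != length(r_mm))
    stop_ffrct("s_mm and r_mm must have equal length", class = "ffrct_geometry_error")
  if (length(s_mm) < 2L)
    stop_ffrct("a centerline profile needs at least 2 samples", class = "ffrct_geometry_error")
  if (any(!is.finite(s_mm)) || any(!is.finite(r_mm)))
    stop_ffrct("non-finite values in centerline profile", class = "ffrct_geometry_error")
  if (any(diff(s_mm) <= 0))
    stop_ffrct("arc length s_mm must be strictly increasing", class = "ffrct_geometry_error")
  if (any(r_mm <= 0))
    stop_ffrct("all radii must be positive", class = "ffrct_geometry_error")
  structure(list(s_mm = s_mm, r_mm = r_mm), class = "centerline_profile")
}

#' @export
print.centerline_profile <- function(x, ...) {
  cat(sprintf("<centerline_profile> %d samples, s in [%.2f, %.2f] mm, d in [%.3f, %.3f] mm\n",
              length(x$s_mm), x$s_mm[1], x$s_mm[length(x$s_mm)],
              2 * min(x$r_mm), 2 * max(x$r_mm)))
  invisible(x)
}

#' Segment length of a profile (mm)
#' @param profile a [centerline_profile()]
#' @return numeric scalar, mm
#' @export
profile_length <- function(profile) {
  profile$s_mm[length(profile$s_mm)] - profile$s_mm[1]
}

#' Resample a centerline profile on a uniform grid
#'
#' Radii are interpolated with a monotone shape-preserving cubic Hermite
#' spline (Fritsch-Carlson), which cannot overshoot and therefore cannot
#' manufacture spurious narrowings. Endpoints are preserved exactly; the
#' last interval may be shorter than `ds` so that the distal endpoint is
#' always retained.
#'
#' @param profile a [centerline_profile()]
#' @param ds target spacing (mm), 0 < ds <= segment length
#' @return a resampled [centerline_profile()]
#' @export
resample_profile <- function(profile, ds) {
  if (!inherits(profile, "centerline_profile"))
    profile <- centerline_profile(profile$s_mm, profile$r_mm)
  len <- profile_length(profile)
  if (!is.finite(ds) || ds <= 0 || ds > len)
    stop_ffrct("ds must satisfy 0 < ds <= segment length (%.3f mm)", len,
               class = "ffrct_geometry_error")
  s0 <- profile$s_mm[1]
  s1 <- profile$s_mm[length(profile$s_mm)]
  s_new <- seq(s0, s1, by = ds)
  if (s_new[length(s_new)] < s1) s_new <- c(s_new, s1)
  f <- stats::splinefun(profile$s_mm, profile$r_mm, method = "monoH.FC")
  r_new <- f(s_new)
  # endpoints bit-exact
  r_new[1] <- profile$r_mm[1]
  r_new[length(r_new)] <- profile$r_mm[length(profile$r_mm)]
  centerline_profile(s_new, r_new)
}

#' Coronary vessel tree
#'
#' A rooted tree of centerline segments. Each segment carries a lumen
#' profile and (except the root) a parent id; a child attaches at its
#' parent's distal end unless `branch_s_mm` names an interior branch point.
#' The tree also carries the myocardial volume, which scales total coronary
#' flow through the allometric inflow model.
#'
#' @param segments named list; each element is a list with components
#'   `profile` (a [centerline_profile()]), `parent` (id or `NULL` for the
#'   root), optional `branch_s_mm` (arc length on the parent where this
#'   branch leaves; `NULL` means the parent's distal end) and optional
#'   `label` (one of "LAD", "LCX", "RCA", "other")
#' @param inlet id of the root segment
#' @param myocardial_volume_ml myocardial volume Vm (mL), > 0
#' @return an object of class `coronary_tree`
#' @export
coronary_tree <- function(segments, inlet, myocardial_volume_ml) {
  if (length(segments) == 0L || is.null(names(segments)) || any(names(segments) == ""))
    stop_ffrct("segments must be a non-empty named list", class = "ffrct_topology_error")
  if (!is.finite(myocardial_volume_ml) || myocardial_volume_ml <= 0)
    stop_ffrct("myocardial_volume must be a positive number (mL)",
               class = "ffrct_schema_error")
  ids <- names(segments)
  roots <- character(0)
  for (id in ids) {
    seg <- segments[[id]]
    if (!inherits(seg$profile, "centerline_profile"))
      segments[[id]]$profile <- centerline_profile(seg$profile$s_mm, seg$profile$r_mm)
    if (is.null(seg$parent)) {
      roots <- c(roots, id)
    } else {
      if (!seg$parent %in% ids)
        stop_ffrct("segment '%s' names unknown parent '%s'", id, seg$parent,
                   class = "ffrct_topology_error")
      if (!is.null(seg$branch_s_mm)) {
        ps <- segments[[seg$parent]]$profile$s_mm
        if (seg$branch_s_mm < ps[1] || seg$branch_s_mm > ps[length(ps)])
          stop_ffrct("branch point of '%s' lies outside parent '%s'", id, seg$parent,
                     class = "ffrct_topology_error")
      }
    }
    segments[[id]]$label <- seg$label %||% "other"
  }
  if (length(roots) != 1L)
    stop_ffrct("tree must have exactly one root (found %d)", length(roots),
               class = "ffrct_topology_error")
  if (!identical(roots, inlet) && !(inlet %in% roots))
    stop_ffrct("inlet '%s' is not the root segment ('%s')", inlet, roots[1],
               class = "ffrct_topology_error")
  # acyclicity: walk to root from every segment
  for (id in ids) {
    seen <- character(0)
    cur <- id
    while (!is.null(segments[[cur]]$parent)) {
      if (cur %in% seen)
        stop_ffrct("cycle in topology involving segment '%s'", cur,
                   class = "ffrct_topology_error")
      seen <- c(seen, cur)
      cur <- segments[[cur]]$parent
    }
  }
  structure(list(segments = segments, inlet = inlet,
                 myocardial_volume_ml = myocardial_volume_ml),
            class = "coronary_tree")
}

#' @export
print.coronary_tree <- function(x, ...) {
  cat(sprintf("<coronary_tree> %d segment(s), inlet '%s', Vm = %.1f mL\n",
              length(x$segments), x$inlet, x$myocardial_volume_ml))
  invisible(x)
}

tree_children <- function(tree, id) {
  kids <- character(0)
  for (k in names(tree$segments))
    if (!is.null(tree$segments[[k]]$parent) && tree$segments[[k]]$parent == id)
      kids <- c(kids, k)
  kids
}

#' Read a coronary tree from its JSON representation
#'
#' The schema is
#' `{"myocardial_volume_ml": number, "inlet": id, "segments": {id:
#' {"s_mm": [...], "r_mm": [...], "parent": id|null,
#' "branch_s_mm": number|null, "label": "LAD|LCX|RCA|other"}}}`.
#' Numbers are serialized with full decimal precision so that a
#' write/read round trip reproduces every numeric field exactly.
#'
#' @param path path to a JSON file
#' @return a [coronary_tree()]
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$myocardial_volume_ml))
    stop_ffrct("tree file is missing field 'myocardial_volume_ml'",
               class = "ffrct_schema_error")
  if (is.null(obj$inlet))
    stop_ffrct("tree file is missing field 'inlet'", class = "ffrct_schema_error")
  if (is.null(obj$segments) || length(obj$segments) == 0L)
    stop_ffrct("tree file is missing field 'segments'", class = "ffrct_schema_error")
  segs <- lapply(obj$segments, function(sg) {
    if (is.null(sg$s_mm) || is.null(sg$r_mm))
      stop_ffrct("segment is missing 's_mm' or 'r_mm'", class = "ffrct_schema_error")
    list(profile = centerline_profile(unlist(sg$s_mm), unlist(sg$r_mm)),
         parent = if (is.null(sg$parent)) NULL else as.character(sg$parent),
         branch_s_mm = if (is.null(sg$branch_s_mm)) NULL else as.numeric(sg$branch_s_mm),
         label = if (is.null(sg$label)) "other" else as.character(sg$label))
  })
  names(segs) <- names(obj$segments)
  coronary_tree(segs, as.character(obj$inlet), as.numeric(obj$myocardial_volume_ml))
}

#' Write a coronary tree to JSON
#'
#' @param tree a [coronary_tree()]
#' @param path output path
#' @return `path`, invisibly
#' @rdname read_tree
#' @export
write_tree <- function(tree, path) {
  segs <- lapply(tree$segments, function(sg) {
    out <- list(s_mm = sg$profile$s_mm, r_mm = sg$profile$r_mm,
                parent = sg$parent, branch_s_mm = sg$branch_s_mm,
                label = sg$label %||% "other")
    out
  })
  obj <- list(myocardial_volume_ml = tree$myocardial_volume_ml,
              inlet = tree$inlet, segments = segs)
  # 17 significant digits: doubles survive the decimal round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Export per-sample geometry with reference diameters as CSV
#'
#' One row per resampled centerline sample with the local diameter, the
#' interpolated reference diameter and percent diameter stenosis.
#'
#' @param tree a [coronary_tree()]
#' @param path output CSV path
#' @param ds resampling spacing (mm)
#' @param ... passed to [detect_lesions()]
#' @return the exported data frame, invisibly
#' @export
write_geometry_csv <- function(tree, path, ds = 0.5, ...) {
  lesions <- detect_lesions(tree, ds = ds, ...)
  rows <- list()
  for (id in names(tree$segments)) {
    prof <- resample_profile(tree$segments[[id]]$profile, ds)
    d <- 2 * prof$r_mm
    ref <- segment_reference(prof, lesions[lesions$segment_id == id, , drop = FALSE])
    rows[[id]] <- data.frame(segment = id, s_mm = prof$s_mm, diameter_mm = d,
                             reference_diameter_mm = ref,
                             pct_ds = 100 * pmax(0, 1 - d / ref))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
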