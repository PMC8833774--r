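#' Charlton-style helical DNA geometry parameters
#'
#' Cylinder-and-arches DNA model: a central cylinder of bases (1 nm diameter)
#' surrounded by two backbone strands occupying the annulus out to a 2.3 nm
#' total diameter, sliced into 0.34 nm slabs (one per base) that rotate by 36
#' degrees per base, giving ten bases per turn. The helix axis is the z axis;
#' base `i` occupies the half-open slab `z in [i*t, (i+1)*t)`. Each slab's
#' annulus is split into two arcs (one per strand) on opposite sides, rotated
#' with the twist; with the default 180-degree arc width the two strands tile
#' the annulus exactly. Radicals within `scavenge_radius` of the axis are
#' treated as scavenged by the strand. The iodine sits in base 0, offset
#' towards strand 0 (the proximal strand).
#'
#' @param base_radius Radius of the central base cylinder, nm (default 0.5).
#' @param outer_radius Outer radius of the backbone annulus, nm (default 1.15).
#' @param slab_thickness Slab thickness per base, nm (default 0.34).
#' @param twist_step Helical twist per base in degrees (default 36); must
#'   divide 360.
#' @param n_bases Number of bases (default 40).
#' @param scavenge_radius OH scavenging radius, nm (default 1.65; strict
#'   inequality).
#' @param arc_width Azimuthal extent of each backbone arc in degrees
#'   (default 180).
#' @param iodine_offset Radial offset of the iodine towards strand 0, nm
#'   (default 0.15).
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(base_radius = 0.5, outer_radius = 1.15,
                            slab_thickness = 0.34, twist_step = 36,
                            n_bases = 40L, scavenge_radius = 1.65,
                            arc_width = 180, iodine_offset = 0.15) {
  if (!(base_radius > 0 && base_radius < outer_radius)) {
    abort("need 0 < base_radius < outer_radius")
  }
  if (slab_thickness <= 0) abort("slab_thickness must be > 0")
  if (360 %% twist_step != 0) abort("twist_step must divide 360")
  if (arc_width <= 0 || arc_width > 180) abort("arc_width must be in (0, 180]")
  structure(
    list(base_radius = base_radius, outer_radius = outer_radius,
         slab_thickness = slab_thickness, twist_step = twist_step,
         n_bases = assert_count(n_bases), scavenge_radius = scavenge_radius,
         arc_width = arc_width, iodine_offset = iodine_offset),
    class = "geometry_params"
  )
}

#' Bases per complete helical turn
#'
#' @param params A [geometry_params()].
#' @return `360 / twist_step`; 10 for the default 36-degree twist.
#' @export
bases_per_turn <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  as.integer(360 / params$twist_step)
}

# Smallest absolute angular difference in degrees, in [0, 180].
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Classify 3D points into DNA volumes
#'
#' Maps each point to exactly one region: `base` (inside the central
#' cylinder), `backbone` (in the annulus, within a strand's arc for that
#' slab), or `outside`. Deterministic; slab intervals are half-open in z so
#' the partition is exact at boundaries.
#'
#' @param points A data frame with columns `x_nm`, `y_nm`, `z_nm`.
#' @param params A [geometry_params()].
#' @return The input tibble with added columns `region` (`"base"`,
#'   `"backbone"` or `"outside"`), `base` (slab index or `NA`) and `strand`
#'   (0/1 or `NA`).
#' @export
classify_points <- function(points, params = geometry_params()) {
  stopifnot(inherits(params, "geometry_params"))
  points <- tibble::as_tibble(points)
  stopifnot(all(c("x_nm", "y_nm", "z_nm") %in% names(points)))
  r <- sqrt(points$x_nm^2 + points$y_nm^2)
  slab <- floor(points$z_nm / params$slab_thickness)
  in_z <- slab >= 0 & slab < params$n_bases
  theta <- (atan2(points$y_nm, points$x_nm) * 180 / pi) %% 360
  # strand s arc centre for slab i: i * twist + s * 180 degrees
  centre0 <- (slab * params$twist_step) %% 360
  d0 <- angle_diff(theta, centre0)
  d1 <- angle_diff(theta, (centre0 + 180) %% 360)
  half <- params$arc_width / 2
  region <- rep("outside", nrow(points))
  strand <- rep(NA_integer_, nrow(points))
  base <- rep(NA_integer_, nrow(points))
  is_base <- in_z & r < params$base_radius
  is_bb <- in_z & r >= params$base_radius & r < params$outer_radius &
    (d0 < half | d1 < half)
  region[is_base] <- "base"
  base[is_base | is_bb] <- as.integer(slab[is_base | is_bb])
  region[is_bb] <- "backbone"
  strand[is_bb] <- ifelse(d0[is_bb] <= d1[is_bb], 0L, 1L)
  dplyr::mutate(points, region = region, base = base, strand = strand)
}

#' OH scavenging predicate
#'
#' A radical is scavenged when its radial distance from the helix axis is
#' strictly less than the scavenging radius (1.65 nm by default).
#'
#' @param points A data frame with columns `x_nm`, `y_nm` (and optionally
#'   `z_nm`, unused: scavenging is radial only).
#' @param params A [geometry_params()].
#' @return Logical vector.
#' @export
is_scavenged <- function(points, params = geometry_params()) {
  stopifnot(inherits(params, "geometry_params"))
  sqrt(points$x_nm^2 + points$y_nm^2) < params$scavenge_radius
}

#' Convert raw-position scored records to a site-indexed event dataset
#'
#' Ingests tuple-scorer style rows carrying 3D positions -- columns
#' `event_id`, `record_type` (`EDEP`/`OH`), `x_nm`, `y_nm`, `z_nm`,
#' `energy_eV` -- and converts them to the (strand, base)-indexed schema the
#' damage models consume. Energy depositions are kept only when they fall in
#' a backbone volume (the scored quantity for direct damage); OH records are
#' kept when scavenged (radial position under the scavenging radius, within
#' the strand's z extent) and are assigned the slab's base index and the
#' azimuthally nearer strand.
#'
#' @param records A data frame with the columns above (`energy_eV` may be
#'   `NA` for OH rows).
#' @param params A [geometry_params()].
#' @param n_decays Number of decays scored; inferred from `event_id` when
#'   omitted.
#' @param label Dataset label.
#' @return A [track_dataset()].
#' @export
positions_to_events <- function(records, params = geometry_params(),
                                n_decays = NULL, label = "raw-positions") {
  records <- tibble::as_tibble(records)
  cls <- classify_points(records, params)
  edep <- dplyr::filter(cls, .data$record_type == "EDEP",
                        .data$region == "backbone")
  slab <- floor(cls$z_nm / params$slab_thickness)
  oh_keep <- cls$record_type == "OH" & is_scavenged(cls, params) &
    slab >= 0 & slab < params$n_bases
  oh <- cls[oh_keep, , drop = FALSE]
  if (nrow(oh)) {
    centre0 <- ((floor(oh$z_nm / params$slab_thickness)) * params$twist_step) %% 360
    theta <- (atan2(oh$y_nm, oh$x_nm) * 180 / pi) %% 360
    oh$strand <- ifelse(angle_diff(theta, centre0) <=
                          angle_diff(theta, (centre0 + 180) %% 360), 0L, 1L)
    oh$base <- as.integer(floor(oh$z_nm / params$slab_thickness))
  }
  out <- dplyr::bind_rows(
    tibble::tibble(event_id = edep$event_id, record_type = "EDEP",
                   strand = edep$strand, base = edep$base,
                   energy_eV = edep$energy_eV),
    tibble::tibble(event_id = oh$event_id, record_type = "OH",
                   strand = oh$strand, base = oh$base, energy_eV = NA_real_)
  )
  n_decays <- n_decays %||% (if (nrow(records)) max(records$event_id) + 1L else 0L)
  track_dataset(out, n_decays = n_decays, n_bases = params$n_bases, label = label)
}
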