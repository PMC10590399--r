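#' Potential-model accessibility index
#'
#' Gravity-style accessibility of a candidate site to a set of transport
#' hubs (airports or railway stations): the sum over hubs of service
#' capacity divided by distance, `sum_j M_j / D_j`. The index is additive
#' over hub partitions, increasing in any capacity and decreasing in any
#' distance; halving all distances doubles the index.
#'
#' @param capacities Nonnegative hub service capacities `M_j` (unitless
#'   scores; only internal consistency matters).
#' @param distances Positive distances `D_j` from the site to each hub
#'   (km).
#' @return The accessibility index (0 for an empty hub list).
#' @examples
#' potential_index(c(100, 50), c(4, 2))  # 25 + 25 = 50
#' @export
potential_index <- function(capacities, distances) {
  stopifnot(is.numeric(capacities), is.numeric(distances),
            length(capacities) == length(distances))
  if (length(capacities) == 0L) return(0)
  if (any(!is.finite(capacities)) || any(capacities < 0)) {
    stop("capacities must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(distances)) || any(distances <= 0)) {
    stop("distances must be finite and > 0 (the potential model is ",
         "undefined at zero distance)", call. = FALSE)
  }
  sum(capacities / distances)
}

#' Distance to the nearest designated hospital
#'
#' The minimum over a facility's distances to eligible hospitals
#' (infectious-disease or top-tier general hospitals; eligibility is
#' resolved upstream by the user's hospital list). Feeds a cost-direction
#' Shili criterion: nearer is better.
#'
#' @param distances Positive distances (km) from one facility to each
#'   designated hospital; must be nonempty.
#' @return The minimum distance.
#' @examples
#' nearest_hospital_distance(c(3.2, 1.1, 7))  # 1.1
#' @export
nearest_hospital_distance <- function(distances) {
  if (length(distances) == 0L) {
    stop("no hospital distances configured for this facility", call. = FALSE)
  }
  stopifnot(is.numeric(distances))
  if (any(!is.finite(distances)) || any(distances <= 0)) {
    stop("hospital distances must be finite and > 0", call. = FALSE)
  }
  min(distances)
}

#' Space-scale (bed-equivalent capacity) of a facility
#'
#' Available indoor area divided by the specified per-capita area: the
#' number of temporary beds the site can host (benefit criterion).
#'
#' @param area_m2 Available indoor area `S` (m^2), positive.
#' @param per_capita_m2 Specified per-capita area `A` (m^2 per bed),
#'   positive.
#' @return Bed-equivalent capacity `S / A`.
#' @examples
#' space_scale(10000, 4)  # 2500 beds
#' @export
space_scale <- function(area_m2, per_capita_m2) {
  stopifnot(is.numeric(area_m2), is.numeric(per_capita_m2))
  if (any(!is.finite(area_m2)) || any(area_m2 <= 0) ||
      any(!is.finite(per_capita_m2)) || any(per_capita_m2 <= 0)) {
    stop("areas must be finite and > 0", call. = FALSE)
  }
  area_m2 / per_capita_m2
}

#' Assemble Shili criterion columns from raw attribute tables
#'
#' Convenience wrapper joining the three calculators over per-facility
#' tables. Road accessibility is deliberately not computed here: it comes
#' from a drive-time isochrone analysis (GIS) and enters as a precomputed
#' "settlements covered" count.
#'
#' @param facilities Data frame with columns `id`, `name` and optionally
#'   `category`, `road_coverage`, `area_m2`.
#' @param air_hubs,rail_hubs Data frames `(facility_id, hub_id, capacity,
#'   distance_km)`; may be `NULL`.
#' @param hospitals Data frame `(facility_id, hospital_id, distance_km)`;
#'   may be `NULL`.
#' @param per_capita_m2 Per-capita area for [space_scale()].
#' @return Data frame keyed by facility `id` with the computed criterion
#'   columns (`air_access`, `rail_access`, `road_access`, `hospital_km`,
#'   `beds`), ready to merge into a Shili decision matrix.
#' @export
shili_criterion_table <- function(facilities, air_hubs = NULL,
                                  rail_hubs = NULL, hospitals = NULL,
                                  per_capita_m2 = 4) {
  stopifnot(is.data.frame(facilities), "id" %in% names(facilities))
  out <- data.frame(id = facilities$id, stringsAsFactors = FALSE)
  pot <- function(tab, fid) {
    rows <- tab[tab$facility_id == fid, , drop = FALSE]
    potential_index(rows$capacity, rows$distance_km)
  }
  if (!is.null(air_hubs)) {
    out$air_access <- vapply(out$id, function(f) pot(air_hubs, f),
                             numeric(1))
  }
  if (!is.null(rail_hubs)) {
    out$rail_access <- vapply(out$id, function(f) pot(rail_hubs, f),
                              numeric(1))
  }
  if (!is.null(facilities$road_coverage)) {
    out$road_access <- facilities$road_coverage
  }
  if (!is.null(hospitals)) {
    out$hospital_km <- vapply(out$id, function(f) {
      nearest_hospital_distance(
        hospitals$distance_km[hospitals$facility_id == f])
    }, numeric(1))
  }
  if (!is.null(facilities$area_m2)) {
    out$beds <- space_scale(facilities$area_m2, per_capita_m2)
  }
  out
}
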