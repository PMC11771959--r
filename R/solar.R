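#' Site configuration
#'
#' Describes the breeding-colony site: geographic position for solar
#' calculations, the fixed UTC offset used to define the local day, and the
#' colony position in the local planar (east/north, meters) frame in which
#' all fix coordinates live.
#'
#' @param latitude Decimal degrees, positive north. Default is the Hula
#'   Valley colony site (33.05).
#' @param longitude Decimal degrees, positive east (default 35.59).
#' @param utc_offset Hours added to UTC to obtain local clock time. Fixed
#'   (no DST transitions); timing metrics are relative to sunrise/sunset and
#'   are offset-invariant.
#' @param colony_xy Numeric length-2, colony position (x, y) in meters.
#' @return A list of class `site_config`.
#' @export
site_config <- function(latitude = 33.05, longitude = 35.59, utc_offset = 3,
                        colony_xy = c(0, 0)) {
  stopifnot(is.numeric(latitude), abs(latitude) <= 90,
            is.numeric(longitude), abs(longitude) <= 180,
            is.numeric(utc_offset), length(colony_xy) == 2)
  structure(list(latitude = latitude, longitude = longitude,
                 utc_offset = utc_offset, colony_xy = as.numeric(colony_xy)),
            class = "site_config")
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Sunrise, sunset and day length for a site and date
#'
#' NOAA solar-position calculation (the spreadsheet formulation), with the
#' standard -0.833 degree zenith correction for refraction and the solar
#' disc. Accuracy is well under a minute at mid latitudes, which is far
#' below the 8-s fix interval that limits the timing metrics anyway.
#'
#' @param site A [site_config()].
#' @param date A `Date` (vectorized).
#' @return A data.frame with one row per date: `date`, `sunrise` and
#'   `sunset` (`POSIXct`, UTC), and `day_length` in hours.
#' @export
sun_times <- function(site, date) {
  stopifnot(inherits(site, "site_config"), inherits(date, "Date"))
  lat <- site$latitude; lon <- site$longitude
  # Julian day at civil noon UTC of the date
  jd <- as.numeric(date) + 2440587.5 + 0.5
  jc <- (jd - 2451545) / 36525
  gmls <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqctr <- sin(.deg2rad(gmas)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(.deg2rad(2 * gmas)) * (0.019993 - 0.000101 * jc) +
    sin(.deg2rad(3 * gmas)) * 0.000289
  truelong <- gmls + eqctr
  applong <- truelong - 0.00569 - 0.00478 * sin(.deg2rad(125.04 - 1934.136 * jc))
  mobliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- mobliq + 0.00256 * cos(.deg2rad(125.04 - 1934.136 * jc))
  declin <- asin(sin(.deg2rad(obliq)) * sin(.deg2rad(applong)))
  vary <- tan(.deg2rad(obliq / 2))^2
  eqtime <- 4 * .rad2deg(
    vary * sin(2 * .deg2rad(gmls)) - 2 * ecc * sin(.deg2rad(gmas)) +
      4 * ecc * vary * sin(.deg2rad(gmas)) * cos(2 * .deg2rad(gmls)) -
      0.5 * vary^2 * sin(4 * .deg2rad(gmls)) -
      1.25 * ecc^2 * sin(2 * .deg2rad(gmas)))
  cos_ha <- cos(.deg2rad(90.833)) / (cos(.deg2rad(lat)) * cos(declin)) -
    tan(.deg2rad(lat)) * tan(declin)
  if (any(cos_ha < -1 | cos_ha > 1)) {
    stop("polar day or night: no sunrise/sunset at latitude ", lat,
         " on ", paste(date[cos_ha < -1 | cos_ha > 1], collapse = ", "))
  }
  ha <- .rad2deg(acos(cos_ha))
  noon_min <- 720 - 4 * lon - eqtime            # minutes after UTC midnight
  sunrise_min <- noon_min - 4 * ha
  sunset_min <- noon_min + 4 * ha
  midnight <- as.POSIXct(as.character(date), tz = "UTC")
  data.frame(
    date = date,
    sunrise = midnight + 60 * sunrise_min,
    sunset = midnight + 60 * sunset_min,
    day_length = (sunset_min - sunrise_min) / 60
  )
}

#' Local calendar date of a UTC timestamp under the site's fixed UTC offset
#'
#' @param t `POSIXct` timestamps (UTC).
#' @param site A [site_config()].
#' @return A `Date` vector.
#' @export
local_date <- function(t, site) {
  as.Date(t + site$utc_offset * 3600, tz = "UTC")
}
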