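#' Solar position from standard declination/hour-angle astronomy
#'
#' Declination follows the Spencer Fourier series; the hour angle assumes
#' local solar time (solar noon at hour 12), which is the convention of all
#' timestamps in this package. Elevation is clamped to [-90, 90].
#'
#' @param latitude degrees North (|latitude| <= 90).
#' @param doy day of year (1-366); vectorized.
#' @param hour local solar time, hours; vectorized.
#' @return list with \code{elevation} and \code{azimuth} (degrees, azimuth
#'   clockwise from North) and \code{declination} (degrees).
#' @export
solar_position <- function(latitude, doy, hour) {
  stopifnot(abs(latitude) <= 90)
  g <- 2 * pi * (doy - 1) / 365
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  phi <- latitude * pi / 180
  H <- (hour - 12) * 15 * pi / 180
  sinel <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(H)
  sinel <- pmin(1, pmax(-1, sinel))
  el <- asin(sinel)
  cosaz <- (sin(decl) - sin(phi) * sinel) / (cos(phi) * pmax(cos(el), 1e-9))
  cosaz <- pmin(1, pmax(-1, cosaz))
  az <- acos(cosaz)
  az <- ifelse(H > 0, 2 * pi - az, az)
  list(elevation = el * 180 / pi, azimuth = az * 180 / pi,
       declination = decl * 180 / pi)
}

# unit vector pointing toward the sun (x east, y north, z up)
sun_vector <- function(elevation, azimuth) {
  el <- elevation * pi / 180; az <- azimuth * pi / 180
  c(sin(az) * cos(el), cos(az) * cos(el), sin(el))
}

#' Diffuse fraction of global radiation (Erbs correlation)
#'
#' @param global global radiation on the horizontal, W m-2.
#' @param elevation solar elevation, degrees.
#' @return fraction of global that is diffuse, in [0, 1].
#' @export
diffuse_fraction <- function(global, elevation) {
  s <- sin(pmax(elevation, 0) * pi / 180)
  kt <- ifelse(s > 0, pmin(global / (1367 * pmax(s, 1e-6)), 1), 0)
  df <- ifelse(kt <= 0.22, 1 - 0.09 * kt,
        ifelse(kt <= 0.80,
               0.9511 - 0.1604 * kt + 4.388 * kt^2 -
                 16.638 * kt^3 + 12.336 * kt^4,
               0.165))
  ifelse(s > 0, pmin(1, pmax(0, df)), 1)
}

# fraction of a parallel beam intercepted by a turbid ellipsoid, exact
# average over the projected disk of 1 - exp(-x * chord/chord_max):
# chords over the projected disk of any ellipsoid are distributed as
# L*sqrt(1-rho^2), giving 1 - 2*(1-(1+x)exp(-x))/x^2 with x = k*lad*L_central
beam_interception_fraction <- function(x) {
  small <- x < 1e-3        # series branch avoids cancellation
  f <- x
  xl <- x[!small]
  f[!small] <- 1 - 2 * (1 - (1 + xl) * exp(-xl)) / xl^2
  xs <- x[small]
  f[small] <- 2 * xs / 3 - xs^2 / 4 + xs^3 / 15
  f
}

# obstacle table: all units of the tree plus the 8 neighbouring trees
# represented as crown envelope ellipsoids at the periodic spacing offsets
shading_obstacles <- function(tree) {
  fu <- tree$fu
  sx <- tree$spacing[1]; sy <- tree$spacing[2]
  offs <- expand.grid(ox = c(-sx, 0, sx), oy = c(-sy, 0, sy))
  offs <- offs[!(offs$ox == 0 & offs$oy == 0), ]
  cr <- tree$crown
  env <- data.frame(
    x = offs$ox, y = offs$oy,
    z = as.numeric((cr["base"] + cr["top"]) / 2),
    ax = as.numeric(cr["radius"]), ay = as.numeric(cr["radius"]),
    az = as.numeric((cr["top"] - cr["base"]) / 2), envelope = TRUE)
  own <- data.frame(x = fu$x, y = fu$y, z = fu$z,
                    ax = fu$ax, ay = fu$ay, az = fu$az, envelope = FALSE)
  rbind(own, env)
}

# 12 sky directions (3 zenith sectors x 4 azimuths) with isotropic-sky
# weights on the horizontal: sectors [0,30), [30,60), [60,90) deg zenith
sky_sectors <- function() {
  elev <- c(75, 45, 15)
  w <- c(0.25, 0.50, 0.25)
  az <- c(45, 135, 225, 315)
  g <- expand.grid(elevation = elev, azimuth = az)
  g$weight <- rep(w, 4) / 4
  g
}

#' Per-unit shortwave interception with mutual shading
#'
#' Beer-Lambert extinction within each unit's turbid ellipsoid (spherical
#' leaf-angle distribution, direct-beam extinction coefficient
#' 0.5/sin(elevation)), with the direct beam attenuated through every other
#' ellipsoid it crosses and through the crown envelopes of the neighbouring
#' trees at the periodic row spacing. Diffuse sky radiation is integrated
#' over three zenith sectors. Sunlit leaf area is the leaf area still reached
#' by the un-attenuated beam; sunlit leaves receive k x beam flux per unit
#' leaf area on top of the diffuse field.
#'
#' @param tree an \code{orchard_tree}.
#' @param elevation,azimuth solar position, degrees.
#' @param global global radiation on the horizontal, W m-2 (>= 0).
#' @param diffuse_frac diffuse fraction of global; default from
#'   \code{diffuse_fraction}.
#' @param leaf_area per-unit leaf areas (m2); default the tree's current ones.
#' @param params parameter set.
#' @param cache optional precomputed \code{radiation_cache(tree)}; build it
#'   once when calling repeatedly over a season.
#' @param diffuse_coef optional precomputed
#'   \code{diffuse_interception_coef(cache, leaf_area)} (it only changes
#'   when the leaf areas do).
#' @return list of per-unit vectors: \code{par_abs}, \code{nir_abs} (absorbed
#'   W), \code{area_sun}, \code{area_shade} (m2), \code{par_sun},
#'   \code{par_shade} (incident PAR on sunlit/shaded leaves,
#'   umol m-2 s-1), and \code{intercepted} (total intercepted shortwave, W).
#' @export
intercept_shortwave <- function(tree, elevation, azimuth, global,
                                diffuse_frac = NULL,
                                leaf_area = tree$fu$leaf_area,
                                params = default_params(), cache = NULL,
                                diffuse_coef = NULL) {
  if (global < 0) stop("incident radiation must be >= 0")
  if (is.null(cache)) cache <- radiation_cache(tree)
  n <- cache$n
  zero <- rep(0, n)
  if (is.null(diffuse_frac)) diffuse_frac <- diffuse_fraction(global, elevation)
  out0 <- list(par_abs = zero, nir_abs = zero, area_sun = zero,
               area_shade = leaf_area, par_sun = zero, par_shade = zero,
               intercepted = zero)
  if (global <= 0) return(out0)
  rad <- params$radiation

  # --- diffuse component (all leaves) ---
  if (is.null(diffuse_coef)) diffuse_coef <- diffuse_interception_coef(
    cache, leaf_area)
  p_diff <- diffuse_coef  # intercepted shortwave per W m-2 horizontal diffuse
  par_diff_int <- global * rad$par_fraction * diffuse_frac * p_diff
  nir_diff_int <- global * (1 - rad$par_fraction) * diffuse_frac * p_diff
  par_shade_flux <- ifelse(leaf_area > 0,
                           par_diff_int / pmax(leaf_area, 1e-9), 0)

  # --- direct beam ---
  dir_glob <- global * (1 - diffuse_frac)
  if (elevation > 0 && dir_glob > 0) {
    d <- sun_vector(elevation, azimuth)
    bi <- dir_interception(cache, leaf_area, elevation,
                           chords_direction(cache, d), d)
    sinel <- max(sin(elevation * pi / 180), 0.05)
    i_perp <- dir_glob / sinel
    p_dir <- i_perp * bi$tau_up * bi$ap * bi$fint   # W intercepted per unit
    area_sun <- pmin(leaf_area, bi$tau_up * bi$ap * bi$fint / bi$k)
    par_dir_int <- p_dir * rad$par_fraction
    nir_dir_int <- p_dir * (1 - rad$par_fraction)
    par_beam_flux <- bi$k * i_perp * rad$par_fraction  # W m-2, sunlit leaves
  } else {
    area_sun <- zero
    par_dir_int <- nir_dir_int <- zero
    par_beam_flux <- 0
  }

  u2m <- rad$par_w_to_umol
  list(
    par_abs = rad$absorptance_par * (par_dir_int + par_diff_int),
    nir_abs = rad$absorptance_nir * (nir_dir_int + nir_diff_int),
    area_sun = area_sun,
    area_shade = pmax(leaf_area - area_sun, 0),
    par_sun = (par_beam_flux + par_shade_flux) * u2m,
    par_shade = par_shade_flux * u2m,
    intercepted = par_dir_int + par_diff_int + nir_dir_int + nir_diff_int
  )
}

#' Precompute the ray geometry of a tree for repeated interception calls
#'
#' Stores the pairwise quadratic-form terms between every unit centroid and
#' every shading obstacle (within-tree ellipsoids plus neighbouring crown
#' envelopes), and the chord matrices for the fixed diffuse sky sectors.
#'
#' @param tree an \code{orchard_tree}.
#' @return opaque list consumed by \code{intercept_shortwave}.
#' @export
radiation_cache <- function(tree) {
  fu <- tree$fu
  obs <- shading_obstacles(tree)
  origins <- as.matrix(fu[, c("x", "y", "z")])
  n <- nrow(origins); m <- nrow(obs)
  inv2 <- cbind(1 / obs$ax^2, 1 / obs$ay^2, 1 / obs$az^2)
  dx <- outer(origins[, 1], obs$x, "-")
  dy <- outer(origins[, 2], obs$y, "-")
  dz <- outer(origins[, 3], obs$z, "-")
  X1 <- sweep(dx, 2, inv2[, 1], "*")
  Y2 <- sweep(dy, 2, inv2[, 2], "*")
  Z3 <- sweep(dz, 2, inv2[, 3], "*")
  C <- X1 * dx + Y2 * dy + Z3 * dz - 1
  cr <- tree$crown
  cache <- list(
    n = n, m = m, inv2 = inv2, X1 = X1, Y2 = Y2, Z3 = Z3, C = C,
    diag_idx = cbind(seq_len(n), seq_len(n)),
    ax = fu$ax, ay = fu$ay, az = fu$az,
    vol = 4 / 3 * pi * fu$ax * fu$ay * fu$az,
    env_vol = as.numeric(4 / 3 * pi * cr["radius"]^2 *
                           (cr["top"] - cr["base"]) / 2),
    sectors = sky_sectors()
  )
  cache$sector_dirs <- lapply(seq_len(nrow(cache$sectors)), function(s)
    sun_vector(cache$sectors$elevation[s], cache$sectors$azimuth[s]))
  cache$sector_chords <- lapply(cache$sector_dirs, function(d)
    chords_direction(cache, d))
  cache
}

#' Per-unit diffuse-sky interception coefficient
#'
#' Intercepted shortwave power (W) per W m-2 of horizontal diffuse
#' irradiance, integrating the sky sectors with the current leaf areas.
#' @param cache a \code{radiation_cache}.
#' @param leaf_area per-unit leaf areas, m2.
#' @return numeric vector, one coefficient per unit.
#' @export
diffuse_interception_coef <- function(cache, leaf_area) {
  sect <- cache$sectors
  p_diff <- numeric(cache$n)
  for (s in seq_len(nrow(sect))) {
    bi <- dir_interception(cache, leaf_area,
                           sect$elevation[s], cache$sector_chords[[s]],
                           cache$sector_dirs[[s]])
    p_diff <- p_diff + sect$weight[s] / sin(sect$elevation[s] * pi / 180) *
      bi$tau_up * bi$ap * bi$fint
  }
  p_diff
}

# chord matrix (units x obstacles) for one direction, from the cache
chords_direction <- function(cache, d) {
  A <- as.numeric(cache$inv2 %*% d^2)
  B <- 2 * (d[1] * cache$X1 + d[2] * cache$Y2 + d[3] * cache$Z3)
  A2 <- matrix(A, cache$n, cache$m, byrow = TRUE)
  disc <- B * B - 4 * A2 * cache$C
  s <- sqrt(pmax(disc, 0))
  t1 <- (-B - s) / (2 * A2)
  t2 <- (-B + s) / (2 * A2)
  ch <- pmax(t2 - pmax(t1, 0), 0)   # argument order keeps the dim attribute
  ch[disc <= 0 | t2 <= 0] <- 0
  ch
}

# per-unit beam interception terms for one direction:
# upstream transmission, projected area, own interception fraction
dir_interception <- function(cache, leaf_area, elevation, chords, d) {
  k <- 0.5 / max(sin(elevation * pi / 180), 0.05)
  lad_own <- leaf_area / cache$vol
  lad_obs <- c(lad_own, rep(sum(leaf_area) / cache$env_vol, cache$m - cache$n))
  dep <- as.numeric(chords %*% (k * lad_obs))
  dep_own <- k * lad_own * chords[cache$diag_idx]
  tau_up <- exp(-pmax(dep - dep_own, 0))
  q <- (d[1] / cache$ax)^2 + (d[2] / cache$ay)^2 + (d[3] / cache$az)^2
  sq <- sqrt(q)
  ap <- pi * cache$ax * cache$ay * cache$az * sq
  x <- k * lad_own * 2 / sq
  list(tau_up = tau_up, ap = ap,
       fint = beam_interception_fraction(x), k = k)
}

#' Brunt-type clear-sky emissivity
#' @param tair_C air temperature, degC.
#' @param rh relative humidity, percent.
#' @return apparent sky emissivity (capped at 1).
#' @export
sky_emissivity <- function(tair_C, rh) {
  es <- saturation_vp(tair_C)
  ea <- es * rh / 100
  pmin(1, 0.52 + 0.065 * sqrt(ea))
}

# saturation vapour pressure, hPa (Tetens)
saturation_vp <- function(t_C) {
  6.1078 * exp(17.269 * t_C / (t_C + 237.3))
}

#' Absorbed thermal infrared radiation of a leaf population
#'
#' View-factor-weighted absorption of sky, soil and surrounding-leaf
#' emission, two-sided: the upper side sees sky (partially enclosed by other
#' leaves), the lower side sees soil (idem).
#'
#' @param leaf_area one-sided leaf area, m2 (emission and absorption act on
#'   both sides).
#' @param t_leaf_env temperature of the surrounding foliage, K.
#' @param t_air air (and apparent sky) temperature, K.
#' @param t_soil soil surface temperature, K.
#' @param sky_emiss apparent sky emissivity in [0, 1].
#' @param enclosure fraction of each hemisphere occupied by other leaves.
#' @param leaf_emiss,soil_emiss emissivities in [0, 1].
#' @return absorbed TIR, W (vectorized over units).
#' @export
thermal_exchange <- function(leaf_area, t_leaf_env, t_air, t_soil,
                             sky_emiss, enclosure = 0.3,
                             leaf_emiss = 1, soil_emiss = 0.95) {
  if (any(c(sky_emiss, leaf_emiss, soil_emiss) < 0) ||
      any(c(sky_emiss, leaf_emiss, soil_emiss) > 1))
    stop("emissivities must lie in [0, 1]")
  if (any(c(t_leaf_env, t_air, t_soil) <= 0)) stop("temperatures must be in K")
  sig <- physical_constants()$sigma
  up <- (1 - enclosure) * sky_emiss * sig * t_air^4 +
    enclosure * leaf_emiss * sig * t_leaf_env^4
  down <- (1 - enclosure) * soil_emiss * sig * t_soil^4 +
    enclosure * leaf_emiss * sig * t_leaf_env^4
  leaf_emiss * leaf_area * (up + down)
}

#' Net radiation of a fruiting unit
#'
#' Absorbed PAR + NIR + TIR minus the two-sided thermal emission at the
#' current leaf temperature.
#'
#' @param par_abs,nir_abs,tir_abs absorbed radiation components, W.
#' @param t_leaf leaf temperature, K.
#' @param leaf_area one-sided leaf area, m2.
#' @return net radiation, W.
#' @export
net_radiation <- function(par_abs, nir_abs, tir_abs, t_leaf, leaf_area) {
  sig <- physical_constants()$sigma
  par_abs + nir_abs + tir_abs - 2 * sig * t_leaf^4 * leaf_area
}
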