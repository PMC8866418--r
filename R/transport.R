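#' Define a tissue layer
#'
#' Layers are stacked along z from the illuminated surface down; the last
#' layer is semi-infinite (`thickness = Inf`). Only isotropic scattering is
#' supported (`anisotropy_g = 0`): in the diffusive regime the reduced
#' scattering coefficient governs the signal, so an anisotropic medium is
#' represented by setting `mu_s_prime` to its reduced value.
#'
#' @param thickness layer thickness, mm (`Inf` for the last layer).
#' @param mu_s_prime reduced scattering coefficient, 1/mm (> 0).
#' @param mu_a absorption coefficient, 1/mm (>= 0). Absorption is not
#'   applied during transport; detected photons are weighted by
#'   `exp(-sum(mu_a * L))` at the speckle-synthesis stage.
#' @param DB Brownian diffusion coefficient of the scatterers, mm^2/s.
#' @param anisotropy_g scattering anisotropy; must be 0.
#' @param refractive_index tissue refractive index (shared across layers).
#' @return A `tissue_layer` object.
#' @export
tissue_layer <- function(thickness, mu_s_prime, mu_a = 0.01, DB = 1e-6,
                         anisotropy_g = 0, refractive_index = 1.33) {
  stopifnot(thickness > 0, mu_s_prime > 0, mu_a >= 0, DB >= 0,
            refractive_index >= 1)
  if (anisotropy_g != 0)
    stop("only isotropic transport is supported: set anisotropy_g = 0 and fold g into mu_s_prime")
  structure(list(thickness = thickness, mu_s_prime = mu_s_prime,
                 mu_a = mu_a, DB = DB, anisotropy_g = 0,
                 refractive_index = refractive_index),
            class = "tissue_layer")
}

#' Two-layer head model used throughout the package examples
#'
#' A 15 mm superficial layer over a semi-infinite deep layer, both with
#' `mu_s_prime` = 1/mm and `mu_a` = 0.01/mm; dynamics (blood flow) can be
#' raised in the deep layer to emulate activation.
#'
#' @param d1 superficial layer thickness, mm.
#' @param mu_s_prime,mu_a optical properties shared by both layers.
#' @param DB length-2 Brownian diffusion coefficients, mm^2/s.
#' @param refractive_index tissue refractive index.
#' @return List of two [tissue_layer()] objects.
#' @export
two_layer_medium <- function(d1 = 15, mu_s_prime = 1, mu_a = 0.01,
                             DB = c(1e-6, 1e-6), refractive_index = 1.33) {
  list(tissue_layer(d1, mu_s_prime, mu_a, DB[1], 0, refractive_index),
       tissue_layer(Inf, mu_s_prime, mu_a, DB[2], 0, refractive_index))
}

#' Source-detector geometry on the surface
#'
#' Pencil-beam source at the origin, normally incident; detector is a disc
#' of diameter `detector_size` centred at `(rho, 0)` on the surface z = 0.
#'
#' @param rho source-detector separation, mm (> 0).
#' @param detector_size detector diameter, mm (> 0).
#' @param shape detector shape; only `"disc"` is supported.
#' @return A `detection_geometry` object.
#' @export
detection_geometry <- function(rho, detector_size = 2, shape = "disc") {
  stopifnot(rho > 0, detector_size > 0)
  shape <- match.arg(shape, "disc")
  structure(list(rho = rho, detector_size = detector_size, shape = shape),
            class = "detection_geometry")
}

validate_layers <- function(layers) {
  if (length(layers) < 1) stop("at least one tissue layer is required")
  if (!all(vapply(layers, inherits, TRUE, "tissue_layer")))
    stop("layers must be a list of tissue_layer objects")
  thick <- vapply(layers, `[[`, 0, "thickness")
  if (any(!is.finite(thick[-length(thick)])))
    stop("only the last layer may be semi-infinite")
  if (!is.infinite(thick[length(thick)]))
    stop("the last layer must have thickness = Inf")
  n <- vapply(layers, `[[`, 0, "refractive_index")
  if (length(unique(n)) != 1)
    stop("all layers must share one refractive index")
  invisible(layers)
}

#' Simulate photon migration and record detected trajectories
#'
#' Runs the photon-migration Monte Carlo: photons are launched as a pencil
#' beam at the origin, scatter isotropically with exponential free paths
#' (rate `mu_s_prime` of the local layer), and are tracked until they
#' escape through the surface or exceed `max_path`. For each detected
#' photon the scattering count and pathlength accumulated in every layer
#' and the exit position are recorded. Absorption is deliberately not
#' applied here; it enters later as the weight `exp(-sum(mu_a * L))` so one
#' transport run can serve several absorption settings.
#'
#' Two boundary models are available at the surface z = 0:
#' `"fresnel"` (default) treats the tissue-air interface as index-mismatched:
#' at each surface contact the photon is specularly reflected with the
#' unpolarized Fresnel probability (including total internal reflection)
#' and escapes otherwise. This is the convention consistent with the
#' extrapolated-boundary reflectivity `Reff = 0.493` used by the analytic
#' pathlength distribution for n = 1.33 tissue. `"absorbing"` terminates
#' the photon at first surface contact (index-matched).
#'
#' Two detection tallies are available: `"direct"` keeps photons whose exit
#' point falls inside the detector disc (weight 1); `"ring"` exploits the
#' rotational symmetry of the medium and keeps every escaping photon whose
#' exit radius overlaps the detector annulus, weighted by the azimuthal
#' fraction of its exit circle covered by the disc. The ring tally is an
#' exact-in-expectation variance reduction: weighted statistics equal the
#' direct tally's at a fraction of the launch budget.
#'
#' @param layers list of [tissue_layer()] objects.
#' @param geometry a [detection_geometry()].
#' @param n_launch number of photons to launch (>= 0).
#' @param seed integer seed (transport sub-stream).
#' @param max_path pathlength cutoff, mm. The default 3000 mm carries an
#'   absorption weight below 1e-13 at mu_a = 0.01/mm.
#' @param boundary `"fresnel"` or `"absorbing"` (see Details).
#' @param n_outside refractive index of the exterior medium.
#' @param tally `"direct"` or `"ring"` (see Details).
#' @return A `photon_records` data frame with columns `ns_<i>` (scattering
#'   counts per layer), `path_<i>` (pathlengths per layer, mm), `exit_x`,
#'   `exit_y` (mm) and `weight`; attributes `launched`, `layers`,
#'   `geometry`, `boundary`, `tally`, `seed`.
#' @export
simulate_photons <- function(layers, geometry, n_launch, seed = NULL,
                             max_path = 3000,
                             boundary = c("fresnel", "absorbing"),
                             n_outside = 1.0,
                             tally = c("direct", "ring")) {
  validate_layers(layers)
  stopifnot(inherits(geometry, "detection_geometry"), n_launch >= 0,
            max_path > 0)
  boundary <- match.arg(boundary)
  tally <- match.arg(tally)
  mu_s <- vapply(layers, `[[`, 0, "mu_s_prime")
  thick <- vapply(layers, `[[`, 0, "thickness")
  bcum <- cumsum(thick[-length(thick)])
  n_in <- layers[[1]]$refractive_index
  cols <- with_seed(seed,
    mc_transport_cpp(mu_s, as.numeric(bcum),
                     geometry$rho, geometry$detector_size / 2,
                     n_in, n_outside, if (boundary == "fresnel") 0L else 1L,
                     as.double(n_launch), max_path,
                     if (tally == "direct") 0L else 1L))
  rec <- as.data.frame(cols)
  structure(rec, class = c("photon_records", "data.frame"),
            launched = as.double(n_launch), layers = layers,
            geometry = geometry, boundary = boundary, tally = tally,
            seed = seed, max_path = max_path)
}

#' @export
print.photon_records <- function(x, ...) {
  g <- attr(x, "geometry")
  cat(sprintf(paste0("<photon_records> %d detected / %.3g launched ",
                     "(rho = %g mm, detector %g mm, %s boundary, %s tally)\n"),
              nrow(x), attr(x, "launched"), g$rho, g$detector_size,
              attr(x, "boundary"), attr(x, "tally")))
  cat(sprintf("  effective detected count sum(weight) = %.1f\n",
              sum(x$weight)))
  invisible(x)
}

n_layers_of <- function(records) sum(grepl("^path_", names(records)))

path_matrix <- function(records) {
  as.matrix(records[, grep("^path_", names(records)), drop = FALSE])
}

ns_matrix <- function(records) {
  as.matrix(records[, grep("^ns_", names(records)), drop = FALSE])
}

#' Total pathlength of each detected photon
#' @param records a `photon_records` object.
#' @return Numeric vector, mm.
#' @export
total_path <- function(records) rowSums(path_matrix(records))

#' Photon transit times within the medium
#'
#' `t = L / v` with `v = c / n`, `c` = 300 mm/ns.
#'
#' @param records a `photon_records` object.
#' @param refractive_index tissue refractive index; defaults to the value
#'   stored in the transport layers.
#' @return Numeric vector of transit times, ns.
#' @export
transit_times <- function(records, refractive_index = NULL) {
  if (is.null(refractive_index))
    refractive_index <- attr(records, "layers")[[1]]$refractive_index
  stopifnot(refractive_index >= 1)
  total_path(records) / (C_MM_PER_NS / refractive_index)
}

#' Absorption weights of detected photons
#'
#' Per-photon field amplitude weight implementing intensity attenuation
#' `exp(-sum_layers(mu_a * L))`. With `mode = "intensity"` (default) the
#' field weight is the square root of the intensity attenuation; with
#' `mode = "field"` the full attenuation multiplies the field, so photon
#' intensities scale as `exp(-2 mu_a L)` (kept for comparison with the
#' field-attenuation convention).
#'
#' @param records a `photon_records` object.
#' @param mu_a per-layer absorption coefficients, 1/mm; defaults to the
#'   values stored in the layers.
#' @param mode `"intensity"` or `"field"`.
#' @return Numeric vector of field amplitude weights.
#' @export
absorption_weights <- function(records, mu_a = NULL,
                               mode = c("intensity", "field")) {
  mode <- match.arg(mode)
  if (is.null(mu_a))
    mu_a <- vapply(attr(records, "layers"), `[[`, 0, "mu_a")
  Lm <- path_matrix(records)
  stopifnot(length(mu_a) == ncol(Lm))
  expo <- as.vector(Lm %*% mu_a)
  if (mode == "intensity") exp(-expo / 2) else exp(-expo)
}

#' Importance subsample of photon records
#'
#' Thins the record set to approximately `m` trajectories by independent
#' Bernoulli keeps with probability proportional to the detection weight
#' (capped at 1), re-weighting kept photons by the inverse keep
#' probability. All weighted statistics are preserved in expectation and
#' no trajectory is duplicated (duplicates would fake perfectly coherent
#' photon pairs in the speckle sum). Used to bound the cost of speckle
#' synthesis for large record sets.
#'
#' @param records a `photon_records` object.
#' @param m target subsample size (expected kept count).
#' @param seed integer seed.
#' @return A `photon_records` object with about `m` rows.
#' @export
subsample_records <- function(records, m, seed = NULL) {
  stopifnot(nrow(records) > 0, m >= 1)
  w <- records$weight
  if (m >= nrow(records)) return(records)
  # scale c such that E[#kept] = sum(min(1, c w)) = m
  c0 <- m / sum(w)
  for (i in 1:20) {
    kept <- pmin(1, c0 * w)
    excess <- sum(kept) - m
    if (abs(excess) < 0.5) break
    free <- kept < 1
    c0 <- (m - sum(!free)) / sum(w[free])
  }
  p <- pmin(1, c0 * w)
  keep <- with_seed(seed, runif(length(p)) < p)
  out <- records[keep, , drop = FALSE]
  out$weight <- w[keep] / p[keep]
  attributes(out)[c("launched", "layers", "geometry", "boundary",
                    "tally", "seed", "max_path")] <-
    attributes(records)[c("launched", "layers", "geometry", "boundary",
                          "tally", "seed", "max_path")]
  class(out) <- class(records)
  rownames(out) <- NULL
  out
}

#' Write / read photon records as a TSV table
#'
#' Plain-text persistence: commented header lines (`# key: value`) carry
#' the launch count and geometry, followed by one row per detected photon.
#'
#' @param records a `photon_records` object.
#' @param path file path.
#' @return `read_photon_records` returns a `photon_records` object (with
#'   geometry and launch count restored; layer objects are not persisted).
#' @export
write_photon_records <- function(records, path) {
  g <- attr(records, "geometry")
  hdr <- c(sprintf("# launched_count: %.0f", attr(records, "launched")),
           sprintf("# rho_mm: %g", g$rho),
           sprintf("# detector_size_mm: %g", g$detector_size),
           sprintf("# boundary: %s", attr(records, "boundary")),
           sprintf("# tally: %s", attr(records, "tally")))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(records, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  invisible(path)
}

#' @rdname write_photon_records
#' @export
read_photon_records <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(NA)
    trimws(sub(".*:", "", m[1]))
  }
  rec <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t")
  structure(rec, class = c("photon_records", "data.frame"),
            launched = as.double(getv("launched_count")),
            geometry = detection_geometry(as.numeric(getv("rho_mm")),
                                          as.numeric(getv("detector_size_mm"))),
            boundary = getv("boundary"), tally = getv("tally"))
}
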