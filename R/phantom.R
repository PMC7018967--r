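#' Orientation field descriptors for phantom layers
#'
#' Each birefringent layer carries a real-space fast-axis orientation field
#' `phi(x, y)` in `[0, pi)`. Fields are described symbolically here and
#' materialized (seeded) inside [simulate_phantom()], so that a
#' [phantom_spec()] stays small and serializable.
#'
#' * `orient_uniform(phi0)` - constant orientation `phi0`.
#' * `orient_random(corr_um)` - spatially correlated field with uniform
#'   marginal orientation; `corr_um` is the Gaussian correlation length of
#'   the two underlying random fields whose half-angle gives `phi`.
#' * `orient_von_mises(mu, kappa, corr_um)` - wrapped-dispersion field around
#'   `mu` whose doubled angle matches a von Mises concentration `kappa`
#'   (spread `1/(2*sqrt(kappa))` radians); `kappa = Inf` is constant,
#'   `kappa = 0` falls back to `orient_random`.
#' * `orient_radial(center_um, kappa, corr_um)` - fibers radiating from a
#'   transverse center (default: field center), with the same von Mises
#'   jitter model around the local radial direction; emulates the uniform
#'   radial collagen pattern of late, organized fibrosis.
#'
#' @param phi0,mu Orientation (radians, `[0, pi)`).
#' @param corr_um Transverse correlation length of the jitter field (um).
#' @param kappa Axial von Mises concentration of the jitter (>= 0, may be
#'   `Inf` for no jitter).
#' @param center_um Length-2 numeric `(x, y)` center in um, or `NULL` for
#'   the field center.
#' @return A list of class `orientation_field`.
#' @name orientation_fields
NULL

new_orientation <- function(type, ...) {
  structure(list(type = type, ...), class = "orientation_field")
}

#' @rdname orientation_fields
#' @export
orient_uniform <- function(phi0 = 0) {
  stopifnot(is.finite(phi0), phi0 >= 0, phi0 < pi)
  new_orientation("uniform", phi0 = phi0)
}

#' @rdname orientation_fields
#' @export
orient_random <- function(corr_um = 60) {
  stopifnot(corr_um > 0)
  new_orientation("random", corr_um = corr_um)
}

#' @rdname orientation_fields
#' @export
orient_von_mises <- function(mu = 0, kappa = 16, corr_um = 60) {
  stopifnot(is.finite(mu), mu >= 0, mu < pi, kappa >= 0, corr_um > 0)
  new_orientation("von_mises", mu = mu, kappa = kappa, corr_um = corr_um)
}

#' @rdname orientation_fields
#' @export
orient_radial <- function(center_um = NULL, kappa = Inf, corr_um = 60) {
  stopifnot(is.null(center_um) || length(center_um) == 2, kappa >= 0,
            corr_um > 0)
  new_orientation("radial", center_um = center_um, kappa = kappa,
                  corr_um = corr_um)
}

# Materialize an orientation descriptor into an nx x ny matrix of angles
# in [0, pi). Consumes the current RNG state (seeded by simulate_phantom).
orientation_matrix <- function(o, nx, ny, dx, dy) {
  jitter_field <- function(kappa, corr_um) {
    if (is.infinite(kappa)) return(matrix(0, nx, ny))
    if (kappa <= 0) stop("kappa = 0 jitter has no scale; use orient_random()")
    g <- smooth_normal_field(nx, ny, corr_um / ((dx + dy) / 2))
    0.5 * g / sqrt(kappa)
  }
  switch(o$type,
    uniform = matrix(o$phi0, nx, ny),
    random = {
      cp <- o$corr_um / ((dx + dy) / 2)
      g1 <- smooth_normal_field(nx, ny, cp)
      g2 <- smooth_normal_field(nx, ny, cp)
      (atan2(g2, g1) / 2) %% pi
    },
    von_mises = {
      if (o$kappa == 0) return(orientation_matrix(
        orient_random(o$corr_um), nx, ny, dx, dy))
      (o$mu + jitter_field(o$kappa, o$corr_um)) %% pi
    },
    radial = {
      ctr <- o$center_um %||% c(nx * dx / 2, ny * dy / 2)
      xs <- (seq_len(nx) - 0.5) * dx - ctr[1]
      ys <- (seq_len(ny) - 0.5) * dy - ctr[2]
      base <- atan2(matrix(ys, nx, ny, byrow = TRUE), matrix(xs, nx, ny)) %% pi
      (base + jitter_field(o$kappa, o$corr_um)) %% pi
    },
    stop("unknown orientation field type: ", o$type)
  )
}

#' Birefringent layer specification
#'
#' One layer of a tissue phantom: an axial slab `[z_from, z_to)` in um below
#' the tissue surface, acting as a linear retarder with a single-pass
#' retardance rate and a transverse fast-axis orientation field.
#'
#' @param z_from,z_to Depth range below the surface (um), `z_from < z_to`.
#' @param retardance_rate Single-pass retardance accumulation rate in
#'   degrees/um (Jones phase, equal to the single-pass Stokes rotation
#'   angle); `>= 0`. Typical dermis at 1300 nm is of order 0.1-0.6 deg/um.
#' @param orientation An orientation field descriptor, see
#'   [orientation_fields].
#' @param scattering_amplitude Relative backscattering amplitude of the
#'   layer (dimensionless, `> 0`).
#' @return A list of class `layer_spec`.
#' @export
layer_spec <- function(z_from, z_to, retardance_rate,
                       orientation = orient_uniform(0),
                       scattering_amplitude = 1) {
  stopifnot(is.finite(z_from), is.finite(z_to), z_from >= 0, z_to > z_from,
            retardance_rate >= 0, scattering_amplitude > 0,
            inherits(orientation, "orientation_field"))
  structure(list(z_from = z_from, z_to = z_to,
                 retardance_rate = retardance_rate,
                 orientation = orientation,
                 scattering_amplitude = scattering_amplitude),
            class = "layer_spec")
}

default_input_states <- function() {
  # linear horizontal (Q) and right circular (V): 90 degrees apart on the
  # Poincare sphere. A circular probe is never an eigenstate of a linear
  # retarder, so the two-state geometric solution stays well-posed for
  # every linear sample axis (two linear probes would leave the axis in
  # their common great circle and degenerate the cross-product construction)
  cbind(c(1 + 0i, 0), c(1 + 0i, 0 + 1i) / sqrt(2))
}

#' Tissue phantom specification
#'
#' Describes a layered birefringent phantom probed by a dual-input-state
#' PS-OCT system: grid geometry, surface position, retarding layers, the two
#' probing polarization states, an optional unknown fiber unitary, and the
#' noise model (depth-decaying signal amplitude, additive complex channel
#' noise, optional fully developed speckle).
#'
#' @param grid Integer length-3 `(nx, ny, nz)` pixel counts.
#' @param pitch Numeric length-3 `(dx, dy, dz)` pixel pitch in um.
#' @param surface_depth Depth of the tissue surface in um: a scalar (flat)
#'   or an `nx x ny` matrix (e.g. a gentle slope).
#' @param layers List of [layer_spec()] objects; their `[z_from, z_to)`
#'   ranges must tile `[0, bottom)` contiguously without overlap.
#' @param input_states Complex 2 x 2 matrix whose columns are the two probing
#'   Jones vectors (unit norm). Defaults to linear horizontal and right
#'   circular, which are orthogonal on the Poincare sphere and keep the
#'   two-state geometric solution non-degenerate for any linear sample axis
#'   (see [local_birefringence()]).
#' @param fiber_rotation `"identity"`, `"random"` (Haar unitary drawn from
#'   the seed), or an explicit complex 2 x 2 unitary applied on both the
#'   illumination and detection paths.
#' @param noise_floor Standard deviation of the additive complex Gaussian
#'   noise per detection channel (relative to a unit-amplitude surface
#'   reflection); `E|n|^2 = noise_floor^2`.
#' @param snr_decay_length Exponential decay length (um) of the backscattered
#'   field amplitude with depth below the surface, emulating the SNR loss
#'   that degrades DOP and retardance at depth.
#' @param speckle Logical; multiply each pixel's field by a circular complex
#'   Gaussian speckle factor (shared across channels and input states).
#' @param seed Integer seed; all simulator randomness derives from it.
#' @param meta Optional named list of sample metadata (id, group label,
#'   ground-truth dermal thickness, ...), carried through to summaries.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid, pitch, surface_depth = 30, layers,
                         input_states = default_input_states(),
                         fiber_rotation = "identity",
                         noise_floor = 0.1, snr_decay_length = 200,
                         speckle = FALSE, seed = 1, meta = list()) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3, all(grid >= 1L),
            length(pitch) == 3, all(pitch > 0),
            is.numeric(surface_depth), all(surface_depth >= 0),
            length(layers) >= 1,
            all(vapply(layers, inherits, TRUE, "layer_spec")),
            is.matrix(input_states), all(dim(input_states) == c(2, 2)),
            noise_floor >= 0, snr_decay_length > 0, is.logical(speckle),
            length(seed) == 1, is.finite(seed))
  norms <- sqrt(colSums(Mod(input_states)^2))
  if (any(abs(norms - 1) > 1e-9)) stop("input states must be unit-norm")
  if (is.matrix(surface_depth) &&
      !all(dim(surface_depth) == grid[1:2]))
    stop("surface_depth matrix must be nx x ny")
  ord <- order(vapply(layers, `[[`, numeric(1), "z_from"))
  layers <- layers[ord]
  froms <- vapply(layers, `[[`, numeric(1), "z_from")
  tos <- vapply(layers, `[[`, numeric(1), "z_to")
  if (froms[1] != 0) stop("layers must start at the surface (z_from = 0)")
  if (length(layers) > 1 && any(abs(froms[-1] - tos[-length(tos)]) > 1e-9))
    stop("layer depth ranges must tile without gaps or overlap")
  if (!(identical(fiber_rotation, "identity") ||
        identical(fiber_rotation, "random") ||
        (is.matrix(fiber_rotation) && all(dim(fiber_rotation) == c(2, 2)))))
    stop("fiber_rotation must be 'identity', 'random', or a 2x2 matrix")
  structure(list(grid = grid, pitch = as.numeric(pitch),
                 surface_depth = surface_depth, layers = layers,
                 input_states = input_states,
                 fiber_rotation = fiber_rotation,
                 noise_floor = noise_floor,
                 snr_decay_length = snr_decay_length,
                 speckle = speckle, seed = as.integer(seed), meta = meta),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> grid", paste(x$grid, collapse = "x"),
      "px, pitch", paste(x$pitch, collapse = "x"), "um\n")
  cat("  surface:", if (is.matrix(x$surface_depth)) "sloped" else
      paste0(x$surface_depth, " um"),
      "| layers:", length(x$layers),
      "| noise sd:", x$noise_floor,
      "| decay:", x$snr_decay_length, "um",
      "| seed:", x$seed, "\n")
  for (l in x$layers)
    cat(sprintf("  [%g, %g) um  %.3g deg/um  %s\n", l$z_from, l$z_to,
                l$retardance_rate, l$orientation$type))
  invisible(x)
}

#' Digest of a phantom specification
#'
#' Deterministic 32-bit hash of the canonical YAML serialization of a spec;
#' identical specs (including seed) produce byte-identical digests.
#'
#' @param spec A [phantom_spec()].
#' @return Character scalar (8 hex digits).
#' @export
spec_digest <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  fnv1a32(yaml::as.yaml(spec_to_list(spec), precision = 17))
}

#' Preset fibrosis-model phantoms
#'
#' Phantom presets emulating a bleomycin-induced skin-fibrosis time course
#' plus PBS-injected controls. Dermal thickness grows with injection day and
#' the collagen orientation field progresses from loose, heterogeneous
#' (control, day 7) through maximally disorganized deposition (day 14) to a
#' concentrated radial pattern around the injection site (days 21 and 28):
#'
#' | day     | thickness (um) | rate (deg/um) | orientation            |
#' |---------|----------------|---------------|------------------------|
#' | control | 200            | 0.15          | random, 60 um corr.    |
#' | 7       | 250            | 0.25          | random, 60 um corr.    |
#' | 14      | 300            | 0.35          | random, 35 um corr.    |
#' | 21      | 350            | 0.45          | radial, kappa = 16     |
#' | 28      | 400            | 0.55          | radial, kappa = 64     |
#'
#' Per-sample biological variability is emulated by a Gaussian jitter of the
#' dermal thickness (sd 10 um, clamped to +/- 25 um). Grids are 56 x 56 x 64
#' px at 10 x 10 x 5 um pitch: a 0.56 x 0.56 mm transverse field, large
#' enough that blocks adjacent to the radial singularity at the injection
#' site are a small minority, and an imaged depth of 320 um covering the
#' analyzed dermal window (the thicker dermes extend below the imaged
#' depth, as in practice). The tissue surface sits at 30 um, the fiber
#' unitary is random, channel noise sd is 0.1 and the amplitude SNR decay
#' length 200 um.
#'
#' @param day One of `"control", "7", "14", "21", "28"` (numbers accepted).
#' @param seed Integer seed for the spec (thickness jitter, fiber unitary,
#'   orientation fields).
#' @return A [phantom_spec()] whose `meta` records `group`, `day_num` and the
#'   ground-truth `thickness_um`.
#' @export
preset_cohort <- function(day, seed = 1) {
  day <- as.character(day)
  tab <- list(
    control = list(num = 0, thick = 200, rate = 0.15,
                   orient = orient_random(60)),
    `7` = list(num = 7, thick = 250, rate = 0.25, orient = orient_random(60)),
    `14` = list(num = 14, thick = 300, rate = 0.35,
                orient = orient_random(35)),
    `21` = list(num = 21, thick = 350, rate = 0.45,
                orient = orient_radial(kappa = 16)),
    `28` = list(num = 28, thick = 400, rate = 0.55,
                orient = orient_radial(kappa = 64)))
  if (!day %in% names(tab)) stop("unknown preset day: ", day)
  p <- tab[[day]]
  set.seed(seed %% .Machine$integer.max)
  thick <- p$thick + round(max(-25, min(25, stats::rnorm(1, 0, 10))), 3)
  phantom_spec(
    grid = c(56L, 56L, 64L), pitch = c(10, 10, 5), surface_depth = 30,
    layers = list(layer_spec(0, thick, p$rate, p$orient)),
    fiber_rotation = "random", noise_floor = 0.1, snr_decay_length = 200,
    speckle = FALSE, seed = seed,
    meta = list(group = if (day == "control") "control" else paste0("day", day),
                day_num = p$num, thickness_um = thick))
}
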