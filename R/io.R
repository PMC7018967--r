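# Serialization: phantom specs as YAML, volumes via base-R serialization.

spec_to_list <- function(spec) {
  lay <- lapply(spec$layers, function(l) {
    o <- unclass(l$orientation)
    list(z_from = l$z_from, z_to = l$z_to,
         retardance_rate = l$retardance_rate,
         orientation = o,
         scattering_amplitude = l$scattering_amplitude)
  })
  fib <- spec$fiber_rotation
  if (is.matrix(fib))
    fib <- list(re = as.vector(Re(fib)), im = as.vector(Im(fib)))
  list(grid = as.integer(spec$grid), pitch = as.numeric(spec$pitch),
       surface_depth = if (is.matrix(spec$surface_depth))
         list(matrix = as.vector(spec$surface_depth)) else spec$surface_depth,
       layers = lay,
       input_states = list(re = as.vector(Re(spec$input_states)),
                           im = as.vector(Im(spec$input_states))),
       fiber_rotation = fib,
       noise_floor = spec$noise_floor,
       snr_decay_length = spec$snr_decay_length,
       speckle = spec$speckle, seed = spec$seed,
       meta = spec$meta)
}

list_to_spec <- function(x) {
  layers <- lapply(x$layers, function(l) {
    o <- l$orientation
    orient <- switch(o$type,
      uniform = orient_uniform(o$phi0),
      random = orient_random(o$corr_um),
      von_mises = orient_von_mises(o$mu, o$kappa, o$corr_um),
      radial = orient_radial(unlist(o$center_um), o$kappa, o$corr_um),
      stop("unknown orientation type in spec file: ", o$type))
    layer_spec(l$z_from, l$z_to, l$retardance_rate, orient,
               l$scattering_amplitude)
  })
  surf <- x$surface_depth
  if (is.list(surf)) surf <- matrix(unlist(surf$matrix), x$grid[1], x$grid[2])
  fib <- x$fiber_rotation
  if (is.list(fib))
    fib <- matrix(complex(real = unlist(fib$re), imaginary = unlist(fib$im)),
                  2, 2)
  phantom_spec(
    grid = unlist(x$grid), pitch = unlist(x$pitch), surface_depth = surf,
    layers = layers,
    input_states = matrix(complex(real = unlist(x$input_states$re),
                                  imaginary = unlist(x$input_states$im)),
                          2, 2),
    fiber_rotation = fib, noise_floor = x$noise_floor,
    snr_decay_length = x$snr_decay_length, speckle = x$speckle,
    seed = x$seed, meta = x$meta %||% list())
}

#' Read and write phantom specifications as YAML
#'
#' @param spec A [phantom_spec()].
#' @param path File path.
#' @return `read_phantom_spec` returns a validated [phantom_spec()];
#'   `write_phantom_spec` returns `path` invisibly. The round trip preserves
#'   the [spec_digest()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  yaml::write_yaml(spec_to_list(spec), path, precision = 17)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  list_to_spec(yaml::read_yaml(path))
}

#' Read and write volume containers
#'
#' Native container for the package's volume objects (`raw_tomogram`,
#' `stokes_volume`, `oa_volume`, ...): base-R serialization with a class
#' check on read.
#'
#' @param x Object to store.
#' @param path File path.
#' @param expect_class Optional class name to require on read.
#' @return `read_volume` returns the object; `write_volume` returns `path`
#'   invisibly.
#' @export
write_volume <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, expect_class = NULL) {
  x <- readRDS(path)
  if (!is.null(expect_class) && !inherits(x, expect_class))
    stop("stored object is not a ", expect_class)
  x
}

#' Write sample summaries as CSV
#'
#' @param samples `data.frame` of sample summaries.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_summaries <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}
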