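#' Describe a synthetic standard spectrum
#'
#' A synthetic standard is a named sum of Lorentzian lines standing in for
#' a database 1H standard spectrum of one metabolite.  Lorentzian line
#' shapes are the natural choice for solution NMR; the default half-width
#' at half-maximum of 0.002 ppm (~1.2 Hz at 600 MHz) is typical for small
#' molecules in biofluids.
#'
#' @param name metabolite name, unique within a library.
#' @param peaks data frame (or coercible) with columns `center` (ppm,
#'   inside 0.5--9.5), `height` (>= 0) and `width` (HWHM in ppm, > 0).
#' @return A list of class `standard_spec`.
#' @examples
#' standard_spec("lactate", data.frame(center = c(1.33, 4.11),
#'                                     height = c(3, 1), width = 0.002))
#' @export
standard_spec <- function(name, peaks) {
  peaks <- as.data.frame(peaks)
  need <- c("center", "height", "width")
  if (!all(need %in% names(peaks)))
    stop("`peaks` needs columns center, height, width")
  if (nrow(peaks) < 1L) stop("standard '", name, "' has no peaks")
  if (any(peaks$center < 0.5 | peaks$center > 9.5))
    stop("standard '", name, "' has peak centers outside 0.5-9.5 ppm")
  if (any(peaks$height < 0)) stop("standard '", name, "': negative height")
  if (any(peaks$width <= 0)) stop("standard '", name, "': width must be > 0")
  structure(list(name = as.character(name), peaks = peaks[, need]),
            class = "standard_spec")
}

## Lorentzian line: height h at center c, half-width at half-max w
lorentzian <- function(x, center, height, width) {
  height * width^2 / ((x - center)^2 + width^2)
}

#' Build a standard library from synthetic standard specs
#'
#' Evaluates each standard's Lorentzian peaks on the shared ppm axis and
#' scales every standard so its total intensity (sum over grid points)
#' equals one, matching the convention used for quantification.
#'
#' @param specs list of [standard_spec()] objects.
#' @param axis strictly monotone ppm grid shared by all standards.
#' @return A [standard_library()] object.
#' @export
make_standard_library <- function(specs, axis) {
  if (!length(specs)) stop("`specs` is empty")
  if (any(diff(axis) <= 0)) stop("`axis` must be strictly ascending")
  nm <- vapply(specs, function(x) x$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate standard names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  rng <- range(axis)
  mat <- t(vapply(specs, function(sp) {
    if (any(sp$peaks$center < rng[1] | sp$peaks$center > rng[2]))
      stop("standard '", sp$name, "' has a peak outside the axis range ",
           sprintf("[%.4g, %.4g] ppm", rng[1], rng[2]))
    y <- numeric(length(axis))
    for (i in seq_len(nrow(sp$peaks)))
      y <- y + lorentzian(axis, sp$peaks$center[i], sp$peaks$height[i],
                          sp$peaks$width[i])
    y
  }, numeric(length(axis))))
  standard_library(nm, mat, axis)
}

#' Standard library container
#'
#' Named standard spectra on a common ppm axis, one row per metabolite,
#' each row normalized to unit total intensity.
#'
#' @param names character vector of metabolite names.
#' @param matrix numeric matrix, standards x grid points.
#' @param axis ppm grid of length `ncol(matrix)`.
#' @return An object of class `standard_library`.
#' @export
standard_library <- function(names, matrix, axis) {
  stopifnot(is.matrix(matrix), length(names) == nrow(matrix),
            length(axis) == ncol(matrix))
  tot <- rowSums(matrix)
  if (any(tot <= 0)) stop("standard(s) with nonpositive total intensity: ",
                          paste(names[tot <= 0], collapse = ", "))
  matrix <- matrix / tot
  rownames(matrix) <- names
  structure(list(names = as.character(names), matrix = matrix,
                 axis = as.numeric(axis)),
            class = "standard_library")
}

#' @export
print.standard_library <- function(x, ...) {
  cat("<standard_library> ", length(x$names), " standards on ",
      length(x$axis), " grid points (",
      sprintf("%.3f..%.3f ppm", min(x$axis), max(x$axis)), ")\n", sep = "")
  cat("  ", paste(head(x$names, 8), collapse = ", "),
      if (length(x$names) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Write / read a standard library as plain-text standards plus manifest
#'
#' Each standard is stored as a two-column ppm/intensity text file; a
#' manifest CSV (columns `name`, `file`) lists them.  On read the
#' standards are re-normalized to unit total intensity.
#'
#' @param lib a [standard_library()].
#' @param dir directory to write into (created if missing).
#' @param manifest manifest file name within `dir`.
#' @return `write_standard_library()` returns `dir` invisibly;
#'   `read_standard_library()` returns a [standard_library()].
#' @export
write_standard_library <- function(lib, dir, manifest = "manifest.csv") {
  stopifnot(inherits(lib, "standard_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- paste0("standard_", gsub("[^A-Za-z0-9._-]", "_", lib$names),
                  ".txt")
  for (i in seq_along(lib$names))
    write_spectrum(nmr_spectrum(lib$axis, lib$matrix[i, ]),
                   file.path(dir, files[i]))
  write.csv(data.frame(name = lib$names, file = files),
            file.path(dir, manifest), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_standard_library
#' @export
read_standard_library <- function(dir, manifest = "manifest.csv") {
  man <- read.csv(file.path(dir, manifest), stringsAsFactors = FALSE)
  if (!all(c("name", "file") %in% names(man)))
    stop("manifest must have columns `name` and `file`")
  specs <- lapply(man$file, function(f) read_spectrum(file.path(dir, f)))
  axis <- specs[[1]]$ppm
  for (i in seq_along(specs))
    if (length(specs[[i]]$ppm) != length(axis) ||
        max(abs(specs[[i]]$ppm - axis)) > 1e-9)
      stop("standard '", man$name[i], "' is not on the shared ppm axis")
  standard_library(man$name,
                   do.call(rbind, lapply(specs, `[[`, "intensity")), axis)
}

#' Synthesize a mixture spectrum with known ground truth
#'
#' Builds `sum_i c_i * standard_i`, applies a circular shift of `shift`
#' ppm (rounded to the nearest grid point, emulating pH-driven peak
#' drift), adds a constant baseline offset and i.i.d. Gaussian noise, and
#' finally adds an isolated reference peak at 0 ppm of known area (so the
#' reference-normalization step downstream has something to find).  All
#' generating parameters are returned as a ground-truth record.
#'
#' @param lib a [standard_library()] whose axis covers 0 ppm (for the
#'   reference peak).
#' @param concentrations nonnegative vector, one value per standard.
#' @param baseline_offset constant added to the whole spectrum.
#' @param shift circular shift in ppm applied to the metabolite signal.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed; the same seed reproduces the spectrum
#'   exactly.
#' @param reference_height,reference_width Lorentzian parameters of the
#'   synthetic reference peak at 0 ppm.
#' @param meta metadata list attached to the spectrum.
#' @return A list with `spectrum` (an [nmr_spectrum()]) and `truth` (a
#'   list recording concentrations, shift in ppm and grid points,
#'   baseline, noise_sd, seed and the trapezoidal reference area).
#' @export
synthesize_mixture_spectrum <- function(lib, concentrations,
                                        baseline_offset = 0, shift = 0,
                                        noise_sd = 0, seed = 1L,
                                        reference_height = 50,
                                        reference_width = 0.002,
                                        meta = list()) {
  stopifnot(inherits(lib, "standard_library"))
  if (length(concentrations) != length(lib$names))
    stop("`concentrations` length (", length(concentrations),
         ") != library size (", length(lib$names), ")")
  if (any(concentrations < 0))
    stop("negative concentration for: ",
         paste(lib$names[concentrations < 0], collapse = ", "))
  axis <- lib$axis
  n <- length(axis)
  if (min(axis) > 0 || max(axis) < 0)
    stop("library axis does not cover 0 ppm; cannot place the reference peak")
  y <- as.numeric(crossprod(lib$matrix, concentrations))
  step <- mean(diff(axis))
  k <- as.integer(round(shift / step))
  if (k %% n != 0) {
    kk <- ((seq_len(n) - 1 - k) %% n) + 1
    y <- y[kk]
  }
  noise <- with_seed(seed, rnorm(n, sd = noise_sd))
  y <- y + baseline_offset + if (noise_sd > 0) noise else 0
  refpk <- lorentzian(axis, 0, reference_height, reference_width)
  y <- y + refpk
  ref_idx <- which(abs(axis) <= 0.05)
  list(spectrum = nmr_spectrum(axis, y, meta = meta),
       truth = list(concentrations = setNames(as.numeric(concentrations),
                                              lib$names),
                    baseline_offset = baseline_offset,
                    shift_ppm = k * step, shift_points = k,
                    noise_sd = noise_sd, seed = seed,
                    reference_area = pracma::trapz(axis[ref_idx],
                                                   refpk[ref_idx])))
}

## evaluate `expr` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
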