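#' Configure the synthetic LIBS spectrum generator
#'
#' Builds a [SynthConfig-class] describing a synthetic acquisition: a
#' uniform wavelength grid, an inventory of Gaussian emission lines with
#' per-class intensity multipliers, a smooth polynomial continuum
#' (baseline drift), additive Gaussian detector noise, and a grouped
#' replicate design of `nClasses x tabletsPerClass x shotsPerTablet`
#' spectra. Per-tablet multiplicative jitter (log-normal, shared by all
#' shots of a tablet) reproduces the pellet-level correlation structure of
#' real acquisitions, so leakage-aware splitting can be exercised.
#'
#' @param gridStart,gridEnd wavelength range in nm (default 370-1100, the
#'   working range of a typical broadband LIBS spectrometer).
#' @param nPoints grid length (default 2048).
#' @param lines `data.frame` with columns `element`, `center_nm`,
#'   `base_intensity` (counts), `width_nm` (Gaussian sd, nm).
#' @param classMultipliers `nClasses x nrow(lines)` matrix of nonnegative
#'   per-class line-intensity multipliers.
#' @param baselineCoeffs polynomial coefficients (ascending powers) of the
#'   continuum, evaluated on the grid rescaled to \[0, 1\].
#' @param noiseSd sd of i.i.d. additive Gaussian noise, counts.
#' @param nClasses,tabletsPerClass,shotsPerTablet replicate design
#'   (defaults 2 x 20 x 50 = 2000 spectra).
#' @param tabletJitterSd sd of the per-tablet log-normal line-intensity
#'   jitter (relative scale).
#' @param classNames class labels (default `class_1`, ...).
#' @param seed root RNG seed; per-tablet streams are derived from it so
#'   generation is reproducible independent of order.
#' @return a validated [SynthConfig-class]
#' @seealso [defaultSynthConfig()], [singleLineConfig()], [generateSpectra()]
#' @export
synthConfig <- function(gridStart = 370, gridEnd = 1100, nPoints = 2048L,
                        lines, classMultipliers, baselineCoeffs = 0,
                        noiseSd = 0, nClasses = 2L, tabletsPerClass = 20L,
                        shotsPerTablet = 50L, tabletJitterSd = 0,
                        classNames = NULL, seed = 1L) {
  if (is.null(classNames)) classNames <- sprintf("class_%d", seq_len(nClasses))
  classMultipliers <- as.matrix(classMultipliers)
  new("SynthConfig", gridStart = as.numeric(gridStart),
      gridEnd = as.numeric(gridEnd), nPoints = as.integer(nPoints),
      lines = as.data.frame(lines), classMultipliers = classMultipliers,
      baselineCoeffs = as.numeric(baselineCoeffs),
      noiseSd = as.numeric(noiseSd), nClasses = as.integer(nClasses),
      tabletsPerClass = as.integer(tabletsPerClass),
      shotsPerTablet = as.integer(shotsPerTablet),
      tabletJitterSd = as.numeric(tabletJitterSd),
      classNames = as.character(classNames), seed = as.integer(seed))
}

# Emission-line inventory of the default two-origin task. The four
# discriminating elements commonly reported for herb pellets (Ca, Na, N, K)
# plus nine filler lines of other plasma species seen in plant-matrix
# LIBS (including both members of the Ca II H/K doublet), all within the
# 370-1100 nm window.
.default_lines <- function() {
  data.frame(
    element = c("Ca", "Na", "N", "K",
                "Ca II", "Ca II", "Ca I", "H", "Mg", "Fe", "O", "N I",
                "Na I"),
    center_nm = c(616.22, 589.14, 656.26, 766.49,
                  393.37, 396.85, 422.67, 486.13, 517.27, 438.35, 777.19,
                  868.34, 819.48),
    base_intensity = c(5200, 4300, 3600, 6000,
                       2400, 2000, 2000, 1200, 1500, 900, 2600, 1100,
                       1300),
    width_nm = c(0.7, 0.7, 0.8, 0.7,
                 0.6, 0.6, 0.6, 0.9, 0.7, 0.6, 0.8, 0.8, 0.7),
    stringsAsFactors = FALSE)
}

#' Default two-origin synthetic task
#'
#' The standard study-sized configuration: 370-1100 nm on 2048 points,
#' twelve emission lines (Ca 616.22, Na 589.14, N 656.26, K 766.49 nm plus
#' eight fillers), a cubic continuum, additive noise, per-tablet jitter,
#' and 2 classes x 20 tablets x 50 shots = 2000 spectra. The two classes
#' share identical multipliers on all non-discriminative lines and differ
#' on the Ca 616.22 and K 766.49 nm lines (ratios 1.35 and 0.75), a
#' moderate elemental-abundance contrast of the kind that separates
#' geographic origins.
#'
#' @param seed root RNG seed.
#' @return a [SynthConfig-class]
#' @export
defaultSynthConfig <- function(seed = 1L) {
  lines <- .default_lines()
  mult <- matrix(1, nrow = 2L, ncol = nrow(lines))
  disc <- match(c(616.22, 766.49), lines$center_nm)
  mult[2L, disc] <- c(1.35, 0.75)
  synthConfig(lines = lines, classMultipliers = mult,
              # positive cubic continuum, decaying towards the red end
              baselineCoeffs = c(1200, -1500, 900, -300),
              noiseSd = 25, tabletJitterSd = 0.08,
              classNames = c("origin_A", "origin_B"), seed = seed)
}

#' Single-discriminative-line localization task
#'
#' A two-class configuration in which a "marked" class is distinguished
#' from a neutral "reference" class by exactly one enhanced emission line
#' (O 777.19 nm at 2.2x by default), used to benchmark saliency
#' localization: a model that separates the classes must attend to that
#' line, and the saliency map probed for the marked class's score should
#' single out its center on every spectrum.
#'
#' The default marker satisfies three structural requirements without
#' which gradient-weighted class-activation maps cannot pin class
#' evidence to a wavelength: (i) the enhanced line stays below the
#' spectrum maximum (K 766.49 nm), since per-spectrum min-max
#' normalization pins the global maximum to 1 and would absorb a
#' multiplier on it, redistributing the signal over the whole spectrum;
#' (ii) it has a companion line (K) at a spacing the pooled feature maps
#' can resolve, so enhancing it alters a local intensity-ratio pattern
#' that translation-invariant convolutional filters can detect in place
#' — an isolated enhanced line of generic shape is indistinguishable
#' from any other line to such filters; and (iii) the enhancement is
#' large enough that the marked line dominates its local neighbourhood's
#' activations.
#'
#' @param seed root RNG seed.
#' @param centerNm the marker-line center, drawn from the default
#'   inventory.
#' @param multiplier enhancement factor of the marker line in the marked
#'   class.
#' @param tabletsPerClass,shotsPerTablet replicate design (default
#'   10 x 20 = 400 spectra, a lighter benchmark than the full design).
#' @return a [SynthConfig-class] with classes `reference` and `marked`.
#' @seealso [markerLines()]
#' @export
singleLineConfig <- function(seed = 1L, centerNm = 777.19,
                             multiplier = 2.2,
                             tabletsPerClass = 10L, shotsPerTablet = 20L) {
  lines <- .default_lines()
  disc <- match(centerNm, lines$center_nm)
  if (is.na(disc)) stop("centerNm must be among the default line centers",
                        call. = FALSE)
  mult <- matrix(1, nrow = 2L, ncol = nrow(lines))
  mult[2L, disc] <- multiplier
  synthConfig(lines = lines, classMultipliers = mult,
              baselineCoeffs = c(1200, -1500, 900, -300),
              noiseSd = 25, tabletJitterSd = 0.08,
              tabletsPerClass = tabletsPerClass,
              shotsPerTablet = shotsPerTablet,
              classNames = c("reference", "marked"), seed = seed)
}

#' Per-class marker lines of a configuration
#'
#' Returns, for each class, the center (nm) of the emission line whose
#' multiplier uniquely marks that class — the wavelength a faithful
#' saliency map should single out for spectra of that class. `NA` for
#' classes without a unique marker.
#'
#' @param cfg a [SynthConfig-class]
#' @return numeric vector of length `nClasses`.
#' @export
markerLines <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  vapply(seq_len(cfg@nClasses), function(k) {
    d <- which(cfg@classMultipliers[k, ] != 1 &
                 vapply(seq_len(ncol(cfg@classMultipliers)), function(j)
                   all(cfg@classMultipliers[-k, j] == 1), logical(1)))
    if (length(d) == 1L) cfg@lines$center_nm[d] else NA_real_
  }, 0)
}

.eval_baseline <- function(coeffs, u) {
  b <- numeric(length(u))
  for (j in seq_along(coeffs)) b <- b + coeffs[j] * u^(j - 1L)
  b
}

#' Generate a synthetic labeled spectral dataset
#'
#' Draws `nClasses x tabletsPerClass x shotsPerTablet` spectra. Each
#' intensity vector is
#' `baseline(lambda) + sum_lines mult[class, line] * jitter[tablet, line] *
#' base_intensity * exp(-(lambda - center)^2 / (2 width^2)) + noise`,
#' clipped at zero. Per-tablet RNG streams are derived from the root seed,
#' so identical configs give bitwise-identical datasets.
#'
#' @param cfg a [SynthConfig-class]
#' @return a [SpectralSet-class] with `tabletsPerClass * shotsPerTablet`
#'   spectra per class.
#' @examples
#' cfg <- singleLineConfig(seed = 7, tabletsPerClass = 2L, shotsPerTablet = 3L)
#' generateSpectra(cfg)
#' @export
generateSpectra <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  validObject(cfg)
  wl <- seq(cfg@gridStart, cfg@gridEnd, length.out = cfg@nPoints)
  u <- (wl - cfg@gridStart) / (cfg@gridEnd - cfg@gridStart)
  base <- .eval_baseline(cfg@baselineCoeffs, u)
  nLines <- nrow(cfg@lines)
  # fixed line profiles on the grid: nPoints x nLines
  prof <- matrix(0, cfg@nPoints, nLines)
  for (j in seq_len(nLines))
    prof[, j] <- cfg@lines$base_intensity[j] *
      exp(-(wl - cfg@lines$center_nm[j])^2 / (2 * cfg@lines$width_nm[j]^2))

  nTab <- cfg@nClasses * cfg@tabletsPerClass
  nShot <- cfg@shotsPerTablet
  # derive independent per-tablet seeds from the root generator, restoring
  # the caller's RNG state afterwards
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(cfg@seed)
  tabletSeeds <- sample.int(.Machine$integer.max - 1L, nTab)
  inten <- matrix(0, cfg@nPoints, nTab * nShot)
  classes <- integer(nTab * nShot)
  tablets <- character(nTab * nShot)
  shots <- integer(nTab * nShot)
  for (t in seq_len(nTab)) {
    cl <- (t - 1L) %/% cfg@tabletsPerClass + 1L
    set.seed(tabletSeeds[t])
    jitter <- if (cfg@tabletJitterSd > 0)
      exp(rnorm(nLines, 0, cfg@tabletJitterSd)) else rep(1, nLines)
    amp <- cfg@classMultipliers[cl, ] * jitter
    clean <- base + as.vector(prof %*% amp)
    cols <- ((t - 1L) * nShot + 1L):(t * nShot)
    noise <- if (cfg@noiseSd > 0)
      matrix(rnorm(cfg@nPoints * nShot, 0, cfg@noiseSd), cfg@nPoints) else 0
    inten[, cols] <- pmax(clean + noise, 0)
    classes[cols] <- cl
    tablets[cols] <- sprintf("%s_tab%02d", cfg@classNames[cl],
                             (t - 1L) %% cfg@tabletsPerClass + 1L)
    shots[cols] <- seq_len(nShot) - 1L
  }
  SpectralSet(inten, wl,
              classes = cfg@classNames[classes],
              tablets = tablets,
              sampleIds = sprintf("%s_s%02d", tablets, shots),
              shotIndex = shots,
              classNames = cfg@classNames)
}
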