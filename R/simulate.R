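#' Configuration of the synthetic leaf-spectra generator
#'
#' The generator emulates the statistical structure of a multi-species,
#' multi-month leaf spectroscopy campaign: 5 species x 10 months
#' (February--November) x 7 replicates = 350 samples on a 350--2500 nm
#' 1 nm grid. Chlorophyll is drawn around species means with a seasonal
#' cosine peaking in August and replicate noise, clipped to the observed
#' field range; absorbance spectra are built additively from a smooth
#' species baseline, a chlorophyll-scaled visible band near 600 nm, a
#' chlorophyll-scaled red-edge/NIR shoulder over 740--1100 nm, water bands
#' at 1450 and 1940 nm, and iid Gaussian noise, then returned as
#' reflectance `R = 10^(-A)`.
#'
#' @param species character vector of species labels.
#' @param species_mean chlorophyll mean per species, mg per g.
#' @param months calendar months sampled (default `2:11`).
#' @param n_reps replicates per species-month cell (default 7).
#' @param wavelengths wavelength grid in nm (default 350--2500 step 1).
#' @param chl_range clip range for chlorophyll draws, mg per g.
#' @param seasonal_amp amplitude of the seasonal cosine (default 0.15).
#' @param peak_month month at which the seasonal factor peaks (default 8,
#'   August).
#' @param sigma_c replicate chlorophyll noise sd, mg per g (default 0.25).
#' @param beta_vis absorbance per mg/g of chlorophyll at the visible band
#'   centre (default 0.15).
#' @param vis_center,vis_sigma visible chlorophyll band: Gaussian centre
#'   and width, nm (defaults 600, 45).
#' @param beta_nir absorbance per mg/g over the NIR shoulder (default
#'   0.08).
#' @param nir_lo,nir_hi red-edge/NIR shoulder ramp positions, nm (defaults
#'   740, 1100).
#' @param water_mean,water_sd per-sample water index distribution (defaults
#'   0.5, 0.1).
#' @param water_amp amplitudes of the 1450 and 1940 nm water bands
#'   (defaults 0.6, 0.9).
#' @param water_sigma water band Gaussian width, nm (default 60).
#' @param sigma_a iid absorbance noise sd (default 0.005).
#' @param a_cap absorbance clip ceiling keeping reflectance positive
#'   (default 6).
#' @param water_chl_cor optional correlation between the water index and
#'   chlorophyll (default 0, uncorrelated).
#' @return a `generator_config` list.
#' @export
generator_config <- function(
    species = c("Galium aparine", "Chrysanthemum indicum",
                "Cercis chinensis", "Cinnamomum camphora",
                "Spathiphyllum"),
    species_mean = c(1.47, 1.95, 1.88, 1.10, 1.77),
    months = 2:11, n_reps = 7,
    wavelengths = seq(350, 2500, by = 1),
    chl_range = c(0.79, 3.03),
    seasonal_amp = 0.15, peak_month = 8, sigma_c = 0.25,
    beta_vis = 0.15, vis_center = 600, vis_sigma = 45,
    beta_nir = 0.08, nir_lo = 740, nir_hi = 1100,
    water_mean = 0.5, water_sd = 0.1, water_amp = c(0.6, 0.9),
    water_sigma = 60, sigma_a = 0.005, a_cap = 6, water_chl_cor = 0) {
  if (length(species) != length(species_mean))
    stop("species and species_mean lengths differ")
  if (sigma_c < 0 || sigma_a < 0 || water_sd < 0)
    stop("noise standard deviations must be >= 0")
  structure(list(species = species, species_mean = species_mean,
                 months = as.integer(months), n_reps = as.integer(n_reps),
                 wavelengths = wavelengths, chl_range = chl_range,
                 seasonal_amp = seasonal_amp, peak_month = peak_month,
                 sigma_c = sigma_c, beta_vis = beta_vis,
                 vis_center = vis_center, vis_sigma = vis_sigma,
                 beta_nir = beta_nir, nir_lo = nir_lo, nir_hi = nir_hi,
                 water_mean = water_mean, water_sd = water_sd,
                 water_amp = water_amp, water_sigma = water_sigma,
                 sigma_a = sigma_a, a_cap = a_cap,
                 water_chl_cor = water_chl_cor),
            class = "generator_config")
}

seasonal_factor <- function(month, cfg) {
  1 + cfg$seasonal_amp * cospi(2 * (month - cfg$peak_month) / 12)
}

#' Simulate sample metadata with chlorophyll content
#'
#' Draws `chl(species, month, rep) = species_mean * seasonal_factor(month)
#' + N(0, sigma_c)`, clipped to the configured range. The seasonal factor
#' is a cosine in month with its maximum at `peak_month`.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed (mandatory; the draw is fully reproducible).
#' @return metadata `data.frame` with columns `sample_id`, `chlorophyll`,
#'   `species`, `month`, `replicate`.
#' @export
simulate_chlorophyll <- function(cfg = generator_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  grid <- expand.grid(replicate = seq_len(cfg$n_reps),
                      month = cfg$months,
                      species = cfg$species,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  mu <- cfg$species_mean[match(grid$species, cfg$species)] *
    seasonal_factor(grid$month, cfg)
  chl <- local_seed(seed, mu + stats::rnorm(n, 0, cfg$sigma_c))
  chl <- pmin(pmax(chl, cfg$chl_range[1]), cfg$chl_range[2])
  validate_metadata(data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    chlorophyll = chl,
    species = grid$species,
    month = as.integer(grid$month),
    replicate = as.integer(grid$replicate)))
}

# smooth species baseline: seeded spline through random knots, with one
# deviant species mimicking a distinct 1200-2400 nm profile
species_baselines <- function(cfg, seed) {
  wl <- cfg$wavelengths
  kx <- seq(min(wl), max(wl), length.out = 8)
  deviant <- which(cfg$species == "Cinnamomum camphora")
  local_seed(seed + 211L, {
    out <- lapply(seq_along(cfg$species), function(s) {
      ky <- stats::runif(length(kx), 0.25, 0.55)
      b <- stats::spline(kx, ky, xout = wl)$y
      if (length(deviant) && s == deviant[1]) {
        b <- b + 0.25 * exp(-(wl - 1800) ^ 2 / (2 * 300 ^ 2))
      }
      pmax(b, 0.05)
    })
    names(out) <- cfg$species
    out
  })
}

#' Simulate reflectance spectra for a metadata table
#'
#' Builds absorbance additively -- species baseline, chlorophyll-scaled
#' visible Gaussian band and NIR shoulder, per-sample water bands, iid
#' noise -- clips it to `(0, a_cap]` (clipped cells are counted in a
#' warning) and returns reflectance `R = 10^(-A)`, guaranteed in `(0, 1]`.
#'
#' @param meta metadata `data.frame` (see [simulate_chlorophyll()]).
#' @param cfg a [generator_config()].
#' @param seed integer seed (mandatory).
#' @return a reflectance-mode [spectra] object.
#' @export
simulate_spectra <- function(meta, cfg = generator_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  meta <- validate_metadata(meta)
  wl <- cfg$wavelengths
  n <- nrow(meta); p <- length(wl)
  base <- species_baselines(cfg, seed)
  gvis <- exp(-(wl - cfg$vis_center) ^ 2 / (2 * cfg$vis_sigma ^ 2))
  shoulder <- stats::plogis((wl - cfg$nir_lo) / 20) *
    stats::plogis((cfg$nir_hi - wl) / 50)
  gw <- cfg$water_amp[1] * exp(-(wl - 1450) ^ 2 / (2 * cfg$water_sigma ^ 2)) +
    cfg$water_amp[2] * exp(-(wl - 1940) ^ 2 / (2 * cfg$water_sigma ^ 2))

  chl <- meta$chlorophyll
  draws <- local_seed(seed + 977L, {
    w_ind <- stats::rnorm(n)
    eps <- matrix(stats::rnorm(n * p, 0, cfg$sigma_a), n, p)
    list(w_ind = w_ind, eps = eps)
  })
  # water index, optionally correlated with (standardised) chlorophyll
  rho <- cfg$water_chl_cor
  z_chl <- if (stats::sd(chl) > 0) scale(chl)[, 1] else numeric(n)
  w <- cfg$water_mean + cfg$water_sd *
    (rho * z_chl + sqrt(1 - rho ^ 2) * draws$w_ind)
  w <- pmax(w, 0)

  A <- do.call(rbind, base[meta$species]) +
    outer(cfg$beta_vis * chl, gvis) +
    outer(cfg$beta_nir * chl, shoulder) +
    outer(w, gw) +
    draws$eps
  n_clip <- sum(A <= 0 | A > cfg$a_cap)
  if (n_clip > 0)
    warning(sprintf("%d absorbance cells clipped to (0, %g]", n_clip,
                    cfg$a_cap))
  A <- pmin(pmax(A, 1e-6), cfg$a_cap)
  spectra(10 ^ (-A), wl, "reflectance", meta$sample_id)
}

#' Simulate a complete leaf dataset
#'
#' Metadata draw plus matching spectra, joined into a `leaf_dataset`.
#'
#' @inheritParams simulate_spectra
#' @return a `leaf_dataset` (see [join_metadata()]).
#' @export
simulate_leaf_dataset <- function(cfg = generator_config(), seed) {
  meta <- simulate_chlorophyll(cfg, seed)
  join_metadata(simulate_spectra(meta, cfg, seed), meta)
}

#' Write a synthetic fixture to disk
#'
#' `"tiny"` is a 12-sample, 200-band design (3 species x 2 months x 2
#' replicates) for fast tests; `"study"` is the full 350-sample, 2151-band
#' campaign design. Regenerating with the same seed is byte-identical.
#'
#' @param size `"tiny"` or `"study"`.
#' @param dir output directory (created if needed).
#' @param seed integer seed (default 1).
#' @return invisibly, `c(spectra = <path>, meta = <path>)`.
#' @export
make_fixture <- function(size = c("tiny", "study"), dir, seed = 1) {
  size <- match.arg(size)
  cfg <- fixture_config(size)
  meta <- simulate_chlorophyll(cfg, seed)
  sp <- simulate_spectra(meta, cfg, seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp_path <- file.path(dir, "spectra.csv")
  meta_path <- file.path(dir, "meta.csv")
  write_spectra(sp, sp_path, layout = "wide")
  lines <- c("sample_id,chlorophyll,species,month,replicate",
             paste(meta$sample_id, format_full(meta$chlorophyll),
                   meta$species, meta$month, meta$replicate, sep = ","))
  writeLines(lines, meta_path)
  invisible(c(spectra = sp_path, meta = meta_path))
}

fixture_config <- function(size) {
  if (size == "study") return(generator_config())
  g <- generator_config()
  generator_config(species = g$species[1:3],
                   species_mean = g$species_mean[1:3],
                   months = c(5L, 8L), n_reps = 2,
                   wavelengths = seq(400, 2400, length.out = 200))
}
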