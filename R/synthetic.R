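#' Configuration for the synthetic growth-rate dataset generator
#'
#' Emulates the published measurement design: a short-filament series of 72
#' cells measured with 5-min intervals over 400-2800 nm, and a
#' long-filament series of 103 cells measured with 20-min intervals over
#' 1000-7500 nm, with additive rate noise and 65-nm pixel quantization of
#' the underlying projected lengths.
#'
#' @param true_D,true_LS Generating model parameters (defaults: the
#'   best-fit pair D = 5000 nm^2/s, LS = 12).
#' @param S_load Loading rate, attempts/s.
#' @param n_short,short_range Points and length range (nm) of the 5-min
#'   series.
#' @param n_long,long_range Points and length range (nm) of the 20-min
#'   series.  Set `n_long = 0` to generate only the short series.
#' @param noise_sd SD of additive Gaussian rate noise, nm/min.  The
#'   published scatter is not quantified; 5 nm/min is a stand-in chosen to
#'   resemble it.
#' @param pixel_nm Pixel size quantizing the projected 2D lengths (0
#'   disables quantization).
#' @param projection_factor 2D-to-3D correction slope applied around the
#'   quantization.
#' @param replicates Simulated traces behind the model curve.
#' @param seed Integer seed making the dataset reproducible.
#' @param sim_args Named list of extra [sim_params()] overrides (e.g. a
#'   coarser `dt`) applied to the generating simulations.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(true_D = 5000, true_LS = 12, S_load = 1.7,
                         n_short = 72, short_range = c(400, 2800),
                         n_long = 103, long_range = c(1000, 7500),
                         noise_sd = 5, pixel_nm = 65,
                         projection_factor = 1.09, replicates = 3,
                         seed = NULL, sim_args = list()) {
  stopifnot(true_D > 0, true_LS >= 0, S_load > 0, n_short >= 0, n_long >= 0,
            noise_sd >= 0, pixel_nm >= 0, projection_factor >= 1,
            replicates >= 1)
  chk_range <- function(r) length(r) == 2L && r[1L] > 0 && r[2L] > r[1L]
  if (n_short > 0 && !chk_range(short_range)) stop("bad 'short_range'")
  if (n_long > 0 && !chk_range(long_range)) stop("bad 'long_range'")
  if (n_short + n_long < 2L) stop("need at least 2 points in total")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  structure(list(true_D = true_D, true_LS = as.integer(true_LS),
                 S_load = S_load, n_short = n_short,
                 short_range = short_range, n_long = n_long,
                 long_range = long_range, noise_sd = noise_sd,
                 pixel_nm = pixel_nm, projection_factor = projection_factor,
                 replicates = replicates, seed = as.integer(seed),
                 sim_args = sim_args),
            class = "synth_config")
}

#' Generate a synthetic growth-rate dataset
#'
#' Simulates replicate traces at the generating parameters, reduces them to
#' a median-filtered model rate curve, then draws one point per synthetic
#' cell: a midpoint length uniform in the series' range, the model rate
#' over the series' interval, measurement emulation (the two underlying
#' endpoint lengths are projected to 2D, quantized to the pixel grid and
#' re-projected before differencing), and additive Gaussian rate noise.
#' Negative noisy rates are clipped at zero.  With `noise_sd = 0` and
#' `pixel_nm = 0` the points lie exactly on the model curve, so the cost at
#' the generating parameters is zero.
#'
#' @param cfg A [synth_config()].
#' @param curve Optional precomputed generating [rate_curve()] (e.g. from
#'   [model_rate_curve()] at the generating parameters), reused instead of
#'   re-simulating; it must span the configured length ranges.  Useful when
#'   drawing many datasets from the same underlying model prediction.
#' @return A [growth_rate_data()] with attributes `config` and
#'   `model_curve` (the curve the points were drawn from).
#' @examples
#' \donttest{
#' dat <- generate_dataset(synth_config(n_short = 20, n_long = 0, seed = 1))
#' }
#' @export
generate_dataset <- function(cfg, curve = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  series <- list()
  if (cfg$n_short > 0)
    series$short <- list(n = cfg$n_short, range = cfg$short_range,
                         interval = 5)
  if (cfg$n_long > 0)
    series$long <- list(n = cfg$n_long, range = cfg$long_range,
                        interval = 20)
  max_len <- max(vapply(series, function(s) s$range[2L], numeric(1)))
  max_int <- max(vapply(series, function(s) s$interval, numeric(1)))
  # traces must cover the far endpoint L + rate * interval / 2
  L_stop <- max_len + 60 * max_int / 2

  withr::with_seed(cfg$seed, {
    if (is.null(curve))
      curve <- do.call(model_rate_curve,
                       c(list(D = cfg$true_D, LS = cfg$true_LS,
                              replicates = cfg$replicates,
                              S_load = cfg$S_load, L_stop = L_stop),
                         cfg$sim_args))
    out <- lapply(series, function(s) {
      L_mid <- runif(s$n, s$range[1L], s$range[2L])
      V <- suppressWarnings(model_rate_at_length(curve, L_mid))
      half <- V * s$interval / 2
      L1 <- .quantize_3d(L_mid - half, cfg)
      L2 <- .quantize_3d(L_mid + half, cfg)
      rate <- (L2 - L1) / s$interval + rnorm(s$n, 0, cfg$noise_sd)
      data.frame(length_nm = (L1 + L2) / 2,
                 rate_nm_per_min = pmax(rate, 0),
                 interval_min = s$interval)
    })
  })
  df <- do.call(rbind, out)
  dat <- growth_rate_data(df$length_nm, df$rate_nm_per_min, df$interval_min)
  attr(dat, "config") <- cfg
  attr(dat, "model_curve") <- curve
  dat
}

# Emulate measurement of a 3D length: project to 2D, snap to the pixel
# grid, convert back.  Identity when pixel_nm = 0.
.quantize_3d <- function(L3D, cfg) {
  if (cfg$pixel_nm == 0) return(L3D)
  L2D <- L3D / cfg$projection_factor
  round(L2D / cfg$pixel_nm) * cfg$pixel_nm * cfg$projection_factor
}

#' Unfolded length of a flagellin monomer
#'
#' Assumes the unfolded peptide length is proportional to residue count,
#' anchored to the 494-residue reference flagellin whose partially unfolded
#' chain is 74 nm.  For the 379-residue *V. alginolyticus* flagellin FlaE
#' this gives 74 * 379 / 494 = 56.77 nm; the simulator uses the truncated
#' canonical value 56 nm (the `ell` default of [sim_params()]).
#'
#' @param n_aa Residue count of the flagellin of interest (default 379,
#'   FlaE).
#' @param ref_len_nm Unfolded length of the reference flagellin, nm.
#' @param ref_aa Residue count of the reference flagellin.
#' @return Estimated unfolded length, nm.
#' @examples
#' unfolded_length()  # 56.77, truncated to 56 for the simulator
#' @export
unfolded_length <- function(n_aa = 379, ref_len_nm = 74, ref_aa = 494) {
  stopifnot(n_aa >= 0, ref_len_nm > 0, ref_aa > 0)
  ref_len_nm * n_aa / ref_aa
}

#' Filament length increment per crystallized monomer
#'
#' One helical turn of 11 flagellins elongates the filament by 5.2 nm
#' (52 Angstrom), so each crystallized monomer adds 5.2/11 = 0.47 nm —
#' the `dL` default of [sim_params()].
#'
#' @param turn_len Axial rise per helical turn (default 5.2 nm).
#' @param monomers_per_turn Flagellins per turn (default 11).
#' @param units Units of `turn_len`: `"nm"` or `"angstrom"`.
#' @param digits Rounding applied to the canonical constant (2 decimals).
#' @return Increment in nm.
#' @examples
#' increment_per_monomer()            # 0.47
#' increment_per_monomer(52, units = "angstrom")
#' @export
increment_per_monomer <- function(turn_len = 5.2, monomers_per_turn = 11,
                                  units = c("nm", "angstrom"), digits = 2) {
  units <- match.arg(units)
  stopifnot(turn_len > 0, monomers_per_turn > 0)
  if (units == "angstrom") turn_len <- turn_len / 10
  round(turn_len / monomers_per_turn, digits)
}
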