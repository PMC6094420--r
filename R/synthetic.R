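#' Gaussian fluorophore band specification
#'
#' A fluorophore's EEM landscape is modelled as the outer product of two
#' unit-peak Gaussian band shapes, one along each wavelength axis:
#' `I(ex, em) = q * exp(-0.5 ((ex - ex_c)/ex_w)^2) * exp(-0.5 ((em - em_c)/em_w)^2)`
#' per molar of fluorophore, a rank-one (bilinear) surface.
#'
#' @param ex_center,em_center Band centres (nm).
#' @param ex_width,em_width Gaussian band widths (nm, standard-deviation
#'   parameterisation), > 0.
#' @param quantum_scale Peak intensity per molar concentration, > 0.
#' @return An object of class `fluorophore`.
#' @export
#' @examples
#' # ibuprofen in chloroform: excitation max 251 nm, emission max 362.5 nm
#' fluorophore(251, 6, 362.5, 22, quantum_scale = 1.7e8)
fluorophore <- function(ex_center, ex_width, em_center, em_width,
                        quantum_scale = 1) {
  stopifnot(is.finite(ex_center), is.finite(em_center),
            ex_width > 0, em_width > 0, quantum_scale > 0)
  structure(
    list(ex_center = ex_center, ex_width = ex_width, em_center = em_center,
         em_width = em_width, quantum_scale = quantum_scale),
    class = "fluorophore"
  )
}

# emission x excitation unit-peak landscape on a grid
band_landscape <- function(fluor, grid) {
  g_em <- exp(-0.5 * ((grid$emission - fluor$em_center) / fluor$em_width)^2)
  g_ex <- exp(-0.5 * ((grid$excitation - fluor$ex_center) / fluor$ex_width)^2)
  outer(g_em, g_ex)
}

#' Simulation design for synthetic EEM cubes
#'
#' @param grid A [wavelength_grid()].
#' @param analyte A [fluorophore()] for the analyte of interest.
#' @param concentrations Molar analyte concentrations, one per sample
#'   (0 = blank).
#' @param interferents List of background [fluorophore()] bands; each entry
#'   may carry an attribute-free companion range in `interferent_ranges`.
#' @param interferent_ranges List of length-2 numeric vectors; per sample,
#'   each interferent's level (peak intensity) is drawn uniformly from its
#'   range, emulating sample-to-sample serum background variability.
#' @param noise_sd Additive homoscedastic Gaussian noise standard deviation
#'   (intensity units).
#' @param heteroscedastic If `TRUE`, noise SD additionally scales with the
#'   local signal as `noise_sd * (1 + signal / max(signal))`.
#' @param scatter_height Optional first-order Rayleigh-like diagonal ridge
#'   height at `em == ex` (0 disables; off by default since solvent
#'   extraction removes most scatter in the emulated setup).
#' @param roles Optional character vector of per-sample roles (recycled
#'   rules not applied; must match `length(concentrations)`); default
#'   `"unknown"` with `"blank"` for zero concentrations.
#' @param seed Integer seed; identical designs give identical cubes.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(grid, analyte, concentrations,
                              interferents = list(),
                              interferent_ranges = list(),
                              noise_sd = 0, heteroscedastic = FALSE,
                              scatter_height = 0, roles = NULL, seed = 1L) {
  if (length(concentrations) == 0) {
    stop("concentration list must be non-empty", call. = FALSE)
  }
  stopifnot(inherits(grid, "wavelength_grid"), inherits(analyte, "fluorophore"),
            all(is.finite(concentrations)), all(concentrations >= 0),
            noise_sd >= 0, length(interferents) == length(interferent_ranges))
  if (is.null(roles)) {
    roles <- ifelse(concentrations == 0, "blank", "unknown")
  }
  stopifnot(length(roles) == length(concentrations))
  structure(
    list(grid = grid, analyte = analyte, concentrations = concentrations,
         interferents = interferents, interferent_ranges = interferent_ranges,
         noise_sd = noise_sd, heteroscedastic = heteroscedastic,
         scatter_height = scatter_height, roles = roles,
         seed = as.integer(seed)),
    class = "simulation_design"
  )
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate an EEM cube from a design
#'
#' Each sample's landscape is the bilinear analyte contribution
#' `c_i * quantum_scale * g_ex %o% g_em` plus one rank-one term per
#' interferent at a per-sample uniform random level, plus additive Gaussian
#' noise. The same design (including seed) always yields the same cube.
#'
#' @param design A [simulation_design()].
#' @return An [eem_cube()] with roles and concentrations from the design.
#' @export
#' @examples
#' g <- wavelength_grid(seq(240, 260, 5), seq(320, 400, 10))
#' d <- simulation_design(g, fluorophore(251, 6, 362.5, 22, 1e8),
#'                        concentrations = c(1e-7, 2e-7), seed = 7)
#' simulate_cube(d)
simulate_cube <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  grid <- design$grid
  analyte_land <- band_landscape(design$analyte, grid) *
    design$analyte$quantum_scale
  interf_lands <- lapply(design$interferents, band_landscape, grid = grid)
  n <- length(design$concentrations)
  n_em <- length(grid$emission)
  n_ex <- length(grid$excitation)
  scatter <- if (design$scatter_height > 0) {
    ridge <- outer(grid$emission, grid$excitation,
                   function(em, ex) exp(-0.5 * ((em - ex) / 5)^2))
    design$scatter_height * ridge
  } else NULL

  samples <- with_seed(design$seed, {
    lapply(seq_len(n), function(i) {
      m <- design$concentrations[i] * analyte_land
      for (j in seq_along(interf_lands)) {
        rng <- design$interferent_ranges[[j]]
        level <- stats::runif(1, rng[1], rng[2])
        m <- m + level * interf_lands[[j]]
      }
      if (!is.null(scatter)) m <- m + scatter
      if (design$noise_sd > 0) {
        sd_mat <- if (design$heteroscedastic && max(m) > 0) {
          design$noise_sd * (1 + m / max(m))
        } else design$noise_sd
        m <- m + stats::rnorm(n_em * n_ex, sd = sd_mat)
      }
      eem_sample(sprintf("S%02d", i), m, role = design$roles[i],
                 concentration = design$concentrations[i])
    })
  })
  eem_cube(grid, samples)
}

# 61-level concentration ladder (x 1e-7 M) of the emulated serum study,
# spanning 0.1e-7 to 47e-7 M
serum_ladder_1e7 <- c(
  11, 12, 13, 1.5, 16, 17, 18, 19, 21, 22, 23, 24, 25, 2.5, 26, 27, 28, 29,
  31, 32, 33, 34, 35, 3.5, 36, 37, 38, 39, 41, 42, 43, 44, 45, 4.5, 46, 47,
  5.5, 7.5, 8.5, 9.5, 10, 1, 0.1, 20, 2, 0.2, 30, 3, 0.3, 40, 4, 0.4, 5,
  0.5, 6, 7, 0.7, 8, 0.8, 9, 0.9
)

#' Default ibuprofen-in-serum simulation design
#'
#' Emulates the reference bioanalytical setup: 61 spiked-serum samples with
#' analyte concentrations on a fixed ladder spanning 0.1--47 x 1e-7 M, an
#' analyte band centred at 251 nm excitation / 362.5 nm emission, two broad
#' serum-like interferent bands at per-sample random levels, additive
#' Gaussian detector noise at roughly 0.5% of the full-scale analyte signal,
#' and (optionally) extra blank samples for detection-limit estimation.
#'
#' @param seed Integer seed for the per-sample interferent levels and noise.
#' @param n_blanks Number of blank (zero-analyte) samples appended after the
#'   61-sample ladder (default 5).
#' @param noise_sd Noise standard deviation in intensity units; the analyte
#'   peak at the top of the ladder is ~800 units, so the default 4 is ~0.5%
#'   of full scale.
#' @return A [simulation_design()] on the [default_grid()].
#' @export
#' @examples
#' d <- ibuprofen_serum_design(seed = 42)
#' length(d$concentrations)  # 61 ladder samples + 5 blanks
ibuprofen_serum_design <- function(seed = 1L, n_blanks = 5, noise_sd = 4) {
  conc <- c(serum_ladder_1e7 * 1e-7, rep(0, n_blanks))
  roles <- c(rep("unknown", length(serum_ladder_1e7)), rep("blank", n_blanks))
  simulation_design(
    grid = default_grid(),
    # peak ~800 intensity units at 47e-7 M: quantum_scale 1.7e8 / M
    analyte = fluorophore(251, 6, 362.5, 22, quantum_scale = 1.7e8),
    concentrations = conc,
    interferents = list(
      fluorophore(245, 15, 335, 40, quantum_scale = 1),
      fluorophore(259, 12, 420, 55, quantum_scale = 1)
    ),
    interferent_ranges = list(c(20, 60), c(5, 30)),
    noise_sd = noise_sd,
    roles = roles,
    seed = seed
  )
}
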