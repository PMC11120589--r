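#' Box-Behnken design skeleton for three factors
#'
#' Generates the 12 edge-midpoint runs (coded +/-1 on two factors, 0 on
#' the third) plus replicated center points of a 3-factor, 3-level
#' Box-Behnken design, in the conventional pair order (T-Conc, T-t,
#' Conc-t). Coded levels are mapped to the physical low/mid/high levels
#' supplied.
#'
#' @param levels named list of three increasing numeric level triplets;
#'   defaults to the packaged experiment's levels (20/40/60 degC,
#'   60/70/80 % mass, 1/3/5 h).
#' @param center_replicates number of center-point runs appended.
#' @return Data frame of class `"od_design"` with `run` and factor
#'   columns; the coded matrix is attached as attribute `"coded"`.
#' @examples
#' d <- bbd_design()
#' colSums(attr(d, "coded"))  # BBD symmetry: each coded column sums to 0
#' @export
bbd_design <- function(levels = list(T = c(20, 40, 60),
                                     Conc = c(60, 70, 80),
                                     t = c(1, 3, 5)),
                       center_replicates = 3L) {
  if (length(levels) != 3L) stop("exactly 3 factors are required")
  for (nm in names(levels)) {
    if (length(levels[[nm]]) != 3L || is.unsorted(levels[[nm]], strictly = TRUE)) {
      stop("levels for factor '", nm, "' must be 3 strictly increasing values")
    }
  }
  pm <- rbind(c(-1, -1), c(1, -1), c(-1, 1), c(1, 1))
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  coded <- matrix(0, nrow = 0L, ncol = 3L)
  for (pr in pairs) {
    block <- matrix(0, nrow = 4L, ncol = 3L)
    block[, pr] <- pm
    coded <- rbind(coded, block)
  }
  coded <- rbind(coded, matrix(0, nrow = center_replicates, ncol = 3L))
  colnames(coded) <- names(levels)
  physical <- vapply(seq_len(3L), function(j) levels[[j]][coded[, j] + 2L],
                     numeric(nrow(coded)))
  colnames(physical) <- names(levels)
  out <- data.frame(run = seq_len(nrow(coded)), physical, check.names = FALSE)
  attr(out, "coded") <- coded
  attr(out, "units") <- od_units()
  class(out) <- c("od_design", "data.frame")
  out
}

#' Specify a quadratic response surface on coded factors
#'
#' The surface is defined on the coded (-1, 0, +1) scale, so coefficient
#' signs directly encode ground-truth effect directions:
#' `y = beta0 + sum(linear * x) + sum(quadratic * x^2) +
#' interaction[1]*x1*x2 + interaction[2]*x1*x3 + interaction[3]*x2*x3`,
#' plus Gaussian noise with standard deviation `noise_sd`.
#'
#' @param name response name.
#' @param beta0 intercept (response units).
#' @param linear,quadratic numeric length-3 coefficient vectors.
#' @param interaction numeric length-3 vector for the x1x2, x1x3, x2x3
#'   cross terms.
#' @param noise_sd Gaussian noise standard deviation, >= 0.
#' @return List of class `"surface_spec"`.
#' @export
surface_spec <- function(name, beta0 = 0, linear = c(0, 0, 0),
                         quadratic = c(0, 0, 0), interaction = c(0, 0, 0),
                         noise_sd = 0) {
  stopifnot(length(linear) == 3L, length(quadratic) == 3L,
            length(interaction) == 3L, noise_sd >= 0)
  structure(list(name = name, beta0 = beta0, linear = linear,
                 quadratic = quadratic, interaction = interaction,
                 noise_sd = noise_sd),
            class = "surface_spec")
}

#' Evaluate a surface spec on a coded design (noise-free)
#'
#' @param spec a [surface_spec()].
#' @param coded matrix of coded factor settings (n x 3).
#' @return Numeric vector of noise-free surface values.
#' @export
surface_value <- function(spec, coded) {
  drop(spec$beta0 +
         coded %*% spec$linear +
         coded^2 %*% spec$quadratic +
         coded[, 1] * coded[, 2] * spec$interaction[1] +
         coded[, 1] * coded[, 3] * spec$interaction[2] +
         coded[, 2] * coded[, 3] * spec$interaction[3])
}

#' Simulate responses on a Box-Behnken design
#'
#' Adds one response column per surface spec: the quadratic surface on
#' the coded factors plus seeded Gaussian noise. Identical seeds give
#' bitwise-identical tables.
#'
#' @param design a [bbd_design()] skeleton.
#' @param specs list of [surface_spec()]s (or a single spec).
#' @param seed integer seed.
#' @return The design with response columns appended (class `"od_design"`).
#' @examples
#' d <- simulate_responses(bbd_design(), default_surface_specs(), seed = 1)
#' @export
simulate_responses <- function(design, specs, seed = 1L) {
  coded <- attr(design, "coded")
  if (is.null(coded)) stop("design has no coded factor matrix; use bbd_design()")
  if (inherits(specs, "surface_spec")) specs <- list(specs)
  set.seed(as.integer(seed))
  out <- design
  for (spec in specs) {
    out[[spec$name]] <- surface_value(spec, coded) +
      stats::rnorm(nrow(coded), 0, spec$noise_sd)
  }
  attr(out, "coded") <- coded
  attr(out, "units") <- od_units()
  class(out) <- c("od_design", "data.frame")
  out
}

#' Default bundle of synthetic response surfaces
#'
#' Thirteen surfaces that qualitatively mimic the packaged experiment:
#' the process indices, minerals and betaine increase with temperature
#' and time; the IC50 responses (DPPH, ABTS) and acidity decrease with
#' them, so the synthetic optimum lands at the high-temperature,
#' long-time corner. Magnitudes and noise levels are set to the order
#' observed in the packaged table.
#'
#' @param noise_scale multiplier applied to every noise_sd (0 gives
#'   noise-free surfaces).
#' @return Named list of [surface_spec()]s.
#' @export
default_surface_specs <- function(noise_scale = 1) {
  mk <- function(name, beta0, linear, sd)
    surface_spec(name, beta0, linear, noise_sd = sd * noise_scale)
  specs <- list(
    mk("DMC", 31, c(7, 2, 10), 1),
    mk("WL", 0.56, c(0.07, 0.02, 0.10), 0.01),
    mk("SG", 0.020, c(0.008, 0.001, 0.013), 0.001),
    mk("Mg", 330, c(20, 30, 60), 10),
    mk("K", 12500, c(1500, 1200, 3500), 300),
    mk("Na", 4400, c(400, 600, 1300), 100),
    mk("Ca", 800, c(250, 100, 350), 20),
    mk("DPPH", 5.1, c(-1.0, -0.3, -1.0), 0.1),
    mk("ABTS", 1.5, c(-0.4, -0.1, -0.5), 0.05),
    mk("flavonoids", 115, c(-4, -3, -8), 3),
    mk("phenols", 430, c(60, 10, 40), 15),
    mk("acidity", 1.28, c(-0.05, -0.02, -0.10), 0.02),
    mk("betaine", 2200, c(400, 200, 800), 50)
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}
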