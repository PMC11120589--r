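#' Construct a mass balance for one dehydrated sample
#'
#' Collects the masses and mass fractions that enter the dehydration
#' response indices: fresh mass `m_i`, post-treatment mass `m_f`, dry-matter
#' mass `m_d`, and the water (`z`) and dry-matter (`s`) mass fractions of
#' the fresh (`_i`) and treated (`_f`) states. Water and dry matter must
#' partition each state completely: `z + s = 1` within `1e-9`.
#'
#' @param m_i fresh-sample mass (g), > 0.
#' @param m_f sample mass after osmotic treatment (g), > 0.
#' @param m_d dry-matter mass (g), > 0; may be `NA` if only WL/SG are needed.
#' @param z_i,z_f water mass fractions (g/g) of the fresh and treated sample.
#' @param s_i,s_f dry-matter mass fractions; default to `1 - z`.
#' @param validate set `FALSE` to skip invariant checks (used to represent
#'   deliberately inconsistent balances for [mass_balance_check()]).
#' @return List of class `"mass_balance"`.
#' @examples
#' b <- mass_balance(m_i = 100, m_f = 50, m_d = 15, z_i = 0.88, z_f = 0.50)
#' compute_wl(b)
#' @export
mass_balance <- function(m_i, m_f, m_d = NA_real_, z_i, z_f,
                         s_i = 1 - z_i, s_f = 1 - z_f, validate = TRUE) {
  b <- structure(list(m_i = m_i, m_f = m_f, m_d = m_d,
                      z_i = z_i, z_f = z_f, s_i = s_i, s_f = s_f),
                 class = "mass_balance")
  if (validate) {
    if (m_i <= 0 || m_f <= 0) stop("masses m_i and m_f must be positive")
    if (!is.na(m_d) && m_d <= 0) stop("dry-matter mass m_d must be positive")
    fr <- c(z_i = z_i, z_f = z_f, s_i = s_i, s_f = s_f)
    if (any(fr < 0 | fr > 1)) {
      stop("mass fractions must lie in [0, 1]: ",
           paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
    }
    if (abs(z_i + s_i - 1) > 1e-9 || abs(z_f + s_f - 1) > 1e-9) {
      stop("water and dry-matter fractions must sum to 1 in each state")
    }
  }
  b
}

#' Dry matter content
#'
#' DMC is the dry-matter mass as a percentage of sample mass. The
#' `"measured"` basis divides by the post-treatment mass `m_f` (the
#' gravimetric oven-drying convention, and the basis consistent with the
#' packaged run table); the `"fresh"` basis divides by the fresh mass
#' `m_i`. Both are exposed because the two conventions circulate in the
#' osmotic-dehydration literature.
#'
#' @param b a [mass_balance()].
#' @param basis `"measured"` (default) or `"fresh"`.
#' @return DMC in percent.
#' @export
compute_dmc <- function(b, basis = c("measured", "fresh")) {
  stopifnot(inherits(b, "mass_balance"))
  basis <- match.arg(basis)
  if (is.na(b$m_d)) stop("mass balance has no dry-matter mass m_d")
  denom <- if (basis == "measured") b$m_f else b$m_i
  if (denom <= 0) stop("zero or negative denominator mass")
  100 * b$m_d / denom
}

#' Water loss
#'
#' Water removed during osmotic treatment per gram of fresh sample:
#' `WL = (m_i * z_i - m_f * z_f) / m_i`.
#'
#' @param b a [mass_balance()].
#' @return WL in g per g fresh sample.
#' @export
compute_wl <- function(b) {
  stopifnot(inherits(b, "mass_balance"))
  (b$m_i * b$z_i - b$m_f * b$z_f) / b$m_i
}

#' Solid gain
#'
#' Solutes absorbed during osmotic treatment per gram of fresh sample:
#' `SG = (m_f * s_f - m_i * s_i) / m_i`.
#'
#' @param b a [mass_balance()].
#' @return SG in g per g fresh sample.
#' @export
compute_sg <- function(b) {
  stopifnot(inherits(b, "mass_balance"))
  (b$m_f * b$s_f - b$m_i * b$s_i) / b$m_i
}

#' Check the water/solid mass-balance identity
#'
#' When water and dry matter partition both states (`z + s = 1`), water
#' loss and solid gain are algebraically tied to the overall mass change:
#' `WL - SG = (m_i - m_f) / m_i`. A violation indicates inconsistent
#' fractions or masses.
#'
#' @param b a [mass_balance()] (possibly built with `validate = FALSE`).
#' @param tol numeric tolerance on the residual.
#' @return `TRUE`/`FALSE`, with the signed residual attached as the
#'   `"residual"` attribute.
#' @export
mass_balance_check <- function(b, tol = 1e-9) {
  stopifnot(inherits(b, "mass_balance"))
  residual <- (compute_wl(b) - compute_sg(b)) - (b$m_i - b$m_f) / b$m_i
  structure(abs(residual) <= tol, residual = residual)
}

#' Append dehydration indices to a table of mass balances
#'
#' Batch interface: takes a data frame with columns `m_i`, `m_f`, `z_i`,
#' `z_f` (and optionally `m_d`, `s_i`, `s_f`) and appends `DMC`, `WL`
#' and `SG` columns. `DMC` is `NA` where `m_d` is missing.
#'
#' @param balances data frame of mass-balance rows.
#' @param basis DMC basis, see [compute_dmc()].
#' @return The input with `DMC`, `WL`, `SG` columns appended.
#' @export
od_indices <- function(balances, basis = c("measured", "fresh")) {
  basis <- match.arg(basis)
  need <- c("m_i", "m_f", "z_i", "z_f")
  missing <- setdiff(need, names(balances))
  if (length(missing) > 0L) {
    stop("mass-balance table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(balances$m_d)) balances$m_d <- NA_real_
  if (is.null(balances$s_i)) balances$s_i <- 1 - balances$z_i
  if (is.null(balances$s_f)) balances$s_f <- 1 - balances$z_f
  rows <- lapply(seq_len(nrow(balances)), function(i) {
    b <- mass_balance(balances$m_i[i], balances$m_f[i], balances$m_d[i],
                      balances$z_i[i], balances$z_f[i],
                      balances$s_i[i], balances$s_f[i])
    c(DMC = if (is.na(b$m_d)) NA_real_ else compute_dmc(b, basis),
      WL = compute_wl(b), SG = compute_sg(b))
  })
  cbind(balances, do.call(rbind, rows))
}
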