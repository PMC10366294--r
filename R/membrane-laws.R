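#' Membrane constitutive-law parameters
#'
#' Constructs the parameter set of one of the three classical membrane
#' constitutive laws used for thin hyper-elastic capsule membranes: the
#' strain-softening neo-Hookean (NH) law, the strain-hardening Skalak (SK)
#' law, and the linear-elastic generalised 2D Hooke law. The membrane shear
#' modulus `Gs` is always stored; the area-dilatation modulus `Ks` is never
#' stored but derived from the law-specific parameter via
#' [area_dilatation_modulus()], so the pair can never fall out of step.
#'
#' @param kind Law class: one of `"NH"`, `"SK"`, `"HK"` (case-insensitive;
#'   the long forms `"neo-hookean"`, `"skalak"`, `"hooke"` are accepted).
#' @param Gs Membrane shear modulus, N/m. Must be positive.
#' @param C Skalak area-dilatation parameter (dimensionless). Required for
#'   and only meaningful with `kind = "SK"`; must be positive.
#' @param nu_s Surface Poisson ratio (dimensionless). Required for and only
#'   meaningful with `kind = "HK"`; must lie strictly in (0, 1).
#'
#' @return An object of class `"law_params"`: a list with elements `kind`
#'   (one of `"NH"`, `"SK"`, `"HK"`), `Gs`, and `C` or `nu_s` as applicable.
#'
#' @examples
#' law_params("SK", Gs = 0.05, C = 0.73)
#' area_dilatation_modulus(law_params("NH", Gs = 1))
#' @export
law_params <- function(kind, Gs, C = NULL, nu_s = NULL) {
  kind <- normalize_law_kind(kind)
  if (!is.numeric(Gs) || length(Gs) != 1L || !is.finite(Gs) || Gs <= 0)
    stop("'Gs' must be a single positive number (N/m)")
  obj <- list(kind = kind, Gs = Gs)
  if (kind == "SK") {
    if (is.null(C))
      stop("Skalak law requires the area-dilatation parameter 'C'")
    if (!is.finite(C) || C <= 0)
      stop("'C' must be positive")
    obj$C <- C
  } else if (!is.null(C)) {
    stop("'C' is only meaningful for the Skalak law")
  }
  if (kind == "HK") {
    if (is.null(nu_s))
      stop("2D Hooke's law requires the surface Poisson ratio 'nu_s'")
    if (!is.finite(nu_s) || nu_s <= 0 || nu_s >= 1)
      stop("'nu_s' must lie strictly in (0, 1)")
    obj$nu_s <- nu_s
  } else if (!is.null(nu_s)) {
    stop("'nu_s' is only meaningful for 2D Hooke's law")
  }
  structure(obj, class = "law_params")
}

law_kinds <- c("NH", "SK", "HK")

normalize_law_kind <- function(kind) {
  if (!is.character(kind) || length(kind) != 1L)
    stop("'kind' must be a single string")
  key <- toupper(gsub("[^A-Za-z]", "", kind))
  kind <- switch(key,
    NH = , NEOHOOKEAN = "NH",
    SK = , SKALAK = "SK",
    HK = , HOOKE = , HOOKES = "HK",
    stop("unknown law kind '", kind, "' (expected NH, SK or HK)")
  )
  kind
}

#' @export
print.law_params <- function(x, ...) {
  full <- c(NH = "neo-Hookean", SK = "Skalak", HK = "2D Hooke")[x$kind]
  cat(sprintf("%s membrane law: Gs = %g N/m", full, x$Gs))
  if (x$kind == "SK") cat(sprintf(", C = %g", x$C))
  if (x$kind == "HK") cat(sprintf(", nu_s = %g", x$nu_s))
  cat(sprintf(" (Ks/Gs = %g)\n", area_dilatation_modulus(x) / x$Gs))
  invisible(x)
}

#' Membrane strain-energy density
#'
#' Evaluates the strain-energy density per unit undeformed membrane area of
#' a `law_params` object at a surface strain state given by the shifted
#' strain invariants `I1 = lambda1^2 + lambda2^2 - 2` and
#' `I2 = lambda1^2 * lambda2^2 - 1`, where `lambda1`, `lambda2` are the
#' in-plane principal stretches. Under this convention the undeformed state
#' is `(I1, I2) = (0, 0)` and all three laws return zero energy there.
#'
#' The three forms are
#' \deqn{W_{NH} = \tfrac{G_s}{2}\left(I_1 - 1 + \tfrac{1}{I_2 + 1}\right),}
#' \deqn{W_{SK} = \tfrac{G_s}{4}\left(I_1^2 + 2 I_1 - 2 I_2\right)
#'       + \tfrac{C G_s}{4} I_2^2,}
#' \deqn{W_{HK} = \tfrac{G_s}{4}\left(2 I_1 - 2 I_2
#'       + \tfrac{I_1^2}{1 - \nu_s}\right).}
#' The neo-Hookean denominator is `I2 + 1` (the determinant of the surface
#' deformation, `lambda1^2 lambda2^2`), which is the standard 2D NH form and
#' the only choice with zero rest-state energy under the shifted invariants;
#' `as_printed = TRUE` instead evaluates the variant with denominator
#' `I2 - 1`, which is singular at rest and provided for comparison only.
#'
#' @param law A [law_params()] object.
#' @param I1,I2 First and second (shifted) surface strain invariants.
#'   `I2` must satisfy `I2 >= -1` (non-negative surface determinant).
#' @param as_printed Logical; use the `1/(I2 - 1)` neo-Hookean variant.
#' @return Strain-energy density `W` in units of `Gs` per unit undeformed
#'   area (vectorised over `I1`, `I2`).
#' @examples
#' strain_energy(law_params("SK", Gs = 1, C = 1), I1 = 2, I2 = 3)  # 2.75
#' @export
strain_energy <- function(law, I1, I2, as_printed = FALSE) {
  stopifnot(inherits(law, "law_params"))
  if (any(!is.finite(I1)) || any(!is.finite(I2)))
    stop("strain invariants must be finite")
  if (any(I2 < -1))
    stop("'I2' must be >= -1 (surface determinant cannot be negative)")
  Gs <- law$Gs
  switch(law$kind,
    NH = {
      den <- if (as_printed) I2 - 1 else I2 + 1
      Gs / 2 * (I1 - 1 + 1 / den)
    },
    SK = Gs / 4 * (I1^2 + 2 * I1 - 2 * I2) + law$C * Gs / 4 * I2^2,
    HK = Gs / 4 * (2 * I1 - 2 * I2 + I1^2 / (1 - law$nu_s))
  )
}

#' Membrane area-dilatation modulus
#'
#' Derives the area-dilatation modulus `Ks` from the stored shear modulus
#' and law-specific parameter: `Ks = 3 Gs` (NH), `Ks = (1 + 2C) Gs` (SK),
#' `Ks = (1 + nu_s) / (1 - nu_s) Gs` (Hooke).
#'
#' @param law A [law_params()] object.
#' @return `Ks` in the units of `Gs` (N/m).
#' @export
area_dilatation_modulus <- function(law) {
  stopifnot(inherits(law, "law_params"))
  switch(law$kind,
    NH = 3 * law$Gs,
    SK = (1 + 2 * law$C) * law$Gs,
    HK = (1 + law$nu_s) / (1 - law$nu_s) * law$Gs
  )
}

#' Equivalent Skalak and Hooke parameters at a given Ks/Gs ratio
#'
#' Inverts the two modulus relations at equal `Ks/Gs`: the Skalak `C` and
#' the Hooke surface Poisson ratio `nu_s` that give the same area-dilatation
#' to shear modulus ratio are `C = (ratio - 1) / 2` and
#' `nu_s = (ratio - 1) / (ratio + 1)`. At `ratio = 3` both coincide with the
#' neo-Hookean value (`C = 1`, `nu_s = 0.5`). Round-trips exactly through
#' [area_dilatation_modulus()].
#'
#' @param ks_over_gs Ratio `Ks/Gs`, must be `>= 1` (smaller ratios would
#'   imply negative `C` or `nu_s`).
#' @return A list with elements `C` and `nu_s`.
#' @examples
#' equivalent_parameters(1 + 2 * 0.73)$nu_s  # 0.42 to 2 d.p.
#' @export
equivalent_parameters <- function(ks_over_gs) {
  if (!is.numeric(ks_over_gs) || any(!is.finite(ks_over_gs)))
    stop("'ks_over_gs' must be a finite number")
  if (any(ks_over_gs < 1))
    stop("'ks_over_gs' must be >= 1 (Ks cannot fall below Gs here)")
  list(C = (ks_over_gs - 1) / 2,
       nu_s = (ks_over_gs - 1) / (ks_over_gs + 1))
}

#' Flow condition of a capsule in tube flow
#'
#' Bundles the physical scales of the tube-flow experiment: suspending
#' viscosity `mu` (Pa s), mean flow speed `U` (m/s), tube radius `R` (m),
#' unstressed capsule radius `a0` (m) and pre-inflation ratio `alpha`
#' (the capsule is osmotically swollen to radius `a = (1 + alpha) a0`
#' before deformation). The confinement ratio is `beta = a / R`.
#'
#' @param mu Suspending dynamic viscosity, Pa s.
#' @param U Mean flow / capsule speed, m/s.
#' @param R Tube radius, m.
#' @param a0 Unstressed capsule radius, m.
#' @param alpha Pre-inflation ratio (default 0).
#' @return Object of class `"flow_condition"` with the fields above plus
#'   derived `a` and `beta`.
#' @export
flow_condition <- function(mu, U, R = 1, a0 = 0.77 * R / 1.03, alpha = 0) {
  vals <- c(mu = mu, U = U, R = R, a0 = a0)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("'mu', 'U', 'R' and 'a0' must all be positive")
  if (!is.finite(alpha) || alpha < 0)
    stop("'alpha' must be non-negative")
  a <- (1 + alpha) * a0
  beta <- a / R
  if (beta >= 1)
    stop("inflated capsule radius exceeds the tube radius (beta >= 1)")
  structure(list(mu = mu, U = U, R = R, a0 = a0, alpha = alpha,
                 a = a, beta = beta),
            class = "flow_condition")
}

#' @export
print.flow_condition <- function(x, ...) {
  cat(sprintf(
    "tube flow: mu = %g Pa s, U = %g m/s, R = %g m, beta = %.4g, alpha = %g\n",
    x$mu, x$U, x$R, x$beta, x$alpha))
  invisible(x)
}

#' Capillary numbers and moduli
#'
#' `capillary_numbers()` maps a membrane law and a flow condition to the
#' two dimensionless capillary numbers `Ca^Gs = mu U / Gs` and
#' `Ca^Ks = mu U / Ks`, the ratios of the viscous fluid stress to the
#' membrane shear and area-dilatation elastic stresses. `moduli_from_capillary()`
#' is its exact inverse: given measured capillary numbers it returns
#' `Gs = mu U / Ca^Gs` and `Ks = mu U / Ca^Ks`.
#'
#' @param flow A [flow_condition()] object.
#' @param law A [law_params()] object.
#' @return For `capillary_numbers()`, a list with `ca_gs` and `ca_ks`;
#'   for `moduli_from_capillary()`, a list with `Gs` and `Ks` (N/m).
#' @examples
#' fl <- flow_condition(mu = 1, U = 1e-3)
#' capillary_numbers(fl, law_params("NH", Gs = 0.01))$ca_gs  # 0.1
#' moduli_from_capillary(fl, ca_gs = 0.1, ca_ks = 0.05)
#' @export
capillary_numbers <- function(flow, law) {
  stopifnot(inherits(flow, "flow_condition"), inherits(law, "law_params"))
  list(ca_gs = flow$mu * flow$U / law$Gs,
       ca_ks = flow$mu * flow$U / area_dilatation_modulus(law))
}

#' @rdname capillary_numbers
#' @param ca_gs,ca_ks Capillary numbers with respect to the shear and
#'   area-dilatation moduli; must be positive.
#' @export
moduli_from_capillary <- function(flow, ca_gs, ca_ks) {
  stopifnot(inherits(flow, "flow_condition"))
  if (any(!is.finite(c(ca_gs, ca_ks))) || any(c(ca_gs, ca_ks) <= 0))
    stop("capillary numbers must be positive")
  list(Gs = flow$mu * flow$U / ca_gs,
       Ks = flow$mu * flow$U / ca_ks)
}

#' Read and write membrane-law parameters as structured config
#'
#' Law parameters serialise to a flat YAML (or JSON) mapping with keys
#' `kind`, `Gs` and, when applicable, `C` or `nu_s`.
#'
#' @param law A [law_params()] object.
#' @param path File path; extension `.json` selects JSON, anything else YAML.
#' @return `write_law_params()` returns `path` invisibly;
#'   `read_law_params()` returns a [law_params()] object.
#' @export
write_law_params <- function(law, path) {
  stopifnot(inherits(law, "law_params"))
  lst <- unclass(law)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname write_law_params
#' @export
read_law_params <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  law_params(kind = lst$kind, Gs = lst$Gs, C = lst$C, nu_s = lst$nu_s)
}
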