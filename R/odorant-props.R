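# Odorant physical chemistry: diffusivity estimation, air-mucus partitioning
# and the dimensionless wall-uptake parameter K.

#' Liquid-phase diffusivity by the Wilke-Chang correlation
#'
#' Estimates the diffusion coefficient of a dilute solute in a liquid solvent,
#' `D = 7.4e-8 * sqrt(phi * M_B) * T / (mu_B * V_A^0.6)` in cm^2/s, returned in
#' m^2/s. Used here for odorant diffusion through the mucus layer
#' (solvent = water, association factor 2.6).
#'
#' @param solvent_molar_mass Solvent molar mass `M_B`, g/mol.
#' @param association_factor Solvent association factor `phi` (2.6 for water).
#' @param temperature Absolute temperature, K.
#' @param solvent_viscosity Solvent dynamic viscosity, cP.
#' @param solute_molar_volume Solute molar volume at the normal boiling point
#'   (Le Bas), cm^3/mol.
#' @return Diffusivity in m^2/s.
#' @export
#' @examples
#' # isoamyl-acetate-sized solute in water at body temperature
#' wilke_chang_diffusivity(18.01, 2.6, 310, 0.69, 140.6)
wilke_chang_diffusivity <- function(solvent_molar_mass, association_factor,
                                    temperature, solvent_viscosity,
                                    solute_molar_volume) {
  check_positive(
    solvent_molar_mass = solvent_molar_mass,
    association_factor = association_factor,
    temperature = temperature,
    solvent_viscosity = solvent_viscosity,
    solute_molar_volume = solute_molar_volume
  )
  d_cm2 <- 7.4e-8 * sqrt(association_factor * solvent_molar_mass) *
    temperature / (solvent_viscosity * solute_molar_volume^0.6)
  d_cm2 * 1e-4
}

#' Gas-phase diffusivity by the Fuller-Schettler-Giddings correlation
#'
#' Optional estimator hook for the air-phase diffusivity when the odorant
#' table does not provide one. `D = 1e-3 T^1.75 sqrt(1/M_A + 1/M_B) /
#' (P (V_A^(1/3) + V_B^(1/3))^2)` in cm^2/s with pressure in atm; returned in
#' m^2/s. Defaults describe air as the second species.
#'
#' @param molar_mass Solute molar mass, g/mol.
#' @param molar_volume Solute diffusion volume, cm^3/mol.
#' @param temperature Absolute temperature, K.
#' @param pressure_atm Total pressure, atm.
#' @param air_molar_mass,air_molar_volume Carrier-gas constants.
#' @return Diffusivity in m^2/s.
#' @export
#' @examples
#' fuller_gas_diffusivity(136.15, 140.6)
fuller_gas_diffusivity <- function(molar_mass, molar_volume,
                                   temperature = 310, pressure_atm = 1,
                                   air_molar_mass = 28.97,
                                   air_molar_volume = 20.1) {
  check_positive(
    molar_mass = molar_mass, molar_volume = molar_volume,
    temperature = temperature, pressure_atm = pressure_atm
  )
  d_cm2 <- 1e-3 * temperature^1.75 *
    sqrt(1 / molar_mass + 1 / air_molar_mass) /
    (pressure_atm * (molar_volume^(1 / 3) + air_molar_volume^(1 / 3))^2)
  d_cm2 * 1e-4
}

#' Construct an odorant record
#'
#' An odorant is described by its molar mass, Le Bas molar volume, air- and
#' mucus-phase diffusivities, and the air-mucus partition coefficient `beta`
#' (air-side concentration over mucus-side concentration at equilibrium, so
#' small `beta` means a highly mucus-soluble odorant).
#'
#' @param name Odorant name.
#' @param molar_mass g/mol.
#' @param molar_volume Le Bas molar volume, cm^3/mol.
#' @param D_a Air-phase diffusivity, m^2/s. Estimated with
#'   [fuller_gas_diffusivity()] when `NA`.
#' @param D_m Mucus-phase diffusivity, m^2/s. Estimated with
#'   [wilke_chang_diffusivity()] (water solvent) when `NA`.
#' @param beta Air-mucus partition coefficient, dimensionless.
#' @param mucosa A [mucosa_spec()] supplying the Wilke-Chang inputs used when
#'   diffusivities must be estimated.
#' @return An object of class `odorant` (named list).
#' @export
#' @examples
#' odorant("isoamyl acetate", 130.19, 148.9, beta = 1e-3)
odorant <- function(name, molar_mass, molar_volume, D_a = NA_real_,
                    D_m = NA_real_, beta, mucosa = mucosa_spec()) {
  check_positive(molar_mass = molar_mass, molar_volume = molar_volume,
                 beta = beta)
  if (is.na(D_m)) {
    D_m <- wilke_chang_diffusivity(
      solvent_molar_mass = 18.015,
      association_factor = mucosa$association_factor,
      temperature = mucosa$temperature,
      solvent_viscosity = mucosa$solvent_viscosity,
      solute_molar_volume = molar_volume
    )
  }
  if (is.na(D_a)) {
    D_a <- fuller_gas_diffusivity(molar_mass, molar_volume,
                                  temperature = mucosa$temperature)
  }
  check_positive(D_a = D_a, D_m = D_m)
  if (D_a <= D_m) {
    abort("`D_a` must exceed `D_m` (gas diffusion is faster than liquid).",
          class = "olfnet_domain_error")
  }
  structure(
    list(name = as.character(name), molar_mass = molar_mass,
         molar_volume = molar_volume, D_a = D_a, D_m = D_m, beta = beta),
    class = "odorant"
  )
}

#' @export
print.odorant <- function(x, ...) {
  cat(sprintf(
    "<odorant> %s  M = %.4g g/mol, V = %.4g cm^3/mol\n  D_a = %.3g m^2/s, D_m = %.3g m^2/s, beta = %.3g\n",
    x$name, x$molar_mass, x$molar_volume, x$D_a, x$D_m, x$beta
  ))
  invisible(x)
}

#' Mucosa description for uptake modelling
#'
#' Houses the mucus-layer thickness `d` of the wall boundary condition and the
#' Wilke-Chang solvent inputs. Defaults: 10 um mucus film, water at body
#' temperature (310 K, 0.6913 cP), association factor 2.6.
#'
#' @param thickness Mucus layer thickness, m.
#' @param D_m_override Optional mucus diffusivity overriding the odorant's, m^2/s.
#' @param solvent_viscosity Solvent viscosity, cP.
#' @param temperature Temperature, K.
#' @param association_factor Wilke-Chang association factor.
#' @return An object of class `mucosa_spec`.
#' @export
#' @examples
#' mucosa_spec()
mucosa_spec <- function(thickness = 1e-5, D_m_override = NULL,
                        solvent_viscosity = 0.6913, temperature = 310,
                        association_factor = 2.6) {
  check_positive(thickness = thickness, solvent_viscosity = solvent_viscosity,
                 temperature = temperature,
                 association_factor = association_factor)
  if (!is.null(D_m_override)) check_positive(D_m_override = D_m_override)
  structure(
    list(thickness = thickness, D_m_override = D_m_override,
         solvent_viscosity = solvent_viscosity, temperature = temperature,
         association_factor = association_factor),
    class = "mucosa_spec"
  )
}

# effective mucus diffusivity for an odorant under a mucosa spec
mucus_diffusivity <- function(odorant, mucosa) {
  mucosa$D_m_override %||% odorant$D_m
}

# wall mass-transfer coefficient k_w = D_m / (beta * d), m/s
wall_permeability <- function(odorant, mucosa) {
  mucus_diffusivity(odorant, mucosa) / (odorant$beta * mucosa$thickness)
}

#' Dimensionless wall-uptake parameter K
#'
#' The air-mucus interface boundary condition is `dC'/dy' + K C' = 0` with
#' `K = d_in * D_m / (D_a * beta * d)`: `d_in` the nostril (hydraulic)
#' diameter used to nondimensionalize the wall-normal coordinate, `D_m`/`D_a`
#' the mucus/air diffusivities, `beta` the air-mucus partition coefficient and
#' `d` the mucus layer thickness. Large K (soluble odorant, thin mucus) means
#' an efficiently absorbing wall.
#'
#' @param d_in Nostril hydraulic diameter, m.
#' @param odorant An [odorant()].
#' @param mucosa A [mucosa_spec()].
#' @return Dimensionless K (> 0).
#' @export
#' @examples
#' od <- odorant("demo", 130, 140, D_a = 1e-5, D_m = 1e-9, beta = 1e-4)
#' wall_uptake_parameter(1e-3, od, mucosa_spec(thickness = 1e-5))
wall_uptake_parameter <- function(d_in, odorant, mucosa) {
  check_positive(d_in = d_in, beta = odorant$beta,
                 thickness = mucosa$thickness)
  D_m <- mucus_diffusivity(odorant, mucosa)
  d_in * D_m / (odorant$D_a * odorant$beta * mucosa$thickness)
}

# Odorant tables -----------------------------------------------------------

odorant_table_columns <- c("name", "molar_mass", "molar_volume",
                           "D_a", "D_m", "beta")

#' Read an odorant property table
#'
#' Reads a comma-separated table with columns `name, molar_mass, molar_volume,
#' D_a, D_m, beta`. Empty `D_a`/`D_m` cells are filled with the
#' Fuller/Wilke-Chang estimators. Rows violating the invariants
#' (positive masses, volumes and `beta`; `D_a > D_m > 0`) are rejected with a
#' per-row report attached as attribute `"problems"` and a warning.
#'
#' @param path Path to the delimited-text file.
#' @param mucosa A [mucosa_spec()] supplying estimator inputs.
#' @return A tibble with one row per valid odorant, class `odorant_table`.
#' @export
load_odorant_table <- function(path, mucosa = mucosa_spec()) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  missing_cols <- setdiff(odorant_table_columns, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Odorant table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "olfnet_format_error")
  }
  if (nrow(raw) == 0) {
    warn("Odorant table has an empty data section; returning zero odorants.")
  }
  # base-R numeric conversion: empty cells are missing values, anything
  # else unparseable is a row error rather than a silent drop
  parse_num <- function(s, field) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_real_)
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) {
      abort(sprintf("unparseable numeric in column '%s': '%s'", field, s),
            class = "olfnet_row_error")
    }
    v
  }
  rows <- vector("list", nrow(raw))
  problems <- list()
  for (i in seq_len(nrow(raw))) {
    r <- raw[i, ]
    od <- tryCatch(
      odorant(r$name, parse_num(r$molar_mass, "molar_mass"),
              parse_num(r$molar_volume, "molar_volume"),
              parse_num(r$D_a, "D_a"), parse_num(r$D_m, "D_m"),
              parse_num(r$beta, "beta"), mucosa = mucosa),
      error = function(e) e
    )
    if (inherits(od, "error")) {
      problems[[length(problems) + 1L]] <-
        tibble(row = i, name = as.character(r$name),
               problem = conditionMessage(od))
    } else {
      rows[[i]] <- tibble(
        name = od$name, molar_mass = od$molar_mass,
        molar_volume = od$molar_volume, D_a = od$D_a, D_m = od$D_m,
        beta = od$beta
      )
    }
  }
  out <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(raw) > 0 && nrow(out) == 0) {
    out <- tibble(name = character(), molar_mass = double(),
                  molar_volume = double(), D_a = double(), D_m = double(),
                  beta = double())
  } else if (nrow(raw) == 0) {
    out <- raw[odorant_table_columns]
  }
  problems <- if (length(problems)) list_rbind(problems) else
    tibble(row = integer(), name = character(), problem = character())
  if (nrow(problems) > 0) {
    warn(sprintf("%d odorant row(s) rejected; see attr(x, 'problems').",
                 nrow(problems)))
  }
  attr(out, "problems") <- problems
  class(out) <- c("odorant_table", class(out))
  out
}

#' Write an odorant property table
#'
#' Inverse of [load_odorant_table()]; numeric fields are written with
#' round-trip precision.
#'
#' @param x A tibble with the odorant-table columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_odorant_table <- function(x, path) {
  stopifnot(all(odorant_table_columns %in% names(x)))
  out <- as_tibble(x)[odorant_table_columns]
  num <- setdiff(odorant_table_columns, "name")
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), "", sprintf("%.17g", v))
  })
  readr::write_csv(out, path)
  invisible(path)
}

#' Turn one row of an odorant table into an `odorant`
#'
#' @param row A one-row data frame with the odorant-table columns.
#' @return An [odorant()].
#' @export
as_odorant <- function(row) {
  row <- as.list(row[1, , drop = FALSE])
  odorant(row$name, row$molar_mass, row$molar_volume, row$D_a, row$D_m,
          row$beta)
}
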