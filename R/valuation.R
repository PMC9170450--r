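# Direct valuation estimators: direct market value, shadow project cost,
# equivalence-factor table, and runoff-regulation shadow engineering.

#' Direct market value of material production
#'
#' Values marketed ecosystem outputs at fair market prices:
#' `V = sum_i S_i * Y_i * P_i` over material lines, where `S_i` is the
#' production area (hm^2), `Y_i` the unit yield and `P_i` the market price
#' per yield unit (yuan).
#'
#' @param lines data.frame with columns `area` (S, hm^2), `yield` (Y,
#'   units/hm^2) and `price` (P, yuan/unit); zero rows allowed.
#' @return Total value in yuan.
#' @export
direct_market_value <- function(lines) {
  if (nrow(lines) == 0) return(0)
  if (!all(c("area", "yield", "price") %in% names(lines)))
    stop_validation("material lines need columns area, yield, price")
  with(lines, {
    if (any(area < 0 | yield < 0 | price < 0))
      stop_validation("material line quantities must be >= 0")
    sum(area * yield * price)
  })
}

#' Shadow project value
#'
#' Values a non-marketed service by the cost of an engineered substitute
#' delivering the same function: `V = U = sum_i X_i` over the component
#' costs of the shadow project.
#'
#' @param costs numeric vector of component costs `X_i` (yuan, >= 0).
#' @return Total value in yuan.
#' @export
shadow_project_value <- function(costs) {
  costs <- as.numeric(costs)
  if (any(costs < 0)) stop_validation("shadow-project costs must be >= 0")
  sum(costs)
}

#' Equivalence-factor table
#'
#' A table of standard unit values `VC` (yuan/(hm^2 * yr)) by ecosystem type
#' and service, adjusted to the study region by a multiplicative biomass
#' factor (the regional basic-farmland biomass ratio).
#'
#' @param vc non-negative numeric matrix, rows = ecosystem types, columns =
#'   services, with dimnames.
#' @param biomass_factor positive regional adjustment scalar.
#' @return An object of class `equivalence_table`.
#' @export
equivalence_table <- function(vc, biomass_factor = 1) {
  vc <- as.matrix(vc)
  if (is.null(rownames(vc)) || is.null(colnames(vc)))
    stop_validation("equivalence table needs ecosystem-type rownames and service colnames")
  if (any(!is.finite(vc) | vc < 0))
    stop_validation("unit values must be >= 0")
  if (!is.finite(biomass_factor) || biomass_factor <= 0)
    stop_validation("biomass_factor must be > 0")
  structure(list(vc = vc, biomass_factor = biomass_factor),
            class = "equivalence_table")
}

#' Equivalence-factor valuation
#'
#' `ESV = sum_i S_i * VC_i` (total over services) and
#' `ESV_j = sum_i S_i * VC_ij` per service `j`, with every `VC` scaled by the
#' table's regional biomass factor.
#'
#' @param areas named numeric vector of areas (hm^2) by ecosystem type.
#' @param t an [equivalence_table()].
#' @param per_service return the per-service breakdown instead of the total.
#' @return Total ESV (yuan/yr) or, with `per_service = TRUE`, a named vector
#'   of per-service ESV.
#' @export
equivalence_value <- function(areas, t, per_service = FALSE) {
  if (!inherits(t, "equivalence_table")) stop_validation("t must be an equivalence_table")
  unknown <- setdiff(names(areas), rownames(t$vc))
  if (length(unknown))
    stop_validation("ecosystem type(s) absent from equivalence table: ",
                    paste(unknown, collapse = ", "))
  if (any(areas < 0)) stop_validation("areas must be >= 0")
  vc <- t$vc[names(areas), , drop = FALSE] * t$biomass_factor
  esv_j <- as.numeric(areas %*% vc)
  names(esv_j) <- colnames(vc)
  if (per_service) esv_j else sum(esv_j)
}

#' Runoff-regulation value by shadow engineering
#'
#' Values the flood regulation and storage function by the cost of building
#' equivalent reservoir capacity: `V = Q_max * C`, with `Q_max` the maximum
#' safe regulation/storage capacity (m^3) and `C` the construction cost per
#' cubic metre of storage (yuan/m^3).
#'
#' @param q_max maximum safe flood regulation and storage capacity, m^3.
#' @param unit_cost reservoir construction cost, yuan per m^3 of capacity.
#' @return Value in yuan.
#' @export
runoff_regulation_value <- function(q_max, unit_cost) {
  if (q_max < 0 || unit_cost < 0)
    stop_validation("q_max and unit_cost must be >= 0")
  q_max * unit_cost
}
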