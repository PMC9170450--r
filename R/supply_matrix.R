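# Land/wetland-type x service supply matrix: 0-10 integer standard
# capacities and the aggregate supply score X_d = sum_j N_ij * A_ij.

#' Construct a supply matrix
#'
#' A supply matrix scores each wetland (land) type's relative capacity to
#' provide each ecosystem service as an integer between 0 and 10. Rows are
#' wetland types, columns are services; every row and column must contain at
#' least one non-zero capacity.
#'
#' @param n integer matrix with entries in `[0, 10]`, dimnames giving the
#'   wetland-type and service codes.
#' @return An object of class `supply_matrix`.
#' @export
supply_matrix <- function(n) {
  n <- as.matrix(n)
  if (is.null(rownames(n)) || is.null(colnames(n)))
    stop_validation("supply matrix needs wetland-type rownames and service colnames")
  if (any(!is.finite(n)) || any(n != round(n)) || any(n < 0) || any(n > 10))
    stop_validation("supply-matrix entries must be integers in [0, 10]")
  storage.mode(n) <- "integer"
  zr <- rownames(n)[rowSums(n) == 0]
  if (length(zr))
    stop_validation("all-zero supply row(s): ", paste(zr, collapse = ", "))
  zc <- colnames(n)[colSums(n) == 0]
  if (length(zc))
    stop_validation("all-zero supply column(s): ", paste(zc, collapse = ", "))
  structure(list(rows = rownames(n), cols = colnames(n), n = n),
            class = "supply_matrix")
}

#' @export
print.supply_matrix <- function(x, ...) {
  cat("Supply matrix (", length(x$rows), " wetland types x ",
      length(x$cols), " services)\n", sep = "")
  print(x$n)
  invisible(x)
}

#' Normalize raw service capacities to 0-10 integer scores
#'
#' Raw (dimensional) capacity estimates are rescaled so the largest capacity
#' along the chosen axis maps to 10, then rounded half-up to the nearest
#' integer: `N = round(10 * raw / max(raw))`. With `axis = "per_service"`
#' (the default) each service column is scaled by its own maximum, so scores
#' express capacity relative to the best-providing wetland type for that
#' service; `axis = "global"` scales the whole table by one maximum.
#'
#' @param raw non-negative numeric matrix of raw capacities with dimnames.
#' @param axis `"per_service"` (column-wise maxima) or `"global"`.
#' @return A [supply_matrix()].
#' @export
normalize_capacities <- function(raw, axis = c("per_service", "global")) {
  axis <- match.arg(axis)
  raw <- as.matrix(raw)
  if (any(!is.finite(raw) | raw < 0))
    stop_validation("raw capacities must be non-negative and finite")
  if (axis == "per_service") {
    mx <- apply(raw, 2, max)
    zero <- colnames(raw)[mx == 0]
    if (length(zero))
      stop_validation("all-zero capacity column(s): ", paste(zero, collapse = ", "))
    scaled <- sweep(raw, 2, mx, "/") * 10
  } else {
    mx <- max(raw)
    if (mx == 0) stop_validation("all capacities are zero")
    scaled <- raw / mx * 10
  }
  supply_matrix(floor(scaled + 0.5))  # round half-up
}

#' Read a supply matrix from CSV
#'
#' First column holds the wetland-type codes; remaining columns are one per
#' service with integer cells.
#'
#' @param path CSV file path.
#' @return A [supply_matrix()].
#' @export
read_supply_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  n <- as.matrix(df[, -1, drop = FALSE])
  rownames(n) <- as.character(df[[1]])
  supply_matrix(n)
}

#' Write a supply matrix to CSV
#' @param sm a [supply_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_supply_matrix <- function(sm, path) {
  df <- data.frame(wetland_type = sm$rows, sm$n, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Aggregate supply score of wetland units
#'
#' For a unit of wetland type `i` and area `A` (hm^2), the supply score over
#' a service set `J` is `X_d = sum_{j in J} N_ij * A`. With
#' `per_service = FALSE` (default) the sum runs over all requested services,
#' giving the total-capacity score the coupling model uses; with
#' `per_service = TRUE` a unit x service matrix of single-service scores is
#' returned.
#'
#' @param inv wetland inventory data.frame (`unit_id`, `wetland_type`,
#'   `area`, ...), see [validate_inventory()].
#' @param sm a [supply_matrix()].
#' @param services service codes to include (default: all columns of `sm`).
#' @param per_service return per-service scores instead of totals.
#' @return Named numeric vector of `X_d` by `unit_id`, or a unit x service
#'   matrix when `per_service = TRUE`.
#' @export
supply_score <- function(inv, sm, services = NULL, per_service = FALSE) {
  if (!inherits(sm, "supply_matrix")) stop_validation("sm must be a supply_matrix")
  if (is.null(services)) services <- sm$cols
  unknown_svc <- setdiff(services, sm$cols)
  if (length(unknown_svc))
    stop_validation("service(s) absent from supply matrix: ",
                    paste(unknown_svc, collapse = ", "))
  unknown <- setdiff(unique(inv$wetland_type), sm$rows)
  if (length(unknown))
    stop_validation("wetland type(s) absent from supply matrix: ",
                    paste(unknown, collapse = ", "))
  nsub <- sm$n[inv$wetland_type, services, drop = FALSE]
  scores <- nsub * inv$area
  rownames(scores) <- inv$unit_id
  if (per_service) return(scores)
  stats::setNames(rowSums(scores), inv$unit_id)
}
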