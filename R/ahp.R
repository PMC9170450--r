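# Analytic hierarchy process: service-function weights from reciprocal
# pairwise-comparison matrices, prioritized by the principal eigenvector.

# Saaty's random consistency index for n = 1..10.
.ahp_random_index <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' Construct a pairwise-comparison matrix
#'
#' Judgment matrices are positive and reciprocal: `a[i, i] == 1` and
#' `a[j, i] == 1 / a[i, j]`. Reciprocality is enforced to a tolerance of
#' 1e-9 on `a[i, j] * a[j, i] - 1`.
#'
#' @param a square numeric matrix of positive judgments.
#' @param items optional character labels for the compared items; defaults
#'   to `rownames(a)`.
#' @return An object of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(a, items = rownames(a)) {
  a <- as.matrix(a)
  n <- nrow(a)
  if (n < 2 || ncol(a) != n)
    stop_validation("pairwise matrix must be square with n >= 2")
  if (is.null(items)) items <- paste0("item", seq_len(n))
  items <- as.character(items)
  if (length(items) != n || anyDuplicated(items))
    stop_validation("items must be ", n, " unique labels")
  if (any(!is.finite(a) | a <= 0))
    stop_validation("all judgments must be positive and finite")
  if (max(abs(diag(a) - 1)) > 1e-9)
    stop_validation("diagonal of a pairwise matrix must be 1")
  if (max(abs(a * t(a) - 1)) > 1e-9)
    stop_validation("matrix is not reciprocal (a[j,i] != 1/a[i,j])")
  dimnames(a) <- list(items, items)
  structure(list(items = items, a = a), class = "pairwise_matrix")
}

#' Read a labelled square pairwise matrix from CSV
#'
#' First column holds the item labels; remaining columns the judgments, in
#' the same item order.
#'
#' @param path CSV file path.
#' @return A [pairwise_matrix()].
#' @export
read_pairwise_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  items <- as.character(df[[1]])
  a <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(a) <- "double"
  pairwise_matrix(a, items = items)
}

#' Priority weights of a pairwise matrix (principal eigenvector)
#'
#' Computes the normalized principal right eigenvector by power iteration
#' (tolerance 1e-12, at most 10000 iterations; a positive matrix has a
#' simple dominant eigenvalue, so the iteration converges). Consistency is
#' summarised by `CI = (lambda_max - n) / (n - 1)` and `CR = CI / RI(n)`
#' with Saaty's random index `RI`.
#'
#' @param m a [pairwise_matrix()] (or a square matrix coerced to one).
#' @return An object of class `weight_vector`: a list with `weights`
#'   (named, summing to 1), `lambda_max`, `ci`, `cr` and `n`.
#' @export
eigen_weights <- function(m) {
  if (!inherits(m, "pairwise_matrix")) m <- pairwise_matrix(m)
  a <- m$a
  n <- nrow(a)
  w <- rep(1 / n, n)
  for (iter in seq_len(10000L)) {
    v <- as.numeric(a %*% w)
    v <- v / sum(v)
    if (max(abs(v - w)) < 1e-12) {
      w <- v
      break
    }
    w <- v
  }
  lambda_max <- sum(as.numeric(a %*% w)) / sum(w)
  ci <- (lambda_max - n) / (n - 1)
  ri <- if (n <= length(.ahp_random_index)) .ahp_random_index[n] else
    .ahp_random_index[length(.ahp_random_index)]
  cr <- if (ri > 0) ci / ri else 0
  structure(list(weights = stats::setNames(w, m$items),
                 lambda_max = lambda_max, ci = ci, cr = cr, n = n),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("AHP weight vector (n =", x$n, ")\n")
  print(round(x$weights, 4))
  cat(sprintf("lambda_max = %.6f, CI = %.6f, CR = %.6f\n",
              x$lambda_max, x$ci, x$cr))
  invisible(x)
}

#' Assemble an AHP hierarchy
#'
#' One pairwise matrix compares beneficiary levels (e.g. local, provincial,
#' national, global); one service matrix per level compares the ecosystem
#' services from that level's viewpoint. All service matrices must compare
#' the same service set.
#'
#' @param level_matrix [pairwise_matrix()] over beneficiary levels.
#' @param service_matrices named list of [pairwise_matrix()], one per level,
#'   names matching `level_matrix$items`.
#' @return An object of class `ahp_hierarchy`.
#' @export
ahp_hierarchy <- function(level_matrix, service_matrices) {
  if (!inherits(level_matrix, "pairwise_matrix"))
    stop_validation("level_matrix must be a pairwise_matrix")
  if (!setequal(names(service_matrices), level_matrix$items))
    stop_validation("service_matrices names must match the beneficiary levels")
  service_matrices <- service_matrices[level_matrix$items]
  svc <- service_matrices[[1]]$items
  for (lv in level_matrix$items) {
    if (!inherits(service_matrices[[lv]], "pairwise_matrix"))
      stop_validation("service matrix for level '", lv, "' is not a pairwise_matrix")
    if (!identical(service_matrices[[lv]]$items, svc))
      stop_validation("service labels differ between levels ('", lv, "')")
  }
  structure(list(level_matrix = level_matrix,
                 service_matrices = service_matrices,
                 services = svc, levels = level_matrix$items),
            class = "ahp_hierarchy")
}

#' Comprehensive service weights from an AHP hierarchy
#'
#' The comprehensive weight of service `s` is the level-weighted sum of its
#' per-level weights, `sum_l w_l * w_{l,s}`, renormalized to sum 1. Every
#' matrix must pass the consistency check `CR <= cr_threshold` unless
#' `enforce_cr = FALSE`.
#'
#' @param h an [ahp_hierarchy()].
#' @param cr_threshold maximum admissible consistency ratio (default 0.1).
#' @param enforce_cr reject inconsistent matrices (default `TRUE`).
#' @return A `weight_vector` over services; `cr` is the worst CR seen, and
#'   the per-matrix CRs are attached as `cr_by_matrix`.
#' @export
composite_weights <- function(h, cr_threshold = 0.1, enforce_cr = TRUE) {
  if (!inherits(h, "ahp_hierarchy")) stop_validation("h must be an ahp_hierarchy")
  lw <- eigen_weights(h$level_matrix)
  crs <- c(levels = lw$cr)
  if (enforce_cr && lw$cr > cr_threshold)
    stop_validation(sprintf("level matrix fails consistency: CR = %.4f > %.2f",
                            lw$cr, cr_threshold))
  comp <- stats::setNames(numeric(length(h$services)), h$services)
  for (lv in h$levels) {
    sw <- eigen_weights(h$service_matrices[[lv]])
    crs[lv] <- sw$cr
    if (enforce_cr && sw$cr > cr_threshold)
      stop_validation(sprintf(
        "service matrix for level '%s' fails consistency: CR = %.4f > %.2f",
        lv, sw$cr, cr_threshold))
    comp <- comp + lw$weights[[lv]] * sw$weights
  }
  comp <- comp / sum(comp)
  out <- structure(list(weights = comp, lambda_max = NA_real_, ci = NA_real_,
                        cr = max(crs), n = length(comp)),
                   class = "weight_vector")
  attr(out, "cr_by_matrix") <- crs
  out
}

#' Published comprehensive service-function weights (packaged fixture)
#'
#' The ten comprehensive weights of coastal-wetland service functions from
#' the questionnaire study this package's case analysis follows. The raw
#' printed values sum to 0.9991 (rounding); set `renormalize = TRUE` to
#' rescale them to sum exactly 1 for use in aggregation.
#'
#' @param renormalize rescale the weights to sum to 1 (default `FALSE`,
#'   returning the printed values verbatim).
#' @return A `weight_vector` over the ten service functions.
#' @export
reference_service_weights <- function(renormalize = FALSE) {
  w <- c(
    "food_production"        = 0.1344,
    "raw_material_production" = 0.1037,
    "bioproductivity"        = 0.0680,
    "water_conservation"     = 0.1255,
    "water_quality_purification" = 0.1185,
    "wave_revetment"         = 0.1296,
    "silt_promotion_epeirogenic" = 0.0593,
    "carbon_sequestration"   = 0.0481,
    "atmosphere_adjustment"  = 0.0910,
    "leisure_travel"         = 0.1210
  )
  if (renormalize) w <- w / sum(w)
  structure(list(weights = w, lambda_max = NA_real_, ci = NA_real_,
                 cr = NA_real_, n = length(w)),
            class = "weight_vector")
}

#' Element-wise geometric mean of several pairwise matrices
#'
#' Utility for aggregating multiple respondents' judgment matrices into one
#' group matrix (the geometric mean preserves reciprocality).
#'
#' @param ms list of [pairwise_matrix()] over identical items.
#' @return A [pairwise_matrix()].
#' @export
aggregate_judgments <- function(ms) {
  if (!length(ms)) stop_validation("need at least one matrix")
  items <- ms[[1]]$items
  for (m in ms)
    if (!identical(m$items, items))
      stop_validation("all matrices must compare the same items in the same order")
  loga <- Reduce(`+`, lapply(ms, function(m) log(m$a))) / length(ms)
  pairwise_matrix(exp(loga), items = items)
}

#' Write a weight vector to CSV
#' @param w a `weight_vector`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path) {
  write_results(data.frame(service = names(w$weights),
                           weight = unname(w$weights),
                           cr = w$cr), path)
}
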