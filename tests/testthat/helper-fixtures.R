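# Fixtures built in code: a small case table, supply matrix and CPI series
# shared by the unit tests.

tiny_supply <- function() {
  supply_matrix(matrix(c(3L, 5L,
                         2L, 8L), nrow = 2, byrow = TRUE,
                       dimnames = list(c("river", "salt_pan"),
                                       c("svcA", "svcB"))))
}

tiny_cpi <- function() {
  cpi_series(c("2011" = 90, "2012" = 95, "2013" = 100), base_year = 2013)
}

tiny_schema <- function() case_schema(natural = "nat_x", environment = "env_z")

tiny_cases <- function(n = 6) {
  data.frame(
    case_id = paste0("c", seq_len(n)),
    wetland_id = paste0("w", seq_len(n)),
    wetland_type = rep(c("river", "salt_pan"), length.out = n),
    service = rep(c("svcA", "svcB"), length.out = n),
    method = rep(c("m1", "m2", "m1"), length.out = n),
    base_year = rep(c(2013L, 2012L, 2011L), length.out = n),
    value_raw = seq(100, by = 50, length.out = n),
    area = seq(2, by = 1, length.out = n),
    nat_x = seq(-1, 1, length.out = n),
    env_z = seq(0.5, 2, length.out = n),
    stringsAsFactors = FALSE)
}

# independent eigenvector oracle for AHP priorities (dense eigensolve)
eigen_oracle <- function(a) {
  e <- eigen(a)
  k <- which.max(Re(e$values))
  v <- Re(e$vectors[, k])
  v <- v / sum(v)
  list(weights = v, lambda_max = Re(e$values[k]))
}

# brute-force double-loop oracle for the aggregate supply score
supply_score_oracle <- function(inv, sm, services = colnames(sm$n)) {
  out <- numeric(nrow(inv))
  for (u in seq_len(nrow(inv))) {
    for (s in services) {
      out[u] <- out[u] + sm$n[inv$wetland_type[u], s] * inv$area[u]
    }
  }
  stats::setNames(out, inv$unit_id)
}
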