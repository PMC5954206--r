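# Independent oracles, written against the closed form directly and kept
# separate from the package implementation paths.

# strain-energy density with the radial stretch eliminated, plain R
oracle_energy <- function(p, lc, la) {
  lr <- 1 / (lc * la)
  i1 <- lc^2 + la^2 + lr^2
  a <- p$alpha * pi / 180
  i4 <- lc^2 * cos(a)^2 + la^2 * sin(a)^2
  e <- p$kappa * (i1 - 3) + (1 - 3 * p$kappa) * (i4 - 1)
  fib <- if (e > 0) (p$k1 / p$k2) * (exp(p$k2 * e^2) - 1) else 0
  p$c10 * (i1 - 3) + fib
}

# plane-stress Cauchy stresses by central differencing of the energy
oracle_stress <- function(p, lc, la, h = 1e-6) {
  dpsi_dlc <- (oracle_energy(p, lc + h, la) - oracle_energy(p, lc - h, la)) / (2 * h)
  dpsi_dla <- (oracle_energy(p, lc, la + h) - oracle_energy(p, lc, la - h)) / (2 * h)
  c(scc = lc * dpsi_dlc, saa = la * dpsi_dla)
}

oracle_sse <- function(p, data) {
  s <- t(vapply(seq_len(nrow(data)),
                function(i) oracle_stress(p, data$lambda_c[i], data$lambda_a[i]),
                numeric(2)))
  sum((s[, 1] - data$sigma_cc_pa)^2 + (s[, 2] - data$sigma_aa_pa)^2)
}

table1 <- aorta_materials("flap")
table2 <- aorta_materials("wall")
all_rows <- c(table1, table2)

mats_for <- function(region, pig = 1) {
  list(flap = table1[[paste0(region, "_flap_", pig)]],
       fl_wall = table2[[if (region == "mid") "mid_fl_wall" else "distal_fl_wall"]],
       tl_wall = table2$tl_wall)
}
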