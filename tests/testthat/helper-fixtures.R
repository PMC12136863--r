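# Fixture builders and independent oracles shared across test files.

base_region_masses <- c(hemihead = 2500, arm = 1800, forearm = 900, hand = 400,
                        hemipelvis = 4000, thigh = 7000, leg = 2800, foot = 900)

# Full 16-record scan with a fixed composition; `mult` scales the total mass
# of named region-sides, e.g. c("thigh.left" = 1.2).
make_scan <- function(id = "p1", rc = c(adipose = 0.30, muscle = 0.65, bone = 0.05),
                      mult = NULL, clinical = NULL, diagnosis = "other",
                      drop = NULL) {
  grid <- expand.grid(side = c("left", "right"), region = names(base_region_masses),
                      stringsAsFactors = FALSE)[, c("region", "side")]
  mt <- base_region_masses[grid$region]
  if (!is.null(mult)) {
    key <- paste(grid$region, grid$side, sep = ".")
    hit <- match(names(mult), key)
    stopifnot(!anyNA(hit))
    mt[hit] <- mt[hit] * mult
  }
  m <- data.frame(region = grid$region, side = grid$side,
                  fat_mass_g = rc[["adipose"]] * mt,
                  lean_mass_g = rc[["muscle"]] * mt,
                  bmc_g = rc[["bone"]] * mt,
                  stringsAsFactors = FALSE)
  if (!is.null(drop)) {
    m <- m[!paste(m$region, m$side, sep = ".") %in% drop, , drop = FALSE]
  }
  patient_scan(id, m, diagnosis = diagnosis, clinical_affected = clinical)
}

# Brute-force two-sided Fisher exact p for a 2x2 table by hypergeometric
# enumeration over all tables with the observed margins.
fisher_2x2_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_min <- max(0L, c1 - (n - r1)); a_max <- min(r1, c1)
  support <- a_min:a_max
  probs <- choose(r1, support) * choose(n - r1, c1 - support) / choose(n, c1)
  p_obs <- probs[match(tab[1, 1], support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random 2x2 table with all margins positive and each margin total <= max_margin.
random_2x2 <- function(max_margin = 12) {
  repeat {
    tab <- matrix(sample(0:max_margin, 4, replace = TRUE), 2)
    if (sum(tab) <= 2 * max_margin && all(rowSums(tab) > 0) &&
        all(colSums(tab) > 0)) {
      return(tab)
    }
  }
}

# Closed-form one-sample t test on a difference vector (independent of t.test).
one_sample_t_oracle <- function(d) {
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# A generator configuration with no overgrowth mask and no noise: perfectly
# symmetric patients.
symmetric_null_config <- function(asym_sd = 0, rc_noise_sd = 0) {
  cfg <- default_generator_config()
  cfg$mask_catalog <- list()
  for (nm in names(cfg$subgroups)) {
    cfg$subgroups[[nm]]$unaffected_asym_sd <- asym_sd
    cfg$subgroups[[nm]]$rc_noise_sd <- rc_noise_sd
  }
  cfg
}
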