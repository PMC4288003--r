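# Shared fixtures for the test suite.  Everything is generated in code; no
# data files are read.

phys70 <- default_physiology()

# Fine and coarse output grids used across tests
grid_fine <- seq(0, 48, by = 0.1)
grid_coarse <- seq(0, 48, by = 0.5)

# Standard sampling schedules for synthetic study arms
obs_iv_times <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12, 24)
obs_po_times <- c(0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 12, 16, 24)

# A random valid genotype spec (for property-style loops)
random_genotype_spec <- function() {
  f <- runif(3)
  f <- f / sum(f)
  genotype_spec(
    frequencies = c(star1a = f[1], star1b = f[2], star15 = f[3]),
    activity_ratio_1b = runif(1, 0.1, 3),
    activity_ratio_15 = runif(1, 0.1, 3),
    expression_mult_1b = runif(1, 0.5, 3),
    expression_mult_15 = runif(1, 0.5, 3),
    f_OATP1B1 = runif(1),
    ethnic_scalar = runif(1, 0.2, 2)
  )
}

plasma_auc <- function(sim, t0 = NULL, t1 = NULL)
  pk_metrics(sim, t0, t1, trace = "plasma")$AUC
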