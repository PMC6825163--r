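# Shared fixtures, all built in code.

# Noiseless curve generated by a model over [1, lam_max].
model_curve <- function(cf, lam_max, n = 200L, id = "fix") {
  lam <- seq(1, lam_max, length.out = n)
  tensile_curve(lam, uniaxial_stress(cf, lam), specimen_id = id)
}

# Model response up to lam_c, then a flat plateau, on a uniform grid.
plateau_curve <- function(cf, lam_c, lam_max, n, noise_sd = 0, slope = 0) {
  lam <- seq(1, lam_max, length.out = n)
  sig <- uniaxial_stress(cf, lam)
  cut <- lam > lam_c
  sig[cut] <- uniaxial_stress(cf, lam_c) + slope * (lam[cut] - lam_c)
  if (noise_sd > 0) sig <- pmax(sig + rnorm(n, 0, noise_sd), 0)
  tensile_curve(lam, sig, specimen_id = "plateau")
}

default_meta <- function(id = "spec", status = "ruptured",
                         thickness = 0.2, width = 3.3, l0 = 10) {
  specimen_meta(id = id, status = status, thickness = thickness,
                width = width, gauge_length_l0 = l0)
}

# Brute-force Mann-Whitney over all group assignments (independent oracle).
mw_oracle <- function(a, b, alternative = "two_sided") {
  x <- c(a, b); n1 <- length(a); n <- length(x)
  r <- rank(x)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  us <- apply(utils::combn(n, n1), 2,
              function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  p <- switch(alternative,
    two_sided = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9),
    greater = mean(us >= u_obs - 1e-9),
    less = mean(us <= u_obs + 1e-9))
  list(U = u_obs, p = p)
}

# Published specimen cohorts, used across cohort tests.
ruptured_stress <- function() {
  sp <- aneurysm_specimens()
  sp$ultimate_stress_MPa[sp$status == "ruptured"]
}
unruptured_stress <- function() {
  sp <- aneurysm_specimens()
  sp$ultimate_stress_MPa[sp$status == "unruptured"]
}
ruptured_strain <- function() {
  sp <- aneurysm_specimens()
  sp$ultimate_strain[sp$status == "ruptured"]
}
unruptured_strain <- function() {
  sp <- aneurysm_specimens()
  sp$ultimate_strain[sp$status == "unruptured"]
}
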