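# Build ad-hoc homogeneous or custom slab stacks in the tissue_stack
# layout, for transport tests that need properties off the tracheal grid.
make_slab_stack <- function(mu_a, mu_s, g, d_mm, n = 1.37,
                            wavelengths = c(500, 542, 556, 576, 586)) {
  k <- length(d_mm)
  stopifnot(length(mu_a) == k, length(mu_s) == k, length(g) == k)
  layers <- lapply(seq_len(k), function(i) {
    list(name = paste0("layer", i),
         thickness_mm = d_mm[i], thickness_cm = d_mm[i] / 10,
         mu_a = rep(mu_a[i], length(wavelengths)),
         mu_s = rep(mu_s[i], length(wavelengths)),
         g = rep(g[i], length(wavelengths)))
  })
  names(layers) <- vapply(layers, `[[`, character(1), "name")
  structure(list(layers = layers, wavelengths_nm = wavelengths, n = n,
                 probe_side = "mucosal", variant = "custom"),
            class = "tissue_stack")
}

# Total-escape standard error of a tally assuming binomial-like counting
# (an upper bound for the weighted kernel, exact for the analog walker).
binom_se <- function(p, n) sqrt(pmax(0, p * (1 - p)) / n)
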