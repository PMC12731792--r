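# Independent reference walker: analog (non-weighted) Monte Carlo for a
# single homogeneous slab, vectorized over photons in plain R. Shares no
# code with the package's transport kernel — absorption is sampled as a
# discrete event per interaction instead of weight attenuation, and the
# direction update is written from the rotation formulas directly. Used
# as an oracle for total diffuse reflectance/transmittance/absorption.
reference_walker <- function(n_photons, mu_a, mu_s, g, d_cm,
                             n_tissue = 1.37, n_ambient = 1.0,
                             na = 0.37, seed = 1) {
  set.seed(seed)
  mut <- mu_a + mu_s
  p_abs <- mu_a / mut

  # launch: cos(theta) uniform within the in-tissue NA cone
  cmax <- sqrt(1 - (na / n_tissue)^2)
  uz <- cmax + (1 - cmax) * runif(n_photons)
  st <- sqrt(pmax(0, 1 - uz^2))
  psi <- 2 * pi * runif(n_photons)
  ux <- st * cos(psi)
  uy <- st * sin(psi)
  z <- rep(0, n_photons)

  alive <- rep(TRUE, n_photons)
  n_rd <- 0L; n_td <- 0L; n_abs <- 0L

  fresnel_r <- function(ci) {
    si <- sqrt(pmax(0, 1 - ci^2))
    stt <- n_tissue / n_ambient * si
    r <- rep(1, length(ci))
    ok <- stt < 1
    ct <- sqrt(pmax(0, 1 - stt[ok]^2))
    rs <- (n_tissue * ci[ok] - n_ambient * ct) /
      (n_tissue * ci[ok] + n_ambient * ct)
    rp <- (n_tissue * ct - n_ambient * ci[ok]) /
      (n_tissue * ct + n_ambient * ci[ok])
    r[ok] <- (rs^2 + rp^2) / 2
    r
  }

  while (any(alive)) {
    idx <- which(alive)
    s <- -log(runif(length(idx))) / mut
    znew <- z[idx] + s * uz[idx]

    # photons crossing a face this step: Fresnel test, escape or reflect
    hit_top <- znew < 0
    hit_bot <- znew > d_cm
    crossing <- hit_top | hit_bot
    if (any(crossing)) {
      ci <- abs(uz[idx][crossing])
      refl <- runif(sum(crossing)) < fresnel_r(ci)
      cid <- idx[crossing]
      # internally reflected: place at the face, flip uz, walk on
      z[cid[refl]] <- ifelse(hit_top[crossing][refl], 0, d_cm)
      uz[cid[refl]] <- -uz[cid[refl]]
      # escaped: tally by face
      esc <- cid[!refl]
      esc_top <- hit_top[crossing][!refl]
      n_rd <- n_rd + sum(esc_top)
      n_td <- n_td + sum(!esc_top)
      alive[esc] <- FALSE
    }

    # interior interactions: absorb or scatter
    inside <- idx[!crossing]
    if (length(inside)) {
      z[inside] <- znew[!crossing]
      absd <- runif(length(inside)) < p_abs
      n_abs <- n_abs + sum(absd)
      alive[inside[absd]] <- FALSE
      sc <- inside[!absd]
      if (length(sc)) {
        u <- runif(length(sc))
        ct <- if (abs(g) < 1e-8) 2 * u - 1 else {
          f <- (1 - g^2) / (1 - g + 2 * g * u)
          pmin(1, pmax(-1, (1 + g^2 - f^2) / (2 * g)))
        }
        stn <- sqrt(pmax(0, 1 - ct^2))
        phi <- 2 * pi * runif(length(sc))
        ox <- ux[sc]; oy <- uy[sc]; oz <- uz[sc]
        near_pole <- abs(oz) > 0.99999
        den <- sqrt(pmax(1e-300, 1 - oz^2))
        nx <- ifelse(near_pole, stn * cos(phi),
                     stn * (ox * oz * cos(phi) - oy * sin(phi)) / den +
                       ox * ct)
        ny <- ifelse(near_pole, stn * sin(phi),
                     stn * (oy * oz * cos(phi) + ox * sin(phi)) / den +
                       oy * ct)
        nz <- ifelse(near_pole, ct * sign(oz), -stn * cos(phi) * den +
                       oz * ct)
        nrm <- sqrt(nx^2 + ny^2 + nz^2)
        ux[sc] <- nx / nrm; uy[sc] <- ny / nrm; uz[sc] <- nz / nrm
      }
    }
  }

  list(
    rd_total = n_rd / n_photons,
    td_total = n_td / n_photons,
    absorbed = n_abs / n_photons,
    rd_se = sqrt(n_rd / n_photons * (1 - n_rd / n_photons) / n_photons),
    td_se = sqrt(n_td / n_photons * (1 - n_td / n_photons) / n_photons)
  )
}
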