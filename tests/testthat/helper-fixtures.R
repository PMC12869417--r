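# Shared simulated fixtures, built once per test session.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

fx_slice64 <- function() fixture("slice64", function() {
  img <- make_phantom(64, 64, 2, seed = 11)
  coils <- make_coil_maps(64, 64, 4, seed = 12)
  ks <- simulate_kspace(img, coils, noise_sigma = 0.01, seed = 13)
  mask <- make_cartesian_mask(64, 4, 0.08)
  x <- zero_filled_rss(ks, mask)
  list(img = img, coils = coils, ks = ks, mask = mask,
       pair = recon_pair(x, img$pixels))
})

# pairs with a known heteroscedastic noise field: y = x + eps,
# eps ~ N(0, sigma_field^2), sigma_field a known function of position
fx_hetero_pairs <- function(n = 6, seed = 21) {
  withr::with_seed(seed, {
    base <- make_phantom(48, 48, 0, seed = 5)$pixels + 0.2
    sig <- 0.02 + 0.25 * base / max(base)  # noise scale tracks intensity
    lapply(seq_len(n), function(i) {
      y <- base + matrix(rnorm(length(base), 0, 1), nrow(base)) * sig
      y[y < 0] <- 0
      recon_pair(base, y)
    })
  })
}

fx_cm2 <- function() fixture("cm2", function() make_coil_maps(16, 16, 2, seed = 4))

fx_sigma_field <- function() {
  base <- make_phantom(48, 48, 0, seed = 5)$pixels + 0.2
  0.02 + 0.25 * base / max(base)
}
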