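# Shared fixtures. Everything is generated in code; heavyweight objects are
# built lazily and cached for the duration of the test run.

# small 2D grid + smooth test image
tiny_grid2 <- function(n = 24, spacing = 0.5) image_grid(c(n, n), spacing)

smooth_image2 <- function(grid = tiny_grid2(), seed = 1) {
  set.seed(seed)
  raw <- array(rnorm(prod(grid$shape)), grid$shape)
  vals <- cpp_gauss_smooth(raw, rep(2, 2))
  scalar_image(grid, as.array(vals) * 100)
}

# smooth random diffeomorphic field (exported elastic generator)
smooth_field3 <- function(grid, sd_mm, seed = 1, smooth_vox = 3,
                          clip_vox = 2) {
  set.seed(seed)
  labelmorph:::elastic_field(grid, sd_mm, smooth_vox = smooth_vox,
                             clip_vox = clip_vox)
}

# small, quick 3D phantom for unit tests
small_phantom <- function(shape = 32, spacing = 0.12, noise_sd = 2,
                          seed = 5) {
  make_template_phantom(phantom_spec(shape = shape, spacing = spacing,
                                     noise_sd = noise_sd, seed = seed))
}

# centroid table from a plain matrix of points
centroid_table_from_points <- function(P, weight = 1) {
  d <- ncol(P)
  tab <- data.frame(label = seq_len(nrow(P)), P, count = 1L,
                    weight = weight)
  names(tab)[2:(1 + d)] <- paste0("c", seq_len(d))
  class(tab) <- c("centroid_table", "data.frame")
  tab
}

# ---- heavyweight shared state for the acceptance suite -------------------
.acceptance_cache <- new.env(parent = emptyenv())

# 9 vs 9 cohort at 48^3 with both registration arms; built once, reused by
# the comparative acceptance criteria (registration, TBM, PCA).
acceptance_cohort <- function() {
  if (!is.null(.acceptance_cache$cohort)) return(.acceptance_cache$cohort)
  spec <- phantom_spec(shape = 48, spacing = 0.08, noise_sd = 4, seed = 11)
  tpl <- make_template_phantom(spec)
  coh <- make_cohort(tpl, n_a = 9, n_b = 9, seed = 1)
  g <- spec$grid
  opts_lab <- pipeline_options("label_informed")
  opts_int <- pipeline_options("intensity_only")
  runs <- lapply(coh$subjects, function(s) {
    list(label = label_image_registration(tpl$intensity, tpl$labels,
                                          s$intensity, s$labels,
                                          mask = tpl$mask,
                                          options = opts_lab),
         intensity = intensity_only_registration(tpl$intensity,
                                                 s$intensity,
                                                 mask = tpl$mask,
                                                 options = opts_int,
                                                 moving_labels = s$labels))
  })
  .acceptance_cache$cohort <- list(template = tpl, cohort = coh,
                                   runs = runs, grid = g)
  .acceptance_cache$cohort
}
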