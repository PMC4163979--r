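# shared fixtures, built lazily and cached for the whole run
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fix_frustum <- function() fixture("frustum", build_frustum)

fix_mt <- function() fixture("mt", function() build_mt_population(seed = 2))

# full-size layer: 33 x 11 grid, 20 pairs, calibrated gain (a few seconds)
fix_layer <- function() {
  fixture("layer", function() {
    build_mst_layer(fix_mt(), heading_grid(), seed = 2, frustum = fix_frustum())
  })
}

# place dots exactly at a subset of the layer's RF locations so the
# measured flow is sampled without positional mismatch
flow_at_rfs <- function(layer, translation, n = 60, seed = 1,
                        depth_range = c(0.5, 15)) {
  sets <- layer$sets
  set.seed(seed)
  idx <- sample(nrow(sets), n)
  z <- runif(n, depth_range[1], depth_range[2])
  cloud <- tibble::tibble(
    dot_id = seq_len(n),
    x = tan(deg2rad(sets$az_deg[idx])) * z,
    y = tan(deg2rad(sets$el_deg[idx])) * z,
    z = z
  )
  flow_field(cloud, translation)
}

# independent Benjamini-Hochberg step-up oracle, executed literally
bh_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= (seq_len(m) / m) * alpha)
  reject <- rep(FALSE, m)
  if (length(k) > 0) reject[ord[seq_len(max(k))]] <- TRUE
  reject
}
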