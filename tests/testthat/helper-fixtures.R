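# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- suppressMessages(force(expr))
  }
  .fixture_cache[[key]]
}

# mid-size diseased phantom shared by segmentation/scoring tests
fixture_phantom <- function() {
  cached("ph64", generate_phantom(
    phantom_spec(shape = c(64, 64, 64), lesion_fraction = 0.08, seed = 11)))
}

# healthy phantom (pure Gaussian parenchyma + vessels)
fixture_phantom_healthy <- function() {
  cached("ph64h", generate_phantom(
    phantom_spec(shape = c(64, 64, 64), lesion_fraction = 0, seed = 5)))
}

# 1-D volume/mask pair around a plain numeric vector: the quickest way to
# exercise histogram/scoring code on hand-chosen values
vol1d <- function(values, spacing = c(1, 1, 1)) {
  suppressMessages(
    ct_volume(array(values, c(length(values), 1, 1)), spacing = spacing))
}

mask1d <- function(n, label = 1L, region_map = c(lung = 1L),
                   spacing = c(1, 1, 1)) {
  lung_mask(array(as.integer(label), c(n, 1, 1)), region_map,
            spacing = spacing)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
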