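# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small single-area dataset used across module tests (desk-scale geometry:
# 6 x 12 mm canvas at 125 um/px, 16 px receptor patches, 256 px cyto).
deskSpec <- function(area = "V1", receptor = "M2", seed = 21, ...) {
  SyntheticSpec(area = area, receptor = receptor, canvas_px = c(48L, 96L),
                receptor_resolution_um = 125, seed = seed, ...)
}

deskDataset <- function() {
  fixture("desk_dataset", function() {
    generateDataset(deskSpec(), n_sections = 2L, seed = 21)
  })
}

# Evenly thinned subset keeping labels and section structure.
thinDataset <- function(ds, n) {
  if (length(ds) <= n) return(ds)
  ds[round(seq(1, length(ds), length.out = n))]
}

# Tiny generator spec for fast unit tests of the training loop.
tinyGenSpec <- function(variant = "single_area") {
  generatorSpec(variant = variant, input_side_px = 64L, output_side_px = 4L,
                backbone_channels = c(2L, 3L, 4L, 6L),
                unet_channels = c(6L, 8L, 10L))
}

# Tiny patch pairs matching tinyGenSpec, with receptor a deterministic
# function of the (downscaled) cyto patch.
tinyPairs <- function(n, seed = 1, sections = 2L) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    lapply(seq_len(n), function(i) {
      cyto <- matrix(runif(64 * 64), 64, 64)
      blocks <- matrix(0, 4, 4)
      for (r in 1:4) for (cc in 1:4)
        blocks[r, cc] <- mean(cyto[(r - 1) * 16 + 1:16, (cc - 1) * 16 + 1:16])
      rec <- 0.2 + 0.6 * blocks
      new("PatchPair", cyto = cyto, receptor = rec, area = "V1",
          receptor_type = "M2",
          window = PatchWindow(c(1, 1), side_mm = 2,
                               section_id = ((i - 1) %% sections) + 1L,
                               area = "V1", receptor = "M2"),
          depth = matrix(numeric(0), 0, 0))
    })
  })
}

tinyDataset <- function(n, seed = 1, sections = 2L) {
  pairs <- tinyPairs(n, seed, sections)
  new("PatchDataset", pairs = pairs,
      section_ids = vapply(pairs, function(p) p@window@section_id,
                           integer(1)),
      provenance = list(seed = seed))
}

# Depth-binned mean intensity profile of predictions over a set of pairs.
predictedDepthProfile <- function(gen, pairs, noise_seed0 = 7000,
                                  condition = NULL) {
  preds <- lapply(seq_along(pairs), function(i)
    generatorForward(gen, pairs[[i]]@cyto, noise_seed = noise_seed0 + i,
                     condition = condition))
  allp <- unlist(preds)
  alld <- unlist(lapply(pairs, function(p) p@depth))
  ok <- !is.na(alld)
  bins <- cut(alld[ok], seq(0, 1, by = 0.1))
  as.numeric(tapply(allp[ok], bins, mean))
}

profileDepthMidpoints <- function() seq(0.05, 0.95, by = 0.1)

# z-score MAE of a trained generator and of the constant per-patch-mean
# predictor on the same pairs.
zmaeVsBaseline <- function(gen, pairs, noise_seed0 = 5000,
                           condition = NULL) {
  out <- vapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    pred <- generatorForward(gen, p@cyto, noise_seed = noise_seed0 + i,
                             condition = condition)
    z <- zscorePair(p@receptor, pred)
    s <- sqrt(mean((p@receptor - mean(p@receptor))^2))
    c(model = mae(z$z_target, z$z_pred),
      baseline = mean(abs(p@receptor - mean(p@receptor))) / s)
  }, numeric(2))
  rowMeans(out)
}
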